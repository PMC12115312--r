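#' Read a protein FASTA file
#'
#' Sequences are uppercased and a single trailing `*` stop symbol is stripped.
#' Residues outside the 20 standard amino acids plus `X` are rejected.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `protein_id`, `sequence`, `length`.
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(paste0("FASTA parse error in ", path, ": ",
                                     conditionMessage(e)))
  )
  if (length(set) == 0L) {
    return(tibble(protein_id = character(), sequence = character(),
                  length = integer()))
  }
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  seqs <- toupper(as.character(set))
  seqs <- sub("\\*$", "", seqs)
  bad <- which(!grepl(paste0("^[", paste(AA_ALPHABET_X, collapse = ""), "]+$"), seqs))
  if (length(bad)) {
    # report the first offending record with an approximate line number
    abort(paste0("illegal residue character in FASTA record '", ids[bad[1]],
                 "' (entry ", bad[1], " of ", path, ")"),
          class = "oryzakin_parse_error")
  }
  tibble(protein_id = ids, sequence = unname(seqs),
         length = nchar(unname(seqs)))
}

#' Write proteins to FASTA
#'
#' Headers are normalised to `>protein_id`; sequences are written unwrapped so
#' that `write_protein_fasta(read_protein_fasta(f))` reproduces sequences
#' byte-identically.
#'
#' @param proteins Tibble with `protein_id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(proteins, path) {
  stopifnot(all(c("protein_id", "sequence") %in% names(proteins)))
  lines <- as.vector(rbind(paste0(">", proteins$protein_id), proteins$sequence))
  writeLines(lines, path)
  invisible(path)
}

#' Read transcript models from GFF3 or GTF
#'
#' The dialect is auto-detected from attribute-column syntax. File coordinates
#' (1-based inclusive) are converted to the internal 0-based half-open
#' convention. Exons and CDS are grouped per transcript and ordered 5'->3'
#' (minus-strand transcripts in descending genomic coordinate).
#'
#' @param path Path to a GFF3/GTF file.
#' @return A tibble with one row per transcript: `transcript_id`, `gene_id`,
#'   `strand`, and list-columns `exons`, `cds`, each a tibble of
#'   `start`,`end` intervals (0-based half-open, 5'->3').
#' @export
read_gff_transcripts <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  fmt <- detect_gff_dialect(path)
  gr <- rtracklayer::import(path, format = fmt)
  df <- as_tibble(as.data.frame(gr))
  if (!"type" %in% names(df)) abort("no feature type column in annotation")
  df <- filter(df, .data$type %in% c("exon", "CDS"))
  if (fmt == "gff3") {
    # exon/CDS Parent is the transcript; walk one level up for the gene
    parents <- as_tibble(as.data.frame(gr))
    tx_gene <- parents %>%
      filter(.data$type %in% c("mRNA", "transcript")) %>%
      mutate(transcript_id = .data$ID,
             gene_id = vapply(.data$Parent, function(p)
               if (length(p)) as.character(p)[1] else NA_character_,
               character(1))) %>%
      select("transcript_id", "gene_id")
    df$transcript_id <- vapply(df$Parent, function(p)
      if (length(p)) as.character(p)[1] else NA_character_, character(1))
    df <- left_join(df, tx_gene, by = "transcript_id")
    if (!"gene_id" %in% names(df)) df$gene_id <- NA_character_
  }
  if (!all(c("transcript_id", "gene_id") %in% names(df))) {
    abort("annotation lacks transcript_id/gene_id attributes")
  }
  out <- df %>%
    mutate(start0 = .data$start - 1L, end0 = .data$end,
           strand = as.character(.data$strand)) %>%
    group_by(.data$transcript_id) %>%
    dplyr::group_map(function(g, key) {
      strand <- g$strand[1]
      exons <- g %>% filter(.data$type == "exon") %>%
        transmute_intervals(strand)
      cds <- g %>% filter(.data$type == "CDS") %>%
        transmute_intervals(strand)
      tibble(transcript_id = key$transcript_id,
             gene_id = g$gene_id[1] %||% NA_character_,
             strand = strand,
             exons = list(exons), cds = list(cds))
    }) %>%
    list_rbind()
  validate_transcripts(out)
  out
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

transmute_intervals <- function(g, strand) {
  tab <- tibble(start = g$start0, end = g$end0)
  tab <- tab[order(tab$start, decreasing = (strand == "-")), , drop = FALSE]
  tab
}

validate_transcripts <- function(tx) {
  for (i in seq_len(nrow(tx))) {
    exons <- tx$exons[[i]]
    cds <- tx$cds[[i]]
    if (nrow(cds) == 0L) next
    contained <- vapply(seq_len(nrow(cds)), function(j) {
      any(cds$start[j] >= exons$start & cds$end[j] <= exons$end)
    }, logical(1))
    if (!all(contained)) {
      abort(paste0("CDS outside exon bounds for transcript ",
                   tx$transcript_id[i]),
            class = "oryzakin_validation_error")
    }
  }
  invisible(tx)
}

detect_gff_dialect <- function(path) {
  lines <- readLines(path, n = 200L, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) return("gff3")
  attrs <- vapply(strsplit(lines, "\t"), function(x)
    if (length(x) >= 9) x[9] else "", character(1))
  if (any(grepl("\\w+ \"", attrs)) && !any(grepl("=", attrs))) "gtf" else "gff3"
}

#' Read a typed TSV table against a schema
#'
#' @param path Tab-separated file with a header row.
#' @param schema Named character vector mapping required column names to types
#'   (`"character"`, `"integer"`, `"double"`, `"logical"`). Extra columns are
#'   carried through untouched; row order is preserved.
#' @return A tibble.
#' @export
read_table_schema <- function(path, schema) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(names(schema), names(tab))
  if (length(missing)) {
    abort(paste0("missing required column(s): ", paste(missing, collapse = ", ")),
          class = "oryzakin_schema_error")
  }
  for (col in names(schema)) {
    tab[[col]] <- switch(schema[[col]],
      character = as.character(tab[[col]]),
      integer   = as.integer(tab[[col]]),
      double    = as.double(tab[[col]]),
      logical   = as.logical(tab[[col]]),
      abort(paste0("unknown schema type: ", schema[[col]]))
    )
  }
  tab
}

#' Read a gene-order table
#'
#' Expects columns `gene_id`, `genome`, `subgenome`, `chromosome`, `start`,
#' `end`, `strand` (1-based inclusive coordinates in the file). Assigns
#' `order_rank` (0-based position along each chromosome's gene order) from
#' start positions, ties broken by `gene_id`.
#'
#' @param path TSV path.
#' @return Tibble of gene records with internal 0-based half-open `start`,
#'   `end` and an `order_rank` column.
#' @export
read_gene_orders <- function(path) {
  tab <- read_table_schema(path, c(
    gene_id = "character", genome = "character", subgenome = "character",
    chromosome = "character", start = "double", end = "double",
    strand = "character"
  ))
  tab <- mutate(tab, start = .data$start - 1)
  if (any(tab$start >= tab$end)) abort("gene with start >= end")
  assign_order_ranks(tab)
}

#' @rdname read_gene_orders
#' @param genes Tibble with at least `genome`, `chromosome`, `start`, `gene_id`.
#' @export
assign_order_ranks <- function(genes) {
  genes %>%
    group_by(.data$genome, .data$chromosome) %>%
    arrange(.data$start, .data$gene_id, .by_group = TRUE) %>%
    mutate(order_rank = dplyr::row_number() - 1L) %>%
    ungroup() %>%
    arrange(.data$genome, .data$chromosome, .data$order_rank)
}

#' Read homology pairs
#'
#' Accepts either the package's 3-column dialect (`gene_a`, `gene_b`, `score`)
#' or a 12-column tabular BLAST (outfmt 6) file without header, in which case
#' the bit score (column 12) becomes `score`. Pairs are canonicalised so
#' `gene_a < gene_b` lexicographically.
#'
#' @param path TSV path.
#' @return Tibble with `gene_a`, `gene_b`, `score`.
#' @export
read_homology_pairs <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  first <- readLines(path, n = 1L)
  if (grepl("\\bgene_a\\b", first)) {
    tab <- read_table_schema(path, c(gene_a = "character", gene_b = "character",
                                     score = "double"))
  } else {
    raw <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                           progress = FALSE)
    if (ncol(raw) < 12) abort("homology file is neither 3-column nor outfmt-6")
    tab <- tibble(gene_a = as.character(raw[[1]]), gene_b = as.character(raw[[2]]),
                  score = as.double(raw[[12]]))
  }
  canonicalise_pairs(tab)
}

canonicalise_pairs <- function(tab) {
  swap <- tab$gene_a > tab$gene_b
  tmp <- tab$gene_a[swap]
  tab$gene_a[swap] <- tab$gene_b[swap]
  tab$gene_b[swap] <- tmp
  tab %>% filter(.data$gene_a != .data$gene_b) %>%
    distinct(.data$gene_a, .data$gene_b, .keep_all = TRUE)
}

#' Read an FPKM expression matrix with sample metadata
#'
#' @param fpkm_path TSV with a `gene_id` column and one column per sample.
#' @param meta_path TSV with columns `sample`, `species`, `tissue`,
#'   `replicate`; every FPKM column must be described.
#' @return A list with `values` (long tibble: `gene_id`, `sample`, `fpkm`) and
#'   `sample_meta`.
#' @export
read_expression <- function(fpkm_path, meta_path) {
  meta <- read_table_schema(meta_path, c(sample = "character",
                                         species = "character",
                                         tissue = "character",
                                         replicate = "character"))
  bad_tissue <- setdiff(unique(meta$tissue), TISSUE_LEVELS)
  if (length(bad_tissue)) {
    abort(paste0("unknown tissue label(s): ", paste(bad_tissue, collapse = ", ")),
          class = "oryzakin_data_error")
  }
  wide <- readr::read_tsv(fpkm_path, show_col_types = FALSE, progress = FALSE)
  if (!"gene_id" %in% names(wide)) {
    abort("missing required column(s): gene_id", class = "oryzakin_schema_error")
  }
  long <- tidyr::pivot_longer(wide, -"gene_id", names_to = "sample",
                              values_to = "fpkm")
  if (any(is.na(long$fpkm)) || any(long$fpkm < 0)) {
    abort("negative or missing FPKM value", class = "oryzakin_validation_error")
  }
  undesc <- setdiff(unique(long$sample), meta$sample)
  if (length(undesc)) {
    abort(paste0("sample(s) without metadata: ", paste(undesc, collapse = ", ")),
          class = "oryzakin_data_error")
  }
  list(values = long, sample_meta = meta)
}

#' Read a 1:1 homoeolog map
#'
#' @param path TSV with columns `group`, `gene_a`, `subgenome_a`, `gene_b`,
#'   `subgenome_b`.
#' @return A tibble.
#' @export
read_homoeolog_map <- function(path) {
  read_table_schema(path, c(group = "character", gene_a = "character",
                            subgenome_a = "character", gene_b = "character",
                            subgenome_b = "character"))
}
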