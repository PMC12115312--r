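#' Write a gene-order table
#'
#' Internal 0-based half-open coordinates are written 1-based inclusive.
#'
#' @param orders Gene-order tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_gene_orders <- function(orders, path) {
  orders %>%
    mutate(start = .data$start + 1) %>%
    select("gene_id", "genome", "subgenome", "chromosome", "start", "end",
           "strand") %>%
    readr::write_tsv(path, progress = FALSE)
  invisible(path)
}

#' Write transcript models as GTF
#'
#' @param transcripts Tibble with `transcript_id`, `gene_id`, `strand` and
#'   list-columns `exons`, `cds` (internal coordinates).
#' @param path Output path.
#' @param seqname Sequence name written in column 1.
#' @return `path`, invisibly.
#' @export
write_gtf_transcripts <- function(transcripts, path, seqname = "synth") {
  lines <- character()
  feat_line <- function(type, start0, end0, strand, gid, tid) {
    paste(seqname, "oryzakin", type, start0 + 1, end0, ".", strand, ".",
          paste0("gene_id \"", gid, "\"; transcript_id \"", tid, "\";"),
          sep = "\t")
  }
  for (i in seq_len(nrow(transcripts))) {
    tid <- transcripts$transcript_id[i]
    gid <- transcripts$gene_id[i]
    strand <- transcripts$strand[i]
    ex <- transcripts$exons[[i]]
    cds <- transcripts$cds[[i]]
    lines <- c(lines,
               feat_line("transcript", min(ex$start), max(ex$end), strand,
                         gid, tid),
               vapply(seq_len(nrow(ex)), function(j)
                 feat_line("exon", ex$start[j], ex$end[j], strand, gid, tid),
                 character(1)),
               vapply(seq_len(nrow(cds)), function(j)
                 feat_line("CDS", cds$start[j], cds$end[j], strand, gid, tid),
                 character(1)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a complete synthetic study to disk
#'
#' Emits every format the readers consume: gene orders, homology pairs,
#' homoeolog map, FPKM matrix with sample metadata, protein and variant
#' FASTA, variant transcripts as GTF, truth tables, and the configuration as
#' JSON. Writing is deterministic: the same study writes byte-identical
#' files.
#'
#' @param study A bundle from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  write_gene_orders(study$orders, p("gene_orders.tsv"))
  readr::write_tsv(select(study$intra_pairs, "gene_a", "gene_b", "score",
                          "genome"),
                   p("intra_pairs.tsv"), progress = FALSE)
  readr::write_tsv(select(study$outgroup_pairs, "gene_a", "gene_b", "score",
                          "genome"),
                   p("outgroup_pairs.tsv"), progress = FALSE)
  readr::write_tsv(study$homoeolog_map, p("homoeolog_map.tsv"),
                   progress = FALSE)
  wide <- tidyr::pivot_wider(study$expression$values, names_from = "sample",
                             values_from = "fpkm") %>%
    arrange(.data$gene_id)
  readr::write_tsv(wide, p("fpkm.tsv"), progress = FALSE)
  readr::write_tsv(study$expression$sample_meta, p("samples.tsv"),
                   progress = FALSE)
  write_protein_fasta(study$proteins, p("proteins.fasta"))
  write_protein_fasta(rename(study$variants, protein_id = "transcript_id"),
                      p("variant_proteins.fasta"))
  write_gtf_transcripts(study$transcripts, p("variants.gtf"))
  readr::write_tsv(study$truth$dup, p("truth_duplications.tsv"),
                   progress = FALSE)
  readr::write_tsv(study$truth$as, p("truth_as_types.tsv"), progress = FALSE)
  readr::write_tsv(study$truth$heb, p("truth_heb.tsv"), progress = FALSE)
  readr::write_tsv(
    mutate(study$truth$arch,
           ca_sites = map_chr(.data$ca_sites, function(x)
             paste(as.integer(x), collapse = ","))),
    p("truth_architectures.tsv"), progress = FALSE)
  cfg <- study$config
  cfg$genomes <- as.data.frame(cfg$genomes)
  cfg$duplication_events <- as.data.frame(cfg$duplication_events)
  jsonlite::write_json(unclass(cfg), p("config.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
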