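#' All-vs-all similarity pairs
#'
#' Smith-Waterman (BLOSUM62, gap 11/1) score for every protein pair; pairs at
#' or above `floor` are kept, sorted by score descending. A raw-score floor
#' stands in for a database E-value cutoff.
#'
#' @param proteins Tibble with `protein_id`, `sequence` (at least 2 rows for a
#'   non-empty result).
#' @param floor Positive raw-score floor.
#' @return Tibble `gene_a`, `gene_b`, `score` (ids canonicalised so
#'   `gene_a < gene_b`).
#' @export
compute_similarity_pairs <- function(proteins, floor = 100) {
  if (floor <= 0) abort("score floor must be positive",
                        class = "oryzakin_config_error")
  n <- nrow(proteins)
  if (n < 2L) return(tibble(gene_a = character(), gene_b = character(),
                            score = double()))
  mat <- blosum62_x0()
  combos <- utils::combn(n, 2)
  scores <- map_dbl(seq_len(ncol(combos)), function(k) {
    i <- combos[1, k]; j <- combos[2, k]
    Biostrings::pairwiseAlignment(
      Biostrings::AAString(proteins$sequence[i]),
      Biostrings::AAString(proteins$sequence[j]),
      type = "local", substitutionMatrix = mat,
      gapOpening = 11, gapExtension = 1, scoreOnly = TRUE
    )
  })
  tab <- tibble(gene_a = proteins$protein_id[combos[1, ]],
                gene_b = proteins$protein_id[combos[2, ]],
                score = scores) %>%
    filter(.data$score >= floor) %>%
    arrange(dplyr::desc(.data$score))
  canonicalise_pairs(tab)
}

# Longest chain of rank-monotone pairs on one chromosome pair, one
# orientation. Pairs sorted by rank_a; chain requires strictly increasing
# rank_a and strictly monotone rank_b, with consecutive gaps <= max_gap on
# both sides. O(n^2) DP; n per chromosome pair is small at family scale.
chain_dp <- function(ra, rb, max_gap, inverted = FALSE) {
  n <- length(ra)
  if (!n) return(list(score = 0L, idx = integer()))
  ord <- order(ra, if (inverted) -rb else rb)
  ra <- ra[ord]; rb <- rb[ord]
  best <- rep(1L, n)
  prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      gap_a <- ra[i] - ra[j]
      gap_b <- if (inverted) rb[j] - rb[i] else rb[i] - rb[j]
      if (gap_a >= 1L && gap_a <= max_gap && gap_b >= 1L && gap_b <= max_gap &&
          best[j] + 1L > best[i]) {
        best[i] <- best[j] + 1L
        prev[i] <- j
      }
    }
  }
  top <- which.max(best)
  idx <- integer()
  while (!is.na(top)) {
    idx <- c(top, idx)
    top <- prev[top]
  }
  list(score = max(best), idx = ord[idx])
}

#' Find collinear blocks by chain dynamic programming
#'
#' For every chromosome pair with homolog pairs, maximal rank-monotone chains
#' (both orientations, consecutive rank gaps at most `max_gap` on both sides)
#' are extracted greedily: the best chain is emitted as a block and its pairs
#' removed, until no chain reaches `min_anchors`.
#'
#' @param pairs Tibble `gene_a`, `gene_b` (plus anything else, carried along).
#' @param orders Gene-order tibble with `gene_id`, `genome`, `chromosome`,
#'   `order_rank` (see [read_gene_orders()]/[assign_order_ranks()]).
#' @param min_anchors Minimum anchors per block (default 5).
#' @param max_gap Maximum rank gap between consecutive anchors (default 25).
#' @return Tibble of anchors: `block_id`, `chrom_a`, `chrom_b`, `orientation`,
#'   `gene_a`, `gene_b`, `rank_a`, `rank_b`, `n_anchors`.
#' @export
find_collinear_blocks <- function(pairs, orders, min_anchors = 5L,
                                  max_gap = 25L) {
  empty <- tibble(block_id = integer(), chrom_a = character(),
                  chrom_b = character(), orientation = character(),
                  gene_a = character(), gene_b = character(),
                  rank_a = integer(), rank_b = integer(),
                  n_anchors = integer())
  if (!nrow(pairs)) return(empty)
  loc <- orders %>%
    mutate(chrom_key = paste(.data$genome, .data$chromosome, sep = ":")) %>%
    select("gene_id", "chrom_key", "order_rank")
  tab <- pairs %>%
    inner_join(loc, by = c(gene_a = "gene_id")) %>%
    rename(chrom_a = "chrom_key", rank_a = "order_rank") %>%
    inner_join(loc, by = c(gene_b = "gene_id")) %>%
    rename(chrom_b = "chrom_key", rank_b = "order_rank")
  # genes absent from the order tables simply cannot anchor blocks;
  # orient each pair so chrom_a <= chrom_b for consistent grouping
  flip <- tab$chrom_a > tab$chrom_b
  if (any(flip)) {
    tmp <- tab[flip, c("gene_a", "chrom_a", "rank_a")]
    tab[flip, c("gene_a", "chrom_a", "rank_a")] <-
      tab[flip, c("gene_b", "chrom_b", "rank_b")]
    tab[flip, c("gene_b", "chrom_b", "rank_b")] <- tmp
  }
  blocks <- list()
  bid <- 0L
  for (key in unique(paste(tab$chrom_a, tab$chrom_b, sep = "|"))) {
    sub <- filter(tab, paste(.data$chrom_a, .data$chrom_b, sep = "|") == key)
    repeat {
      fwd <- chain_dp(sub$rank_a, sub$rank_b, max_gap, inverted = FALSE)
      rev <- chain_dp(sub$rank_a, sub$rank_b, max_gap, inverted = TRUE)
      pick <- if (fwd$score >= rev$score) fwd else rev
      orient <- if (fwd$score >= rev$score) "same" else "inverted"
      if (pick$score < min_anchors) break
      bid <- bid + 1L
      blk <- sub[pick$idx, , drop = FALSE] %>%
        mutate(block_id = bid, orientation = orient,
               n_anchors = pick$score)
      blocks[[length(blocks) + 1L]] <- blk
      sub <- sub[-pick$idx, , drop = FALSE]
      if (!nrow(sub)) break
    }
  }
  if (!length(blocks)) return(empty)
  list_rbind(blocks) %>%
    select("block_id", "chrom_a", "chrom_b", "orientation",
           "gene_a", "gene_b", "rank_a", "rank_b", "n_anchors")
}

#' Classify duplicate gene pairs into duplication modes
#'
#' Hierarchical assignment in priority order WGD > TD > PD > TRD > DSD:
#' whole-genome (pair is an anchor of an intra-genome collinear block, or lies
#' inside a block's rank envelope when `block_envelope = TRUE`); tandem (same
#' chromosome, adjacent gene-order ranks); proximal (same chromosome, rank
#' distance at most `proximal_window` but not adjacent); transposed (exactly
#' one gene of the pair sits at an ancestral locus -- an anchor of a block
#' against the outgroup genome -- and the pair is in no intra-genome block);
#' dispersed (everything else). Each gene receives the mode of its
#' highest-priority surviving pair; family genes without any pair are
#' singletons.
#'
#' @param family_pairs Within-genome homolog pairs among family genes
#'   (`gene_a`, `gene_b`).
#' @param blocks Intra-genome blocks from [find_collinear_blocks()].
#' @param orders Gene-order tibble (must cover all pair members).
#' @param outgroup_blocks Blocks of this genome against the outgroup genome.
#' @param family_genes Character vector of family gene ids (defines the
#'   SINGLETON complement).
#' @param proximal_window Maximum rank distance for a proximal call
#'   (default 10).
#' @param block_envelope Count non-anchor genes inside a block's rank envelope
#'   as WGD evidence (default `FALSE`: anchors only).
#' @return Tibble: `gene_id`, `mode`, `partner`, `evidence`.
#' @export
classify_duplications <- function(family_pairs, blocks, orders,
                                  outgroup_blocks = NULL,
                                  family_genes = NULL,
                                  proximal_window = 10L,
                                  block_envelope = FALSE) {
  loc <- orders %>% select("gene_id", "genome", "chromosome", "order_rank")
  if (is.null(family_genes)) {
    family_genes <- unique(c(family_pairs$gene_a, family_pairs$gene_b))
  }
  anchor_key <- if (nrow(blocks)) {
    paste(pmin(blocks$gene_a, blocks$gene_b),
          pmax(blocks$gene_a, blocks$gene_b))
  } else character()
  block_members <- unique(c(blocks$gene_a, blocks$gene_b))
  ancestral <- if (!is.null(outgroup_blocks) && nrow(outgroup_blocks)) {
    unique(c(outgroup_blocks$gene_a, outgroup_blocks$gene_b))
  } else character()
  env_lookup <- NULL
  if (block_envelope && nrow(blocks)) {
    env_lookup <- blocks %>%
      group_by(.data$block_id, .data$chrom_a, .data$chrom_b) %>%
      summarise(a_lo = min(.data$rank_a), a_hi = max(.data$rank_a),
                b_lo = min(.data$rank_b), b_hi = max(.data$rank_b),
                .groups = "drop")
  }
  pr <- family_pairs %>%
    select("gene_a", "gene_b") %>%
    left_join(loc, by = c(gene_a = "gene_id")) %>%
    rename(genome_a = "genome", chrom_a = "chromosome", rank_a = "order_rank") %>%
    left_join(loc, by = c(gene_b = "gene_id")) %>%
    rename(genome_b = "genome", chrom_b = "chromosome", rank_b = "order_rank")
  if (any(is.na(pr$rank_a)) || any(is.na(pr$rank_b))) {
    missing <- unique(c(pr$gene_a[is.na(pr$rank_a)], pr$gene_b[is.na(pr$rank_b)]))
    abort(paste0("gene(s) missing from gene order: ",
                 paste(missing, collapse = ", ")),
          class = "oryzakin_data_error")
  }
  in_envelope <- function(i) {
    if (is.null(env_lookup)) return(FALSE)
    ka <- paste(pr$genome_a[i], pr$chrom_a[i], sep = ":")
    kb <- paste(pr$genome_b[i], pr$chrom_b[i], sep = ":")
    any((env_lookup$chrom_a == ka & env_lookup$chrom_b == kb &
           pr$rank_a[i] >= env_lookup$a_lo & pr$rank_a[i] <= env_lookup$a_hi &
           pr$rank_b[i] >= env_lookup$b_lo & pr$rank_b[i] <= env_lookup$b_hi) |
        (env_lookup$chrom_a == kb & env_lookup$chrom_b == ka &
           pr$rank_b[i] >= env_lookup$a_lo & pr$rank_b[i] <= env_lookup$a_hi &
           pr$rank_a[i] >= env_lookup$b_lo & pr$rank_a[i] <= env_lookup$b_hi))
  }
  pr$mode <- vapply(seq_len(nrow(pr)), function(i) {
    key <- paste(pmin(pr$gene_a[i], pr$gene_b[i]),
                 pmax(pr$gene_a[i], pr$gene_b[i]))
    same_chrom <- pr$genome_a[i] == pr$genome_b[i] &&
      pr$chrom_a[i] == pr$chrom_b[i]
    drank <- abs(pr$rank_a[i] - pr$rank_b[i])
    if (key %in% anchor_key || in_envelope(i)) return("WGD")
    if (same_chrom && drank == 1L) return("TD")
    if (same_chrom && drank > 1L && drank <= proximal_window) return("PD")
    in_block <- (pr$gene_a[i] %in% block_members) ||
      (pr$gene_b[i] %in% block_members)
    one_ancestral <- xor(pr$gene_a[i] %in% ancestral,
                         pr$gene_b[i] %in% ancestral)
    if (one_ancestral && !in_block) return("TRD")
    "DSD"
  }, character(1))
  pr$priority <- match(pr$mode, DUP_MODES)
  calls <- map(family_genes, function(g) {
    rows <- pr %>% filter(.data$gene_a == g | .data$gene_b == g)
    if (!nrow(rows)) {
      return(tibble(gene_id = g, mode = "SINGLETON", partner = NA_character_,
                    evidence = NA_character_))
    }
    best <- rows %>% arrange(.data$priority) %>% dplyr::slice(1)
    partner <- if (best$gene_a == g) best$gene_b else best$gene_a
    ev <- switch(best$mode,
      WGD = "anchor_or_envelope_of_collinear_block",
      TD = "adjacent_rank",
      PD = paste0("rank_distance=", abs(best$rank_a - best$rank_b)),
      TRD = "one_ancestral_locus_no_block",
      DSD = "no_other_signature")
    tibble(gene_id = g, mode = best$mode, partner = partner, evidence = ev)
  }) %>% list_rbind()
  calls
}

#' Copy-number variation matrix
#'
#' Copy counts of family genes per ortholog group and genome/subgenome.
#' Absent combinations are reported as 0.
#'
#' @param genes Tibble with `gene_id`, `genome`, `subgenome`, `family`,
#'   `ortholog_group` (genes with family `"none"` are ignored).
#' @return Wide tibble: one row per `ortholog_group` (+ `family`), one column
#'   per genome/subgenome label, integer counts.
#' @export
build_cnv_matrix <- function(genes) {
  fam <- genes %>%
    filter(.data$family != "none", !is.na(.data$ortholog_group)) %>%
    mutate(column = if_else(is.na(.data$subgenome) | .data$subgenome == "" |
                              endsWith(.data$genome, .data$subgenome),
                            .data$genome,
                            paste(.data$genome, .data$subgenome, sep = "_")))
  counts <- fam %>%
    count(.data$ortholog_group, .data$family, .data$column, name = "copies")
  tidyr::pivot_wider(counts, names_from = "column", values_from = "copies",
                     values_fill = 0L) %>%
    arrange(.data$family, .data$ortholog_group)
}
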