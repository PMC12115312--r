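#' Expression filter
#'
#' A gene counts as expressed in a tissue when its mean FPKM over that
#' tissue's replicates is strictly above the threshold (default 0.5 FPKM).
#'
#' @param expression List with `values` (long tibble `gene_id`, `sample`,
#'   `fpkm`) and `sample_meta` (`sample`, `species`, `tissue`, `replicate`),
#'   as returned by [read_expression()] or [generate_expression()].
#' @param threshold FPKM threshold (default 0.5).
#' @return Tibble `gene_id`, `tissue`, `mean_fpkm`, `expressed`.
#' @export
filter_expressed <- function(expression, threshold = 0.5) {
  stopifnot(threshold >= 0)
  meta <- expression$sample_meta
  bad <- setdiff(unique(meta$tissue), TISSUE_LEVELS)
  if (length(bad)) {
    abort(paste0("unknown tissue label(s): ", paste(bad, collapse = ", ")),
          class = "oryzakin_data_error")
  }
  expression$values %>%
    left_join(meta, by = "sample") %>%
    group_by(.data$gene_id, .data$tissue) %>%
    summarise(mean_fpkm = mean(.data$fpkm), .groups = "drop") %>%
    mutate(expressed = .data$mean_fpkm > threshold)
}

#' Normalized subgenome contributions of a homoeolog pair
#'
#' @param fpkm_a,fpkm_b Non-negative FPKM values with positive sum.
#' @return Numeric vector `c(p_a, p_b)` summing to 1.
#' @export
normalize_pair <- function(fpkm_a, fpkm_b) {
  total <- fpkm_a + fpkm_b
  if (total <= 0) {
    abort("both homoeologs have zero expression; route to NOT_EXPRESSED",
          class = "oryzakin_input_error")
  }
  p_a <- fpkm_a / total
  c(p_a = p_a, p_b = 1 - p_a)
}

#' Homoeolog expression bias classification
#'
#' Per homoeolog pair and tissue: if neither member passes the expression
#' filter, the call is NOT_EXPRESSED. Otherwise the pair's mean FPKM values
#' are normalized to relative subgenome contributions (a sub-threshold member
#' keeps its measured value) and the pair is assigned the category of the
#' Euclidean-nearest ideal contribution vector; exact ties go to BALANCED.
#' With the default ideals (1,0), (0,1), (0.5,0.5) the decision boundary sits
#' at a dominant contribution of 0.75: DOM calls require p strictly above it.
#'
#' @param pairs Homoeolog map tibble: `group`, `gene_a`, `subgenome_a`,
#'   `gene_b`, `subgenome_b`.
#' @param expression Expression list (see [filter_expressed()]).
#' @param threshold Expression filter threshold (FPKM, default 0.5).
#' @param ideals Named list of ideal `(p_a, p_b)` vectors for DOM_A, DOM_B,
#'   BALANCED.
#' @param require_both Require both members above threshold (default `FALSE`:
#'   at least one suffices).
#' @return Tibble: one row per pair x tissue with `group`, `gene_a`, `gene_b`,
#'   `tissue`, `fpkm_a`, `fpkm_b`, `p_a`, `p_b`, `d_dom_a`, `d_dom_b`,
#'   `d_balanced`, `category`.
#' @export
classify_heb <- function(pairs, expression, threshold = 0.5,
                         ideals = list(DOM_A = c(1, 0), DOM_B = c(0, 1),
                                       BALANCED = c(0.5, 0.5)),
                         require_both = FALSE) {
  expr <- filter_expressed(expression, threshold)
  get_side <- function(genes, nm) {
    expr %>% filter(.data$gene_id %in% genes) %>%
      select("gene_id", "tissue", "mean_fpkm", "expressed") %>%
      setNames(c(nm, "tissue", paste0("fpkm_", sub("gene_", "", nm)),
                 paste0("expressed_", sub("gene_", "", nm))))
  }
  tab <- pairs %>%
    inner_join(get_side(pairs$gene_a, "gene_a"), by = "gene_a") %>%
    inner_join(get_side(pairs$gene_b, "gene_b"), by = c("gene_b", "tissue"))
  missing_tissues <- pairs %>%
    anti_join(tab, by = c("gene_a", "gene_b"))
  if (nrow(missing_tissues)) {
    abort(paste0("no shared tissue measurements for pair(s): ",
                 paste(missing_tissues$group, collapse = ", ")),
          class = "oryzakin_data_error")
  }
  tab %>%
    mutate(
      included = if (require_both) .data$expressed_a & .data$expressed_b
                 else .data$expressed_a | .data$expressed_b,
      p_a = if_else(.data$included,
                    .data$fpkm_a / (.data$fpkm_a + .data$fpkm_b), NA_real_),
      p_b = 1 - .data$p_a,
      d_dom_a = sqrt((.data$p_a - ideals$DOM_A[1])^2 +
                       (.data$p_b - ideals$DOM_A[2])^2),
      d_dom_b = sqrt((.data$p_a - ideals$DOM_B[1])^2 +
                       (.data$p_b - ideals$DOM_B[2])^2),
      d_balanced = sqrt((.data$p_a - ideals$BALANCED[1])^2 +
                          (.data$p_b - ideals$BALANCED[2])^2),
      category = dplyr::case_when(
        !included ~ "NOT_EXPRESSED",
        d_balanced <= d_dom_a & d_balanced <= d_dom_b ~ "BALANCED",
        d_dom_a < d_dom_b ~ "DOM_A",
        d_dom_b < d_dom_a ~ "DOM_B",
        TRUE ~ "BALANCED"
      )
    ) %>%
    select("group", "gene_a", "gene_b", "tissue", "fpkm_a", "fpkm_b",
           "p_a", "p_b", "d_dom_a", "d_dom_b", "d_balanced", "category")
}

#' Expression-atlas summary per gene
#'
#' Per-tissue mean FPKM, the dominant tissue, and a predominance flag: a gene
#' is predominantly expressed in its top tissue when the ratio of the top to
#' the second-highest tissue mean is at least `predominance_factor` and the
#' gene passes the expression filter there. Display transforms
#' `log10(FPKM + 0.01)` and `log2(FPKM + 1)` are recorded alongside.
#'
#' @param expression Expression list (see [filter_expressed()]).
#' @param predominance_factor Top-to-second ratio required (default 2).
#' @param threshold Expression filter threshold (default 0.5 FPKM).
#' @return A list with `tissue_means` (long tibble incl. display transforms)
#'   and `summary` (per gene: `dominant_tissue`, `predominance_ratio`,
#'   `predominant`, `expressed_anywhere`).
#' @export
summarize_atlas <- function(expression, predominance_factor = 2.0,
                            threshold = 0.5) {
  means <- filter_expressed(expression, threshold) %>%
    mutate(log10_display = log10(.data$mean_fpkm + 0.01),
           log2_display = log2(.data$mean_fpkm + 1))
  summary <- means %>%
    group_by(.data$gene_id) %>%
    dplyr::group_modify(function(g, key) {
      g <- arrange(g, dplyr::desc(.data$mean_fpkm))
      ratio <- if (nrow(g) >= 2L && g$mean_fpkm[2] > 0) {
        g$mean_fpkm[1] / g$mean_fpkm[2]
      } else if (nrow(g) >= 2L && g$mean_fpkm[1] > 0) {
        Inf
      } else {
        1
      }
      tibble(dominant_tissue = g$tissue[1],
             predominance_ratio = max(ratio, 1),
             predominant = ratio >= predominance_factor && g$expressed[1],
             expressed_anywhere = any(g$expressed))
    }) %>%
    ungroup()
  list(tissue_means = means, summary = summary)
}

#' Compare expression of a duplicate or homoeolog pair
#'
#' Per-tissue log2 ratio (pseudocount +1) and the Pearson concordance of the
#' two tissue profiles. The pair is `one_silent` when exactly one member is
#' expressed nowhere; `redundant` when concordance is at least `r_floor` and
#' the mean absolute log2 ratio is at most 1; otherwise `diverged`. With
#' fewer than 3 tissues the concordance is undefined and the call rests on
#' the ratios alone.
#'
#' @param gene_a,gene_b Gene ids.
#' @param expression Expression list.
#' @param silent_threshold FPKM threshold for the silence test (default 0.5).
#' @param r_floor Concordance floor for redundancy (default 0.8).
#' @return A one-row tibble: `gene_a`, `gene_b`, `concordance`,
#'   `mean_abs_log2_ratio`, `call`, plus a `per_tissue` list-column.
#' @export
compare_pair_expression <- function(gene_a, gene_b, expression,
                                    silent_threshold = 0.5, r_floor = 0.8) {
  expr <- filter_expressed(expression, silent_threshold)
  a <- filter(expr, .data$gene_id == gene_a)
  b <- filter(expr, .data$gene_id == gene_b)
  if (!nrow(a) || !nrow(b)) {
    abort("both genes must be present in the expression matrix",
          class = "oryzakin_data_error")
  }
  tab <- inner_join(select(a, "tissue", fpkm_a = "mean_fpkm",
                           expressed_a = "expressed"),
                    select(b, "tissue", fpkm_b = "mean_fpkm",
                           expressed_b = "expressed"),
                    by = "tissue") %>%
    mutate(log2_ratio = log2((.data$fpkm_a + 1) / (.data$fpkm_b + 1)))
  silent_a <- !any(tab$expressed_a)
  silent_b <- !any(tab$expressed_b)
  conc <- if (nrow(tab) >= 3L) {
    suppressWarnings(cor(tab$fpkm_a, tab$fpkm_b, method = "pearson"))
  } else {
    NA_real_
  }
  mean_ratio <- mean(abs(tab$log2_ratio))
  call <- if (xor(silent_a, silent_b)) {
    "one_silent"
  } else if ((is.na(conc) || conc >= r_floor) && mean_ratio <= 1) {
    "redundant"
  } else {
    "diverged"
  }
  tibble(gene_a = gene_a, gene_b = gene_b,
         concordance = conc, mean_abs_log2_ratio = mean_ratio,
         call = call, per_tissue = list(tab))
}
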