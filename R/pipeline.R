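#' Run the full analysis pipeline on a synthetic study
#'
#' Executes every stage in order: simulate (or accept a pre-built study),
#' domain scan, family classification, architecture clustering per ortholog
#' group, collinear blocks and duplication typing per genome, copy-number
#' matrix, splice-variant typing, homoeolog-bias calling, and atlas
#' summaries. When planted truth is present, per-stage confusion tables are
#' attached.
#'
#' @param config A [sim_config()] (ignored when `study` is given).
#' @param study Optionally a pre-built study bundle from [simulate_study()].
#' @return An object of class `kinase_pipeline`: a list of stage result
#'   tibbles plus `confusion` and `params`.
#' @export
run_pipeline <- function(config = sim_config(), study = NULL) {
  study <- study %||% simulate_study(config)
  config <- study$config
  scanned <- scan_proteins(rename(study$proteins,
                                  planted_family = "family"))
  fam <- classify_family(scanned, study$seeds)
  arch_classes <- cluster_architectures(
    filter(fam, .data$family != "none"), by = "ortholog_group")
  orders <- study$orders
  fam_gene_tab <- filter(orders, .data$family != "none")
  dup_calls <- list()
  for (glab in setdiff(unique(orders$genome), study$outgroup_genome)) {
    ip <- filter(study$intra_pairs, .data$genome == glab)
    op <- filter(study$outgroup_pairs, .data$genome == glab)
    blocks <- find_collinear_blocks(ip, orders)
    oblocks <- find_collinear_blocks(op, orders)
    fam_ids <- fam_gene_tab$gene_id[fam_gene_tab$genome == glab]
    fam_pairs <- filter(ip, .data$gene_a %in% fam_ids |
                          .data$gene_b %in% fam_ids)
    calls <- classify_duplications(fam_pairs, blocks, orders, oblocks,
                                   family_genes = fam_ids)
    calls$genome <- glab
    dup_calls[[length(dup_calls) + 1L]] <- calls
  }
  dup_calls <- list_rbind(dup_calls)
  cnv <- build_cnv_matrix(fam_gene_tab)
  as_calls <- classify_transcripts(
    study$variants,
    scanned %>% rename(gene_id = "protein_id"))
  heb <- classify_heb(study$homoeolog_map, study$expression)
  atlas <- summarize_atlas(study$expression)
  confusion <- list(
    as = confusion_table(study$truth$as, as_calls,
                         by = "transcript_id",
                         truth_col = "planted_type", call_col = "type"),
    heb = confusion_table(
      study$truth$heb, select(heb, "group", "tissue", "category"),
      by = c("group", "tissue"),
      truth_col = "category", call_col = "category"),
    dup = confusion_table(
      select(study$truth$dup, gene_id = "gene_copy", truth_mode = "mode"),
      select(dup_calls, "gene_id", call_mode = "mode"),
      by = "gene_id", truth_col = "truth_mode", call_col = "call_mode"),
    family = confusion_table(
      select(fam, "protein_id", "planted_family"),
      select(fam, "protein_id", "family"),
      by = "protein_id", truth_col = "planted_family", call_col = "family")
  )
  structure(list(
    proteins = fam, architectures = arch_classes,
    duplications = dup_calls, cnv = cnv, as_calls = as_calls,
    heb = heb, atlas = atlas, confusion = confusion,
    truth = study$truth, study = study,
    params = list(seed = config$seed,
                  n_genomes = nrow(config$genomes),
                  families = config$family_counts,
                  p_dom = config$p_dom,
                  expression_noise_sd = config$expression_noise_sd)
  ), class = "kinase_pipeline")
}

confusion_table <- function(truth, calls, by, truth_col, call_col) {
  if (is.null(truth) || !nrow(truth)) return(NULL)
  call_sel <- calls
  if (truth_col == call_col) {
    truth <- rename(truth, truth_value = dplyr::all_of(truth_col))
    call_sel <- rename(call_sel, call_value = dplyr::all_of(call_col))
  } else {
    truth <- rename(truth, truth_value = dplyr::all_of(truth_col))
    call_sel <- rename(call_sel, call_value = dplyr::all_of(call_col))
  }
  inner_join(truth, call_sel, by = by) %>%
    count(.data$truth_value, .data$call_value, name = "n")
}

#' @export
print.kinase_pipeline <- function(x, ...) {
  cat("<kinase_pipeline>\n")
  cat("  proteins scanned:     ", nrow(x$proteins), "\n")
  cat("  duplication calls:    ", nrow(x$duplications), "\n")
  cat("  splice-variant calls: ", nrow(x$as_calls), "\n")
  cat("  HEB calls:            ", nrow(x$heb), "\n")
  invisible(x)
}

#' Tidy a pipeline result
#'
#' One row per gene with family, architecture signature and duplication mode.
#'
#' @param x A `kinase_pipeline`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.kinase_pipeline <- function(x, ...) {
  x$proteins %>%
    select("protein_id", "genome", "ortholog_group", "family", "signature",
           "kinase_state", "ef_count", "ca_count") %>%
    left_join(select(x$duplications, gene_id = "gene_id", "mode", "partner"),
              by = c(protein_id = "gene_id"))
}

#' Glance at a pipeline result
#'
#' One-row summary: record counts per stage and truth-recovery rates where
#' planted truth is available.
#'
#' @inheritParams tidy.kinase_pipeline
#' @return A one-row tibble.
#' @export
glance.kinase_pipeline <- function(x, ...) {
  rec <- function(conf) {
    if (is.null(conf) || !nrow(conf)) return(NA_real_)
    sum(conf$n[conf$truth_value == conf$call_value]) / sum(conf$n)
  }
  tibble(
    n_proteins = nrow(x$proteins),
    n_families = dplyr::n_distinct(x$proteins$family[x$proteins$family != "none"]),
    n_dup_calls = nrow(x$duplications),
    n_as_calls = nrow(x$as_calls),
    n_heb_calls = nrow(x$heb),
    as_recovery = rec(x$confusion$as),
    heb_recovery = rec(x$confusion$heb),
    dup_recovery = rec(x$confusion$dup)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
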