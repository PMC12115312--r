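#' BLOSUM62 with neutral ambiguity residue
#'
#' The shipped BLOSUM62 scores `X` against everything at -1; motif and family
#' calls here treat `X` as uninformative, so its rows and columns are zeroed.
#'
#' @return A substitution matrix.
#' @keywords internal
blosum62_x0 <- function() {
  mat <- get_blosum62()
  if ("X" %in% rownames(mat)) {
    mat["X", ] <- 0L
    mat[, "X"] <- 0L
  }
  mat
}

get_blosum62 <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62
}

#' Local-alignment similarity score
#'
#' Smith-Waterman score under BLOSUM62 (ambiguity-neutralised), gap open 11,
#' gap extend 1 -- the conventional protein-search scoring used as a stand-in
#' for database bit scores.
#'
#' @param a,b Amino-acid strings.
#' @return Numeric raw score.
#' @export
alignment_score <- function(a, b) {
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "local", substitutionMatrix = blosum62_x0(),
    gapOpening = 11, gapExtension = 1, scoreOnly = TRUE
  )
}

# family -> architecture consistency rules; violations only warn, the
# similarity vote still decides the label
family_arch_consistent <- function(family, kinase_state, ef_count, ca_count) {
  switch(family,
    CCaMK = kinase_state == "complete" && ef_count == 3L,
    CPK   = kinase_state == "complete" && ef_count >= 3L && ef_count <= 4L,
    CRK   = kinase_state != "absent" && ef_count <= 1L && ca_count == 0L,
    PPCK  = kinase_state != "absent" && ef_count == 0L,
    PEPRK = kinase_state != "absent" && ef_count == 0L,
    TRUE
  )
}

#' Assign family labels by seeded local alignment
#'
#' Each query is aligned against every seed; the best-scoring seed's family
#' becomes the label, unless the best score falls below `score_floor`, in
#' which case the label is `"none"`. When the query's domain architecture
#' contradicts the labelled family's canonical rules (CCaMK: complete kinase
#' with 3 EF-hands; CPK: complete kinase with 3-4; CRK: kinase with at most
#' one calcium-blind EF-hand; PPCK/PEPRK: kinase only) a warning string is
#' attached, but the similarity vote stands.
#'
#' @param proteins Tibble with `protein_id`, `sequence` and, if available,
#'   architecture columns from [scan_proteins()] (added on the fly otherwise).
#' @param seeds Tibble with `protein_id`, `sequence`, `family` -- at least one
#'   seed per family to be assignable.
#' @param score_floor Raw-score floor below which no family is assigned.
#' @return `proteins` with `family`, `family_score`, `best_seed` and
#'   `family_warning` columns.
#' @export
classify_family <- function(proteins, seeds, score_floor = 100) {
  if (is.null(seeds) || nrow(seeds) == 0L) {
    abort("empty seed set", class = "oryzakin_config_error")
  }
  stopifnot(all(c("protein_id", "sequence", "family") %in% names(seeds)))
  if (!"signature" %in% names(proteins)) proteins <- scan_proteins(proteins)
  mat <- blosum62_x0()
  seed_set <- Biostrings::AAStringSet(seeds$sequence)
  res <- map(seq_len(nrow(proteins)), function(i) {
    scores <- Biostrings::pairwiseAlignment(
      seed_set, Biostrings::AAString(proteins$sequence[i]),
      type = "local", substitutionMatrix = mat,
      gapOpening = 11, gapExtension = 1, scoreOnly = TRUE
    )
    best <- which.max(scores)
    fam <- if (scores[best] < score_floor) "none" else seeds$family[best]
    warning_msg <- NA_character_
    if (fam != "none" &&
        !family_arch_consistent(fam, proteins$kinase_state[i],
                                proteins$ef_count[i], proteins$ca_count[i])) {
      warning_msg <- paste0("architecture inconsistent with family ", fam)
    }
    tibble(family = fam, family_score = scores[best],
           best_seed = seeds$protein_id[best], family_warning = warning_msg)
  }) %>% list_rbind()
  bind_cols(proteins, res)
}

#' Cluster architectures into representative type and variants
#'
#' Within each group, architecture signatures supported by a single protein
#' are set aside (solo exclusion); among the rest the maximal-support
#' signature is the representative, ties broken by more total calcium-binding
#' sites, then by lexicographically smaller signature. Remaining signatures
#' are the variants, sorted by support descending (same tie-breaks).
#'
#' @param members Tibble with columns `signature` and a grouping column, plus
#'   `ca_count`.
#' @param by Name of the grouping column (default `"ortholog_group"`).
#' @return An object of class `arch_classification`: a tibble with one row per
#'   group x signature, columns `role`
#'   (`representative`/`variant`/`solo_excluded`), `support`, `ca_count`.
#'   Groups where every signature is solo get `role = "solo_excluded"` for all
#'   rows and are flagged in the `flagged` attribute.
#' @export
cluster_architectures <- function(members, by = "ortholog_group") {
  stopifnot(by %in% names(members), "signature" %in% names(members))
  tab <- members %>%
    group_by(.data[[by]], .data$signature) %>%
    summarise(support = dplyr::n(), ca_count = first(.data$ca_count),
              .groups = "drop")
  out <- tab %>%
    group_by(.data[[by]]) %>%
    dplyr::group_modify(function(g, key) {
      g <- arrange(g, dplyr::desc(.data$support), dplyr::desc(.data$ca_count),
                   .data$signature)
      g$role <- "variant"
      g$role[g$support == 1L] <- "solo_excluded"
      nonsolo <- which(g$role == "variant")
      if (length(nonsolo)) g$role[nonsolo[1]] <- "representative"
      g
    }) %>%
    ungroup()
  flagged <- out %>%
    group_by(.data[[by]]) %>%
    summarise(all_solo = !any(.data$role == "representative"),
              .groups = "drop") %>%
    filter(.data$all_solo) %>% pull(1)
  structure(out, class = c("arch_classification", class(out)),
            flagged = flagged)
}
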