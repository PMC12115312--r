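#' Classify a splice-variant architecture into the nine-type taxonomy
#'
#' The consequence of alternative splicing on domain architecture is labelled
#' by the absolute domain content of the variant protein: with a complete
#' kinase domain and fewer EF-hands than the reference, 3/2/1/0 EF-hands give
#' Types 1-4 (truncated EF-hand motifs); an incomplete kinase domain gives
#' Type 5 regardless of EF-hands (truncated kinase domain); with the kinase
#' domain absent, 4/3/2/1 EF-hands give Types 6-9 (remaining EF-hand motifs).
#' A variant whose signature equals the reference is CANONICAL; anything
#' outside the taxonomy (kinase absent with no EF-hands, or more EF-hands than
#' the reference) is UNCLASSIFIED. Calcium-site flags do not affect the label
#' but are carried in the signatures for audit.
#'
#' @param variant One-row architecture tibble (from [build_architecture()]).
#' @param reference One-row architecture tibble; must have a complete kinase
#'   domain and 3-4 EF-hands (a CPK or CCaMK representative).
#' @return A one-row tibble: `type`, `variant_signature`,
#'   `reference_signature`.
#' @export
classify_as_type <- function(variant, reference) {
  if (reference$kinase_state != "complete" ||
      reference$ef_count < 3L || reference$ef_count > 4L) {
    abort("reference architecture must have a complete kinase and 3-4 EF-hands",
          class = "oryzakin_config_error")
  }
  v_ef <- variant$ef_count
  r_ef <- reference$ef_count
  type <- if (identical(variant$signature, reference$signature)) {
    "CANONICAL"
  } else if (variant$kinase_state == "incomplete") {
    "T5"
  } else if (variant$kinase_state == "complete") {
    if (v_ef < r_ef && v_ef <= 3L) {
      c(`3` = "T1", `2` = "T2", `1` = "T3", `0` = "T4")[[as.character(v_ef)]]
    } else {
      "UNCLASSIFIED"
    }
  } else {  # kinase absent
    if (v_ef >= 1L && v_ef <= 4L && v_ef <= r_ef) {
      c(`4` = "T6", `3` = "T7", `2` = "T8", `1` = "T9")[[as.character(v_ef)]]
    } else {
      "UNCLASSIFIED"
    }
  }
  tibble(type = type,
         variant_signature = variant$signature,
         reference_signature = reference$signature)
}

#' Classify transcript variants of a gene set
#'
#' Scans each variant protein, builds its architecture, and classifies it
#' against the gene's reference architecture. Transcripts without a protein
#' record are skipped with a warning.
#'
#' @param variants Tibble with `transcript_id`, `gene_id`, `sequence` (the
#'   translated variant protein).
#' @param references Tibble with `gene_id` plus reference architecture columns
#'   (`kinase_state`, `ef_count`, `signature`), e.g. the canonical isoform's
#'   scan.
#' @return Tibble of calls: `transcript_id`, `gene_id`, `type`,
#'   `variant_signature`, `reference_signature`.
#' @export
classify_transcripts <- function(variants, references) {
  stopifnot(all(c("transcript_id", "gene_id", "sequence") %in% names(variants)))
  refs <- references
  if (!"signature" %in% names(refs)) {
    refs <- scan_proteins(rename(refs, protein_id = "gene_id") %>%
                            mutate(gene_id = .data$protein_id))
  }
  out <- map(seq_len(nrow(variants)), function(i) {
    g <- variants$gene_id[i]
    ref <- filter(refs, .data$gene_id == g)
    if (!nrow(ref)) {
      warn(paste0("no reference architecture for gene ", g, "; skipped"))
      return(NULL)
    }
    if (is.na(variants$sequence[i]) || !nzchar(variants$sequence[i])) {
      warn(paste0("transcript ", variants$transcript_id[i],
                  " has no protein; skipped"))
      return(NULL)
    }
    arch <- build_architecture(scan_domains(variants$sequence[i]),
                               nchar(variants$sequence[i]))
    call <- classify_as_type(arch, ref[1, ])
    bind_cols(tibble(transcript_id = variants$transcript_id[i], gene_id = g),
              call)
  }) %>% list_rbind()
  out
}
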