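#' Scan a protein for EF-hand motifs
#'
#' An EF-hand is reported for any 13-residue window whose loop either matches
#' the calcium-binding-site pattern strictly (`ca_site = TRUE`) or matches a
#' relaxed variant of it (`ca_site = FALSE`, a "degenerated" EF-hand unable to
#' bind calcium). The relaxed variant tolerates up to two violations among the
#' coordinating loop positions 1, 3, 5, 9 and 12 provided at least one
#' invariant anchor survives (D at position 1, or D/E at position 12) and all
#' non-coordinating position classes still hold. Overlapping candidates are
#' resolved greedily left to right, keeping non-overlapping hits; at equal
#' start a strict match beats a relaxed one.
#'
#' @param sequence Amino-acid string.
#' @return Tibble of hits: `kind` (`"EF_HAND"`), `start`, `end` (0-based
#'   half-open), `ca_site`, `evidence`.
#' @export
scan_ef_hands <- function(sequence) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  n <- length(chars)
  w <- 13L
  empty <- tibble(kind = character(), start = integer(), end = integer(),
                  ca_site = logical(), evidence = character())
  if (n < w) return(empty)
  classes <- prosite_fixed_classes(ps00018_pattern())
  coord <- EF_COORDINATING_POSITIONS
  noncoord <- setdiff(seq_len(w), coord)
  n_win <- n - w + 1L
  pos_ok <- matrix(FALSE, nrow = n_win, ncol = w)
  for (j in seq_len(w)) {
    pos_ok[, j] <- chars[j:(n - w + j)] %in% classes[[j]]
  }
  strict <- rowSums(pos_ok) == w
  anchor <- pos_ok[, 1L] | pos_ok[, 12L]
  coord_viol <- rowSums(!pos_ok[, coord, drop = FALSE])
  noncoord_ok <- rowSums(pos_ok[, noncoord, drop = FALSE]) == length(noncoord)
  relaxed <- !strict & noncoord_ok & anchor & coord_viol <= 2L
  cand <- tibble(start = which(strict | relaxed) - 1L) %>%
    mutate(ca_site = strict[.data$start + 1L])
  if (!nrow(cand)) return(empty)
  # greedy left-to-right non-overlap; strict preferred at equal start
  cand <- arrange(cand, .data$start, dplyr::desc(.data$ca_site))
  keep <- integer()
  last_end <- -1L
  for (i in seq_len(nrow(cand))) {
    if (cand$start[i] >= last_end) {
      keep <- c(keep, i)
      last_end <- cand$start[i] + w
    }
  }
  cand <- cand[keep, , drop = FALSE]
  tibble(kind = "EF_HAND", start = cand$start, end = cand$start + w,
         ca_site = cand$ca_site, evidence = "builtin_scan")
}

KINASE_ANCHOR_SPAN_MIN <- 180L
KINASE_ANCHOR_SPAN_MAX <- 340L

kinase_anchor_positions <- function(chars) {
  n <- length(chars)
  walker <- if (n >= 4L) {
    idx <- seq_len(n - 3L)
    which(chars[idx] %in% c("A", "V") &
            chars[idx + 2L] %in% c("I", "V") &
            chars[idx + 3L] == "K")
  } else integer()
  find_lit <- function(motif) {
    m <- strsplit(motif, "")[[1]]
    if (n < length(m)) return(integer())
    idx <- seq_len(n - length(m) + 1L)
    ok <- rep(TRUE, length(idx))
    for (j in seq_along(m)) ok <- ok & chars[idx + j - 1L] == m[j]
    which(ok)
  }
  list(walker = walker, hrd = find_lit("HRD"), dfg = find_lit("DFG"))
}

#' Scan a protein for a kinase domain
#'
#' Detects the three ordered anchor motifs of the serine/threonine kinase
#' fold: the Walker-lysine context `[AV]-x-[IV]-K`, the catalytic `HRD`
#' triplet and the activation-segment `DFG` triplet. The domain is complete
#' when some ordered walker-HRD-DFG triple spans 180-340 residues (first
#' anchor start to last anchor end); 1-2 anchors (or all three without an
#' admissible span) give an incomplete domain; no anchors, no hit. The
#' reported span runs from the first to the last found anchor padded by 25
#' residues each side, clipped to the protein.
#'
#' @param sequence Amino-acid string.
#' @return A one-row tibble (`kind`, `start`, `end`, `complete`, `evidence`)
#'   or a zero-row tibble when no anchor is present.
#' @export
scan_kinase <- function(sequence) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  n <- length(chars)
  anch <- kinase_anchor_positions(chars)
  present <- c(length(anch$walker) > 0, length(anch$hrd) > 0, length(anch$dfg) > 0)
  empty <- tibble(kind = character(), start = integer(), end = integer(),
                  complete = logical(), evidence = character())
  if (!any(present)) return(empty)
  complete <- FALSE
  if (all(present)) {
    for (wk in anch$walker) {
      hs <- anch$hrd[anch$hrd > wk]
      for (h in hs) {
        ds <- anch$dfg[anch$dfg > h]
        for (d in ds) {
          span <- (d + 3L) - wk  # walker start to DFG end, residues
          if (span >= KINASE_ANCHOR_SPAN_MIN && span <= KINASE_ANCHOR_SPAN_MAX) {
            complete <- TRUE
            break
          }
        }
        if (complete) break
      }
      if (complete) break
    }
  }
  starts <- c(anch$walker, anch$hrd, anch$dfg)
  ends <- c(anch$walker + 4L, anch$hrd + 3L, anch$dfg + 3L)
  span_start <- max(0L, min(starts) - 1L - 25L)
  span_end <- min(n, max(ends) - 1L + 25L)
  tibble(kind = "KINASE", start = span_start, end = span_end,
         complete = complete, evidence = "builtin_scan")
}

#' Scan one protein for all domains
#'
#' @param sequence Amino-acid string.
#' @return Tibble of `DomainHit` rows (kinase first, then EF-hands N to C)
#'   with columns `kind`, `start`, `end`, `complete`, `ca_site`, `evidence`.
#' @export
scan_domains <- function(sequence) {
  kin <- scan_kinase(sequence)
  ef <- scan_ef_hands(sequence)
  if (nrow(kin)) kin$ca_site <- NA
  if (nrow(ef)) ef$complete <- NA
  bind_rows(kin, ef) %>%
    select("kind", "start", "end", "complete", "ca_site", "evidence")
}

#' Load precomputed domain annotations
#'
#' Bypass for real proteomes scanned with external profile tools. Rows with
#' `source_id` PS50011 become complete kinase domains, PS50222 rows become
#' EF-hands, and a PS00018 row marks its containing EF-hand as a functional
#' calcium-binding site. File coordinates are 1-based inclusive. A PS00018 row
#' falling outside every EF span is attached to the nearest EF-hand ending
#' within 5 residues, or dropped with a warning.
#'
#' @param table Tibble (or TSV path) with columns `protein_id`, `source_id`,
#'   `start`, `end`.
#' @return Tibble of domain hits per protein (`protein_id`, `kind`, `start`,
#'   `end`, `complete`, `ca_site`, `evidence = "external_table"`).
#' @export
load_external_domains <- function(table) {
  if (is.character(table)) {
    table <- read_table_schema(table, c(protein_id = "character",
                                        source_id = "character",
                                        start = "double", end = "double"))
  }
  stopifnot(all(c("protein_id", "source_id", "start", "end") %in% names(table)))
  table <- mutate(table, start = .data$start - 1)  # to 0-based half-open
  out <- table %>%
    filter(.data$source_id %in% c("PS50011", "PS50222")) %>%
    mutate(kind = if_else(.data$source_id == "PS50011", "KINASE", "EF_HAND"),
           complete = if_else(.data$kind == "KINASE", TRUE, NA),
           ca_site = if_else(.data$kind == "EF_HAND", FALSE, NA),
           evidence = "external_table") %>%
    select("protein_id", "kind", "start", "end", "complete", "ca_site",
           "evidence")
  ca_rows <- filter(table, .data$source_id == "PS00018")
  for (i in seq_len(nrow(ca_rows))) {
    pid <- ca_rows$protein_id[i]
    efs <- which(out$protein_id == pid & out$kind == "EF_HAND")
    inside <- efs[ca_rows$start[i] >= out$start[efs] &
                    ca_rows$end[i] <= out$end[efs]]
    if (length(inside)) {
      out$ca_site[inside[1]] <- TRUE
    } else {
      gap <- abs(out$end[efs] - ca_rows$start[i])
      near <- efs[gap <= 5]
      if (length(near)) {
        warn(paste0("PS00018 row outside EF span for ", pid,
                    "; attached to nearest EF-hand"))
        out$ca_site[near[which.min(gap[gap <= 5])]] <- TRUE
      } else {
        warn(paste0("PS00018 row outside any EF span for ", pid, "; dropped"))
      }
    }
  }
  arrange(out, .data$protein_id, .data$kind != "KINASE", .data$start)
}

#' Build a domain architecture from hits
#'
#' EF-hands are ordered N to C. Lobes are assigned when the protein has a
#' kinase domain and at least two EF-hands: the last two EF-hands form the
#' C-lobe of the calmodulin-like domain, all preceding ones the N-lobe.
#' The signature string is `K|` / `k|` / `|` for complete / incomplete /
#' absent kinase followed by one `E` per EF-hand, `*`-suffixed when it carries
#' a functional calcium-binding site (e.g. `"K|E*E*E*E*"`).
#'
#' @param hits Tibble of domain hits for one protein (as from
#'   [scan_domains()] or [load_external_domains()]).
#' @param protein_length Protein length in residues (used for validation).
#' @return A one-row tibble: `kinase_state`, `ef_count`, `ca_count`,
#'   `signature`, plus list-columns `ca_sites` (logical, N to C) and `lobes`.
#' @export
build_architecture <- function(hits, protein_length = NA_integer_) {
  if (is.null(hits) || !nrow(hits) || !"kind" %in% names(hits)) {
    return(tibble(kinase_state = "absent", ef_count = 0L, ca_count = 0L,
                  signature = architecture_signature("absent", logical()),
                  ca_sites = list(logical()), lobes = list(character())))
  }
  kin <- filter(hits, .data$kind == "KINASE")
  if (nrow(kin) > 1L) abort("more than one kinase domain hit",
                            class = "oryzakin_validation_error")
  ef <- hits %>% filter(.data$kind == "EF_HAND") %>% arrange(.data$start)
  if (!is.na(protein_length) && nrow(hits) &&
      any(hits$end > protein_length | hits$start < 0)) {
    abort("domain hit outside protein bounds",
          class = "oryzakin_validation_error")
  }
  kinase_state <- if (nrow(kin) == 0L) "absent"
                  else if (isTRUE(kin$complete[1])) "complete" else "incomplete"
  ca <- as.logical(ef$ca_site)
  n_ef <- length(ca)
  lobes <- if (kinase_state != "absent" && n_ef >= 2L) {
    c(rep("N", n_ef - 2L), rep("C", 2L))
  } else {
    rep("none", n_ef)
  }
  tibble(kinase_state = kinase_state, ef_count = n_ef,
         ca_count = sum(ca),
         signature = architecture_signature(kinase_state, ca),
         ca_sites = list(ca), lobes = list(lobes))
}

#' @rdname build_architecture
#' @param kinase_state One of `"complete"`, `"incomplete"`, `"absent"`.
#' @param ca_sites Logical vector of per-EF-hand calcium-site flags, N to C.
#' @export
architecture_signature <- function(kinase_state, ca_sites) {
  k <- switch(kinase_state, complete = "K", incomplete = "k", absent = "")
  paste0(k, "|", paste0(ifelse(ca_sites, "E*", "E"), collapse = ""))
}

#' Scan a protein table and build architectures
#'
#' @param proteins Tibble with `protein_id`, `sequence`.
#' @param external Optional external-domain tibble (see
#'   [load_external_domains()]); proteins present there use the external hits
#'   instead of the built-in scan.
#' @return `proteins` with architecture columns appended (`kinase_state`,
#'   `ef_count`, `ca_count`, `signature`, `ca_sites`, `lobes`).
#' @export
scan_proteins <- function(proteins, external = NULL) {
  ext <- if (!is.null(external)) load_external_domains(external) else NULL
  arch <- map(seq_len(nrow(proteins)), function(i) {
    pid <- proteins$protein_id[i]
    hits <- if (!is.null(ext) && pid %in% ext$protein_id) {
      filter(ext, .data$protein_id == pid) %>% select(-"protein_id")
    } else {
      scan_domains(proteins$sequence[i])
    }
    build_architecture(hits, nchar(proteins$sequence[i]))
  }) %>% list_rbind()
  bind_cols(proteins, arch)
}
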