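# Independent oracles used across the suite. These deliberately avoid the
# package's vectorised code paths: the pattern oracle walks windows
# element-by-element, and the chain oracle enumerates subsets exhaustively.

random_aa <- function(n, alphabet = oryzakin:::AA_STANDARD) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# naive exhaustive position-class matcher for fixed-width patterns
oracle_match_fixed <- function(sequence, pattern) {
  classes <- oryzakin:::prosite_fixed_classes(pattern)
  chars <- strsplit(sequence, "")[[1]]
  w <- length(classes)
  n <- length(chars)
  starts <- integer()
  if (n >= w) {
    for (s in 0:(n - w)) {
      ok <- TRUE
      for (j in seq_len(w)) {
        r <- chars[s + j]
        if (r == "X" || !(r %in% classes[[j]])) { ok <- FALSE; break }
      }
      if (ok) starts <- c(starts, s)
    }
  }
  starts
}

# exhaustive best-chain search: max subset of pairs forming a rank-monotone
# chain (either orientation) with consecutive gaps <= max_gap on both sides
oracle_best_chain <- function(ra, rb, max_gap = 25L) {
  n <- length(ra)
  if (!n) return(0L)
  best <- 0L
  valid_chain <- function(idx, inverted) {
    idx <- idx[order(ra[idx])]
    a <- ra[idx]
    b <- rb[idx]
    if (length(idx) == 1L) return(TRUE)
    da <- diff(a)
    db <- if (inverted) -diff(b) else diff(b)
    all(da >= 1L & da <= max_gap) && all(db >= 1L & db <= max_gap)
  }
  for (mask in seq_len(2^n) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    if (length(idx) <= best) next
    if (valid_chain(idx, FALSE) || valid_chain(idx, TRUE)) {
      best <- length(idx)
    }
  }
  best
}

# a strict calcium-binding EF loop and helpers to degrade it
canonical_ef_loop <- function() "DKDGDGTITTKEL"

flip_loop <- function(loop, at, to) {
  chars <- strsplit(loop, "")[[1]]
  chars[at] <- to
  paste(chars, collapse = "")
}

# architecture row constructor for splice-type tests
arch_row <- function(kinase_state, ca_sites) {
  ca <- as.logical(ca_sites)
  tibble::tibble(
    kinase_state = kinase_state, ef_count = length(ca), ca_count = sum(ca),
    signature = oryzakin::architecture_signature(kinase_state, ca),
    ca_sites = list(ca), lobes = list(rep("none", length(ca)))
  )
}

# embed motif strings in inert linker context
linker <- function(n) paste(rep("A", n), collapse = "")

small_sim_config <- function(seed = 11L) {
  sim_config(
    seed = seed,
    genomes = tibble::tibble(
      species = c("Ocult", "Owild", "Otet", "Otet", "Lout"),
      subgenome = c("", "", "BB", "CC", ""),
      ploidy_role = c("diploid", "diploid", "subgenome_of_allotetraploid",
                      "subgenome_of_allotetraploid", "outgroup"),
      n_chrom = 3L, genes_per_chrom = 40L
    ),
    family_counts = c(CCaMK = 1L, CPK = 8L, CRK = 2L, PEPRK = 1L, PPCK = 1L),
    duplication_events = tibble::tibble(
      ortholog_group = c("CPK1", "CPK2", "CPK3", "CPK4", "CPK5"),
      genome = "Owild",
      mode = c("WGD", "TD", "PD", "TRD", "DSD")
    )
  )
}
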