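# Average (isotope-weighted) residue masses in daltons, as used by
# ProtParam-style calculators; 'X' is treated as an average residue (110 Da).
AA_RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326,
  X = 110.0
)
WATER_MASS <- 18.01524

# pKa tables for the ionizable groups. "bjellqvist" follows the values used
# by the classic ProtParam/Compute-pI implementation; "emboss" is the
# alternative set from the EMBOSS iep tool.
PKA_TABLES <- list(
  bjellqvist = c(nterm = 7.50, cterm = 3.55, D = 4.05, E = 4.45, C = 9.00,
                 Y = 10.00, H = 5.98, K = 10.00, R = 12.00),
  emboss = c(nterm = 8.60, cterm = 3.60, D = 3.90, E = 4.10, C = 8.50,
             Y = 10.10, H = 6.50, K = 10.80, R = 12.50)
)

#' Protein molecular weight
#'
#' Sum of average residue masses plus one water, in kilodaltons. Additive up
#' to the water term: `molecular_weight(paste0(a, b))` equals
#' `molecular_weight(a) + molecular_weight(b)` minus one water.
#'
#' @param sequence Non-empty amino-acid string (`X` counts as an average
#'   residue of 110 Da).
#' @return Molecular weight in kDa.
#' @examples
#' molecular_weight("G")  # 0.0750671 kDa
#' @export
molecular_weight <- function(sequence) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  if (!length(chars)) abort("empty sequence", class = "oryzakin_input_error")
  masses <- AA_RESIDUE_MASS[chars]
  if (any(is.na(masses))) {
    abort(paste0("unknown residue: ",
                 paste(unique(chars[is.na(masses)]), collapse = ",")),
          class = "oryzakin_input_error")
  }
  (sum(masses) + WATER_MASS) / 1000
}

#' Net charge of a peptide at a given pH
#'
#' Henderson-Hasselbalch sum over the N-terminus, C-terminus and the side
#' chains of D, E, C, Y, H, K, R.
#'
#' @param sequence Amino-acid string.
#' @param pH pH value(s).
#' @param pka One of `"bjellqvist"`, `"emboss"`, or a named numeric vector
#'   with entries `nterm`, `cterm`, `D`, `E`, `C`, `Y`, `H`, `K`, `R`.
#' @return Net charge (vectorised over `pH`).
#' @export
net_charge <- function(sequence, pH, pka = "bjellqvist") {
  tab <- if (is.character(pka)) PKA_TABLES[[match.arg(pka, names(PKA_TABLES))]] else pka
  chars <- strsplit(toupper(sequence), "")[[1]]
  counts <- table(factor(chars, levels = AA_ALPHABET_X))
  pos_frac <- function(pk) 1 / (1 + 10^(pH - pk))   # protonated fraction
  neg_frac <- function(pk) 1 / (1 + 10^(pk - pH))   # deprotonated fraction
  pos <- pos_frac(tab[["nterm"]]) +
    counts[["H"]] * pos_frac(tab[["H"]]) +
    counts[["K"]] * pos_frac(tab[["K"]]) +
    counts[["R"]] * pos_frac(tab[["R"]])
  neg <- neg_frac(tab[["cterm"]]) +
    counts[["D"]] * neg_frac(tab[["D"]]) +
    counts[["E"]] * neg_frac(tab[["E"]]) +
    counts[["C"]] * neg_frac(tab[["C"]]) +
    counts[["Y"]] * neg_frac(tab[["Y"]])
  pos - neg
}

#' Isoelectric point by bisection
#'
#' Bisects the monotone net-charge curve until the absolute net charge at the
#' midpoint is below `tol` (or the bracket collapses to machine precision).
#' The result always lies between the smallest and largest pKa of the
#' ionizable groups present.
#'
#' @inheritParams net_charge
#' @param tol Convergence tolerance on |net charge|.
#' @return pI in pH units.
#' @export
isoelectric_point <- function(sequence, pka = "bjellqvist", tol = 1e-4) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  if (!length(chars)) abort("empty sequence", class = "oryzakin_input_error")
  lo <- 0; hi <- 14
  for (i in seq_len(500L)) {
    mid <- (lo + hi) / 2
    q <- net_charge(sequence, mid, pka)
    if (abs(q) < tol || (hi - lo) < 1e-13) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
  mid
}

#' N-myristoylation site prediction
#'
#' A glycine at position 2 is called a myristoylation site when the initiator
#' methionine is present and the sequence that follows the removable Met
#' satisfies the consensus `G-{EDRKHPFYW}-x(2)-[STAGCN]-{P}`.
#'
#' @param sequence Amino-acid string.
#' @return A one-row tibble: `myristoylation` (logical), `myr_site`
#'   (`"G2"` or `NA`).
#' @export
predict_myristoylation <- function(sequence) {
  seq <- toupper(sequence)
  ok <- FALSE
  if (nchar(seq) >= 7L && substr(seq, 1, 2) == "MG") {
    core <- substr(seq, 2, 7)  # after initiator-Met removal: positions 1..6
    pat <- parse_prosite("G-{EDRKHPFYW}-x(2)-[STAGCN]-{P}", id = "NMYR")
    ok <- nrow(match_pattern(core, pat)) > 0 &&
      any(match_pattern(core, pat)$start == 0L)
  }
  tibble(myristoylation = ok,
         myr_site = if (ok) "G2" else NA_character_)
}

#' N-terminal cysteine palmitoylation prediction
#'
#' Reports every cysteine within the first `window` residues as a candidate
#' S-palmitoylation site -- a transparent positional heuristic standing in for
#' dedicated lipidation predictors.
#'
#' @param sequence Amino-acid string.
#' @param window Number of N-terminal residues to inspect (default 25).
#' @return Integer vector of 1-based Cys positions (possibly empty).
#' @export
predict_palmitoylation <- function(sequence, window = 25L) {
  stopifnot(window >= 1L)
  head_seq <- substr(toupper(sequence), 1L, window)
  which(strsplit(head_seq, "")[[1]] == "C")
}

#' Localization rule from lipidation sites
#'
#' Proteins carrying a myristoylation and/or palmitoylation site are predicted
#' to target the cell membrane; all others, cytoplasm or nucleus.
#'
#' @param myristoylation Logical.
#' @param palm_sites Integer vector of palmitoylation positions.
#' @return `"membrane"` or `"cytoplasm_nucleus"`.
#' @export
predict_localization <- function(myristoylation, palm_sites) {
  if (isTRUE(myristoylation) || length(palm_sites) > 0L) "membrane"
  else "cytoplasm_nucleus"
}

#' Molecular-property table for a protein set
#'
#' @param proteins Tibble with `protein_id`, `sequence`.
#' @param pka pKa table selector, see [net_charge()].
#' @return Tibble: `protein_id`, `length`, `mw_kda`, `pi`, `myristoylation`,
#'   `myr_site`, `palm_sites` (list-column), `n_palm`, `localization`.
#' @export
protein_properties <- function(proteins, pka = "bjellqvist") {
  map(seq_len(nrow(proteins)), function(i) {
    s <- proteins$sequence[i]
    myr <- predict_myristoylation(s)
    palm <- predict_palmitoylation(s)
    tibble(protein_id = proteins$protein_id[i],
           length = nchar(s),
           mw_kda = molecular_weight(s),
           pi = isoelectric_point(s, pka),
           myristoylation = myr$myristoylation,
           myr_site = myr$myr_site,
           palm_sites = list(palm),
           n_palm = length(palm),
           localization = predict_localization(myr$myristoylation, palm))
  }) %>% list_rbind()
}
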