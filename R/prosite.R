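#' PROSITE-style pattern engine
#'
#' Parses the classic PROSITE pattern syntax into a list of position elements
#' and matches it against amino-acid sequences. Supported elements: literal
#' residues (`D`), allowed sets (`[DNS]`), forbidden sets (`{GP}`), the
#' wildcard `x`, and repeated wildcards `x(2)` / `x(2,4)`. The ambiguity
#' residue `X` never satisfies any position, including wildcards, so motif
#' calls stay conservative on partially determined sequences.
#'
#' @param pattern Pattern string, e.g. `"D-x-[DNS]-{ILVFYW}"`. A trailing
#'   period (as printed in PROSITE entries) is tolerated.
#' @param id Identifier carried along with the parsed pattern.
#' @return An object of class `prosite_pattern`: a list with `id` and
#'   `elements`, each element a list with fields `kind`
#'   (`literal`/`allowed`/`forbidden`/`wildcard`), `residues`, `min`, `max`.
#' @examples
#' pat <- parse_prosite("D-x-[DNS]-{ILVFYW}-x(2)-[DE]", id = "demo")
#' match_pattern("DKDAAADAAAAA", pat)
#' @export
parse_prosite <- function(pattern, id = "pattern") {
  stopifnot(is.character(pattern), length(pattern) == 1L)
  txt <- sub("\\.$", "", trimws(pattern))
  if (!nzchar(txt)) abort("empty PROSITE pattern", class = "oryzakin_pattern_error")
  parts <- strsplit(txt, "-", fixed = TRUE)[[1]]
  elements <- lapply(parts, parse_prosite_element)
  structure(list(id = id, elements = elements), class = "prosite_pattern")
}

parse_prosite_element <- function(tok) {
  tok <- trimws(tok)
  bad <- function() {
    abort(paste0("unparseable PROSITE element: '", tok, "'"),
          class = "oryzakin_pattern_error")
  }
  if (!nzchar(tok)) bad()
  rep_match <- regmatches(tok, regexec("^([^()]+)\\((\\d+)(?:,(\\d+))?\\)$", tok))[[1]]
  rep_min <- 1L
  rep_max <- 1L
  core <- tok
  if (length(rep_match)) {
    core <- rep_match[2]
    rep_min <- as.integer(rep_match[3])
    rep_max <- if (nzchar(rep_match[4])) as.integer(rep_match[4]) else rep_min
    if (rep_min < 1L || rep_max < rep_min) bad()
  }
  if (core == "x") {
    return(list(kind = "wildcard", residues = character(), min = rep_min, max = rep_max))
  }
  if (grepl("^\\[[A-Z]+\\]$", core)) {
    res <- strsplit(substr(core, 2, nchar(core) - 1), "")[[1]]
    if (!all(res %in% AA_STANDARD)) bad()
    return(list(kind = "allowed", residues = res, min = rep_min, max = rep_max))
  }
  if (grepl("^\\{[A-Z]+\\}$", core)) {
    res <- strsplit(substr(core, 2, nchar(core) - 1), "")[[1]]
    if (!all(res %in% AA_STANDARD)) bad()
    return(list(kind = "forbidden", residues = res, min = rep_min, max = rep_max))
  }
  if (grepl("^[A-Z]$", core) && core %in% AA_STANDARD) {
    return(list(kind = "literal", residues = core, min = rep_min, max = rep_max))
  }
  bad()
}

#' @rdname parse_prosite
#' @details `prosite_element_ok()` tests one residue against one parsed
#'   element; exported for use as a brute-force oracle in verification code.
#' @param residue Single residue character.
#' @param element One element of a parsed pattern.
#' @export
prosite_element_ok <- function(residue, element) {
  if (residue == "X") return(FALSE)
  switch(element$kind,
    wildcard  = residue %in% AA_STANDARD,
    literal   = residue == element$residues,
    allowed   = residue %in% element$residues,
    forbidden = residue %in% AA_STANDARD && !(residue %in% element$residues),
    FALSE
  )
}

# Expand a parsed pattern into per-position residue sets when it has no
# variable-length elements; NULL otherwise. Fixed-width patterns then match
# by vectorised set membership, which is what the scanners rely on.
prosite_fixed_classes <- function(pattern) {
  if (any(map_int(pattern$elements, "min") != map_int(pattern$elements, "max"))) {
    return(NULL)
  }
  classes <- list()
  for (el in pattern$elements) {
    set <- switch(el$kind,
      wildcard  = AA_STANDARD,
      literal   = el$residues,
      allowed   = el$residues,
      forbidden = setdiff(AA_STANDARD, el$residues)
    )
    classes <- c(classes, rep(list(set), el$min))
  }
  classes
}

#' Match a PROSITE pattern against a sequence
#'
#' Reports every match at every start position; overlapping matches are all
#' returned, sorted by start. Coordinates are 0-based half-open, the
#' package-wide internal convention.
#'
#' @param sequence Amino-acid string (uppercase; `X` allowed but never matches
#'   any pattern position).
#' @param pattern A `prosite_pattern` from [parse_prosite()], or a pattern
#'   string (parsed on the fly).
#' @return A tibble with columns `start`, `end` (0-based half-open).
#' @examples
#' match_pattern("DKDGDGTITTKEL", ps00018_pattern())
#' @export
match_pattern <- function(sequence, pattern) {
  if (is.character(pattern)) pattern <- parse_prosite(pattern)
  stopifnot(inherits(pattern, "prosite_pattern"))
  chars <- strsplit(toupper(sequence), "")[[1]]
  n <- length(chars)
  fixed <- prosite_fixed_classes(pattern)
  if (!is.null(fixed)) {
    w <- length(fixed)
    if (n < w) return(tibble(start = integer(), end = integer()))
    ok <- rep(TRUE, n - w + 1L)
    for (j in seq_len(w)) {
      ok <- ok & chars[j:(n - w + j)] %in% fixed[[j]]
    }
    starts <- which(ok) - 1L
    return(tibble(start = starts, end = starts + w))
  }
  # variable-width fallback: recursive element-by-element match
  ends_from <- function(pos, idx) {
    if (idx > length(pattern$elements)) return(pos)
    el <- pattern$elements[[idx]]
    out <- integer()
    for (k in el$min:el$max) {
      if (pos + k > n) break
      seg <- chars[seq_len(k) + pos]
      if (all(vapply(seg, prosite_element_ok, logical(1), element = el))) {
        out <- c(out, ends_from(pos + k, idx + 1L))
      } else if (el$kind != "wildcard") {
        break
      }
    }
    unique(out)
  }
  res <- map(0:(max(n - 1L, 0L)), function(s) {
    ends <- ends_from(s, 1L)
    if (length(ends)) tibble(start = s, end = ends) else NULL
  })
  out <- list_rbind(res)
  if (nrow(out)) arrange(out, .data$start, .data$end) else tibble(start = integer(), end = integer())
}

#' The calcium-binding-site pattern (PROSITE PS00018)
#'
#' The canonical 12-coordinating-position EF-hand loop pattern
#' `D-x-[DNS]-{ILVFYW}-[DENSTG]-[DNQGHRK]-{GP}-[LIVMC]-[DENQSTAGC]-x(2)-[DE]-[LIVMFYW]`,
#' spanning 13 residues. A strict match constitutes a functional
#' calcium-binding site.
#'
#' @return A parsed `prosite_pattern`.
#' @export
ps00018_pattern <- function() {
  parse_prosite(
    "D-x-[DNS]-{ILVFYW}-[DENSTG]-[DNQGHRK]-{GP}-[LIVMC]-[DENQSTAGC]-x(2)-[DE]-[LIVMFYW]",
    id = "PS00018"
  )
}

# Loop positions (1-based within the 13-residue window) whose side chains
# coordinate the calcium ion; the relaxed "degenerated EF-hand" rule operates
# on these.
EF_COORDINATING_POSITIONS <- c(1L, 3L, 5L, 9L, 12L)
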