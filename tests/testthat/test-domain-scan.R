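test_that("EF-hand scanning separates functional, degenerate, and dead loops", {
  loop <- canonical_ef_loop()
  ctx <- function(s) paste0(linker(20), s, linker(20))
  strict <- scan_ef_hands(ctx(loop))
  expect_equal(nrow(strict), 1L)
  expect_true(strict$ca_site)
  expect_equal(strict$start, 20L)

  # position-5 class violated only -> degenerate hit (relaxed rule)
  one_flip <- flip_loop(loop, 5, "A")
  hit <- scan_ef_hands(ctx(one_flip))
  expect_equal(nrow(hit), 1L)
  expect_false(hit$ca_site)

  # two interior coordinating violations still degenerate
  two_flip <- flip_loop(flip_loop(loop, 3, "A"), 5, "A")
  hit2 <- scan_ef_hands(ctx(two_flip))
  expect_equal(nrow(hit2), 1L)
  expect_false(hit2$ca_site)

  # three coordinating violations -> no hit
  three_flip <- flip_loop(two_flip, 9, "K")
  expect_equal(nrow(scan_ef_hands(ctx(three_flip))), 0L)

  # both anchors destroyed -> no hit even with only two violations
  no_anchor <- flip_loop(flip_loop(loop, 1, "A"), 12, "A")
  expect_equal(nrow(scan_ef_hands(ctx(no_anchor))), 0L)
})

test_that("overlapping EF candidates resolve greedily with strict preferred", {
  # two loops 13 apart: both kept, non-overlapping
  s <- paste0(linker(5), canonical_ef_loop(), canonical_ef_loop(), linker(5))
  hits <- scan_ef_hands(s)
  expect_equal(hits$start, c(5L, 18L))
  expect_true(all(hits$ca_site))
  # a hit never overlaps the previous one
  expect_true(all(diff(hits$start) >= 13L))
})

test_that("kinase anchors drive completeness and the span rule", {
  complete <- paste0(linker(10), "AVIK", linker(110), "HRD", linker(75),
                     "DFG", linker(10))
  hit <- scan_kinase(complete)
  expect_equal(nrow(hit), 1L)
  expect_true(hit$complete)

  # anchors in order but span below 180 -> incomplete
  short <- paste0(linker(10), "AVIK", linker(60), "HRD", linker(60),
                  "DFG", linker(10))
  expect_false(scan_kinase(short)$complete)

  # span above 340 -> incomplete
  long <- paste0(linker(10), "AVIK", linker(200), "HRD", linker(150),
                 "DFG", linker(10))
  expect_false(scan_kinase(long)$complete)

  # subset of anchors -> incomplete; none -> no hit
  subset <- paste0(linker(10), "AVIK", linker(110), "HRD", linker(40))
  expect_false(scan_kinase(subset)$complete)
  expect_equal(nrow(scan_kinase(strrep("A", 300))), 0L)

  # anchors out of order never count as complete
  disordered <- paste0(linker(10), "DFG", linker(110), "HRD", linker(75),
                       "AVIK", linker(10))
  expect_false(scan_kinase(disordered)$complete)
})

test_that("architectures order EF-hands, assign lobes, and build signatures", {
  mk_hits <- function(kin_complete, ca_flags) {
    kin <- if (!is.na(kin_complete)) {
      tibble::tibble(kind = "KINASE", start = 0L, end = 250L,
                     complete = kin_complete, ca_site = NA,
                     evidence = "builtin_scan")
    } else {
      NULL
    }
    ef <- if (length(ca_flags)) {
      tibble::tibble(kind = "EF_HAND",
                     start = 260L + 30L * (seq_along(ca_flags) - 1L),
                     end = 273L + 30L * (seq_along(ca_flags) - 1L),
                     complete = NA, ca_site = as.logical(ca_flags),
                     evidence = "builtin_scan")
    } else {
      NULL
    }
    dplyr::bind_rows(kin, ef)
  }
  a <- build_architecture(mk_hits(TRUE, c(TRUE, TRUE, TRUE, TRUE)), 400L)
  expect_equal(a$signature, "K|E*E*E*E*")
  expect_equal(a$lobes[[1]], c("N", "N", "C", "C"))

  # 3 EFs, calcium site only in the last: the site sits in the C-lobe
  b <- build_architecture(mk_hits(TRUE, c(FALSE, FALSE, TRUE)), 400L)
  expect_equal(b$lobes[[1]], c("N", "C", "C"))
  expect_equal(b$signature, "K|EEE*")
  expect_equal(b$lobes[[1]][which(b$ca_sites[[1]])], "C")

  # no hits at all
  none <- build_architecture(mk_hits(NA, logical()), 100L)
  expect_equal(none$kinase_state, "absent")
  expect_equal(none$signature, "|")

  # kinase absent or < 2 EFs: no lobes
  c1 <- build_architecture(mk_hits(NA, c(TRUE, TRUE)), 400L)
  expect_equal(c1$lobes[[1]], c("none", "none"))
  c2 <- build_architecture(mk_hits(TRUE, TRUE), 400L)
  expect_equal(c2$lobes[[1]], "none")

  two_kin <- dplyr::bind_rows(mk_hits(TRUE, logical()),
                              mk_hits(TRUE, logical()))
  expect_error(build_architecture(two_kin, 600L),
               class = "oryzakin_validation_error")
})

test_that("external domain tables map profile hits onto architectures", {
  tab <- tibble::tibble(
    protein_id = c("p1", "p1", "p1", "p2", "p3", "p3"),
    source_id = c("PS50011", "PS50222", "PS00018", "PS50222", "PS50222",
                  "PS00018"),
    start = c(10, 300, 302, 50, 100, 200),
    end = c(280, 330, 314, 80, 113, 212))
  expect_warning(hits <- load_external_domains(tab), "dropped")
  p1 <- hits[hits$protein_id == "p1", ]
  expect_equal(p1$kind, c("KINASE", "EF_HAND"))
  expect_true(p1$complete[1])
  expect_true(p1$ca_site[2])            # PS00018 inside the EF span
  expect_false(hits$ca_site[hits$protein_id == "p2"])  # EF alone
  expect_false(hits$ca_site[hits$protein_id == "p3"])  # PS00018 too far
})

test_that("every strict calcium-site call contains a strict pattern match", {
  set.seed(99)
  for (i in 1:40) {
    s <- paste0(random_aa(30), canonical_ef_loop(),
                random_aa(20), flip_loop(canonical_ef_loop(), 5, "A"),
                random_aa(30))
    hits <- scan_ef_hands(s)
    for (j in seq_len(nrow(hits))) {
      window <- substr(s, hits$start[j] + 1, hits$end[j])
      strict <- nrow(match_pattern(window, ps00018_pattern())) > 0
      expect_equal(hits$ca_site[j], strict)
    }
  }
})
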