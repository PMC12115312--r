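make_expr <- function(fpkm_by_gene_tissue, n_rep = 1L) {
  # fpkm_by_gene_tissue: tibble gene_id, tissue, fpkm
  vals <- tidyr::expand_grid(fpkm_by_gene_tissue,
                             replicate = paste0("rep", seq_len(n_rep))) |>
    dplyr::mutate(sample = paste(tissue, replicate, sep = "_")) |>
    dplyr::select(gene_id, sample, fpkm)
  meta <- tidyr::expand_grid(tissue = unique(fpkm_by_gene_tissue$tissue),
                             replicate = paste0("rep", seq_len(n_rep))) |>
    dplyr::mutate(sample = paste(tissue, replicate, sep = "_"),
                  species = "sp") |>
    dplyr::select(sample, species, tissue, replicate)
  list(values = vals, sample_meta = meta)
}

pair_map <- tibble::tibble(group = "g", gene_a = "A", subgenome_a = "BB",
                           gene_b = "B", subgenome_b = "CC")

heb_one <- function(fa, fb, ...) {
  expr <- make_expr(tibble::tibble(gene_id = c("A", "B"), tissue = "root",
                                   fpkm = c(fa, fb)))
  classify_heb(pair_map, expr, ...)
}

test_that("the expression filter is strictly greater-than on replicate means", {
  expr <- make_expr(tibble::tibble(
    gene_id = c("x", "y", "z", "z"),
    tissue = c("root", "root", "root", "stem"),
    fpkm = c(0.5, 0.6, 0.2, 1.0)))
  # replicate-mean rule: z has (0.2, 1.0) across tissues, but within root only 0.2
  f <- filter_expressed(expr)
  expect_false(f$expressed[f$gene_id == "x"])   # 0.5 exactly: not expressed
  expect_true(f$expressed[f$gene_id == "y"])    # 0.6: expressed
  # replicates averaged before the threshold
  expr2 <- make_expr(tibble::tibble(gene_id = "w", tissue = "root",
                                    fpkm = 0.6), n_rep = 2L)
  expr2$values$fpkm <- c(0.2, 1.0)
  f2 <- filter_expressed(expr2)
  expect_true(f2$expressed)
  expect_equal(f2$mean_fpkm, 0.6)
  # unknown tissue labels are data errors
  expr3 <- make_expr(tibble::tibble(gene_id = "x", tissue = "root", fpkm = 1))
  expr3$sample_meta$tissue <- "callus"
  expect_error(filter_expressed(expr3), class = "oryzakin_data_error")
})

test_that("pair normalization and its degenerate case behave as specified", {
  expect_equal(unname(normalize_pair(10, 10)), c(0.5, 0.5))
  expect_equal(unname(normalize_pair(3, 1)), c(0.75, 0.25))
  expect_equal(unname(normalize_pair(0, 5)), c(0, 1))
  expect_error(normalize_pair(0, 0), class = "oryzakin_input_error")
})

test_that("bias categories follow nearest-ideal with ties to balanced", {
  expect_equal(heb_one(5, 5)$category, "BALANCED")
  expect_equal(heb_one(10, 0)$category, "DOM_A")
  expect_equal(heb_one(0, 10)$category, "DOM_B")
  # p = 0.75 is equidistant from dominant and balanced ideals: tie -> BALANCED
  r <- heb_one(7.5, 2.5)
  expect_equal(r$p_a, 0.75)
  expect_equal(r$d_dom_a, r$d_balanced, tolerance = 1e-12)
  expect_equal(r$d_dom_a, sqrt(2 * 0.25^2), tolerance = 1e-12)
  expect_equal(r$category, "BALANCED")
  # neither expressed -> NOT_EXPRESSED with undefined contributions
  r0 <- heb_one(0.4, 0.3)
  expect_equal(r0$category, "NOT_EXPRESSED")
  expect_true(is.na(r0$p_a))
  # one sub-threshold member keeps its measured value
  r1 <- heb_one(9.5, 0.4)
  expect_equal(r1$category, "DOM_A")
  expect_equal(r1$p_a, 9.5 / 9.9)
  # require_both drops such pairs to NOT_EXPRESSED
  expect_equal(heb_one(9.5, 0.4, require_both = TRUE)$category,
               "NOT_EXPRESSED")
})

test_that("the decision boundary sits exactly at a dominant share of 0.75", {
  for (p in seq(0.50, 1.00, by = 0.005)) {
    cat_p <- heb_one(100 * p, 100 * (1 - p))$category
    expect_equal(cat_p, if (p > 0.75) "DOM_A" else "BALANCED")
  }
})

test_that("bias calls are invariant to rescaling both members", {
  set.seed(21)
  for (i in 1:20) {
    fa <- runif(1, 0.6, 50)
    fb <- runif(1, 0.6, 50)
    base <- heb_one(fa, fb)$category
    for (c_mult in c(0.1, 3, 40)) {
      if (max(fa, fb) * c_mult > 0.5) {
        expect_equal(heb_one(fa * c_mult, fb * c_mult)$category, base)
      }
    }
  }
})

test_that("atlas summaries find dominant tissues and record display transforms", {
  expr <- make_expr(tibble::tibble(
    gene_id = rep(c("g1", "g2", "g0"), each = 4),
    tissue = rep(c("root", "stem", "leaf", "panicle"), 3),
    fpkm = c(20, 2, 1, 1,   5, 5, 5, 5,   0, 0, 0, 0)))
  atlas <- summarize_atlas(expr)
  s1 <- atlas$summary[atlas$summary$gene_id == "g1", ]
  expect_equal(s1$dominant_tissue, "root")
  expect_true(s1$predominant)
  expect_equal(s1$predominance_ratio, 10)
  s2 <- atlas$summary[atlas$summary$gene_id == "g2", ]
  expect_false(s2$predominant)
  expect_equal(s2$predominance_ratio, 1)
  s0 <- atlas$summary[atlas$summary$gene_id == "g0", ]
  expect_false(s0$expressed_anywhere)
  # zero FPKM displays as log10(0.01) = -2
  z <- atlas$tissue_means[atlas$tissue_means$gene_id == "g0", ]
  expect_true(all(z$log10_display == -2))
  expect_true(all(z$log2_display == 0))
})

test_that("pair comparison calls silence, redundancy and divergence", {
  prof <- function(a, b) make_expr(tibble::tibble(
    gene_id = rep(c("A", "B"), each = 4),
    tissue = rep(c("root", "stem", "leaf", "panicle"), 2),
    fpkm = c(a, b)))
  # exactly one silent member
  r <- compare_pair_expression("A", "B", prof(c(0, 0, 0, 0), c(5, 8, 2, 1)))
  expect_equal(r$call, "one_silent")
  # identical profiles are redundant
  r2 <- compare_pair_expression("A", "B", prof(c(5, 8, 2, 1), c(5, 8, 2, 1)))
  expect_equal(r2$call, "redundant")
  expect_equal(r2$mean_abs_log2_ratio, 0)
  # anticorrelated profiles diverge: r = cor((1,1,1,100),(100,1,1,1)) < 0.8
  r3 <- compare_pair_expression("A", "B",
                                prof(c(1, 1, 1, 100), c(100, 1, 1, 1)))
  expect_equal(r3$call, "diverged")
  expect_lt(r3$concordance, 0)
  # fewer than 3 tissues: concordance undefined, ratios decide
  short <- make_expr(tibble::tibble(gene_id = rep(c("A", "B"), each = 2),
                                    tissue = rep(c("root", "stem"), 2),
                                    fpkm = c(4, 4, 4, 4)))
  r4 <- compare_pair_expression("A", "B", short)
  expect_true(is.na(r4$concordance))
  expect_equal(r4$call, "redundant")
  expect_error(compare_pair_expression("A", "nope", short),
               class = "oryzakin_data_error")
})
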