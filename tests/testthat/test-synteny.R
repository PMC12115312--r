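make_orders <- function(n_per_chrom, chroms = c("c1", "c2"), genome = "G") {
  dplyr::bind_rows(lapply(chroms, function(ch) {
    tibble::tibble(gene_id = paste0(genome, "_", ch, "_", seq_len(n_per_chrom)),
                   genome = genome, subgenome = "", chromosome = ch,
                   start = (seq_len(n_per_chrom) - 1) * 1000,
                   end = (seq_len(n_per_chrom) - 1) * 1000 + 500,
                   strand = "+")
  })) |> assign_order_ranks()
}

test_that("chain DP recovers planted blocks and honours the anchor threshold", {
  orders <- make_orders(40)
  anchor_idx <- c(3, 5, 8, 9, 12, 15, 17, 20)
  pairs <- tibble::tibble(
    gene_a = paste0("G_c1_", anchor_idx),
    gene_b = paste0("G_c2_", anchor_idx + 5),
    score = 500)
  blocks <- find_collinear_blocks(pairs, orders)
  expect_equal(length(unique(blocks$block_id)), 1L)
  expect_equal(nrow(blocks), 8L)
  expect_equal(unique(blocks$orientation), "same")
  # 4 anchors with min_anchors = 5: nothing
  expect_equal(nrow(find_collinear_blocks(pairs[1:4, ], orders)), 0L)
  # but lowering min_anchors only ever adds blocks
  b4 <- find_collinear_blocks(pairs[1:4, ], orders, min_anchors = 4L)
  expect_equal(nrow(b4), 4L)
})

test_that("inverted-orientation chains are found", {
  orders <- make_orders(30)
  idx <- c(2, 5, 8, 11, 14, 17)
  pairs <- tibble::tibble(
    gene_a = paste0("G_c1_", idx),
    gene_b = paste0("G_c2_", rev(idx)),
    score = 500)
  blocks <- find_collinear_blocks(pairs, orders)
  expect_equal(nrow(blocks), 6L)
  expect_equal(unique(blocks$orientation), "inverted")
})

test_that("the max_gap constraint splits distant runs", {
  orders <- make_orders(80)
  idx <- c(1:5, 40:44)  # two runs separated by a rank gap of 35 > 25
  pairs <- tibble::tibble(
    gene_a = paste0("G_c1_", idx), gene_b = paste0("G_c2_", idx), score = 500)
  blocks <- find_collinear_blocks(pairs, orders, min_anchors = 5L)
  expect_equal(length(unique(blocks$block_id)), 2L)
  expect_true(all(table(blocks$block_id) == 5L))
})

test_that("DP chain size equals the exhaustive subset oracle on random instances", {
  set.seed(77)
  orders <- make_orders(30)
  for (i in 1:60) {
    n <- sample(4:12, 1)
    ra <- sample(0:29, n)
    rb <- sample(0:29, n)
    pairs <- tibble::tibble(gene_a = paste0("G_c1_", ra + 1),
                            gene_b = paste0("G_c2_", rb + 1), score = 500)
    blocks <- find_collinear_blocks(pairs, orders, min_anchors = 1L)
    got <- if (nrow(blocks)) max(blocks$n_anchors) else 0L
    expect_equal(got, oracle_best_chain(ra, rb))
  }
})

test_that("duplication modes follow the definitional rule table", {
  orders <- make_orders(40)
  add_gene <- function(orders, gene_id, chrom, after_rank, genome = "G") {
    dplyr::bind_rows(
      dplyr::select(orders, -"order_rank"),
      tibble::tibble(gene_id = gene_id, genome = genome, subgenome = "",
                     chromosome = chrom, start = after_rank * 1000 + 500,
                     end = after_rank * 1000 + 900, strand = "+")) |>
      assign_order_ranks()
  }
  # tandem copy right after gene 10 on c1; proximal copy 7 ranks from gene 20
  orders2 <- orders |>
    add_gene("td_copy", "c1", 9) |>
    add_gene("pd_copy", "c1", 26)
  fam_pairs <- tibble::tibble(
    gene_a = c("G_c1_10", "G_c1_20"),
    gene_b = c("td_copy", "pd_copy"),
    score = 500)
  calls <- classify_duplications(fam_pairs, blocks = tibble::tibble(
    block_id = integer(), chrom_a = character(), chrom_b = character(),
    orientation = character(), gene_a = character(), gene_b = character(),
    rank_a = integer(), rank_b = integer(), n_anchors = integer()),
    orders = orders2)
  expect_equal(calls$mode[calls$gene_id == "td_copy"], "TD")
  expect_equal(calls$mode[calls$gene_id == "pd_copy"], "PD")
  pd_rank <- abs(diff(orders2$order_rank[match(c("G_c1_20", "pd_copy"),
                                               orders2$gene_id)]))
  expect_gt(pd_rank, 1)
  expect_lte(pd_rank, 10)

  # an anchor pair of a >= 5-anchor block is WGD even on the same chromosome
  idx <- c(3, 6, 9, 12, 15)
  wgd_pairs <- tibble::tibble(gene_a = paste0("G_c1_", idx),
                              gene_b = paste0("G_c2_", idx), score = 500)
  blocks <- find_collinear_blocks(wgd_pairs, orders)
  calls2 <- classify_duplications(wgd_pairs[3, ], blocks, orders)
  expect_true(all(calls2$mode == "WGD"))

  # genes without any pair are singletons
  calls3 <- classify_duplications(fam_pairs[0, ], blocks[0, ], orders,
                                  family_genes = "G_c1_1")
  expect_equal(calls3$mode, "SINGLETON")
  expect_true(is.na(calls3$partner))
})

test_that("transposed requires exactly one ancestral locus; dispersed is the remainder", {
  orders <- make_orders(40)
  add <- function(orders, gene_id, chrom, pos) {
    dplyr::bind_rows(
      dplyr::select(orders, -"order_rank"),
      tibble::tibble(gene_id = gene_id, genome = "G", subgenome = "",
                     chromosome = chrom, start = pos, end = pos + 400,
                     strand = "+")) |>
      assign_order_ranks()
  }
  orders2 <- orders |> add("trd_copy", "c2", 90500) |>
    add("dsd_copy", "c2", 95500)
  # outgroup collinearity: gene G_c1_10 anchors a block vs the outgroup
  out_blocks <- tibble::tibble(
    block_id = 1L, chrom_a = "G:c1", chrom_b = "OUT:c1",
    orientation = "same",
    gene_a = paste0("G_c1_", 8:12), gene_b = paste0("O_c1_", 8:12),
    rank_a = 7:11, rank_b = 7:11, n_anchors = 5L)
  pairs <- tibble::tibble(
    gene_a = c("G_c1_10", "G_c1_30"),
    gene_b = c("trd_copy", "dsd_copy"), score = 500)
  calls <- classify_duplications(pairs, blocks = out_blocks[0, ],
                                 orders = orders2,
                                 outgroup_blocks = out_blocks)
  expect_equal(calls$mode[calls$gene_id == "trd_copy"], "TRD")
  expect_equal(calls$mode[calls$gene_id == "dsd_copy"], "DSD")
})

test_that("every family gene receives exactly one call and the CNV matrix counts copies", {
  cfg <- small_sim_config()
  study <- simulate_study(cfg)
  pl <- run_pipeline(study = study)
  fam_genes <- study$orders$gene_id[study$orders$family != "none" &
                                      study$orders$genome !=
                                        study$outgroup_genome]
  expect_setequal(pl$duplications$gene_id, fam_genes)
  expect_equal(anyDuplicated(pl$duplications$gene_id), 0L)
  cnv <- pl$cnv
  # the tandem event doubles its group's count in the carrier genome only
  expect_equal(cnv$Owild[cnv$ortholog_group == "CPK2"], 2L)
  expect_equal(cnv$Ocult[cnv$ortholog_group == "CPK2"], 1L)
  # the dispersed-duplication group is absent from the outgroup
  expect_equal(cnv$Lout[cnv$ortholog_group == "CPK5"], 0L)
})

test_that("similarity pairs keep related sequences and drop random ones", {
  set.seed(41)
  a <- random_aa(120)
  prot <- tibble::tibble(protein_id = c("a1", "a2", "r1", "r2"),
                         sequence = c(a, a, random_aa(100), random_aa(100)))
  pairs <- compute_similarity_pairs(prot, floor = 100)
  expect_true(any(pairs$gene_a == "a1" & pairs$gene_b == "a2"))
  expect_false(any(pairs$gene_a == "r1" & pairs$gene_b == "r2"))
  expect_equal(pairs$score, sort(pairs$score, decreasing = TRUE))
  expect_equal(nrow(compute_similarity_pairs(prot[1, ])), 0L)
  expect_error(compute_similarity_pairs(prot, floor = 0),
               class = "oryzakin_config_error")
})
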