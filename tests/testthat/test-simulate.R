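test_that("generated proteins rescan to their planted layout exactly", {
  set.seed(17)
  tpl <- oryzakin:::default_architecture_templates()
  layouts <- list(
    CPK = tpl$CPK, CCaMK = tpl$CCaMK, CRK = tpl$CRK, PPCK = tpl$PPCK,
    mixed1 = list(kinase = "complete", ca_sites = c(TRUE, FALSE, TRUE),
                  myristoylation = FALSE),
    mixed2 = list(kinase = "incomplete", ca_sites = c(FALSE, FALSE),
                  myristoylation = TRUE),
    mixed3 = list(kinase = "absent", ca_sites = c(TRUE, TRUE, FALSE, TRUE),
                  myristoylation = FALSE)
  )
  for (nm in names(layouts)) {
    for (rep in 1:10) {
      gp <- generate_protein(paste0(nm, rep), nm, layouts[[nm]])
      arch <- build_architecture(scan_domains(gp$protein$sequence),
                                 nchar(gp$protein$sequence))
      expect_equal(arch$kinase_state, layouts[[nm]]$kinase, info = nm)
      expect_equal(arch$ef_count, length(layouts[[nm]]$ca_sites), info = nm)
      expect_equal(arch$ca_sites[[1]], as.logical(layouts[[nm]]$ca_sites),
                   info = nm)
    }
  }
  expect_error(
    generate_protein("x", "CPK",
                     list(kinase = "complete", ca_sites = rep(TRUE, 7),
                          myristoylation = FALSE)),
    class = "oryzakin_config_error")
})

test_that("CRK and CCaMK canonical proteins carry their published EF layouts", {
  set.seed(18)
  tpl <- oryzakin:::default_architecture_templates()
  crk <- generate_protein("crk", "CRK", tpl$CRK)
  hits <- scan_ef_hands(crk$protein$sequence)
  expect_lte(nrow(hits), 1L)
  expect_false(any(hits$ca_site))
  ccamk <- generate_protein("ccamk", "CCaMK", tpl$CCaMK)
  hits2 <- scan_ef_hands(ccamk$protein$sequence)
  expect_equal(nrow(hits2), 3L)
  expect_true(all(hits2$ca_site))
})

test_that("template mutation preserves motifs and the lipidation signal", {
  set.seed(19)
  tpl <- oryzakin:::default_architecture_templates()
  base <- generate_protein("b", "CPK", tpl$CPK)
  for (i in 1:5) {
    mut <- generate_protein(paste0("m", i), "CPK", tpl$CPK,
                            template = base$template, mutate_rate = 0.2)
    arch <- build_architecture(scan_domains(mut$protein$sequence),
                               nchar(mut$protein$sequence))
    expect_equal(arch$signature, "K|E*E*E*E*")
    expect_true(predict_myristoylation(mut$protein$sequence)$myristoylation)
    expect_false(identical(mut$protein$sequence, base$protein$sequence))
  }
})

test_that("the genome set plants each duplication signature verifiably", {
  cfg <- small_sim_config()
  gs <- generate_genome_set(cfg)
  truth <- gs$dup_truth
  orders <- gs$orders
  rank_of <- function(g) orders$order_rank[match(g, orders$gene_id)]
  chrom_of <- function(g) orders$chromosome[match(g, orders$gene_id)]
  # tandem: adjacent ranks; proximal: within 10 but not adjacent
  td <- truth[truth$mode == "TD", ]
  expect_equal(abs(rank_of(td$gene_parent) - rank_of(td$gene_copy)), 1L)
  pd <- truth[truth$mode == "PD", ]
  d <- abs(rank_of(pd$gene_parent) - rank_of(pd$gene_copy))
  expect_true(d > 1 && d <= 10)
  # WGD: the pair is flanked by a chain of >= anchor-count homolog pairs,
  # verified by the exhaustive chain oracle on the emitted tables
  wgd <- truth[truth$mode == "WGD", ]
  gpairs <- gs$intra_pairs[gs$intra_pairs$genome == wgd$genome, ]
  pc <- chrom_of(wgd$gene_parent)
  cc <- chrom_of(wgd$gene_copy)
  ca <- chrom_of(gpairs$gene_a)
  cb <- chrom_of(gpairs$gene_b)
  fwd <- ca == pc & cb == cc
  bwd <- ca == cc & cb == pc
  ra <- c(rank_of(gpairs$gene_a[fwd]), rank_of(gpairs$gene_b[bwd]))
  rb <- c(rank_of(gpairs$gene_b[fwd]), rank_of(gpairs$gene_a[bwd]))
  expect_gte(oracle_best_chain(ra, rb), cfg$wgd_block_anchor_count)
  expect_true(wgd$gene_parent %in% c(gpairs$gene_a[fwd | bwd],
                                     gpairs$gene_b[fwd | bwd]))
  # transposed: parent at an ancestral locus, copy not, different chromosome
  trd <- truth[truth$mode == "TRD", ]
  expect_false(chrom_of(trd$gene_parent) == chrom_of(trd$gene_copy))
  out_groups <- orders$ortholog_group[orders$genome == gs$outgroup_genome]
  trd_group <- truth$ortholog_group[truth$mode == "TRD"]
  expect_true(trd_group %in% out_groups)
  # dispersed: the group is absent from the outgroup, so neither member can
  # be outgroup-collinear
  dsd_group <- truth$ortholog_group[truth$mode == "DSD"]
  expect_false(dsd_group %in% out_groups)
  # the outgroup itself carries no duplications
  out_dup <- orders[orders$genome == gs$outgroup_genome, ] |>
    dplyr::count(ortholog_group) |> dplyr::filter(n > 1)
  expect_equal(nrow(out_dup), 0L)
})

test_that("expression generation honours planted categories and noise settings", {
  cfg <- small_sim_config()
  pairs <- tibble::tibble(group = paste0("g", 1:30),
                          gene_a = paste0("A", 1:30), subgenome_a = "BB",
                          gene_b = paste0("B", 1:30), subgenome_b = "CC")
  res <- generate_expression(cfg, pairs)
  expect_equal(sort(unique(res$heb_truth$group)), sort(pairs$group))
  # NOT_EXPRESSED pairs sit at or below the filter threshold everywhere
  ne <- res$heb_truth[res$heb_truth$category == "NOT_EXPRESSED", ]
  vals <- res$expression$values |>
    dplyr::left_join(res$expression$sample_meta, by = "sample")
  for (i in seq_len(nrow(ne))) {
    genes <- unlist(pairs[pairs$group == ne$group[i], c("gene_a", "gene_b")])
    v <- vals$fpkm[vals$gene_id %in% genes & vals$tissue == ne$tissue[i]]
    expect_true(all(v <= 0.5))
  }
  # zero noise: balanced pairs split exactly evenly
  cfg0 <- small_sim_config()
  cfg0$expression_noise_sd <- 0
  res0 <- generate_expression(cfg0, pairs)
  bal <- res0$heb_truth[res0$heb_truth$category == "BALANCED", ][1, ]
  genes <- pairs[pairs$group == bal$group, ]
  va <- vals0 <- res0$expression$values |>
    dplyr::left_join(res0$expression$sample_meta, by = "sample")
  a <- vals0$fpkm[vals0$gene_id == genes$gene_a & vals0$tissue == bal$tissue]
  b <- vals0$fpkm[vals0$gene_id == genes$gene_b & vals0$tissue == bal$tissue]
  expect_equal(a, b)
  expect_error(sim_config(expression_noise_sd = -1),
               class = "oryzakin_config_error")
  expect_error(sim_config(p_dom = 0.5), class = "oryzakin_config_error")
  expect_error(sim_config(wgd_block_anchor_count = 4),
               class = "oryzakin_config_error")
})

test_that("identical configurations write byte-identical studies", {
  cfg <- small_sim_config(seed = 23L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_study(simulate_study(cfg), d1)
  write_study(simulate_study(small_sim_config(seed = 23L)), d2)
  files <- list.files(d1)
  expect_true(length(files) >= 10)
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("the cultivated-like census yields 40 family genes per genome", {
  cfg <- sim_config(seed = 2L)
  expect_equal(sum(cfg$family_counts), 40L)
  expect_equal(unname(cfg$family_counts[c("CCaMK", "CPK", "CRK", "PEPRK",
                                          "PPCK")]),
               c(1L, 29L, 5L, 2L, 3L))
  gs <- generate_genome_set(cfg)
  counts <- gs$orders |>
    dplyr::filter(family != "none", is.na(copy_of), genome == "Osativa") |>
    dplyr::count(family)
  expect_equal(counts$n[match(c("CCaMK", "CPK", "CRK", "PEPRK", "PPCK"),
                              counts$family)],
               c(1L, 29L, 5L, 2L, 3L))
})
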