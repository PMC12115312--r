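# Residue pools used by the generator. Linkers are drawn from an alphabet
# that provably cannot seed an EF-hand window (the position-8 class [LIVMC]
# is unreachable and no anchor residue D/E occurs) nor any kinase anchor
# motif (no K, H, R, D, F, I, V), so every motif the scanners report is one
# the generator planted.
LINKER_ALPHABET <- c("A", "G", "S", "T", "P", "Q", "N")

# Per-position residue pools for a functional EF loop. Subsets of the strict
# pattern classes, further restricted (positions 2, 4, 13) so that no shifted
# window overlapping the loop can satisfy the relaxed rule and no D-F-G or
# walker motif can arise across a loop/linker boundary.
EF_LOOP_POOLS <- list(
  c("D"),
  c("K", "T", "A", "G"),
  c("D", "N", "S"),
  c("A", "G", "S", "T", "Q", "N"),
  c("D", "E", "N", "S", "T", "G"),
  c("D", "N", "Q", "G", "H", "R", "K"),
  c("A", "S", "T", "N", "Q", "K"),
  c("L", "I", "V", "M", "C"),
  c("D", "E", "N", "Q", "S", "T", "A", "G", "C"),
  c("K", "T", "A", "G"),
  c("K", "T", "A", "G"),
  c("D", "E"),
  c("L", "I", "V", "M", "Y", "W")
)

# Interior coordinating positions and the class-violating residues used to
# degenerate a loop while keeping both invariant anchors intact.
EF_DEGENERATE_FLIPS <- c(`3` = "A", `5` = "A", `9` = "K")

rand_linker <- function(n) {
  paste(sample(LINKER_ALPHABET, n, replace = TRUE), collapse = "")
}

rand_ef_loop <- function(functional, rng_flip_n = NULL) {
  loop <- vapply(EF_LOOP_POOLS, function(pool) sample(pool, 1L), character(1))
  if (!functional) {
    n_flip <- if (is.null(rng_flip_n)) sample(1:2, 1L) else rng_flip_n
    flip_at <- sample(c(3L, 5L, 9L), n_flip)
    loop[flip_at] <- EF_DEGENERATE_FLIPS[as.character(flip_at)]
  }
  loop
}

#' Default canonical architecture templates per family
#'
#' CPK: complete kinase plus a calmodulin-like domain with four functional
#' EF-hand motifs, myristoylation site in the variable N-terminus. CCaMK:
#' complete kinase plus a visinin-like domain with three functional EF-hands,
#' no lipidation sites. CRK: kinase plus one degenerated EF-hand unable to
#' bind calcium. PEPRK and PPCK: kinase only.
#'
#' @return Named list of layouts: `kinase`, `ca_sites` (logical per EF),
#'   `myristoylation`.
#' @export
default_architecture_templates <- function() {
  list(
    CPK   = list(kinase = "complete", ca_sites = c(TRUE, TRUE, TRUE, TRUE),
                 myristoylation = TRUE),
    CCaMK = list(kinase = "complete", ca_sites = c(TRUE, TRUE, TRUE),
                 myristoylation = FALSE),
    CRK   = list(kinase = "complete", ca_sites = c(FALSE),
                 myristoylation = TRUE),
    PEPRK = list(kinase = "complete", ca_sites = logical(),
                 myristoylation = FALSE),
    PPCK  = list(kinase = "complete", ca_sites = logical(),
                 myristoylation = FALSE)
  )
}

# A protein template is a named list of segments; assembly order is fixed.
# Kinase inner linkers are sized so a complete walker->HRD->DFG span is 195
# residues, inside the 180-340 window the scanner demands.
make_protein_template <- function(layout) {
  if (length(layout$ca_sites) > 6L) {
    abort("layouts with more than 6 EF-hands are not supported",
          class = "oryzakin_config_error")
  }
  segs <- list()
  segs$nterm <- if (isTRUE(layout$myristoylation)) {
    paste0("MGNAASA", rand_linker(10L))
  } else {
    paste0("M", rand_linker(16L))
  }
  segs$kin_pre <- rand_linker(8L)
  segs$walker <- "AVIK"
  segs$kin_mid1 <- rand_linker(110L)
  segs$hrd <- "HRD"
  segs$kin_mid2 <- rand_linker(75L)
  segs$dfg <- "DFG"
  segs$kin_post <- rand_linker(20L)
  for (i in seq_along(layout$ca_sites)) {
    segs[[paste0("ef_linker_", i)]] <- rand_linker(15L)
    segs[[paste0("ef_loop_", i)]] <-
      paste(rand_ef_loop(layout$ca_sites[i]), collapse = "")
  }
  segs$cterm <- rand_linker(12L)
  segs
}

# Segment names whose residues may be mutated without touching motifs.
template_linker_segments <- function(segs) {
  grep("^(nterm|kin_pre|kin_mid1|kin_mid2|kin_post|ef_linker_|cterm)",
       names(segs), value = TRUE)
}

mutate_template <- function(segs, rate) {
  if (rate <= 0) return(segs)
  for (nm in template_linker_segments(segs)) {
    chars <- strsplit(segs[[nm]], "")[[1]]
    # the first residues of the N-terminus carry the lipidation signal
    idx_ok <- if (nm == "nterm") seq_along(chars)[-seq_len(min(7L, length(chars)))]
              else seq_along(chars)
    hit <- idx_ok[runif(length(idx_ok)) < rate]
    if (length(hit)) chars[hit] <- sample(LINKER_ALPHABET, length(hit),
                                          replace = TRUE)
    segs[[nm]] <- paste(chars, collapse = "")
  }
  segs
}

# Assemble a (possibly truncated) protein from a template according to a
# layout; used both for canonical proteins and splice-variant proteins.
assemble_protein <- function(segs, kinase = "complete", n_ef = NULL) {
  if (is.null(n_ef)) {
    n_ef <- length(grep("^ef_loop_", names(segs)))
  }
  parts <- segs$nterm
  if (kinase == "complete") {
    parts <- c(parts, segs$kin_pre, segs$walker, segs$kin_mid1, segs$hrd,
               segs$kin_mid2, segs$dfg, segs$kin_post)
  } else if (kinase == "incomplete") {
    parts <- c(parts, segs$kin_pre, segs$walker, segs$kin_mid1, segs$hrd)
  }
  for (i in seq_len(n_ef)) {
    parts <- c(parts, segs[[paste0("ef_linker_", i)]],
               segs[[paste0("ef_loop_", i)]])
  }
  if (n_ef == length(grep("^ef_loop_", names(segs)))) {
    parts <- c(parts, segs$cterm)
  }
  paste(parts, collapse = "")
}

#' Generate a synthetic kinase protein
#'
#' Builds a protein realising the requested architecture exactly: a kinase
#' block carrying the three ordered anchor motifs iff complete (a strict
#' subset iff incomplete), one 13-residue EF loop per requested EF-hand that
#' strictly matches the calcium-binding-site pattern iff its flag is true and
#' violates 1-2 interior coordinating positions otherwise, and inert random
#' linkers everywhere else. Rescanning the protein reproduces the layout by
#' construction.
#'
#' @param protein_id Identifier for the record.
#' @param family Family label (stored in the truth row).
#' @param layout List with `kinase` (`"complete"`/`"incomplete"`/`"absent"`),
#'   `ca_sites` (logical vector, one per EF-hand, at most 6), and
#'   `myristoylation`.
#' @param template Optional pre-built template (for family-sharing); built
#'   fresh when `NULL`.
#' @param mutate_rate Per-residue substitution rate applied to linker segments
#'   of a shared template (default 0).
#' @return List with `protein` (one-row tibble `protein_id`, `sequence`) and
#'   `truth` (planted `kinase_state`, `ef_count`, `ca_sites`).
#' @export
generate_protein <- function(protein_id, family, layout, template = NULL,
                             mutate_rate = 0) {
  if (length(layout$ca_sites) > 6L) {
    abort("layouts with more than 6 EF-hands are not supported",
          class = "oryzakin_config_error")
  }
  segs <- template %||% make_protein_template(layout)
  segs <- mutate_template(segs, mutate_rate)
  seq <- assemble_protein(segs, kinase = layout$kinase)
  kinase_state <- layout$kinase
  if (kinase_state == "absent") {
    # rebuild without any kinase segments
    seq <- assemble_protein(segs, kinase = "absent")
  }
  list(
    protein = tibble(protein_id = protein_id, sequence = seq),
    truth = tibble(protein_id = protein_id, family = family,
                   kinase_state = kinase_state,
                   ef_count = length(layout$ca_sites),
                   ca_sites = list(as.logical(layout$ca_sites))),
    template = segs
  )
}

#' Simulation configuration
#'
#' Defaults emulate the study design: a cultivated-like diploid genome, two
#' wild diploids, one allotetraploid with two subgenomes, and an outgroup
#' genome in unduplicated ancestral order; the cultivated-like family census
#' of 1 CCaMK, 29 CPK, 5 CRK, 2 PEPRK and 3 PPCK genes per genome; one
#' planted duplication event of each mode; the four-tissue expression panel
#' (root, stem, leaf, panicle) with two replicates, dominance fraction 0.9
#' and log-normal noise sd 0.2 on the FPKM scale.
#'
#' @param seed Integer RNG seed.
#' @param genomes Tibble of genome units: `species`, `subgenome`,
#'   `ploidy_role`, `n_chrom`, `genes_per_chrom`.
#' @param family_counts Named integer vector of family copy counts per genome.
#' @param duplication_events Tibble `ortholog_group`, `genome`, `mode`.
#' @param wgd_block_anchor_count Anchors flanking a planted WGD pair (>= 5).
#' @param p_dom Dominant-subgenome fraction for DOM categories (> 0.5).
#' @param expression_noise_sd Log-normal noise sd (log scale, >= 0).
#' @param tissues Tissue panel.
#' @param n_replicates Replicates per tissue.
#' @param heb_category_weights Sampling weights for planted HEB categories.
#' @param mutate_rate Linker substitution rate within a family (sequence
#'   divergence among family members).
#' @param as_types AS types planted per AS-profiled gene.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       genomes = NULL,
                       family_counts = c(CCaMK = 1L, CPK = 29L, CRK = 5L,
                                         PEPRK = 2L, PPCK = 3L),
                       duplication_events = NULL,
                       wgd_block_anchor_count = 8L,
                       p_dom = 0.9,
                       expression_noise_sd = 0.2,
                       tissues = c("root", "stem", "leaf", "panicle"),
                       n_replicates = 2L,
                       heb_category_weights = c(BALANCED = 0.4, DOM_A = 0.25,
                                                DOM_B = 0.25,
                                                NOT_EXPRESSED = 0.1),
                       mutate_rate = 0.05,
                       as_types = c("CANONICAL", paste0("T", 1:9))) {
  if (p_dom <= 0.5 || p_dom > 1) {
    abort("p_dom must lie in (0.5, 1]", class = "oryzakin_config_error")
  }
  if (expression_noise_sd < 0) {
    abort("expression noise sd must be >= 0", class = "oryzakin_config_error")
  }
  if (wgd_block_anchor_count < 5L) {
    abort("wgd_block_anchor_count must be >= 5",
          class = "oryzakin_config_error")
  }
  if (any(family_counts < 0)) {
    abort("family counts must be >= 0", class = "oryzakin_config_error")
  }
  if (is.null(genomes)) {
    genomes <- tibble(
      species = c("Osativa", "OwildB", "OwildE", "Otetra", "Otetra",
                  "Lperrieri"),
      subgenome = c("", "", "", "BB", "CC", ""),
      ploidy_role = c("diploid", "diploid", "diploid",
                      "subgenome_of_allotetraploid",
                      "subgenome_of_allotetraploid", "outgroup"),
      n_chrom = 4L, genes_per_chrom = 60L
    )
  }
  if (is.null(duplication_events)) {
    duplication_events <- tibble(
      ortholog_group = c("CPK2", "CPK12", "CPK15", "CPK29", "CPK26"),
      genome = "OwildB",
      mode = c("WGD", "TD", "PD", "TRD", "DSD")
    )
  }
  structure(list(
    seed = as.integer(seed), genomes = genomes,
    family_counts = family_counts,
    duplication_events = duplication_events,
    wgd_block_anchor_count = as.integer(wgd_block_anchor_count),
    p_dom = p_dom, expression_noise_sd = expression_noise_sd,
    tissues = tissues, n_replicates = as.integer(n_replicates),
    heb_category_weights = heb_category_weights,
    mutate_rate = mutate_rate, as_types = as_types
  ), class = "sim_config")
}

genome_label <- function(species, subgenome) {
  if_else(subgenome == "", species, paste(species, subgenome, sep = "_"))
}

family_group_names <- function(family_counts) {
  unlist(imap(as.list(family_counts), function(n, fam) {
    if (n > 0) paste0(fam, seq_len(n)) else character()
  }), use.names = FALSE)
}

#' Generate the multi-genome gene-order landscape with planted duplications
#'
#' Lays family and background ortholog groups onto chromosomes in a shared
#' ancestral order, emits every genome unit (the outgroup always in
#' unduplicated ancestral order), plants each requested duplication event so
#' its definitional signature holds, and produces within-genome and
#' genome-vs-outgroup homology pair tables.
#'
#' @param config A [sim_config()].
#' @return A list: `orders` (gene records incl. `ortholog_group`, `family`),
#'   `intra_pairs` (within-genome homology, `genome` column), `outgroup_pairs`
#'   (per-genome vs outgroup), `dup_truth` (planted events with both gene
#'   ids), `outgroup_genome` (label).
#' @export
generate_genome_set <- function(config) {
  set.seed(config$seed)
  genomes <- config$genomes
  fam_groups <- family_group_names(config$family_counts)
  n_slots <- genomes$n_chrom[1] * genomes$genes_per_chrom[1]
  if (length(fam_groups) + 20L > n_slots) {
    abort("chromosomes too short to host the family groups",
          class = "oryzakin_config_error")
  }
  n_bg <- n_slots - length(fam_groups)
  groups <- tibble(
    ortholog_group = c(fam_groups, sprintf("BG%04d", seq_len(n_bg))),
    family = c(sub("[0-9]+$", "", fam_groups), rep("none", n_bg))
  )
  # shared ancestral order: shuffle groups across chromosomes once
  groups <- groups[sample(nrow(groups)), ]
  groups$chromosome <- paste0("chr", rep(seq_len(genomes$n_chrom[1]),
                                         each = genomes$genes_per_chrom[1]))
  groups$slot <- rep(seq_len(genomes$genes_per_chrom[1]),
                     times = genomes$n_chrom[1])
  events <- config$duplication_events
  if (nrow(events)) {
    dup_modes_per_group <- events %>% distinct(.data$ortholog_group, .data$mode)
    if (any(duplicated(dup_modes_per_group$ortholog_group))) {
      abort("an ortholog group may carry events of only one mode",
            class = "oryzakin_config_error")
    }
    bad <- setdiff(events$ortholog_group, groups$ortholog_group)
    if (length(bad)) {
      abort(paste0("unknown ortholog group in duplication events: ",
                   paste(bad, collapse = ", ")),
            class = "oryzakin_config_error")
    }
  }
  dsd_groups <- events$ortholog_group[events$mode == "DSD"]
  out_row <- which(genomes$ploidy_role == "outgroup")
  if (!length(out_row)) {
    abort("an outgroup genome is required", class = "oryzakin_config_error")
  }
  gap <- 10000
  glen <- 2000
  orders <- list()
  intra_pairs <- list()
  outgroup_pairs <- list()
  dup_truth <- list()
  for (gi in seq_len(nrow(genomes))) {
    glab <- genome_label(genomes$species[gi], genomes$subgenome[gi])
    is_outgroup <- genomes$ploidy_role[gi] == "outgroup"
    gtab <- groups
    if (is_outgroup && length(dsd_groups)) {
      gtab <- filter(gtab, !(.data$ortholog_group %in% dsd_groups))
    }
    gtab <- gtab %>%
      mutate(genome = glab,
             species = genomes$species[gi],
             subgenome = genomes$subgenome[gi],
             gene_id = paste0(glab, "_", .data$ortholog_group),
             # leave headroom before the first slot so transposed/dispersed
             # copies can be planted upstream of every ancestral gene
             start = (.data$slot - 1 + 50) * gap,
             end = (.data$slot - 1 + 50) * gap + glen,
             strand = "+", copy_of = NA_character_)
    my_events <- if (is_outgroup) events[0, ] else
      filter(events, .data$genome == glab | .data$genome == genomes$species[gi])
    extra <- list()
    used_dest <- character()
    for (ei in seq_len(nrow(my_events))) {
      grp <- my_events$ortholog_group[ei]
      mode <- my_events$mode[ei]
      parent <- filter(gtab, .data$ortholog_group == grp)
      if (!nrow(parent)) next
      copy_id <- paste0(parent$gene_id, "-c2")
      # transposed/dispersed/WGD copies land on distinct non-parent
      # chromosomes so their off-diagonal homology cannot chain together
      pick_dest <- function() {
        cands <- setdiff(unique(groups$chromosome),
                         c(parent$chromosome, used_dest))
        if (!length(cands)) cands <- setdiff(unique(groups$chromosome),
                                             parent$chromosome)
        cands[1]
      }
      # proximal/tandem copies go downstream unless the parent sits too close
      # to the chromosome end
      n_down <- sum(gtab$chromosome == parent$chromosome &
                      gtab$start > parent$start)
      dir <- if (n_down >= 6L) 1 else -1
      if (mode == "TD") {
        copy <- mutate(parent, gene_id = copy_id,
                       start = .data$start + dir * gap / 2,
                       end = .data$start + dir * gap / 2 + glen,
                       copy_of = parent$gene_id)
      } else if (mode == "PD") {
        offset <- 5L  # lands 5-6 gene ranks away: proximal, not adjacent
        copy <- mutate(parent, gene_id = copy_id,
                       start = .data$start + dir * (offset * gap + gap / 2),
                       end = .data$start + dir * (offset * gap + gap / 2) + glen,
                       copy_of = parent$gene_id)
      } else if (mode == "WGD") {
        # copy a window of consecutive groups around the parent onto another
        # chromosome, creating a collinear block whose anchors flank the pair
        k <- config$wgd_block_anchor_count
        other_event_groups <- setdiff(my_events$ortholog_group, grp)
        chrom_tab <- gtab %>%
          filter(.data$chromosome == parent$chromosome,
                 !(.data$ortholog_group %in% other_event_groups)) %>%
          arrange(.data$slot)
        centre <- which(chrom_tab$ortholog_group == grp)
        lo <- max(1L, centre - floor((k + 1) / 2))
        hi <- min(nrow(chrom_tab), lo + k)  # k + 1 genes: pair + k anchors
        lo <- max(1L, hi - k)
        window <- chrom_tab[lo:hi, ]
        dest_chrom <- pick_dest()
        used_dest <- c(used_dest, dest_chrom)
        base <- max(gtab$start[gtab$chromosome == dest_chrom]) + 10 * gap
        copy <- window %>%
          mutate(gene_id = paste0(.data$gene_id, "-c2"),
                 chromosome = dest_chrom,
                 start = base + (dplyr::row_number() - 1) * gap,
                 end = base + (dplyr::row_number() - 1) * gap + glen,
                 copy_of = window$gene_id)
        copy_id <- paste0(parent$gene_id, "-c2")
      } else if (mode %in% c("TRD", "DSD")) {
        dest_chrom <- pick_dest()
        used_dest <- c(used_dest, dest_chrom)
        # upstream of all ancestral genes: more than max_gap ranks from any
        # appended block, so the pair can never chain into one
        base <- min(gtab$start[gtab$chromosome == dest_chrom]) -
          (10 + ei) * gap
        copy <- mutate(parent, gene_id = copy_id, chromosome = dest_chrom,
                       start = base, end = base + glen,
                       copy_of = parent$gene_id)
      }
      extra[[length(extra) + 1L]] <- copy
      dup_truth[[length(dup_truth) + 1L]] <- tibble(
        genome = glab, ortholog_group = grp, mode = mode,
        gene_parent = parent$gene_id, gene_copy = copy_id
      )
    }
    gtab <- bind_rows(gtab, !!!extra)
    orders[[length(orders) + 1L]] <- gtab
  }
  orders <- list_rbind(orders) %>%
    select("gene_id", "genome", "species", "subgenome", "chromosome",
           "start", "end", "strand", "ortholog_group", "family",
           "copy_of") %>%
    assign_order_ranks()
  out_label <- genome_label(genomes$species[out_row[1]],
                            genomes$subgenome[out_row[1]])
  # homology pairs: genes sharing an ortholog group
  score0 <- 500
  for (glab in setdiff(unique(orders$genome), out_label)) {
    g <- filter(orders, .data$genome == glab)
    dups <- g %>% group_by(.data$ortholog_group) %>%
      filter(dplyr::n() > 1L) %>% ungroup()
    ip <- if (nrow(dups)) {
      split(dups$gene_id, dups$ortholog_group) %>%
        map(function(ids) {
          m <- utils::combn(sort(ids), 2)
          tibble(gene_a = m[1, ], gene_b = m[2, ])
        }) %>%
        list_rbind() %>%
        mutate(score = score0, genome = glab)
    } else {
      tibble(gene_a = character(), gene_b = character(), score = double(),
             genome = character())
    }
    intra_pairs[[length(intra_pairs) + 1L]] <- ip
    og <- filter(orders, .data$genome == out_label) %>%
      select("ortholog_group", out_gene = "gene_id")
    op <- g %>% inner_join(og, by = "ortholog_group") %>%
      transmute(gene_a = .data$gene_id, gene_b = .data$out_gene,
                score = score0, genome = glab) %>%
      canonicalise_pairs()
    outgroup_pairs[[length(outgroup_pairs) + 1L]] <- op
  }
  list(orders = orders,
       intra_pairs = list_rbind(intra_pairs),
       outgroup_pairs = list_rbind(outgroup_pairs),
       dup_truth = if (length(dup_truth)) list_rbind(dup_truth) else
         tibble(genome = character(), ortholog_group = character(),
                mode = character(), gene_parent = character(),
                gene_copy = character()),
       outgroup_genome = out_label)
}

#' Generate an FPKM expression matrix with planted homoeolog bias
#'
#' For each homoeolog pair and tissue a total abundance T is drawn log-uniform
#' in \[2, 200\] and split by the planted category: DOM_A gives subgenome A a
#' fraction `p_dom` of T (DOM_B symmetrically), BALANCED splits evenly, and
#' NOT_EXPRESSED draws both members uniform in \[0, 0.5\] (below the
#' expression filter). Every replicate value carries independent
#' multiplicative log-normal noise of sd `expression_noise_sd`.
#'
#' @param config A [sim_config()].
#' @param pairs Homoeolog map (`group`, `gene_a`, `subgenome_a`, `gene_b`,
#'   `subgenome_b`).
#' @param heb_truth Optional tibble `group`, `tissue`, `category`; sampled
#'   from `config$heb_category_weights` when `NULL`.
#' @return List: `expression` (list of `values` + `sample_meta`, the
#'   [read_expression()] shape) and `heb_truth`.
#' @export
generate_expression <- function(config, pairs, heb_truth = NULL) {
  set.seed(config$seed + 1L)
  tissues <- config$tissues
  if (is.null(heb_truth)) {
    heb_truth <- tidyr::expand_grid(group = pairs$group, tissue = tissues) %>%
      mutate(category = sample(names(config$heb_category_weights),
                               dplyr::n(), replace = TRUE,
                               prob = config$heb_category_weights))
  }
  sd <- config$expression_noise_sd
  meta <- tidyr::expand_grid(tissue = tissues,
                             replicate = paste0("rep", seq_len(config$n_replicates))) %>%
    mutate(sample = paste(.data$tissue, .data$replicate, sep = "_"),
           species = "synthetic") %>%
    select("sample", "species", "tissue", "replicate")
  noise <- function(n) if (sd == 0) rep(1, n) else exp(rnorm(n, 0, sd))
  rows <- heb_truth %>% left_join(pairs, by = "group")
  values <- map(seq_len(nrow(rows)), function(i) {
    tot <- exp(runif(1, log(2), log(200)))
    nr <- config$n_replicates
    cat <- rows$category[i]
    if (cat == "NOT_EXPRESSED") {
      a <- runif(nr, 0, 0.5); b <- runif(nr, 0, 0.5)
    } else {
      p <- switch(cat, DOM_A = config$p_dom, DOM_B = 1 - config$p_dom, 0.5)
      a <- tot * p * noise(nr)
      b <- tot * (1 - p) * noise(nr)
    }
    tibble(gene_id = c(rep(rows$gene_a[i], nr), rep(rows$gene_b[i], nr)),
           sample = rep(paste(rows$tissue[i], paste0("rep", seq_len(nr)),
                              sep = "_"), 2),
           fpkm = c(a, b))
  }) %>% list_rbind()
  list(expression = list(values = values, sample_meta = meta),
       heb_truth = heb_truth)
}

# layout realised by each AS type, given a canonical layout
as_type_layout <- function(type, canonical) {
  n_ef <- length(canonical$ca_sites)
  spec <- switch(type,
    CANONICAL = list(kinase = canonical$kinase, n_ef = n_ef),
    T1 = list(kinase = "complete", n_ef = 3L),
    T2 = list(kinase = "complete", n_ef = 2L),
    T3 = list(kinase = "complete", n_ef = 1L),
    T4 = list(kinase = "complete", n_ef = 0L),
    T5 = list(kinase = "incomplete", n_ef = 0L),
    T6 = list(kinase = "absent", n_ef = 4L),
    T7 = list(kinase = "absent", n_ef = 3L),
    T8 = list(kinase = "absent", n_ef = 2L),
    T9 = list(kinase = "absent", n_ef = 1L),
    abort(paste0("unknown AS type: ", type), class = "oryzakin_config_error")
  )
  ok <- if (type == "CANONICAL") TRUE
        else if (spec$kinase == "complete" && type != "T5") spec$n_ef < n_ef
        else if (spec$kinase == "absent") spec$n_ef <= n_ef && spec$n_ef >= 1L
        else TRUE
  if (!ok) {
    abort(paste0("AS type ", type, " is incompatible with a ", n_ef,
                 "-EF canonical layout"),
          class = "oryzakin_config_error")
  }
  spec
}

#' Generate transcript variants realising AS consequence types
#'
#' Builds a toy gene model whose CDS segments mirror the protein template's
#' segments, then emits one transcript per requested type: EF-side truncations
#' shorten the terminal exon (Types 1-4), kinase truncation cuts inside the
#' kinase exon (Type 5), and kinase loss skips the kinase exon entirely
#' (Types 6-9). The variant protein is assembled from the same template, so
#' rescanning it realises exactly the requested architecture.
#'
#' @param gene_id Gene identifier.
#' @param template Protein template (from `generate_protein()$template`).
#' @param canonical Canonical layout (see [default_architecture_templates()]).
#' @param types Character vector of types to emit.
#' @return List: `variants` (tibble `transcript_id`, `gene_id`, `sequence`),
#'   `transcripts` (tibble with exon/cds list-columns, GTF-writable),
#'   `as_truth`.
#' @export
generate_transcript_variants <- function(gene_id, template, canonical,
                                         types = c("CANONICAL", paste0("T", 1:9))) {
  seg_names <- names(template)
  seg_len <- vapply(template, nchar, integer(1))
  cds_start <- cumsum(c(0L, seg_len))[seq_along(seg_len)] * 3L
  names(cds_start) <- seg_names
  out_var <- list(); out_tx <- list(); out_truth <- list()
  kin_segs <- c("kin_pre", "walker", "kin_mid1", "hrd", "kin_mid2", "dfg",
                "kin_post")
  for (ti in seq_along(types)) {
    type <- types[ti]
    spec <- as_type_layout(type, canonical)
    tx_id <- paste0(gene_id, ".", ti)
    seq <- assemble_protein(template, kinase = spec$kinase, n_ef = spec$n_ef)
    keep <- "nterm"
    if (spec$kinase == "complete") keep <- c(keep, kin_segs)
    if (spec$kinase == "incomplete") keep <- c(keep, "kin_pre", "walker",
                                               "kin_mid1", "hrd")
    if (spec$n_ef > 0) {
      keep <- c(keep, as.vector(rbind(paste0("ef_linker_", seq_len(spec$n_ef)),
                                      paste0("ef_loop_", seq_len(spec$n_ef)))))
    }
    cds <- tibble(start = cds_start[keep],
                  end = cds_start[keep] + seg_len[keep] * 3L) %>%
      arrange(.data$start)
    # merge abutting segments into exons; gaps become skipped introns
    exons <- cds %>%
      mutate(grp = cumsum(.data$start != dplyr::lag(.data$end, default = -1))) %>%
      group_by(.data$grp) %>%
      summarise(start = min(.data$start), end = max(.data$end),
                .groups = "drop") %>%
      select("start", "end")
    out_var[[ti]] <- tibble(transcript_id = tx_id, gene_id = gene_id,
                            sequence = seq)
    ex_list <- list(exons)
    out_tx[[ti]] <- tibble(transcript_id = tx_id, gene_id = gene_id,
                           strand = "+", exons = ex_list, cds = ex_list)
    out_truth[[ti]] <- tibble(transcript_id = tx_id, gene_id = gene_id,
                              planted_type = type)
  }
  list(variants = list_rbind(out_var), transcripts = list_rbind(out_tx),
       as_truth = list_rbind(out_truth))
}

#' Generate a complete synthetic study
#'
#' Runs every generator under one seed: the genome landscape with planted
#' duplications, one protein per family gene (family members share a mutated
#' template), per-family seed proteins, transcript variants with planted AS
#' types for the CPK and CCaMK genes of the first genome, the 1:1 homoeolog
#' map of the allotetraploid, and the FPKM matrix with planted bias
#' categories.
#'
#' @param config A [sim_config()].
#' @return A list bundling all inputs and a `truth` list (`arch`, `dup`,
#'   `as`, `heb`, `family`).
#' @export
simulate_study <- function(config = sim_config()) {
  gs <- generate_genome_set(config)
  set.seed(config$seed + 2L)
  templates <- default_architecture_templates()
  fam_templates <- list()
  seeds <- list()
  for (fam in names(templates)) {
    gp <- generate_protein(paste0("seed_", fam), fam, templates[[fam]])
    fam_templates[[fam]] <- gp$template
    seeds[[fam]] <- mutate(gp$protein, family = fam)
  }
  seeds <- list_rbind(seeds)
  fam_genes <- filter(gs$orders, .data$family != "none")
  prot <- list(); truth <- list()
  for (i in seq_len(nrow(fam_genes))) {
    fam <- fam_genes$family[i]
    gp <- generate_protein(fam_genes$gene_id[i], fam, templates[[fam]],
                           template = fam_templates[[fam]],
                           mutate_rate = config$mutate_rate)
    prot[[i]] <- gp$protein
    truth[[i]] <- gp$truth
  }
  proteins <- list_rbind(prot) %>%
    left_join(select(fam_genes, "gene_id", "ortholog_group", "family",
                     "genome"),
              by = c(protein_id = "gene_id"))
  arch_truth <- list_rbind(truth)
  # AS variants for the first genome's CPK and CCaMK genes
  set.seed(config$seed + 3L)
  g1 <- gs$orders$genome[1]
  as_genes <- fam_genes %>%
    filter(.data$genome == g1, .data$family %in% c("CPK", "CCaMK"))
  as_out <- map(seq_len(nrow(as_genes)), function(i) {
    fam <- as_genes$family[i]
    compatible <- purrr::keep(config$as_types, function(tp) {
      !inherits(try(as_type_layout(tp, templates[[fam]]), silent = TRUE),
                "try-error")
    })
    generate_transcript_variants(as_genes$gene_id[i], fam_templates[[fam]],
                                 templates[[fam]], compatible)
  })
  variants <- list_rbind(map(as_out, "variants"))
  transcripts <- list_rbind(map(as_out, "transcripts"))
  as_truth <- list_rbind(map(as_out, "as_truth"))
  # homoeolog map across the allotetraploid's subgenomes
  tetra <- config$genomes %>%
    filter(.data$ploidy_role == "subgenome_of_allotetraploid")
  homoeolog_map <- tibble(group = character(), gene_a = character(),
                          subgenome_a = character(), gene_b = character(),
                          subgenome_b = character())
  if (nrow(tetra) >= 2L) {
    ga <- genome_label(tetra$species[1], tetra$subgenome[1])
    gb <- genome_label(tetra$species[2], tetra$subgenome[2])
    a <- gs$orders %>% filter(.data$genome == ga, .data$family != "none",
                              is.na(.data$copy_of))
    b <- gs$orders %>% filter(.data$genome == gb, .data$family != "none",
                              is.na(.data$copy_of))
    homoeolog_map <- inner_join(
      select(a, "ortholog_group", gene_a = "gene_id", subgenome_a = "subgenome"),
      select(b, "ortholog_group", gene_b = "gene_id", subgenome_b = "subgenome"),
      by = "ortholog_group") %>%
      rename(group = "ortholog_group")
  }
  expr <- generate_expression(config, homoeolog_map)
  list(config = config,
       orders = gs$orders,
       intra_pairs = gs$intra_pairs,
       outgroup_pairs = gs$outgroup_pairs,
       outgroup_genome = gs$outgroup_genome,
       proteins = proteins,
       seeds = seeds,
       variants = variants,
       transcripts = transcripts,
       homoeolog_map = homoeolog_map,
       expression = expr$expression,
       truth = list(arch = arch_truth, dup = gs$dup_truth, as = as_truth,
                    heb = expr$heb_truth,
                    family = select(fam_genes, "gene_id", "family",
                                    "ortholog_group", "genome")))
}
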