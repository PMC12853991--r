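test_that("cohort design expands to one record per sample", {
  cfg <- truth_config(cohort_design = tibble::tibble(
    cohort = "c1", group = c("healthy", "MASLD"),
    role = c("control", "case"), n = c(117L, 121L)))
  samples <- simulate_cohort_design(cfg)
  expect_equal(nrow(samples), 238)
  expect_equal(sum(samples$role == "control"), 117)
  expect_true(all(samples$library_size >= 5e5 &
                    samples$library_size <= 2e6))
  expect_false(anyDuplicated(samples$sample_id) > 0)
})

test_that("degenerate designs are rejected", {
  expect_error(truth_config(cohort_design = tibble::tibble(
    cohort = "c1", group = c("a", "b"), role = c("control", "case"),
    n = c(0L, 5L))), "zero")
  expect_error(truth_config(cohort_design = tibble::tibble(
    cohort = character(), group = character(), role = character(),
    n = integer())), "nonempty")
  expect_error(truth_config(cohort_design = tibble::tibble(
    cohort = "c1", group = "a", role = "control", n = 5L)),
    "exactly two")
})

test_that("the generator is deterministic under a fixed seed", {
  cfg <- tiny_truth(seed = 9L)
  expect_identical(simulate_cohort_design(cfg), simulate_cohort_design(cfg))
  s1 <- simulate_gene_families(cfg)
  s2 <- simulate_gene_families(cfg)
  expect_identical(s1$fasta, s2$fasta)
  samples <- simulate_cohort_design(cfg)
  h1 <- simulate_alignment_hits(s1, samples, cfg)
  h2 <- simulate_alignment_hits(s2, samples, cfg)
  expect_identical(h1$hits, h2$hits)
  expect_identical(simulate_taxa_table(samples, seed = 5L),
                   simulate_taxa_table(samples, seed = 5L))
})

test_that("gene families respect size and divergence settings", {
  cfg <- truth_config(n_families = 3, S_range = c(2L, 4L),
                      cohort_design = tiny_design(), seed = 2L)
  sim <- simulate_gene_families(cfg)
  expect_equal(nrow(sim$families), 3)
  expect_true(all(sim$families$S >= 2 & sim$families$S <= 4))
  members <- sim$members[sim$members$is_member, ]
  expect_equal(sum(members$is_reference), 3)

  cfg0 <- truth_config(n_families = 2, divergence = 0,
                       cohort_design = tiny_design(), seed = 2L)
  sim0 <- simulate_gene_families(cfg0)
  for (fid in sim0$families$family_id) {
    ref <- sim0$families$reference_id[sim0$families$family_id == fid]
    ids <- sim0$members$member_id[sim0$members$family_id == fid &
                                    sim0$members$is_member]
    expect_true(all(sim0$sequences[ids] == sim0$sequences[[ref]]))
  }
  expect_error(truth_config(length_range = c(50L, 10L)), "length_range")
})

test_that("decoy records are present and labelled", {
  sim <- simulate_gene_families(tiny_truth())
  kinds <- table(sim$members$kind)
  expect_true(all(c("decoy_divergent", "decoy_spurious",
                    "decoy_fragment") %in% names(kinds)))
  frags <- sim$members[sim$members$kind == "decoy_fragment", ]
  refs <- sim$families$mean_length_nt[match(frags$family_id,
                                            sim$families$family_id)] / 3
  expect_true(all(frags$length_aa < 0.5 * refs))
})

test_that("true read counts follow the Poisson design mean", {
  # a = 2, S = 2, mean length ~1 kb, lib = 1e6: mean count ~4 per sample
  cfg <- truth_config(
    n_families = 1, S_range = c(2L, 2L), length_range = c(334L, 334L),
    baseline_abundance = 2,
    cohort_design = tibble::tibble(cohort = "c1", group = c("a", "b"),
                                   role = c("control", "case"),
                                   n = c(250L, 250L)),
    library_size_range = c(1e6, 1e6),
    noise_subthreshold = 0, noise_multihit = 0, seed = 31L)
  sim <- simulate_gene_families(cfg)
  samples <- simulate_cohort_design(cfg)
  hits <- simulate_alignment_hits(sim, samples, cfg)
  mu <- 2 * 2 * (sim$families$mean_length_nt / 1000) * 1
  xbar <- mean(hits$truth$n_true)
  se <- sqrt(mu / nrow(samples))
  expect_lt(abs(xbar - mu), 3 * se)
})

test_that("zero baseline yields zero true hits and noise is injected", {
  cfg <- truth_config(
    n_families = 2, baseline_abundance = c(0, 500),
    cohort_design = tiny_design(2), S_range = c(2L, 2L),
    noise_subthreshold = 0.5, noise_multihit = 0.2, seed = 8L)
  sim <- simulate_gene_families(cfg)
  samples <- simulate_cohort_design(cfg)
  hits <- simulate_alignment_hits(sim, samples, cfg)
  expect_true(all(hits$truth$n_true[hits$truth$family_id == "F001"] == 0))
  one <- hits$hits[[1]]
  expect_gt(sum(one$evalue >= 1e-10), 0)          # sub-threshold noise
  expect_gt(sum(duplicated(one$qseqid)), 0)       # secondary hits
  # every noise-free true hit is strictly below the read threshold
  true_rows <- one[grepl("_r", one$qseqid) & !duplicated(one$qseqid), ]
  expect_true(all(true_rows$evalue < 1e-10))
})

test_that("taxon tables are compositional and carry the cleaning traps", {
  samples <- simulate_cohort_design(tiny_truth())
  taxa <- simulate_taxa_table(samples, seed = 4L)
  sums <- taxa |>
    dplyr::group_by(.data$sample_id, .data$rank) |>
    dplyr::summarise(total = sum(.data$abundance), .groups = "drop")
  expect_true(all(abs(sums$total - 100) < 1e-9))
  expect_true(all(taxa$abundance >= 0))
  truth <- attr(taxa, "truth")
  excl <- taxa[taxa$clade == truth$exclusive_clade & taxa$rank == "genus", ]
  meta <- samples[match(excl$sample_id, samples$sample_id), ]
  expect_true(all(excl$abundance[!(meta$cohort == "c1" &
                                     meta$role == "case")] == 0))
  expect_gt(sum(excl$abundance), 0)
  zero <- taxa[taxa$clade == truth$zero_cohort_clade & taxa$rank == "genus", ]
  meta0 <- samples[match(zero$sample_id, samples$sample_id), ]
  expect_true(all(zero$abundance[meta0$cohort == "c1"] == 0))
  expect_true("unclassified" %in% taxa$clade)
})

test_that("metaphlan-style round trip preserves the table", {
  samples <- simulate_cohort_design(tiny_truth())
  taxa <- simulate_taxa_table(samples, seed = 4L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_metaphlan(taxa, path)
  back <- read_metaphlan(path)
  merged <- dplyr::inner_join(
    taxa, back, by = c("clade", "rank", "sample_id"),
    suffix = c("", ".rt"))
  expect_equal(nrow(merged), nrow(taxa))
  expect_equal(merged$abundance.rt, merged$abundance, tolerance = 1e-12)
})

test_that("screen simulator realizes configured prevalence and counts", {
  cfg <- screen_truth_config(
    clades = tibble::tibble(clade = c("CladeA", "CladeB"),
                            n_genomes = c(200L, 160L)),
    prevalence = tidyr::expand_grid(clade = c("CladeA", "CladeB"),
                                    gene = c("geneX", "geneY")) |>
      dplyr::mutate(prevalence = c(0.85, 0.3, 0.05, 0)),
    plasmid_counts = c(geneX = 7L, geneY = 2L), seed = 13L)
  scr <- simulate_screen_inputs(cfg)
  tp <- scr$truth$prevalence
  # exact carrier assignment: realized prevalence equals truth up to rounding
  expect_true(all(abs(tp$prevalence_realized - tp$prevalence_true) <=
                    0.5 / tp$n_retained))
  zero <- tp[tp$prevalence_true == 0, ]
  expect_true(all(zero$n_carrying == 0))
  pres <- call_presence(scr$scan)
  counts <- plasmid_gene_counts(pres, curate_plasmids(scr$plasmids))
  expect_equal(counts$n_plasmids[counts$gene == "geneX"], 7L)
  expect_equal(counts$n_plasmids[counts$gene == "geneY"], 2L)
  # curation traps exist: excluded plasmids with passing hits
  excluded <- scr$plasmids[scr$plasmids$partial_flag |
                             scr$plasmids$control_flag |
                             scr$plasmids$host_assignment == "unassigned", ]
  expect_gt(nrow(excluded), 0)
  expect_gt(sum(pres$replicon_id %in% excluded$plasmid_id), 0)
})
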