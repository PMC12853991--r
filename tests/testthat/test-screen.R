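scan_row <- function(orf, profile, plen, from, to, e, ie) {
  tibble::tibble(orf_id = orf,
                 replicon_id = sub("_[0-9]+$", "", orf),
                 profile_id = profile, profile_length = plen,
                 hmm_from = from, hmm_to = to,
                 e_value_full = e, e_value_independent = ie)
}

test_that("presence calls enforce strict coverage and E-value bounds", {
  hits <- dplyr::bind_rows(
    scan_row("G1_00001", "geneX", 100L, 5L, 96L, 1e-5, 1e-4),   # cov 0.92
    scan_row("G2_00001", "geneX", 100L, 6L, 95L, 1e-5, 1e-4),   # cov 0.90
    scan_row("G3_00001", "geneX", 100L, 2L, 99L, 0.02, 1e-4),   # E fails
    scan_row("G4_00001", "geneX", 100L, 2L, 99L, 1e-4, 0.02))   # iE fails
  pres <- call_presence(hits)
  expect_equal(pres$replicon_id, "G1")
  # relaxing thresholds never shrinks the presence set
  relaxed <- call_presence(hits, cov_min = 0.5, e_max = 0.1, ie_max = 0.1)
  expect_true(all(paste(pres$replicon_id, pres$profile_id) %in%
                    paste(relaxed$replicon_id, relaxed$profile_id)))
  expect_equal(nrow(relaxed), 4)
  bad <- scan_row("G9_00001", "geneX", 100L, 50L, 20L, 1e-5, 1e-5)
  expect_error(call_presence(bad), "G9_00001")
})

test_that("multiple ORF hits collapse to one presence per replicon", {
  hits <- dplyr::bind_rows(
    scan_row("G1_00001", "geneX", 100L, 1L, 95L, 1e-5, 1e-5),
    scan_row("G1_00002", "geneX", 100L, 1L, 97L, 1e-8, 1e-8))
  expect_equal(nrow(call_presence(hits)), 1)
})

test_that("genome filtering needs >95% completeness and all five USCGs", {
  g <- tibble::tibble(
    genome_id = c("a", "b", "c"), genus = "X", species = "X sp",
    completeness = c(96, 95.0, 99),
    argS = TRUE, dnaA = TRUE, rpoA = TRUE, rpoB = TRUE,
    rpoC = c(TRUE, TRUE, FALSE))
  kept <- filter_genomes(g)
  expect_equal(kept$genome_id, "a")
  # flag requirement can be lifted
  kept2 <- filter_genomes(g, require_all_uscg = FALSE)
  expect_setequal(kept2$genome_id, c("a", "c"))
})

test_that("clade prevalence excludes small clades and computes fractions", {
  genomes <- tibble::tibble(
    genome_id = c(sprintf("A_%03d", 1:200), sprintf("B_%03d", 1:100)),
    genus = rep(c("CladeA", "CladeB"), c(200, 100)),
    species = rep(c("CladeA sp", "CladeB sp"), c(200, 100)))
  presence <- tibble::tibble(
    replicon_id = sprintf("A_%03d", 1:170),
    profile_id = "geneX")
  prev <- clade_prevalence(presence, genomes)
  expect_equal(nrow(prev), 1)            # CladeB at exactly 100 excluded
  expect_equal(prev$clade, "CladeA")
  expect_equal(prev$prevalence, 0.85)
  expect_equal(prev$class, "core")
  # a gene absent everywhere is reported as absent
  prev2 <- clade_prevalence(presence, genomes, genes = c("geneX", "geneZ"))
  expect_equal(prev2$prevalence[prev2$gene == "geneZ"], 0)
  expect_equal(prev2$class[prev2$gene == "geneZ"], "absent")
})

test_that("prevalence classes follow the printed brackets", {
  expect_equal(classify_prevalence(c(0.85, 0.80, 0.5, 0.20, 0.19, 0)),
               c("core", "accessory", "accessory", "accessory",
                 "highly_accessory", "absent"))
  expect_error(classify_prevalence(1.2), "\\[0, 1\\]")
})

test_that("plasmid curation and distinct counting", {
  plasmids <- tibble::tibble(
    plasmid_id = c("p1", "p2", "p3", "p4", "p5"),
    host_assignment = c("CladeA", "unassigned", "CladeA", "CladeB",
                        "CladeA"),
    partial_flag = c(FALSE, FALSE, TRUE, FALSE, FALSE),
    control_flag = c(FALSE, FALSE, FALSE, TRUE, FALSE))
  curated <- curate_plasmids(plasmids)
  expect_setequal(curated$plasmid_id, c("p1", "p5"))
  presence <- tibble::tibble(
    replicon_id = c("p1", "p1", "p1", "p2", "p3", "p5"),
    profile_id = c("geneY", "geneY", "geneY", "geneY", "geneY", "geneZ"))
  counts <- plasmid_gene_counts(presence, curated)
  expect_equal(counts$n_plasmids[counts$gene == "geneY"], 1L)  # copies
  expect_equal(counts$n_plasmids[counts$gene == "geneZ"], 1L)
})

test_that("domtblout writing and parsing round-trip the fields", {
  cfg <- screen_truth_config(
    clades = tibble::tibble(clade = "CladeA", n_genomes = 30L),
    prevalence = tibble::tibble(clade = "CladeA", gene = "geneX",
                                prevalence = 0.5),
    plasmid_counts = c(geneX = 3L), seed = 4L)
  scr <- simulate_screen_inputs(cfg)
  path <- withr::local_tempfile(fileext = ".domtbl")
  write_domtblout(scr$scan, path)
  back <- parse_domtblout(path)
  expect_equal(nrow(back), nrow(scr$scan))
  key <- c("orf_id", "replicon_id", "profile_id", "profile_length",
           "hmm_from", "hmm_to")
  expect_equal(back[key], scr$scan[key])
  expect_equal(back$e_value_full, scr$scan$e_value_full, tolerance = 0.05)
  expect_equal(back$e_value_independent, scr$scan$e_value_independent,
               tolerance = 0.05)
  # presence calls agree on the round-tripped table
  expect_equal(call_presence(back), call_presence(scr$scan))
})

test_that("simulated screen recovers prevalence classes end to end", {
  cfg <- screen_truth_config(
    clades = tibble::tibble(clade = c("CladeA", "CladeB"),
                            n_genomes = c(200L, 180L)),
    prevalence = tidyr::expand_grid(clade = c("CladeA", "CladeB"),
                                    gene = c("gX", "gY")) |>
      dplyr::mutate(prevalence = c(0.85, 0.05, 0.5, 0)),
    plasmid_counts = c(gX = 5L, gY = 0L), seed = 23L)
  scr <- simulate_screen_inputs(cfg)
  pres <- call_presence(scr$scan)
  retained <- filter_genomes(scr$genomes)
  prev <- clade_prevalence(pres, retained, genes = c("gX", "gY"))
  truth <- scr$truth$prevalence
  merged <- dplyr::inner_join(prev, truth, by = c("clade", "gene"))
  expect_equal(merged$n_genomes, merged$n_retained)
  expect_equal(merged$prevalence, merged$prevalence_realized)
  expect_equal(merged$class,
               classify_prevalence(merged$prevalence_true))
  m <- prevalence_matrix(prev)
  expect_equal(dim(m), c(2L, 3L))
})
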