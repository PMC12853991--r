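aln_line <- function(read, gene, evalue, bits) {
  paste(read, gene, "98.5", "50", "1", "0", "1", "150", "10", "59",
        format(evalue), format(bits), sep = "\t")
}

test_that("alignment tables parse and reject malformed rows", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(aln_line("r1", "g1", 1e-20, 200),
               aln_line("r2", "g1", "1e-20", 150),
               aln_line("r3", "g2", 0.5, 30)), path)
  hits <- parse_alignment_table(path)
  expect_equal(nrow(hits), 3)
  expect_equal(hits$evalue[2], 1e-20)
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(aln_line("r1", "g1", 1e-20, 200),
               paste(rep("x", 11), collapse = "\t")), bad)
  expect_error(parse_alignment_table(bad), "line 2")
  expect_error(parse_alignment_table("/no/such/file.tsv"), "no such")
})

test_that("best-hit filtering applies the threshold and tie-breaks", {
  hits <- tibble::tibble(
    qseqid = c("r1", "r1", "r2", "r3", "r3"),
    sseqid = c("g1", "g2", "g1", "g2", "g1"),
    evalue = c(1e-20, 1e-15, 1e-9, 1e-30, 1e-30),
    bitscore = c(200, 150, 100, 120, 120))
  best <- best_hit_filter(hits)
  expect_equal(best$sseqid[best$qseqid == "r1"], "g1")  # lowest E wins
  expect_false("r2" %in% best$qseqid)                   # 1e-9 discarded
  expect_equal(best$sseqid[best$qseqid == "r3"], "g1")  # lexicographic tie
  # a hit exactly at the threshold is discarded (strict <)
  at <- tibble::tibble(qseqid = "r9", sseqid = "g1",
                       evalue = 1e-10, bitscore = 99)
  expect_equal(nrow(best_hit_filter(at)), 0)
})

test_that("best-hit filter matches an exhaustive per-read sort", {
  withr::with_seed(17, {
    n <- 1000
    tab <- tibble::tibble(
      qseqid = sample(sprintf("r%03d", 1:300), n, TRUE),
      sseqid = sample(sprintf("g%02d", 1:40), n, TRUE),
      evalue = 10^-sample(c(5:9, 11:40), n, TRUE),
      bitscore = sample(50:300, n, TRUE))
  })
  got <- best_hit_filter(tab) |> dplyr::arrange(qseqid)
  oracle <- tab[tab$evalue < 1e-10, ]
  oracle <- do.call(rbind, lapply(split(oracle, oracle$qseqid), function(d) {
    d[order(d$evalue, -d$bitscore, d$sseqid), ][1, ]
  }))
  oracle <- tibble::as_tibble(oracle) |> dplyr::arrange(qseqid)
  expect_equal(got, oracle)
})

test_that("reads are assigned to exactly one family with conservation", {
  members <- tibble::tibble(member_id = c("g1", "g2", "g3"),
                            family_id = c("F1", "F1", "F2"))
  best <- tibble::tibble(
    qseqid = sprintf("r%d", 1:7),
    sseqid = c("g1", "g2", "g1", "g3", "g1", "g2", "gX"),
    evalue = 1e-20, bitscore = 100)
  counts <- assign_reads_to_families(best, members)
  expect_equal(counts$count[counts$family_id == "F1"], 5L)
  expect_equal(counts$count[counts$family_id == "F2"], 1L)
  expect_equal(counts$count[counts$family_id == "unassigned"], 1L)
  expect_equal(sum(counts$count), nrow(best))
  expect_error(assign_reads_to_families(
    best[c(1, 1), ], members), "duplicate read")
  expect_error(assign_reads_to_families(
    best, tibble::tibble(member_id = c("g1", "g1"),
                         family_id = c("F1", "F2"))), "more than one")
})

test_that("RPKSM follows its closed form", {
  expect_equal(compute_rpksm(100, 1000, 1, 1e6), 100)
  expect_equal(compute_rpksm(50, 500, 4, 2e6), 12.5)
  expect_equal(compute_rpksm(0, 800, 3, 1e6), 0)
  # scale invariance: counts and library scaled together
  expect_equal(compute_rpksm(100, 1000, 2, 1e6),
               compute_rpksm(300, 1000, 2, 3e6))
  # doubling the library halves RPKSM at constant counts
  expect_equal(compute_rpksm(100, 1000, 2, 2e6),
               compute_rpksm(100, 1000, 2, 1e6) / 2)
  # total-length basis divides by S once more
  expect_equal(compute_rpksm(100, 1000, 4, 1e6, "total"),
               compute_rpksm(100, 1000, 4, 1e6) / 4)
  expect_error(compute_rpksm(10, 0, 1, 1e6), "positive")
  expect_error(compute_rpksm(10, 100, 0, 1e6), "positive")
  expect_error(compute_rpksm(10, 100, 1, 0), "positive")
})

test_that("the abundance table is complete and conserves reads", {
  cfg <- tiny_truth(seed = 3L)
  sim <- simulate_gene_families(cfg)
  samples <- simulate_cohort_design(cfg)
  dir <- withr::local_tempdir()
  hits <- simulate_alignment_hits(sim, samples, cfg, dir = dir)
  members <- sim$members[sim$members$is_member, ]
  ab <- build_abundance_table(dir, sim$families, members, samples)
  expect_equal(nrow(ab), nrow(sim$families) * nrow(samples))
  expect_true(all(ab$rpksm >= 0))
  expect_true(all((ab$rpksm == 0) == (ab$count == 0)))
  # conservation per sample: family counts + unassigned = retained hits
  un <- attr(ab, "unassigned")
  for (sid in samples$sample_id[1:3]) {
    retained <- best_hit_filter(hits$hits[[sid]])
    expect_equal(sum(ab$count[ab$sample_id == sid]) +
                   un$count[un$sample_id == sid], nrow(retained))
  }
  expect_error(
    build_abundance_table(dir, sim$families, members,
                          dplyr::mutate(samples,
                                        sample_id = paste0(sample_id, "zz"))),
    "missing alignment file")
})

test_that("RPKSM recovers the simulated concentrations", {
  cfg <- truth_config(
    n_families = 12, S_range = c(1L, 6L), length_range = c(100L, 500L),
    cohort_design = tibble::tibble(cohort = "c1", group = c("a", "b"),
                                   role = c("control", "case"),
                                   n = c(3L, 3L)),
    library_size_range = c(5e5, 1e6), seed = 77L)
  sim <- simulate_gene_families(cfg)
  samples <- simulate_cohort_design(cfg)
  hits <- simulate_alignment_hits(sim, samples, cfg)
  ab <- build_abundance_table(hits$hits, sim$families,
                              sim$members[sim$members$is_member, ], samples)
  joined <- dplyr::inner_join(ab, hits$truth,
                              by = c("family_id", "sample_id"))
  rho <- joined |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(rho = stats::cor(.data$rpksm, .data$a_fs,
                                      method = "spearman"))
  expect_true(all(rho$rho >= 0.95))
  # global proportionality constant is ~1 by construction
  expect_equal(median(joined$rpksm / joined$a_fs), 1, tolerance = 0.05)
})
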