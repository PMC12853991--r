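test_that("header extraction honours include and exclude patterns", {
  recs <- tibble::tibble(
    header = c("g1 butyrate kinase", "g2 butyrate kinase 2",
               "g3 hypothetical"),
    sequence = c("MKV", "MKL", "MQP"))
  got <- extract_candidates(recs, "butyrate kinase", "kinase 2")
  expect_equal(got$id, "g1")
  # exclusion empty reduces to pure include behaviour
  got2 <- extract_candidates(recs, "butyrate kinase")
  expect_equal(got2$id, c("g1", "g2"))
  # case folding
  got3 <- extract_candidates(recs, "BUTYRATE Kinase", "KINASE 2")
  expect_equal(got3$id, "g1")
  expect_warning(
    out <- extract_candidates(recs, "no such annotation"),
    "no records matched")
  expect_equal(nrow(out), 0)
  expect_error(extract_candidates(recs, character()), "include pattern")
  expect_error(extract_candidates("/nonexistent.faa", "x"), "FASTA")
})

test_that("length filter bounds are inclusive fractions of the reference", {
  cand <- tibble::tibble(
    id = c("a", "b", "c", "d"),
    header = c("a", "b", "c", "d"),
    sequence = vapply(c(200, 199, 600, 601),
                      function(n) strrep("A", n), character(1)))
  kept <- filter_by_length(cand, reference_length = 400,
                           min_frac = 0.5, max_frac = 1.5)
  expect_equal(kept$id, c("a", "c"))
  exact <- filter_by_length(cand, 200, 1, 1)
  expect_equal(exact$id, "a")
})

msa_from_rows <- function(ids, rows) {
  rpksm:::new_msa(tibble::tibble(id = ids, aligned = rows))
}

test_that("gap filter removes rows at or above the threshold", {
  msa <- msa_from_rows(
    c("r30", "r20", "allgap", "clean"),
    c("ACDEFGH---", "ACDEFGHI-K", "----------", "ACDEFGHIKL"))
  out <- gap_filter(msa, 0.30)
  expect_setequal(out$id, c("r20", "clean"))   # exactly 30% is removed
  expect_equal(out$aligned[out$id == "r20"], "ACDEFGHI-K")
  expect_error(gap_filter(msa_from_rows("x", "A---------"), 0.1,
                          family_id = "F9"), "F9")
})

test_that("reference anchoring preserves shape and distance", {
  cand <- tibble::tibble(
    id = paste0("m", 1:5), header = paste0("m", 1:5),
    sequence = c("MKVLAADEFG", "MKVLAADEFG", "MKVLATDEFG",
                 "MKVLAADQFG", "MKVLAADEFG"))
  msa <- align_msa(cand)
  withref <- anchor_reference(msa, "ref", "MKVLAADEFG")
  expect_equal(nrow(withref), 6)
  expect_equal(length(unique(nchar(withref$aligned))), 1)
  expect_equal(attr(withref, "reference_id"), "ref")
  d <- p_distance_matrix(withref)
  expect_equal(d["ref", "m1"], 0)  # identical to member m1
  expect_error(anchor_reference(msa, "m1", "MKVL"), "collides")
  expect_error(anchor_reference(msa, "ref", ""), "empty reference")
})

test_that("p-distances are symmetric with zero diagonal", {
  sim <- simulate_gene_families(tiny_truth())
  ids <- sim$members$member_id[sim$members$family_id == "F001" &
                                 sim$members$kind != "decoy_fragment"]
  cand <- tibble::tibble(id = ids, header = ids,
                         sequence = unname(sim$sequences[ids]))
  d <- p_distance_matrix(align_msa(cand))
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 1))
})

test_that("the distance tree recovers simple additive topology", {
  base <- strrep("ACDEFGHIKLMNPQRSTVWY", 3)  # 60 residues
  flip <- function(s, pos, to) {
    v <- strsplit(s, "")[[1]]; v[pos] <- to; paste(v, collapse = "")
  }
  a <- base
  b <- flip(base, 1:3, "G")
  cc <- Reduce(function(s, p) flip(s, p, "W"), 10:35, base)
  d <- flip(cc, 4:6, "G")
  msa <- msa_from_rows(c("A", "B", "C", "D"), c(a, b, cc, d))
  tree <- build_distance_tree(msa)
  expect_setequal(tree$tip.label, c("A", "B", "C", "D"))
  expect_true(all(tree$edge.length >= 0))
  rooted <- phangorn::midpoint(tree)
  expect_true(ape::is.monophyletic(rooted, c("A", "B")))
  expect_true(ape::is.monophyletic(rooted, c("C", "D")))
  expect_error(build_distance_tree(msa_from_rows(c("A", "B"), c(a, b))),
               "at least 3")
})

test_that("identical sequences give a star-like zero-length tree", {
  msa <- msa_from_rows(paste0("s", 1:4), rep(strrep("MKV", 20), 4))
  tree <- build_distance_tree(msa)
  expect_true(all(tree$edge.length == 0))
})

test_that("delimitation keeps the reference-centred clade within d_max", {
  tree <- ape::read.tree(
    text = "((ref:0.05,A:0.05):0.01,(B:0.05,X:0.75):0.01);")
  fam <- delimit_family(tree, "ref", d_max = 0.5)
  expect_setequal(fam$member_ids, c("A", "B"))
  expect_equal(fam$S, 2)
  all_in <- delimit_family(tree, "ref", d_max = 2)
  expect_setequal(all_in$member_ids, c("A", "B", "X"))
  expect_warning(empty <- delimit_family(tree, "ref", d_max = 0),
                 "empty family")
  expect_equal(empty$S, 0)
  expect_error(delimit_family(tree, "nope"), "not a leaf")
})

test_that("end-to-end build recovers simulated family membership", {
  cfg <- tiny_truth(seed = 21L, n_families = 6)
  sim <- simulate_gene_families(cfg)
  recs <- tibble::tibble(
    header = sim$members$header,
    sequence = unname(sim$sequences[sim$members$member_id]))
  for (i in seq_len(nrow(sim$families))) {
    f <- sim$families[i, ]
    fam <- build_family(recs, paste0("^", f$family_id, "_"),
                        "putative", reference_id = f$reference_id,
                        family_id = f$family_id)
    truth <- sim$members$member_id[sim$members$family_id == f$family_id &
                                     sim$members$is_member &
                                     !sim$members$is_reference]
    expect_setequal(fam$member_ids, truth)
  }
})

test_that("each pipeline step only removes records", {
  cfg <- tiny_truth(seed = 22L)
  sim <- simulate_gene_families(cfg)
  recs <- tibble::tibble(
    header = sim$members$header,
    sequence = unname(sim$sequences[sim$members$member_id]))
  f <- sim$families[1, ]
  cand <- extract_candidates(recs, paste0("^", f$family_id, "_"),
                             "putative")
  lenf <- filter_by_length(cand, f$mean_length_nt / 3)
  expect_lte(nrow(lenf), nrow(cand))
  msa <- align_msa(lenf, anchor_id = f$reference_id)
  gapf <- gap_filter(msa, 0.30)
  expect_lte(nrow(gapf), nrow(msa))
  expect_true(all(gapf$id %in% cand$id))
})
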