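AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# gene-product names used to annotate simulated families, cycled as needed;
# tags follow the metabolite classes the real pipeline targets
annotation_pool <- function() {
  tibble::tribble(
    ~annotation,                                   ~pathway_tag,
    "butyrate kinase",                             "butyrate",
    "phosphate butyryltransferase",                "butyrate",
    "butyryl-CoA dehydrogenase",                   "butyrate",
    "butyryl-CoA:acetate CoA-transferase",         "butyrate",
    "alcohol dehydrogenase",                       "SCA",
    "aldehyde-alcohol dehydrogenase",              "SCA",
    "choline trimethylamine-lyase",                "TMA",
    "carnitine monooxygenase",                     "TMA",
    "methyl-coenzyme M reductase subunit alpha",   "methane",
    "tetrahydromethanopterin S-methyltransferase", "methane",
    "arginyl-tRNA synthetase",                     "USCG",
    "chromosomal replication initiator protein DnaA", "USCG",
    "DNA-directed RNA polymerase subunit alpha",   "USCG",
    "DNA-directed RNA polymerase subunit beta",    "USCG",
    "DNA-directed RNA polymerase subunit beta'",   "USCG"
  )
}

# uniform integer draw on [lo, hi]; safe when lo == hi (unlike sample())
sample_range <- function(lo, hi, n = 1) {
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

random_protein <- function(n) {
  paste(sample(AA_ALPHABET, n, replace = TRUE), collapse = "")
}

# substitution-only mutation: each site flips to a different residue with
# probability `rate`, so expected p-distance to the parent is ~rate
mutate_protein <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- runif(length(chars)) < rate
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(a) {
      sample(setdiff(AA_ALPHABET, a), 1)
    }, character(1), USE.NAMES = FALSE)
  }
  paste(chars, collapse = "")
}

#' Expand a cohort design into per-sample records
#'
#' One record per stool metagenome, with its cohort, phenotypic group, the
#' group's role in the comparison, and a library size drawn uniformly from
#' the configured range. Deterministic under the configuration seed.
#'
#' @param config A [truth_config()].
#' @return Tibble with columns `sample_id`, `cohort`, `group`, `role`,
#'   `library_size`.
#' @export
#' @examples
#' cfg <- truth_config(cohort_design = tibble::tibble(
#'   cohort = "c1", group = c("healthy", "MASLD"),
#'   role = c("control", "case"), n = c(4, 4)))
#' simulate_cohort_design(cfg)
simulate_cohort_design <- function(config) {
  stopifnot(inherits(config, "rpksm_truth_config"))
  design <- validate_cohort_design(config$cohort_design)
  withr::with_seed(config$seed, {
    samples <- design |>
      dplyr::mutate(.group_idx = dplyr::row_number()) |>
      dplyr::group_by(.data$.group_idx) |>
      dplyr::reframe(
        cohort = .data$cohort,
        group = .data$group,
        role = .data$role,
        idx = seq_len(.data$n)
      ) |>
      dplyr::ungroup()
    samples |>
      dplyr::group_by(.data$cohort) |>
      dplyr::mutate(sample_id = sprintf("%s_s%03d", .data$cohort,
                                        dplyr::row_number())) |>
      dplyr::ungroup() |>
      dplyr::mutate(
        library_size = as.integer(round(runif(
          dplyr::n(),
          config$library_size_range[1],
          config$library_size_range[2]
        )))
      ) |>
      dplyr::select("sample_id", "cohort", "group", "role", "library_size")
  })
}

#' Simulate annotated gene-family pangenome sequences
#'
#' Builds `n_families` protein families. Each family grows from a random
#' reference sequence by per-site substitutions at the configured divergence;
#' the first member is flagged as the experimentally validated reference.
#' Alongside the true members the FASTA carries three kinds of decoy for the
#' family builder to remove: headers with a spurious variant annotation
#' (negative matching), short fragments (length filter), and far-divergent
#' same-name sequences (tree delimitation).
#'
#' @param config A [truth_config()].
#' @return List of class `rpksm_sim_families` with elements
#'   \describe{
#'     \item{members}{tibble of every FASTA record: `family_id`, `member_id`,
#'       `header`, `kind` (member / reference / decoy_divergent /
#'       decoy_spurious / decoy_fragment), `length_aa`, `length_nt`,
#'       `is_reference`, `is_member` (counts toward the family truth)}
#'     \item{families}{per-family tibble: `family_id`, `annotation`,
#'       `pathway_tag`, `S`, `mean_length_nt`, `baseline`, `reference_id`}
#'     \item{sequences}{named character vector of amino-acid sequences}
#'     \item{fasta}{the full FASTA text as a single string}
#'   }
#' @export
simulate_gene_families <- function(config) {
  stopifnot(inherits(config, "rpksm_truth_config"))
  if (config$length_range[1] > config$length_range[2] ||
      config$length_range[1] < 1) {
    abort("degenerate length_range")
  }
  pool <- annotation_pool()
  withr::with_seed(config$seed + 1L, {
    baselines <- resolve_baselines(config)
    fam_rows <- list()
    rec_rows <- list()
    seqs <- character()
    for (i in seq_len(config$n_families)) {
      fid <- sprintf("F%03d", i)
      k <- (i - 1L) %% nrow(pool) + 1L
      ann <- pool$annotation[k]
      if (i > nrow(pool)) ann <- paste(ann, ceiling(i / nrow(pool)))
      tag <- pool$pathway_tag[k]
      len <- sample_range(config$length_range[1], config$length_range[2])
      S <- sample_range(config$S_range[1], config$S_range[2])
      ref_seq <- random_protein(len)
      ids <- sprintf("%s_g%02d", fid, seq_len(S))
      member_seqs <- c(ref_seq,
                       vapply(seq_len(max(S - 1L, 0L)), function(j) {
                         mutate_protein(ref_seq, config$divergence)
                       }, character(1)))[seq_len(S)]
      names(member_seqs) <- ids
      headers <- sprintf("%s %s", ids, ann)
      rec <- tibble::tibble(
        family_id = fid, member_id = ids, header = headers,
        kind = c("reference", rep("member", S - 1L)),
        length_aa = nchar(member_seqs),
        is_reference = c(TRUE, rep(FALSE, S - 1L)),
        is_member = TRUE
      )
      # decoys: same annotation, divergence far beyond any family radius
      if (config$decoys_per_family > 0) {
        did <- sprintf("%s_x%02d", fid, seq_len(config$decoys_per_family))
        dseq <- vapply(did, function(j) {
          mutate_protein(ref_seq, config$decoy_divergence)
        }, character(1))
        names(dseq) <- did
        member_seqs <- c(member_seqs, dseq)
        rec <- dplyr::bind_rows(rec, tibble::tibble(
          family_id = fid, member_id = did,
          header = sprintf("%s %s", did, ann),
          kind = "decoy_divergent", length_aa = nchar(dseq),
          is_reference = FALSE, is_member = FALSE
        ))
      }
      # spurious-annotation decoys for negative header matching
      if (config$spurious_per_family > 0) {
        sid <- sprintf("%s_p%02d", fid, seq_len(config$spurious_per_family))
        sseq <- vapply(sid, function(j) random_protein(len), character(1))
        names(sseq) <- sid
        member_seqs <- c(member_seqs, sseq)
        rec <- dplyr::bind_rows(rec, tibble::tibble(
          family_id = fid, member_id = sid,
          header = sprintf("%s putative %s 2", sid, ann),
          kind = "decoy_spurious", length_aa = nchar(sseq),
          is_reference = FALSE, is_member = FALSE
        ))
      }
      # fragments: true annotation but well below the length bounds
      if (config$fragments_per_family > 0) {
        fidr <- sprintf("%s_f%02d", fid, seq_len(config$fragments_per_family))
        flen <- max(1L, as.integer(round(config$fragment_frac * len)))
        fseq <- vapply(fidr, function(j) substr(ref_seq, 1L, flen),
                       character(1))
        names(fseq) <- fidr
        member_seqs <- c(member_seqs, fseq)
        rec <- dplyr::bind_rows(rec, tibble::tibble(
          family_id = fid, member_id = fidr,
          header = sprintf("%s %s", fidr, ann),
          kind = "decoy_fragment", length_aa = nchar(fseq),
          is_reference = FALSE, is_member = FALSE
        ))
      }
      seqs <- c(seqs, member_seqs)
      rec_rows[[i]] <- rec
      fam_rows[[i]] <- tibble::tibble(
        family_id = fid, annotation = ann, pathway_tag = tag,
        S = S, mean_length_nt = 3 * len, baseline = baselines[i],
        reference_id = ids[1]
      )
    }
    members <- dplyr::bind_rows(rec_rows) |>
      dplyr::mutate(length_nt = 3L * .data$length_aa, .after = "length_aa")
    families <- dplyr::bind_rows(fam_rows)
    fasta <- paste0(
      paste0(">", members$header, "\n", seqs[members$member_id],
             collapse = "\n"),
      "\n"
    )
    structure(
      list(members = members, families = families,
           sequences = seqs, fasta = fasta),
      class = "rpksm_sim_families"
    )
  })
}

resolve_baselines <- function(config) {
  if (is.null(config$baseline_abundance)) {
    exp(runif(config$n_families,
              log(config$baseline_range[1]),
              log(config$baseline_range[2])))
  } else {
    rep_len(config$baseline_abundance, config$n_families)
  }
}

fold_change_for <- function(config, group, n_families) {
  fc <- config$fold_changes[[group]]
  if (is.null(fc)) rep(1, n_families) else rep_len(fc, n_families)
}

#' Simulate per-sample tabular alignment hits
#'
#' For every (family, sample) pair the number of true reads is Poisson with
#' mean `a * S * Lkb * lib / 1e6`, where `a` is the family baseline times
#' the sample group's fold change, `S` the family size, `Lkb` the mean
#' member length in kilobases and `lib` the library size — so the expected
#' RPKSM of the family equals `a` by construction. Hits are spread across
#' member genes; true hits get E-values strictly below 1e-10. Contamination
#' is injected at the configured rates: extra sub-threshold hits
#' (E-value >= 1e-10, to be removed by the E-value filter) and duplicate
#' secondary hits for a fraction of reads (to be removed by best-hit
#' filtering).
#'
#' @param sim A [simulate_gene_families()] result.
#' @param samples A [simulate_cohort_design()] tibble.
#' @param config The same [truth_config()] used for both.
#' @param dir Optional directory; when given, one 12-column TSV per sample
#'   (`<sample_id>.aln.tsv`, no header) is written there.
#' @return List of class `rpksm_sim_hits`: `hits` (named list of per-sample
#'   tibbles in the 12-column alignment dialect), `truth` (tibble
#'   `sample_id`, `family_id`, `a_fs`, `n_true`), and `files` (paths, when
#'   `dir` was given).
#' @export
simulate_alignment_hits <- function(sim, samples, config, dir = NULL) {
  stopifnot(inherits(sim, "rpksm_sim_families"),
            inherits(config, "rpksm_truth_config"))
  fams <- sim$families
  member_tbl <- sim$members |>
    dplyr::filter(.data$is_member)
  all_genes <- member_tbl$member_id
  gene_len_aa <- setNames(member_tbl$length_aa, member_tbl$member_id)
  withr::with_seed(config$seed + 2L, {
    truth <- list()
    hits <- vector("list", nrow(samples))
    names(hits) <- samples$sample_id
    for (si in seq_len(nrow(samples))) {
      s <- samples[si, ]
      fc <- fold_change_for(config, s$group, nrow(fams))
      a_fs <- fams$baseline * fc
      mu <- a_fs * fams$S * (fams$mean_length_nt / 1000) *
        s$library_size / 1e6
      if (config$overdispersion > 0) {
        shape <- 1 / config$overdispersion
        mu <- mu * rgamma(length(mu), shape = shape, rate = shape)
      }
      n_true <- rpois(length(mu), mu)
      truth[[si]] <- tibble::tibble(
        sample_id = s$sample_id, family_id = fams$family_id,
        a_fs = a_fs, n_true = n_true
      )
      fam_members <- split(member_tbl$member_id, member_tbl$family_id)
      genes <- unlist(lapply(seq_along(n_true), function(f) {
        m <- fam_members[[fams$family_id[f]]]
        if (n_true[f] == 0) character() else
          sample(m, n_true[f], replace = TRUE)
      }), use.names = FALSE)
      n_tot <- length(genes)
      read_ids <- sprintf("%s_r%06d", s$sample_id, seq_len(n_tot))
      expo <- runif(n_tot, 10.5, 60)
      tab <- alignment_rows(read_ids, genes, gene_len_aa, expo)

      # secondary (worse) hits for a fraction of reads: still below the
      # E-value threshold so only best-hit filtering removes them
      n_multi <- rpois(1, config$noise_multihit * n_tot)
      if (n_multi > 0 && n_tot > 0 && length(all_genes) > 1) {
        pick <- sample(n_tot, min(n_multi, n_tot))
        sec_gene <- vapply(genes[pick], function(g) {
          sample(setdiff(all_genes, g), 1)
        }, character(1), USE.NAMES = FALSE)
        sec_expo <- pmax(10.2, expo[pick] - runif(length(pick), 0.5, 5))
        sec <- alignment_rows(read_ids[pick], sec_gene, gene_len_aa,
                              sec_expo, bit_offset = -20)
        tab <- dplyr::bind_rows(tab, sec)
      }
      # sub-threshold noise hits: E-value >= 1e-10, new read ids
      n_noise <- rpois(1, config$noise_subthreshold * max(n_tot, 1))
      if (n_noise > 0) {
        nz_ids <- sprintf("%s_n%06d", s$sample_id, seq_len(n_noise))
        nz_gene <- sample(all_genes, n_noise, replace = TRUE)
        nz_expo <- runif(n_noise, 0, 9.9)
        tab <- dplyr::bind_rows(
          tab, alignment_rows(nz_ids, nz_gene, gene_len_aa, nz_expo)
        )
      }
      hits[[si]] <- dplyr::arrange(tab, .data$qseqid, .data$evalue)
    }
    truth <- dplyr::bind_rows(truth)
    files <- NULL
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      files <- vapply(names(hits), function(sid) {
        path <- file.path(dir, paste0(sid, ".aln.tsv"))
        readr::write_tsv(hits[[sid]], path, col_names = FALSE,
                         progress = FALSE)
        path
      }, character(1))
    }
    structure(list(hits = hits, truth = truth, files = files),
              class = "rpksm_sim_hits")
  })
}

# build rows of the 12-column tabular alignment dialect
alignment_rows <- function(read_ids, genes, gene_len_aa, expo,
                           bit_offset = 0) {
  n <- length(read_ids)
  alen <- pmax(20L, as.integer(round(gene_len_aa[genes] *
                                       runif(n, 0.25, 0.45))))
  pid <- round(runif(n, 80, 100), 1)
  mism <- as.integer(round(alen * (100 - pid) / 100))
  sstart <- as.integer(pmax(1, round(runif(n, 1, pmax(
    1, gene_len_aa[genes] - alen)))))
  tibble::tibble(
    qseqid = read_ids,
    sseqid = unname(genes),
    pident = pid,
    length = alen,
    mismatch = mism,
    gapopen = 0L,
    qstart = 1L,
    qend = alen * 3L,
    sstart = sstart,
    send = sstart + alen - 1L,
    evalue = 10^(-expo),
    bitscore = round(40 + 1.8 * expo + bit_offset + rnorm(n, 0, 2), 1)
  )
}
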