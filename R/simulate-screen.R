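#' Ground truth for the genome/plasmid screening simulator
#'
#' @param clades Tibble with columns `clade` and `n_genomes`.
#' @param prevalence Tibble with columns `clade`, `gene`, `prevalence`
#'   (fraction in `[0, 1]` of *retained* genomes of the clade that carry the
#'   gene).
#' @param plasmid_counts Named integer vector: gene to the number of curated
#'   plasmids carrying it.
#' @param completeness_fail_rate Fraction of genomes drawn below the >95%
#'   completeness cutoff.
#' @param uscg_fail_rate Fraction of genomes missing one of the five
#'   universal single-copy genes.
#' @param noise_false_hit_rate Rate of decoy scan hits with E-value above
#'   the scan threshold (must be removed by the E-value filters).
#' @param noise_partial_rate Rate of decoy scan hits with profile coverage
#'   at or below 90% (must be removed by the coverage filter).
#' @param stochastic_prevalence If `TRUE`, carriers are drawn per genome as
#'   independent Bernoulli trials; the default assigns exactly
#'   `round(prevalence * n_retained)` carriers by sampling without
#'   replacement, so realized prevalence equals the configured fraction up
#'   to rounding.
#' @param n_excluded_plasmids Number each of partial, unassigned-host and
#'   internal-control plasmids added (each carrying passing hits, so only
#'   curation removes them).
#' @param profile_length Profile length (positions) used for every family
#'   model.
#' @param seed Integer seed.
#' @return A list of class `rpksm_screen_config`.
#' @export
screen_truth_config <- function(clades,
                                prevalence,
                                plasmid_counts = integer(),
                                completeness_fail_rate = 0.1,
                                uscg_fail_rate = 0.05,
                                noise_false_hit_rate = 0.05,
                                noise_partial_rate = 0.05,
                                stochastic_prevalence = FALSE,
                                n_excluded_plasmids = 2,
                                profile_length = 300L,
                                seed = 1L) {
  stopifnot(
    is.data.frame(clades), all(c("clade", "n_genomes") %in% names(clades)),
    all(clades$n_genomes >= 1),
    is.data.frame(prevalence),
    all(c("clade", "gene", "prevalence") %in% names(prevalence)),
    all(prevalence$prevalence >= 0 & prevalence$prevalence <= 1)
  )
  structure(
    list(clades = clades, prevalence = prevalence,
         plasmid_counts = plasmid_counts,
         completeness_fail_rate = completeness_fail_rate,
         uscg_fail_rate = uscg_fail_rate,
         noise_false_hit_rate = noise_false_hit_rate,
         noise_partial_rate = noise_partial_rate,
         stochastic_prevalence = stochastic_prevalence,
         n_excluded_plasmids = n_excluded_plasmids,
         profile_length = as.integer(profile_length),
         seed = as.integer(seed)),
    class = "rpksm_screen_config"
  )
}

USCG_NAMES <- c("argS", "dnaA", "rpoA", "rpoB", "rpoC")

passing_scan_rows <- function(orf_ids, profile, plen, n) {
  width <- as.integer(round(runif(n, 0.92, 1) * plen))
  width <- pmin(width, plen)
  from <- as.integer(1 + floor(runif(n) * (plen - width + 1)))
  tibble::tibble(
    orf_id = orf_ids, profile_id = profile, profile_length = plen,
    hmm_from = from, hmm_to = from + width - 1L,
    e_value_full = 10^(-runif(n, 5, 40)),
    e_value_independent = 10^(-runif(n, 5, 40))
  )
}

#' Simulate genome metadata, plasmid metadata and a profile-scan table
#'
#' Builds a genome collection per clade (with a configured fraction failing
#' the completeness / universal-single-copy-gene filter), a plasmid
#' collection with the curation traps (partial sequences, unassignable
#' hosts, internal sequencing controls — each carrying otherwise-passing
#' hits), and a per-domain scan table whose passing hits reflect the
#' configured per-(clade, gene) prevalence over *retained* genomes plus
#' decoy hits that violate the coverage or E-value rules.
#'
#' @param config A [screen_truth_config()].
#' @param dir Optional directory; when given, writes `genomes.tsv`,
#'   `plasmids.tsv` and `scan.domtbl` (HMMER3 per-domain dialect) there.
#' @return List of class `rpksm_sim_screen`: `genomes`, `plasmids`, `scan`
#'   tibbles and a `truth` list with the realized per-(clade, gene)
#'   prevalence and the curated-plasmid counts per gene.
#' @export
simulate_screen_inputs <- function(config, dir = NULL) {
  stopifnot(inherits(config, "rpksm_screen_config"))
  plen <- config$profile_length
  withr::with_seed(config$seed, {
    ## genomes
    g_rows <- list()
    for (i in seq_len(nrow(config$clades))) {
      cl <- config$clades$clade[i]
      n <- config$clades$n_genomes[i]
      ids <- sprintf("GEN_%s_%04d", gsub("[^A-Za-z0-9]", "", cl), seq_len(n))
      fail_c <- runif(n) < config$completeness_fail_rate
      completeness <- ifelse(fail_c, runif(n, 80, 95), runif(n, 95.2, 100))
      uscg <- matrix(TRUE, n, 5, dimnames = list(NULL, USCG_NAMES))
      miss <- runif(n) < config$uscg_fail_rate
      if (any(miss)) {
        for (j in which(miss)) uscg[j, sample(5, 1)] <- FALSE
      }
      g_rows[[i]] <- dplyr::bind_cols(
        tibble::tibble(genome_id = ids, genus = cl,
                       species = paste0(cl, " sp001"),
                       completeness = round(completeness, 2)),
        tibble::as_tibble(uscg)
      )
    }
    genomes <- dplyr::bind_rows(g_rows)
    retained <- genomes |>
      dplyr::filter(.data$completeness > 95,
                    .data$argS & .data$dnaA & .data$rpoA &
                      .data$rpoB & .data$rpoC)

    ## genome scan hits from prevalence truth
    scan_rows <- list()
    truth_prev <- list()
    orf_counter <- 0L
    for (i in seq_len(nrow(config$prevalence))) {
      p <- config$prevalence[i, ]
      cl_genomes <- retained$genome_id[retained$genus == p$clade]
      n_ret <- length(cl_genomes)
      if (n_ret == 0) {
        truth_prev[[i]] <- tibble::tibble(
          clade = p$clade, gene = p$gene, n_retained = 0L,
          n_carrying = 0L, prevalence_true = p$prevalence,
          prevalence_realized = NA_real_)
        next
      }
      if (config$stochastic_prevalence) {
        carriers <- cl_genomes[runif(n_ret) < p$prevalence]
      } else {
        k <- round(p$prevalence * n_ret)
        carriers <- if (k > 0) sample(cl_genomes, k) else character()
      }
      if (length(carriers)) {
        orfs <- sprintf("%s_%05d", carriers,
                        orf_counter + seq_along(carriers))
        orf_counter <- orf_counter + length(carriers)
        scan_rows[[length(scan_rows) + 1L]] <-
          passing_scan_rows(orfs, p$gene, plen, length(carriers))
      }
      # decoy hits on non-carriers: fail E-value or coverage
      non <- setdiff(cl_genomes, carriers)
      n_fe <- rpois(1, config$noise_false_hit_rate * n_ret)
      if (n_fe > 0 && length(non)) {
        gsel <- sample(non, min(n_fe, length(non)))
        width <- as.integer(round(runif(length(gsel), 0.92, 1) * plen))
        from <- as.integer(1 + floor(runif(length(gsel)) *
                                       (plen - width + 1)))
        scan_rows[[length(scan_rows) + 1L]] <- tibble::tibble(
          orf_id = sprintf("%s_%05d", gsel,
                           orf_counter + seq_along(gsel)),
          profile_id = p$gene, profile_length = plen,
          hmm_from = from, hmm_to = from + width - 1L,
          e_value_full = runif(length(gsel), 0.02, 5),
          e_value_independent = runif(length(gsel), 0.02, 5)
        )
        orf_counter <- orf_counter + length(gsel)
      }
      n_pc <- rpois(1, config$noise_partial_rate * n_ret)
      if (n_pc > 0 && length(non)) {
        gsel <- sample(non, min(n_pc, length(non)))
        width <- pmax(10L, as.integer(floor(runif(length(gsel), 0.4, 0.88) *
                                              plen)))
        from <- as.integer(1 + floor(runif(length(gsel)) *
                                       (plen - width + 1)))
        scan_rows[[length(scan_rows) + 1L]] <- tibble::tibble(
          orf_id = sprintf("%s_%05d", gsel,
                           orf_counter + seq_along(gsel)),
          profile_id = p$gene, profile_length = plen,
          hmm_from = from, hmm_to = from + width - 1L,
          e_value_full = 10^(-runif(length(gsel), 5, 30)),
          e_value_independent = 10^(-runif(length(gsel), 5, 30))
        )
        orf_counter <- orf_counter + length(gsel)
      }
      truth_prev[[i]] <- tibble::tibble(
        clade = p$clade, gene = p$gene, n_retained = n_ret,
        n_carrying = length(carriers), prevalence_true = p$prevalence,
        prevalence_realized = length(carriers) / n_ret
      )
    }

    ## plasmids
    genes <- names(config$plasmid_counts)
    p_rows <- list()
    pl_counter <- 0L
    hosts <- config$clades$clade
    for (g in genes) {
      k <- config$plasmid_counts[[g]]
      if (k > 0) {
        ids <- sprintf("PLAS%05d", pl_counter + seq_len(k))
        pl_counter <- pl_counter + k
        p_rows[[length(p_rows) + 1L]] <- tibble::tibble(
          plasmid_id = ids,
          host_assignment = sample(hosts, k, replace = TRUE),
          partial_flag = FALSE, control_flag = FALSE
        )
        # first carrier gets a duplicate hit: distinct-plasmid counting
        n_hits <- c(2L, rep(1L, k - 1L))[seq_len(k)]
        orfs <- sprintf("%s_%05d", rep(ids, n_hits),
                        seq_len(sum(n_hits)))
        scan_rows[[length(scan_rows) + 1L]] <-
          passing_scan_rows(orfs, g, plen, sum(n_hits))
      }
    }
    # curation traps: excluded plasmids that nevertheless carry passing hits
    if (config$n_excluded_plasmids > 0 && length(genes)) {
      traps <- tibble::tibble(
        plasmid_id = sprintf("PLASX%04d",
                             seq_len(3 * config$n_excluded_plasmids)),
        host_assignment = rep(c(hosts[1], "unassigned", hosts[1]),
                              each = config$n_excluded_plasmids),
        partial_flag = rep(c(TRUE, FALSE, FALSE),
                           each = config$n_excluded_plasmids),
        control_flag = rep(c(FALSE, FALSE, TRUE),
                           each = config$n_excluded_plasmids)
      )
      p_rows[[length(p_rows) + 1L]] <- traps
      orfs <- sprintf("%s_%05d", traps$plasmid_id, seq_len(nrow(traps)))
      scan_rows[[length(scan_rows) + 1L]] <- passing_scan_rows(
        orfs, sample(genes, nrow(traps), replace = TRUE), plen, nrow(traps))
    }
    plasmids <- if (length(p_rows)) dplyr::bind_rows(p_rows) else
      tibble::tibble(plasmid_id = character(), host_assignment = character(),
                     partial_flag = logical(), control_flag = logical())

    scan <- dplyr::bind_rows(scan_rows) |>
      dplyr::mutate(replicon_id = sub("_[0-9]+$", "", .data$orf_id),
                    .after = "orf_id")

    files <- NULL
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      files <- c(
        genomes = file.path(dir, "genomes.tsv"),
        plasmids = file.path(dir, "plasmids.tsv"),
        scan = file.path(dir, "scan.domtbl")
      )
      readr::write_tsv(genomes, files[["genomes"]], progress = FALSE)
      readr::write_tsv(plasmids, files[["plasmids"]], progress = FALSE)
      write_domtblout(scan, files[["scan"]])
    }

    structure(
      list(genomes = genomes, plasmids = plasmids, scan = scan,
           truth = list(prevalence = dplyr::bind_rows(truth_prev),
                        plasmid_counts = config$plasmid_counts),
           files = files),
      class = "rpksm_sim_screen"
    )
  })
}
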