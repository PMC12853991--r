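GENUS_POOL <- c(
  "Agathobacter", "Ruminococcus", "Mediterraneibacter", "Gemmiger",
  "Streptococcus", "Bacteroides", "Prevotella", "Faecalibacterium",
  "Blautia", "Roseburia", "Dorea", "Alistipes", "Akkermansia",
  "Dialister", "Coprococcus", "Phocaeicola", "Parabacteroides",
  "Anaerostipes", "Eubacterium", "Bifidobacterium", "Collinsella",
  "Oscillibacter", "Lachnospira", "Fusicatenibacter", "Holdemanella"
)

#' Simulate a taxonomic relative-abundance table
#'
#' Produces genus- and species-rank relative abundances (percent, summing to
#' 100 per sample within each rank) for a multi-cohort two-group design.
#' The composition deliberately exercises every cleaning rule downstream:
#' an `unclassified` row at each rank, a clade that is entirely absent from
#' the first cohort but present in both groups elsewhere, a clade present
#' exclusively in the case group of the first cohort, per-cohort private
#' clades, and rare clades sitting below the mean-abundance thresholds. A
#' shared core of abundant genera is present in every cohort.
#'
#' @param samples A sample tibble as from [simulate_cohort_design()].
#' @param n_shared Number of shared core genera present in all cohorts.
#' @param n_private Cohort-private abundant genera per cohort.
#' @param n_rare Rare genera (below the genus retention threshold).
#' @param effects Optional named numeric vector: clade name to multiplier
#'   applied in case-group samples (all cohorts).
#' @param seed Integer seed.
#' @return Long tibble `clade`, `rank`, `sample_id`, `abundance` with a
#'   `truth` attribute listing `shared_genera`, `exclusive_clade` and
#'   `zero_cohort_clade`.
#' @export
simulate_taxa_table <- function(samples, n_shared = 10, n_private = 2,
                                n_rare = 3, effects = NULL, seed = 1L) {
  stopifnot(nrow(samples) > 0, n_shared >= 1)
  cohorts <- unique(samples$cohort)
  shared <- GENUS_POOL[seq_len(n_shared)]
  used <- n_shared
  private <- list()
  for (co in cohorts) {
    private[[co]] <- paste0(GENUS_POOL[(used %% length(GENUS_POOL)) +
                                         seq_len(n_private)], "_", co)
    used <- used + n_private
  }
  rare <- paste0("Rarum_", seq_len(n_rare))
  exclusive_clade <- "Exclusivum"
  zero_cohort_clade <- "Cohortless"
  genera <- c(shared, unlist(private, use.names = FALSE), rare,
              exclusive_clade, zero_cohort_clade, "unclassified")

  withr::with_seed(seed, {
    base_w <- setNames(numeric(length(genera)), genera)
    base_w[shared] <- exp(runif(length(shared), log(2), log(15)))
    base_w[unlist(private)] <- 5
    base_w[rare] <- 0.03
    base_w[exclusive_clade] <- 1
    base_w[zero_cohort_clade] <- 3
    base_w["unclassified"] <- 12

    one_rank <- function(rank, clade_names, weights) {
      rows <- lapply(seq_len(nrow(samples)), function(si) {
        s <- samples[si, ]
        w <- unname(weights)
        for (co in cohorts) {
          if (co != s$cohort) w[genera %in% private[[co]]] <- 0
        }
        # absent from the first cohort entirely, both groups elsewhere
        if (s$cohort == cohorts[1]) w[genera == zero_cohort_clade] <- 0
        # present only in the case group of the first cohort
        excl <- genera == exclusive_clade
        if (!(s$cohort == cohorts[1] && s$role == "case")) w[excl] <- 0
        if (!is.null(effects) && s$role == "case") {
          hit <- match(names(effects), clade_names)
          ok <- !is.na(hit)
          w[hit[ok]] <- w[hit[ok]] * effects[ok]
        }
        draw <- w * rgamma(length(w), shape = 25, rate = 25)
        draw[w == 0] <- 0
        tibble::tibble(
          clade = clade_names, rank = rank, sample_id = s$sample_id,
          abundance = 100 * draw / sum(draw)
        )
      })
      dplyr::bind_rows(rows)
    }

    genus_tbl <- one_rank("genus", genera, base_w)
    sp_names <- ifelse(genera == "unclassified", "unclassified",
                       paste0(genera, "_intestinalis"))
    sp_w <- setNames(as.numeric(base_w), sp_names)
    species_tbl <- one_rank("species", sp_names, sp_w)
    out <- dplyr::bind_rows(genus_tbl, species_tbl)
    attr(out, "truth") <- list(
      shared_genera = shared,
      exclusive_clade = exclusive_clade,
      zero_cohort_clade = zero_cohort_clade,
      private = private,
      rare = rare
    )
    out
  })
}

#' Write a merged MetaPhlAn-style taxon table
#'
#' Serialises a long taxon table to the merged-profile dialect: one
#' `clade_name` column carrying a rank prefix (`g__` genus, `s__` species)
#' and one column per sample with relative
#' abundances in percent.
#'
#' @param taxa Long tibble as from [simulate_taxa_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_metaphlan <- function(taxa, path) {
  wide <- taxa |>
    dplyr::mutate(clade_name = paste0(
      ifelse(.data$rank == "genus", "g__", "s__"), .data$clade
    )) |>
    dplyr::select("clade_name", "sample_id", "abundance") |>
    tidyr::pivot_wider(names_from = "sample_id",
                       values_from = "abundance", values_fill = 0)
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' Read a merged MetaPhlAn-style taxon table
#'
#' Parses the merged-profile dialect back into the package's long form.
#' Lineage strings are reduced to their last level; the rank is taken from
#' that level's prefix (`g__`/`s__`) and the prefix is stripped.
#'
#' @param path TSV path as written by [write_metaphlan()] or by merging
#'   per-sample profiler outputs.
#' @return Long tibble `clade`, `rank`, `sample_id`, `abundance`.
#' @export
read_metaphlan <- function(path) {
  wide <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(wide)[1] <- "clade_name"
  wide |>
    dplyr::mutate(
      last = vapply(strsplit(.data$clade_name, "|", fixed = TRUE),
                    function(x) x[length(x)], character(1)),
      rank = dplyr::case_when(
        startsWith(.data$last, "g__") ~ "genus",
        startsWith(.data$last, "s__") ~ "species",
        TRUE ~ NA_character_
      ),
      clade = sub("^[a-z]__", "", .data$last)
    ) |>
    dplyr::filter(!is.na(.data$rank)) |>
    dplyr::select(-"clade_name", -"last") |>
    tidyr::pivot_longer(cols = -c("clade", "rank"),
                        names_to = "sample_id",
                        values_to = "abundance") |>
    dplyr::select("clade", "rank", "sample_id", "abundance")
}
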