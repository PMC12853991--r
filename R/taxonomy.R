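strip_rank_prefix <- function(x) sub("^[a-z]__", "", x)

#' Clean a taxonomic profile table
#'
#' Applies the two cleaning rules for merged relative-abundance profiles:
#' clades predicted as `unclassified` (case-insensitive, with or without a
#' rank prefix) are removed, and clades with zero mean abundance across all
#' samples of any cohort are removed — unless the clade is present
#' exclusively in one comparison group of some cohort, in which case it is
#' retained as a potential clear group marker.
#'
#' @param taxa Long tibble `clade`, `rank`, `sample_id`, `abundance`.
#' @param samples Sample tibble with `sample_id`, `cohort`, `role`; every
#'   sample in `taxa` must be present.
#' @return The filtered long tibble.
#' @export
clean_clades <- function(taxa, samples) {
  missing_samples <- setdiff(unique(taxa$sample_id), samples$sample_id)
  if (length(missing_samples)) {
    abort(paste0("sample(s) absent from metadata: ",
                 paste(missing_samples, collapse = ", ")))
  }
  taxa <- taxa |>
    dplyr::filter(tolower(strip_rank_prefix(.data$clade)) != "unclassified")
  joined <- taxa |>
    dplyr::inner_join(samples |>
                        dplyr::select("sample_id", "cohort", "role"),
                      by = "sample_id")
  status <- joined |>
    dplyr::group_by(.data$clade, .data$rank, .data$cohort) |>
    dplyr::summarise(
      zero_cohort = mean(.data$abundance) == 0,
      group_exclusive =
        dplyr::n_distinct(.data$role[.data$abundance > 0]) == 1,
      .groups = "drop_last"
    ) |>
    dplyr::summarise(
      drop = any(.data$zero_cohort) && !any(.data$group_exclusive),
      .groups = "drop"
    )
  taxa |>
    dplyr::anti_join(status |> dplyr::filter(.data$drop),
                     by = c("clade", "rank"))
}

#' Retain clades above rank-specific mean-abundance thresholds
#'
#' Within each cohort, keeps genus rows whose mean relative abundance over
#' all of the cohort's samples (both groups pooled) strictly exceeds
#' `genus_min` percent, and species rows exceeding `species_min` percent.
#' A clade may survive in one cohort and be dropped in another; downstream
#' shared-clade computations operate on what survives per cohort.
#'
#' @param taxa Long tibble `clade`, `rank`, `sample_id`, `abundance`.
#' @param samples Sample tibble with `sample_id` and `cohort`.
#' @param genus_min,species_min Strict thresholds in percent (defaults 0.5
#'   and 0.2).
#' @return The filtered long tibble (rows of surviving (clade, cohort)
#'   pairs).
#' @export
abundance_threshold_filter <- function(taxa, samples, genus_min = 0.5,
                                       species_min = 0.2) {
  if (!all(taxa$rank %in% c("genus", "species"))) {
    bad <- setdiff(unique(taxa$rank), c("genus", "species"))
    abort(paste0("unknown rank(s): ", paste(bad, collapse = ", ")))
  }
  joined <- taxa |>
    dplyr::inner_join(samples |> dplyr::select("sample_id", "cohort"),
                      by = "sample_id")
  keep <- joined |>
    dplyr::group_by(.data$clade, .data$rank, .data$cohort) |>
    dplyr::summarise(mean_ab = mean(.data$abundance), .groups = "drop") |>
    dplyr::filter(
      (.data$rank == "genus" & .data$mean_ab > .env$genus_min) |
        (.data$rank == "species" & .data$mean_ab > .env$species_min)
    )
  joined |>
    dplyr::semi_join(keep, by = c("clade", "rank", "cohort")) |>
    dplyr::select("clade", "rank", "sample_id", "abundance")
}

#' Clades shared across all cohorts, with their summed abundance
#'
#' Intersects the surviving clade names across cohorts (at each rank) and
#' reports, per cohort, the mean total relative abundance that the shared
#' set represents.
#'
#' @param taxa A filtered long tibble (after [clean_clades()] and
#'   [abundance_threshold_filter()]).
#' @param samples Sample tibble with `sample_id` and `cohort` (at least two
#'   cohorts).
#' @param rank Rank to evaluate, `"genus"` (default) or `"species"`.
#' @return List with `shared` (character vector of clade names) and
#'   `summary` (tibble `cohort`, `n_shared`, `shared_total_abundance` —
#'   the per-cohort mean summed percent of the shared set).
#' @export
shared_clades <- function(taxa, samples, rank = "genus") {
  joined <- taxa |>
    dplyr::filter(.data$rank == .env$rank) |>
    dplyr::inner_join(samples |> dplyr::select("sample_id", "cohort"),
                      by = "sample_id")
  cohorts <- unique(joined$cohort)
  if (length(cohorts) < 2) abort("need at least two cohorts")
  sets <- joined |>
    dplyr::distinct(.data$cohort, .data$clade)
  shared <- Reduce(intersect, split(sets$clade, sets$cohort))
  per_sample_total <- joined |>
    dplyr::filter(.data$clade %in% shared) |>
    dplyr::group_by(.data$cohort, .data$sample_id) |>
    dplyr::summarise(total = sum(.data$abundance), .groups = "drop")
  summary <- per_sample_total |>
    dplyr::group_by(.data$cohort) |>
    dplyr::summarise(n_shared = length(shared),
                     shared_total_abundance = mean(.data$total),
                     .groups = "drop")
  list(shared = sort(shared), summary = summary)
}
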