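#' Ground-truth configuration for the metagenome simulator
#'
#' Describes the synthetic study the generator produces: gene-family sizes
#' and lengths, per-family baseline concentrations, per-group fold changes,
#' the cohort/group/sample-count design, library sizes, and the contamination
#' rates injected so downstream filters have something real to remove. The
#' defaults mirror a three-cohort stool-metagenome case/control study with
#' families large enough that count noise is small relative to the simulated
#' effects.
#'
#' @param n_families Number of gene families to simulate.
#' @param S_range Integer interval, members per family (the flagged
#'   reference counts as a genuine member).
#' @param length_range Integer interval, reference protein length in amino
#'   acids.
#' @param baseline_abundance Per-family baseline concentration (arbitrary
#'   units; the expected RPKSM of the family in a control sample). A scalar
#'   is recycled; `NULL` draws log-uniform values in `baseline_range` under
#'   the seed.
#' @param baseline_range Log-uniform draw interval used when
#'   `baseline_abundance` is `NULL`.
#' @param fold_changes Named list mapping a group label to a positive
#'   multiplier vector (length 1 or `n_families`) applied to the baseline in
#'   samples of that group. Unlisted groups get 1.
#' @param cohort_design Tibble with columns `cohort`, `group`, `role`
#'   (`"control"`/`"case"`) and `n` (samples per group).
#' @param library_size_range Integer interval of per-sample read totals.
#' @param divergence Per-site substitution probability between a family
#'   member and its reference.
#' @param decoy_divergence Per-site substitution probability of same-name
#'   decoy sequences, chosen well above any sensible delimitation radius.
#' @param decoys_per_family Same-name, far-divergent decoys per family
#'   (removed only by tree delimitation).
#' @param spurious_per_family Decoys whose header carries a spurious variant
#'   of the annotation (removed by negative header matching).
#' @param fragments_per_family Short same-name fragments per family (removed
#'   by the length filter); length is `fragment_frac` of the reference.
#' @param fragment_frac Fragment length as a fraction of the reference.
#' @param noise_subthreshold Sub-threshold alignment noise: expected extra
#'   hits with E-value above the read threshold, as a fraction of true hits.
#' @param noise_multihit Fraction of true reads that also receive a worse
#'   secondary hit on another gene (removed by best-hit filtering).
#' @param overdispersion Optional extra-Poisson dispersion; 0 gives pure
#'   Poisson counts, d > 0 gamma-mixes the Poisson mean with variance
#'   multiplier (1 + d * mean).
#' @param seed Integer seed; identical configurations and seeds give
#'   byte-identical outputs.
#'
#' @return A list of class `rpksm_truth_config`.
#' @export
truth_config <- function(n_families = 20,
                         S_range = c(1L, 6L),
                         length_range = c(100L, 500L),
                         baseline_abundance = NULL,
                         baseline_range = c(100, 2000),
                         fold_changes = list(),
                         cohort_design = default_cohort_design(),
                         library_size_range = c(5e5, 2e6),
                         divergence = 0.05,
                         decoy_divergence = 0.75,
                         decoys_per_family = 1,
                         spurious_per_family = 1,
                         fragments_per_family = 1,
                         fragment_frac = 0.3,
                         noise_subthreshold = 0.02,
                         noise_multihit = 0.02,
                         overdispersion = 0,
                         seed = 1L) {
  stopifnot(
    "n_families must be >= 1" = n_families >= 1,
    "S_range must be a positive nondegenerate interval" =
      length(S_range) == 2 && S_range[1] >= 1 && S_range[1] <= S_range[2],
    "length_range must be a positive nondegenerate interval" =
      length(length_range) == 2 && length_range[1] >= 1 &&
      length_range[1] <= length_range[2],
    "library_size_range must be a positive interval" =
      length(library_size_range) == 2 && library_size_range[1] >= 1 &&
      library_size_range[1] <= library_size_range[2],
    "divergence must lie in [0, 1]" = divergence >= 0 && divergence <= 1,
    "noise rates must lie in [0, 1]" =
      noise_subthreshold >= 0 && noise_subthreshold <= 1 &&
      noise_multihit >= 0 && noise_multihit <= 1,
    "overdispersion must be nonnegative" = overdispersion >= 0
  )
  if (!is.null(baseline_abundance)) {
    stopifnot("baseline_abundance must be nonnegative" =
                all(baseline_abundance >= 0),
              "baseline_abundance must be scalar or length n_families" =
                length(baseline_abundance) %in% c(1L, n_families))
  }
  if (length(fold_changes)) {
    ok <- vapply(fold_changes, function(x) {
      is.numeric(x) && all(x > 0) && length(x) %in% c(1L, n_families)
    }, logical(1))
    stopifnot("fold_changes must be positive, length 1 or n_families" =
                all(ok))
  }
  validate_cohort_design(cohort_design)
  structure(
    list(
      n_families = as.integer(n_families),
      S_range = as.integer(S_range),
      length_range = as.integer(length_range),
      baseline_abundance = baseline_abundance,
      baseline_range = baseline_range,
      fold_changes = fold_changes,
      cohort_design = cohort_design,
      library_size_range = library_size_range,
      divergence = divergence,
      decoy_divergence = decoy_divergence,
      decoys_per_family = decoys_per_family,
      spurious_per_family = spurious_per_family,
      fragments_per_family = fragments_per_family,
      fragment_frac = fragment_frac,
      noise_subthreshold = noise_subthreshold,
      noise_multihit = noise_multihit,
      overdispersion = overdispersion,
      seed = as.integer(seed)
    ),
    class = "rpksm_truth_config"
  )
}

#' Default simulated cohort design
#'
#' Two-group design for each of three cohorts, matching the sample counts of
#' the three-cohort MASLD study summarised by [masld_cohort_design()].
#'
#' @return Tibble with columns `cohort`, `group`, `role`, `n`.
#' @export
default_cohort_design <- function() {
  masld_cohort_design() |>
    dplyr::group_by(.data$cohort, .data$group, .data$role) |>
    dplyr::summarise(n = sum(.data$n_samples), .groups = "drop") |>
    dplyr::arrange(.data$cohort, dplyr::desc(.data$role == "control"))
}

validate_cohort_design <- function(design) {
  if (!is.data.frame(design) || nrow(design) == 0) {
    abort("cohort_design must be a nonempty data frame")
  }
  need <- c("cohort", "group", "role", "n")
  missing_cols <- setdiff(need, names(design))
  if (length(missing_cols)) {
    abort(paste0("cohort_design lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (any(design$n <= 0)) {
    abort("cohort_design has a group with zero (or negative) samples")
  }
  if (!all(design$role %in% c("control", "case"))) {
    abort("cohort_design roles must be 'control' or 'case'")
  }
  n_groups <- design |>
    dplyr::count(.data$cohort) |>
    dplyr::pull(.data$n)
  if (any(n_groups != 2)) {
    abort("each cohort needs exactly two comparison groups")
  }
  invisible(design)
}
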