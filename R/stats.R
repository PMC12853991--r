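#' Two-sided Mann-Whitney test
#'
#' Rank-sum comparison of two independent groups. The reported statistic is
#' `U = min(Ua, Ub)` with midrank handling of ties. The p-value is exact
#' (full enumeration over labelings) when the combined sample size is at
#' most `exact_max` and there are no ties, and otherwise uses the normal
#' approximation with tie and continuity corrections.
#'
#' @param group_a,group_b Nonempty numeric vectors.
#' @param exact_max Exact/approximate switchover on `length(a) + length(b)`.
#' @return List of class `rpksm_mw` with elements `U`, `p_value`, `n_a`,
#'   `n_b`, `exact`.
#' @export
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))$p_value  # 0.1
mann_whitney <- function(group_a, group_b, exact_max = 12) {
  if (!length(group_a) || !length(group_b)) {
    abort("both groups must be nonempty")
  }
  n_a <- length(group_a)
  n_b <- length(group_b)
  has_ties <- anyDuplicated(c(group_a, group_b)) > 0
  use_exact <- (n_a + n_b) <= exact_max && !has_ties
  wt <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = use_exact,
                       correct = TRUE, alternative = "two.sided")
  )
  u_a <- unname(wt$statistic)
  p <- unname(wt$p.value)
  # degenerate case: all observations tied across both groups
  if (is.na(p)) p <- 1
  structure(
    list(U = min(u_a, n_a * n_b - u_a), p_value = p,
         n_a = n_a, n_b = n_b, exact = use_exact),
    class = "rpksm_mw"
  )
}

#' @export
tidy.rpksm_mw <- function(x, ...) {
  tibble::tibble(U = x$U, p_value = x$p_value, n_a = x$n_a, n_b = x$n_b,
                 exact = x$exact)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: the adjusted value of the i-th
#' smallest p is `min over j >= i of p_(j) * m / j`, capped at 1, returned
#' in the original order.
#'
#' @param p_values Numeric vector in `[0, 1]`.
#' @return Adjusted q-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Two-group comparisons per feature and cohort
#'
#' Runs a Mann-Whitney test for every (feature, cohort) pair of a long
#' feature table, summarises group medians and their ratio, and applies the
#' Benjamini-Hochberg adjustment within each cohort's batch of features.
#' Fold change is disease-role over control-role median; `0/0` is flagged
#' `flat` and `x/0` is infinite.
#'
#' @param data Long tibble with one value per (feature, sample).
#' @param samples Sample tibble with `sample_id`, `cohort`, `role`
#'   (`"control"`/`"case"`).
#' @param feature_col,value_col Column names in `data` (defaults
#'   `"family_id"`, `"rpksm"`).
#' @return Tibble of class `rpksm_comparison`: `feature`, `cohort`,
#'   `median_control`, `median_case`, `fold_change`, `direction`
#'   (`up`/`down`/`flat`, from the median ordering), `U`, `p`, `q`.
#' @export
compare_groups <- function(data, samples, feature_col = "family_id",
                           value_col = "rpksm") {
  roles <- samples |>
    dplyr::distinct(.data$cohort, .data$role) |>
    dplyr::count(.data$cohort)
  if (any(roles$n != 2)) {
    abort("every cohort must have exactly two groups (control and case)")
  }
  joined <- data |>
    dplyr::rename(feature = dplyr::all_of(feature_col),
                  value = dplyr::all_of(value_col)) |>
    dplyr::select("feature", "sample_id", "value") |>
    dplyr::inner_join(samples |>
                        dplyr::select("sample_id", "cohort", "role"),
                      by = "sample_id")
  res <- joined |>
    dplyr::group_by(.data$feature, .data$cohort) |>
    dplyr::group_modify(function(d, key) {
      a <- d$value[d$role == "case"]
      b <- d$value[d$role == "control"]
      mw <- mann_whitney(a, b)
      m_case <- median(a)
      m_ctrl <- median(b)
      fc <- m_case / m_ctrl
      tibble::tibble(
        median_control = m_ctrl, median_case = m_case,
        fold_change = fc,
        direction = dplyr::case_when(
          m_case > m_ctrl ~ "up",
          m_case < m_ctrl ~ "down",
          TRUE ~ "flat"
        ),
        U = mw$U, p = mw$p_value
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::group_by(.data$cohort) |>
    dplyr::mutate(q = bh_adjust(.data$p)) |>
    dplyr::ungroup()
  class(res) <- c("rpksm_comparison", class(res))
  res
}

#' Cross-cohort consistency calls
#'
#' A feature is `consistent-significant` when its direction of change is
#' identical (and not flat) in every cohort where it was tested and its
#' adjusted p-value is below `alpha` in at least `min_significant` cohorts;
#' `trend-only` when the directions agree but the significance count falls
#' short; otherwise `inconsistent`. Cohorts on the exemption list (e.g. a
#' cohort with no healthy-control arm) are dropped from the significance
#' count but still must agree in direction.
#'
#' @param results An [compare_groups()] tibble.
#' @param min_significant Cohorts that must reach `q < alpha` (default 2).
#' @param alpha Significance level on `q` (default 0.05).
#' @param exempt_cohorts Cohort ids excluded from the significance count.
#' @return Tibble: `feature`, `direction`, `n_cohorts`, `n_significant`,
#'   `verdict`. Features tested in fewer than two cohorts are skipped with
#'   a warning.
#' @export
cross_cohort_consistency <- function(results, min_significant = 2,
                                     alpha = 0.05,
                                     exempt_cohorts = character()) {
  few <- results |>
    dplyr::count(.data$feature) |>
    dplyr::filter(.data$n < 2)
  if (nrow(few)) {
    warn(paste0("feature(s) tested in fewer than 2 cohorts skipped: ",
                paste(few$feature, collapse = ", ")))
  }
  results |>
    dplyr::anti_join(few, by = "feature") |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(
      n_cohorts = dplyr::n(),
      same_direction = dplyr::n_distinct(.data$direction) == 1 &&
        all(.data$direction != "flat"),
      direction = if (dplyr::n_distinct(.data$direction) == 1)
        .data$direction[1] else "mixed",
      n_significant = sum(.data$q < .env$alpha &
                            !(.data$cohort %in% .env$exempt_cohorts)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      verdict = dplyr::case_when(
        .data$same_direction &
          .data$n_significant >= .env$min_significant ~
          "consistent-significant",
        .data$same_direction ~ "trend-only",
        TRUE ~ "inconsistent"
      )
    ) |>
    dplyr::select("feature", "direction", "n_cohorts", "n_significant",
                  "verdict")
}

#' Universal single-copy gene negative control
#'
#' Runs the group comparison restricted to the universal single-copy gene
#' (USCG) families. Because every cell carries exactly one copy of each
#' USCG, their normalized abundance should not differ between phenotypic
#' groups; the control passes when no USCG family reaches `q < alpha` in
#' any cohort.
#'
#' @param data Long abundance tibble (as for [compare_groups()]).
#' @param samples Sample tibble.
#' @param uscg_families Character vector of USCG family ids present in
#'   `data`; an empty intersection is an error.
#' @param alpha Significance level.
#' @inheritParams compare_groups
#' @return List of class `rpksm_uscg`: `results` (the comparison tibble,
#'   with an extra `q_control` column), `pass` (logical), `alpha`.
#' @details The control is one procedure, so its multiplicity family is the
#'   whole batch of (USCG family, cohort) tests: the pass decision uses a
#'   single Benjamini-Hochberg adjustment over all of them (`q_control`),
#'   not the per-cohort `q` batches used for discovery comparisons.
#' @export
uscg_control <- function(data, samples, uscg_families, alpha = 0.05,
                         feature_col = "family_id", value_col = "rpksm") {
  present <- intersect(uscg_families, unique(data[[feature_col]]))
  if (!length(present)) {
    abort("no USCG families present in the abundance table")
  }
  sub <- data[data[[feature_col]] %in% present, , drop = FALSE]
  res <- compare_groups(sub, samples, feature_col, value_col)
  res$q_control <- bh_adjust(res$p)
  structure(
    list(results = res, pass = !any(res$q_control < alpha), alpha = alpha),
    class = "rpksm_uscg"
  )
}

#' @export
tidy.rpksm_uscg <- function(x, ...) tibble::as_tibble(x$results)

#' @export
glance.rpksm_uscg <- function(x, ...) {
  tibble::tibble(
    pass = x$pass, alpha = x$alpha,
    n_families = dplyr::n_distinct(x$results$feature),
    n_cohorts = dplyr::n_distinct(x$results$cohort),
    min_q = min(x$results$q_control)
  )
}

#' @export
print.rpksm_uscg <- function(x, ...) {
  cat("USCG negative control:", if (x$pass) "PASS" else "FAIL",
      sprintf("(alpha = %g, min q = %.3g)\n", x$alpha, min(x$results$q_control)))
  invisible(x)
}
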