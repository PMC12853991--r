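#' Study design of the three MASLD stool-metagenome cohorts
#'
#' The per-study breakdown of the three-cohort MASLD study design the package
#' emulates: each cohort is split into a control-role and a disease-role
#' phenotypic group, and one study contributed repeated stool samples from
#' fewer subjects, so sample and subject counts are carried separately.
#'
#' @return A tibble with one row per (cohort, group, study) combination and
#'   columns `cohort`, `group`, `role` (`"control"` or `"case"` within the
#'   cohort's comparison), `accession` (source study identifier),
#'   `n_samples` and `n_subjects`.
#' @export
#' @examples
#' design <- masld_cohort_design()
#' sum(design$n_samples)  # 554 stool metagenomes in total
masld_cohort_design <- function() {
  tibble::tribble(
    ~cohort, ~group,                               ~role,     ~accession,    ~n_samples, ~n_subjects,
    "c1",    "healthy control",                    "control", "PRJNA544527", 117L,       117L,
    "c1",    "MASLD, early-stage fibrosis (F0-F2)", "case",    "PRJEB14215",  73L,        73L,
    "c1",    "MASLD, early-stage fibrosis (F0-F2)", "case",    "PRJNA420817", 48L,        10L,
    "c2",    "MASLD, early-stage fibrosis (F0-F2)", "control", "PRJNA373901", 72L,        72L,
    "c2",    "MASLD, advanced fibrosis (F3-F4)",    "case",    "PRJNA373901", 14L,        14L,
    "c3",    "healthy control",                    "control", "PRJEB6337",   105L,       105L,
    "c3",    "MASLD-related cirrhosis",            "case",    "PRJEB6337",   125L,       125L
  )
}

#' Summarise a cohort design
#'
#' Sums sample and subject counts overall and per cohort, the bookkeeping a
#' study-design table must reproduce before any sample-level simulation.
#'
#' @param design A design tibble as returned by [masld_cohort_design()].
#' @return A tibble with one row per cohort plus a `"total"` row, columns
#'   `cohort`, `n_samples`, `n_subjects`, `n_case_subjects`.
#' @export
cohort_totals <- function(design) {
  per <- design |>
    dplyr::group_by(.data$cohort) |>
    dplyr::summarise(
      n_case_subjects = sum(.data$n_subjects[.data$role == "case"]),
      n_samples = sum(.data$n_samples),
      n_subjects = sum(.data$n_subjects),
      .groups = "drop"
    ) |>
    dplyr::select("cohort", "n_samples", "n_subjects", "n_case_subjects")
  dplyr::bind_rows(
    per,
    tibble::tibble(
      cohort = "total",
      n_samples = sum(per$n_samples),
      n_subjects = sum(per$n_subjects),
      n_case_subjects = sum(per$n_case_subjects)
    )
  )
}
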