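#' Pipeline configuration
#'
#' All numeric thresholds used anywhere in the pipeline live in one place, so
#' a run can be reproduced from its configuration echo alone. Defaults follow
#' the published protocol the package implements: strict E-value < 1e-10 for
#' read alignments, >90% profile coverage with E < 0.01 and independent
#' E < 0.01 for genome/plasmid scans, >95% genome completeness, the
#' core (>80%) / accessory (20-80%) / highly accessory (<20%) prevalence
#' brackets, >0.5% genus and >0.2% species mean-abundance retention, the
#' >100-genome clade rule, and alpha = 0.05 with significance required in at
#' least two cohorts for a consistency call.
#'
#' @param e_max_reads Strict upper E-value bound for read alignment hits.
#' @param e_max_scan Full-sequence E-value bound for profile scan hits.
#' @param ie_max_scan Independent (per-domain) E-value bound for scan hits.
#' @param cov_min Minimum profile coverage fraction (strict `>`).
#' @param gap_max Alignment rows with gap fraction `>= gap_max` are removed.
#' @param completeness_min Genome completeness percent (strict `>`).
#' @param prevalence_core Prevalence above which a gene is core (strict `>`).
#' @param prevalence_accessory_low Lower bound of the accessory bracket
#'   (inclusive); below it (and above zero) a gene is highly accessory.
#' @param genus_abundance_min Mean relative abundance (percent) a genus must
#'   exceed (strict `>`) to be retained.
#' @param species_abundance_min As above for species.
#' @param clade_min_genomes Clades need strictly more than this many retained
#'   genomes to enter prevalence classification.
#' @param alpha Significance level on BH-adjusted p-values.
#' @param min_significant_cohorts Cohorts that must reach `q < alpha` for a
#'   consistent-significant verdict.
#' @param d_max Maximum leaf-to-reference path distance (substitutions per
#'   site) for gene-family delimitation.
#' @param length_frac_bounds Length filter as fractions of the reference
#'   length, inclusive bounds.
#' @param seed Integer seed controlling every stochastic step.
#' @param cohort_exemptions Cohort ids dropped from the significance count of
#'   the consistency rule (e.g. a cohort with no healthy-control arm).
#'
#' @return A list of class `rpksm_config`.
#' @export
#' @examples
#' cfg <- pipeline_config()
#' validate_config(cfg)
pipeline_config <- function(e_max_reads = 1e-10,
                            e_max_scan = 0.01,
                            ie_max_scan = 0.01,
                            cov_min = 0.90,
                            gap_max = 0.30,
                            completeness_min = 95,
                            prevalence_core = 0.80,
                            prevalence_accessory_low = 0.20,
                            genus_abundance_min = 0.5,
                            species_abundance_min = 0.2,
                            clade_min_genomes = 100,
                            alpha = 0.05,
                            min_significant_cohorts = 2,
                            d_max = 0.6,
                            length_frac_bounds = c(0.5, 1.5),
                            seed = 1L,
                            cohort_exemptions = character()) {
  cfg <- list(
    e_max_reads = e_max_reads,
    e_max_scan = e_max_scan,
    ie_max_scan = ie_max_scan,
    cov_min = cov_min,
    gap_max = gap_max,
    completeness_min = completeness_min,
    prevalence_core = prevalence_core,
    prevalence_accessory_low = prevalence_accessory_low,
    genus_abundance_min = genus_abundance_min,
    species_abundance_min = species_abundance_min,
    clade_min_genomes = clade_min_genomes,
    alpha = alpha,
    min_significant_cohorts = min_significant_cohorts,
    d_max = d_max,
    length_frac_bounds = length_frac_bounds,
    seed = as.integer(seed),
    cohort_exemptions = as.character(cohort_exemptions)
  )
  class(cfg) <- "rpksm_config"
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks every invariant of the configuration and returns the violations
#' (empty character vector when the configuration is valid) rather than
#' throwing, so callers can report all problems at once.
#'
#' @param config An [pipeline_config()] object.
#' @return Character vector of violations; `character(0)` means valid.
#' @export
validate_config <- function(config) {
  v <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  in01 <- function(x) is.numeric(x) && length(x) == 1 && x >= 0 && x <= 1

  chk(is.numeric(config$e_max_reads) && config$e_max_reads > 0,
      "e_max_reads: must be a positive number")
  chk(is.numeric(config$e_max_scan) && config$e_max_scan > 0,
      "e_max_scan: must be a positive number")
  chk(is.numeric(config$ie_max_scan) && config$ie_max_scan > 0,
      "ie_max_scan: must be a positive number")
  chk(in01(config$cov_min), "cov_min: must lie in [0, 1]")
  chk(in01(config$gap_max), "gap_max: must lie in [0, 1]")
  chk(is.numeric(config$completeness_min) &&
        config$completeness_min >= 0 && config$completeness_min <= 100,
      "completeness_min: must lie in [0, 100]")
  chk(in01(config$prevalence_core), "prevalence_core: must lie in [0, 1]")
  chk(in01(config$prevalence_accessory_low),
      "prevalence_accessory_low: must lie in [0, 1]")
  chk(isTRUE(config$prevalence_accessory_low <= config$prevalence_core),
      "prevalence_accessory_low: must not exceed prevalence_core")
  chk(is.numeric(config$genus_abundance_min) && config$genus_abundance_min >= 0,
      "genus_abundance_min: must be nonnegative")
  chk(is.numeric(config$species_abundance_min) &&
        config$species_abundance_min >= 0,
      "species_abundance_min: must be nonnegative")
  chk(is.numeric(config$clade_min_genomes) && config$clade_min_genomes >= 0,
      "clade_min_genomes: must be nonnegative")
  chk(in01(config$alpha), "alpha: must lie in [0, 1]")
  chk(is.numeric(config$min_significant_cohorts) &&
        config$min_significant_cohorts >= 1,
      "min_significant_cohorts: must be >= 1")
  chk(is.numeric(config$d_max) && config$d_max >= 0,
      "d_max: must be nonnegative")
  chk(is.numeric(config$length_frac_bounds) &&
        length(config$length_frac_bounds) == 2 &&
        config$length_frac_bounds[1] > 0 &&
        config$length_frac_bounds[1] <= config$length_frac_bounds[2],
      "length_frac_bounds: must be two positive increasing fractions")
  chk(is.integer(config$seed) && length(config$seed) == 1 &&
        !is.na(config$seed),
      "seed: must be a single integer")
  v
}

#' @export
print.rpksm_config <- function(x, ...) {
  cat("<rpksm pipeline configuration>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-26s %s\n", nm, paste(x[[nm]], collapse = ", ")))
  }
  invisible(x)
}
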