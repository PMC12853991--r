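PIPELINE_STAGES <- c("simulate", "quantify", "taxa", "compare", "screen")

manifest_requirements <- list(
  quantify = c("samples", "hits_dir", "families", "members"),
  taxa = c("samples", "taxa"),
  compare = c("samples", "rpksm"),
  screen = c("scan", "genomes", "plasmids")
)

#' Run the pipeline end to end
#'
#' Executes the requested stages in order — simulate, quantify, taxa,
#' compare, screen — writing versioned TSV outputs and a structured log
#' (full configuration echo plus per-stage record counts) into `outdir`.
#' With no `manifest`, the `simulate` stage must be first and generates
#' every downstream input with the ground truth configs; with a
#' `manifest`, stages consume the listed prebuilt files. Manifest entries
#' are validated before any stage runs, so a failed run writes no partial
#' outputs.
#'
#' @param config A [pipeline_config()]; validated before anything runs.
#' @param outdir Output directory (created).
#' @param stages Subset of `c("simulate", "quantify", "taxa", "compare",
#'   "screen")`, executed in canonical order.
#' @param manifest Named list of input paths for non-simulated stages:
#'   `samples`, `hits_dir`, `families`, `members`, `taxa`, `rpksm`,
#'   `scan`, `genomes`, `plasmids`.
#' @param truth A [truth_config()] for the simulate stage. The default
#'   derives its seed from `config` and uses a scaled demonstration design
#'   (three cohorts, 20 control / 20 case samples each) so a full synthetic
#'   run stays light; pass an explicit [truth_config()] to simulate at the
#'   full 554-sample study design.
#' @param screen_truth A [screen_truth_config()] for the simulate stage;
#'   `NULL` uses a small default screen.
#' @return List of class `rpksm_run`: `outdir`, `files`, `log`, and the
#'   in-memory stage results (`samples`, `abundance`, `taxa`,
#'   `comparisons`, `consistency`, `uscg`, `prevalence`,
#'   `plasmid_counts`).
#' @export
run_pipeline <- function(config = pipeline_config(),
                         outdir,
                         stages = PIPELINE_STAGES,
                         manifest = NULL,
                         truth = NULL,
                         screen_truth = NULL) {
  violations <- validate_config(config)
  if (length(violations)) {
    abort(paste0("invalid configuration:\n  ",
                 paste(violations, collapse = "\n  ")))
  }
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  if (!length(stages)) abort("no recognised stages requested")

  # fail-fast manifest validation before any stage runs
  if (!"simulate" %in% stages) {
    if (is.null(manifest)) {
      abort("a manifest is required when the simulate stage is not run")
    }
    needed <- unique(unlist(manifest_requirements[
      intersect(stages, names(manifest_requirements))]))
    needed <- setdiff(needed, "rpksm")  # may be produced by quantify
    if ("compare" %in% stages && !"quantify" %in% stages) {
      needed <- c(needed, "rpksm")
    }
    missing_entries <- setdiff(needed, names(manifest))
    if (length(missing_entries)) {
      abort(paste0("manifest missing entries: ",
                   paste(missing_entries, collapse = ", ")))
    }
    gone <- unlist(manifest[needed])
    gone <- gone[!file.exists(gone)]
    if (length(gone)) {
      abort(paste0("manifest file(s) not found: ",
                   paste(gone, collapse = ", ")))
    }
  }
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  log_lines <- c("# pipeline run", format(Sys.time(), "# %Y-%m-%d"),
                 "# configuration:")
  for (nm in names(unclass(config))) {
    log_lines <- c(log_lines, sprintf("#   %s = %s", nm,
                                      paste(config[[nm]], collapse = ",")))
  }
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))
  files <- character()
  state <- list()

  if ("simulate" %in% stages) {
    if (is.null(truth)) {
      truth <- truth_config(
        cohort_design = tibble::tibble(
          cohort = rep(c("c1", "c2", "c3"), each = 2),
          group = rep(c("control", "disease"), 3),
          role = rep(c("control", "case"), 3),
          n = rep(20L, 6)),
        seed = config$seed)
    }
    sim <- simulate_gene_families(truth)
    samples <- simulate_cohort_design(truth)
    hits_dir <- file.path(outdir, "hits")
    hits <- simulate_alignment_hits(sim, samples, truth, dir = hits_dir)
    taxa <- simulate_taxa_table(samples, seed = truth$seed + 3L)
    if (is.null(screen_truth)) {
      screen_truth <- screen_truth_config(
        clades = tibble::tibble(clade = c("Agathobacter", "Bacteroides"),
                                n_genomes = c(150L, 150L)),
        prevalence = tidyr::expand_grid(
          clade = c("Agathobacter", "Bacteroides"),
          gene = sim$families$family_id[1:2]) |>
          dplyr::mutate(prevalence = c(0.9, 0.3, 0.1, 0.6)),
        plasmid_counts = setNames(c(4L, 2L), sim$families$family_id[1:2]),
        seed = truth$seed + 4L
      )
    }
    screen <- simulate_screen_inputs(screen_truth,
                                     dir = file.path(outdir, "screen"))
    readr::write_tsv(samples, file.path(outdir, "samples.tsv"),
                     progress = FALSE)
    readr::write_tsv(sim$families, file.path(outdir, "families.tsv"),
                     progress = FALSE)
    readr::write_tsv(sim$members |> dplyr::filter(.data$is_member),
                     file.path(outdir, "members.tsv"), progress = FALSE)
    writeLines(sim$fasta, file.path(outdir, "pangenome.faa"))
    write_metaphlan(taxa, file.path(outdir, "taxa.tsv"))
    note("stage simulate: %d samples, %d families, %d fasta records, %d genomes",
         nrow(samples), nrow(sim$families), nrow(sim$members),
         nrow(screen$genomes))
    state <- list(sim = sim, samples = samples, hits = hits, taxa = taxa,
                  screen = screen)
    manifest <- list(
      samples = file.path(outdir, "samples.tsv"),
      hits_dir = hits_dir,
      families = file.path(outdir, "families.tsv"),
      members = file.path(outdir, "members.tsv"),
      taxa = file.path(outdir, "taxa.tsv"),
      scan = screen$files[["scan"]],
      genomes = screen$files[["genomes"]],
      plasmids = screen$files[["plasmids"]]
    )
  }

  read_samples <- function() {
    if (!is.null(state$samples)) state$samples else
      readr::read_tsv(manifest$samples, show_col_types = FALSE,
                      progress = FALSE)
  }

  if ("quantify" %in% stages) {
    samples <- read_samples()
    families <- if (!is.null(state$sim)) state$sim$families else
      readr::read_tsv(manifest$families, show_col_types = FALSE,
                      progress = FALSE)
    members <- if (!is.null(state$sim)) {
      state$sim$members |> dplyr::filter(.data$is_member)
    } else {
      readr::read_tsv(manifest$members, show_col_types = FALSE,
                      progress = FALSE)
    }
    abundance <- build_abundance_table(manifest$hits_dir, families,
                                       members, samples,
                                       e_max = config$e_max_reads)
    files <- c(files, write_abundance_table(abundance, outdir))
    state$abundance <- abundance
    state$families <- families
    note("stage quantify: %d families x %d samples, e_max = %g",
         dplyr::n_distinct(abundance$family_id),
         dplyr::n_distinct(abundance$sample_id), config$e_max_reads)
  }

  if ("taxa" %in% stages) {
    samples <- read_samples()
    taxa <- if (!is.null(state$taxa)) state$taxa else
      read_metaphlan(manifest$taxa)
    cleaned <- clean_clades(taxa, samples) |>
      abundance_threshold_filter(samples,
                                 genus_min = config$genus_abundance_min,
                                 species_min = config$species_abundance_min)
    shared <- shared_clades(cleaned, samples, rank = "genus")
    readr::write_tsv(cleaned, file.path(outdir, "taxa_filtered.tsv"),
                     progress = FALSE)
    readr::write_tsv(shared$summary, file.path(outdir, "taxa_shared.tsv"),
                     progress = FALSE)
    state$taxa_filtered <- cleaned
    state$shared <- shared
    note("stage taxa: %d clade rows retained, %d shared genera (genus_min = %g, species_min = %g)",
         dplyr::n_distinct(cleaned$clade), length(shared$shared),
         config$genus_abundance_min, config$species_abundance_min)
  }

  if ("compare" %in% stages) {
    samples <- read_samples()
    abundance <- state$abundance
    if (is.null(abundance)) {
      wide <- readr::read_tsv(manifest$rpksm, show_col_types = FALSE,
                              progress = FALSE)
      abundance <- wide |>
        tidyr::pivot_longer(-"family_id", names_to = "sample_id",
                            values_to = "rpksm")
    }
    comparisons <- compare_groups(abundance, samples)
    consistency <- cross_cohort_consistency(
      comparisons, min_significant = config$min_significant_cohorts,
      alpha = config$alpha, exempt_cohorts = config$cohort_exemptions)
    readr::write_tsv(comparisons, file.path(outdir, "comparisons.tsv"),
                     progress = FALSE)
    readr::write_tsv(consistency, file.path(outdir, "consistency.tsv"),
                     progress = FALSE)
    state$comparisons <- comparisons
    state$consistency <- consistency
    fams <- state$families
    if (!is.null(fams) && "pathway_tag" %in% names(fams) &&
        any(fams$pathway_tag == "USCG")) {
      uscg <- uscg_control(abundance, samples,
                           fams$family_id[fams$pathway_tag == "USCG"],
                           alpha = config$alpha)
      state$uscg <- uscg
      note("stage compare: USCG control %s",
           if (uscg$pass) "passed" else "FAILED")
    }
    note("stage compare: %d results, alpha = %g, min_significant = %d, exempt = [%s]",
         nrow(comparisons), config$alpha, config$min_significant_cohorts,
         paste(config$cohort_exemptions, collapse = ","))
  }

  if ("screen" %in% stages) {
    scan <- if (!is.null(state$screen)) state$screen$scan else
      parse_domtblout(manifest$scan)
    genomes <- if (!is.null(state$screen)) state$screen$genomes else
      readr::read_tsv(manifest$genomes, show_col_types = FALSE,
                      progress = FALSE)
    plasmids <- if (!is.null(state$screen)) state$screen$plasmids else
      readr::read_tsv(manifest$plasmids, show_col_types = FALSE,
                      progress = FALSE)
    presence <- call_presence(scan, cov_min = config$cov_min,
                              e_max = config$e_max_scan,
                              ie_max = config$ie_max_scan)
    retained <- filter_genomes(genomes,
                               completeness_min = config$completeness_min)
    prevalence <- clade_prevalence(
      presence, retained, min_genomes = config$clade_min_genomes,
      core_min = config$prevalence_core,
      accessory_low = config$prevalence_accessory_low)
    curated <- curate_plasmids(plasmids)
    counts <- plasmid_gene_counts(presence, curated)
    readr::write_tsv(prevalence, file.path(outdir, "prevalence.tsv"),
                     progress = FALSE)
    readr::write_tsv(prevalence_matrix(prevalence),
                     file.path(outdir, "prevalence_matrix.tsv"),
                     progress = FALSE)
    readr::write_tsv(counts, file.path(outdir, "plasmid_counts.tsv"),
                     progress = FALSE)
    state$prevalence <- prevalence
    state$plasmid_counts <- counts
    note("stage screen: %d/%d genomes retained (completeness_min = %g), %d presence calls, cov_min = %g, %d/%d plasmids curated",
         nrow(retained), nrow(genomes), config$completeness_min,
         nrow(presence), config$cov_min, nrow(curated), nrow(plasmids))
  }

  log_path <- file.path(outdir, "run.log")
  writeLines(log_lines, log_path)
  structure(
    c(list(outdir = outdir, log = log_lines, log_path = log_path,
           config = config, manifest = manifest),
      state),
    class = "rpksm_run"
  )
}

#' @export
print.rpksm_run <- function(x, ...) {
  cat("<rpksm pipeline run>", x$outdir, "\n")
  cat(paste0("  ", grep("^stage", x$log, value = TRUE), "\n"), sep = "")
  invisible(x)
}

#' @export
glance.rpksm_run <- function(x, ...) {
  tibble::tibble(
    outdir = x$outdir,
    n_samples = if (!is.null(x$samples)) nrow(x$samples) else NA_integer_,
    n_families = if (!is.null(x$abundance))
      dplyr::n_distinct(x$abundance$family_id) else NA_integer_,
    n_comparisons = if (!is.null(x$comparisons))
      nrow(x$comparisons) else NA_integer_,
    uscg_pass = if (!is.null(x$uscg)) x$uscg$pass else NA
  )
}
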