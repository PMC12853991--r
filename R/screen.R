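#' Parse a HMMER3 per-domain scan table
#'
#' Reads the per-domain tabular output dialect of `hmmscan` (domtblout):
#' `#`-prefixed comment lines are skipped and each data line is
#' whitespace-split into the 22 fixed fields plus a free-text description
#' tail. The fields the presence caller needs are extracted: target
#' (profile) name and length, query ORF name, full-sequence E-value,
#' per-domain independent E-value, and the profile (hmm) coordinates of the
#' domain. The replicon (genome or plasmid) id is recovered from the ORF id
#' by stripping its trailing `_<number>` ORF index.
#'
#' @param path File path.
#' @return Tibble: `orf_id`, `replicon_id`, `profile_id`,
#'   `profile_length`, `hmm_from`, `hmm_to`, `e_value_full`,
#'   `e_value_independent`.
#' @export
parse_domtblout <- function(path) {
  if (!file.exists(path)) abort(paste0("no such scan table: ", path))
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  empty <- tibble::tibble(
    orf_id = character(), replicon_id = character(),
    profile_id = character(), profile_length = integer(),
    hmm_from = integer(), hmm_to = integer(),
    e_value_full = numeric(), e_value_independent = numeric()
  )
  if (!length(lines)) return(empty)
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 22)) {
    bad <- which(nf < 22)[1]
    abort(sprintf("scan table line %d has %d fields, expected >= 22",
                  bad, nf[bad]))
  }
  get <- function(k) vapply(fields, `[`, character(1), k)
  out <- tibble::tibble(
    orf_id = get(4),
    profile_id = get(1),
    profile_length = as.integer(get(3)),
    hmm_from = as.integer(get(16)),
    hmm_to = as.integer(get(17)),
    e_value_full = as.numeric(get(7)),
    e_value_independent = as.numeric(get(13))
  ) |>
    dplyr::mutate(replicon_id = sub("_[0-9]+$", "", .data$orf_id),
                  .after = "orf_id")
  validate_scan_hits(out)
  out
}

validate_scan_hits <- function(hits) {
  bad <- hits$hmm_from < 1 | hits$hmm_from > hits$hmm_to |
    hits$hmm_to > hits$profile_length
  if (any(bad)) {
    abort(paste0("invalid profile coordinates for ORF(s): ",
                 paste(head(hits$orf_id[bad], 5), collapse = ", ")))
  }
  invisible(hits)
}

#' Write a scan-hit tibble in the per-domain table dialect
#'
#' Emits one line per hit with the 22 standard fields (fields the package
#' does not model are filled with placeholders) plus a description, so the
#' real [parse_domtblout()] path is exercised on simulated data.
#'
#' @param hits Tibble as produced by [simulate_screen_inputs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_domtblout <- function(hits, path) {
  header <- paste0(
    "#                                                               ",
    "--- full sequence --- -------------- this domain -------------   ",
    "hmm coord   ali coord   env coord\n",
    "# target name        accession   tlen query name           ",
    "accession   qlen   E-value  score  bias   #  of  c-Evalue  ",
    "i-Evalue  score  bias  from    to  from    to  from    to  acc ",
    "description of target\n#---\n"
  )
  rows <- sprintf(
    "%-20s %-10s %5d %-20s %-10s %5d %9.2g %6.1f %5.1f %3d %3d %9.2g %9.2g %6.1f %5.1f %5d %5d %5d %5d %5d %5d %4.2f %s",
    hits$profile_id, "-", hits$profile_length, hits$orf_id, "-",
    as.integer(round((hits$hmm_to - hits$hmm_from + 1) * 1.02)),
    hits$e_value_full, 150.0, 1.2, 1L, 1L,
    hits$e_value_independent, hits$e_value_independent, 148.0, 1.0,
    hits$hmm_from, hits$hmm_to,
    1L, hits$hmm_to - hits$hmm_from + 1L,
    1L, hits$hmm_to - hits$hmm_from + 1L,
    0.95, "simulated ORF"
  )
  readr::write_lines(c(sub("\n$", "", header), rows), path)
  invisible(path)
}

#' Call gene presence on replicons from scan hits
#'
#' A replicon (genome or plasmid) carries a gene family when at least one
#' of its ORF hits covers strictly more than `cov_min` of the profile
#' (`(hmm_to - hmm_from + 1) / profile_length`) with full-sequence E-value
#' and independent E-value both strictly below their cutoffs.
#'
#' @param hits Scan-hit tibble (see [parse_domtblout()]).
#' @param cov_min Strict profile-coverage bound (default 0.90).
#' @param e_max,ie_max Strict E-value bounds (defaults 0.01).
#' @return Tibble of distinct `(replicon_id, profile_id)` presence pairs.
#' @export
call_presence <- function(hits, cov_min = 0.90, e_max = 0.01,
                          ie_max = 0.01) {
  validate_scan_hits(hits)
  hits |>
    dplyr::filter(
      (.data$hmm_to - .data$hmm_from + 1) / .data$profile_length >
        .env$cov_min,
      .data$e_value_full < .env$e_max,
      .data$e_value_independent < .env$ie_max
    ) |>
    dplyr::distinct(.data$replicon_id, .data$profile_id)
}

#' Retain complete genomes carrying all five USCGs
#'
#' Keeps genomes with completeness strictly above `completeness_min`
#' percent and, when required, all five universal single-copy genes
#' present.
#'
#' @param genomes Genome metadata tibble with `completeness` and the five
#'   USCG flag columns (`argS`, `dnaA`, `rpoA`, `rpoB`, `rpoC`).
#' @param completeness_min Strict completeness bound (default 95).
#' @param require_all_uscg Require all five flags (default `TRUE`).
#' @return The filtered genome tibble.
#' @export
filter_genomes <- function(genomes, completeness_min = 95,
                           require_all_uscg = TRUE) {
  stopifnot(nrow(genomes) >= 1)
  keep <- genomes$completeness > completeness_min
  if (require_all_uscg) {
    flags <- as.matrix(genomes[, USCG_NAMES])
    keep <- keep & rowSums(flags) == 5
  }
  genomes[keep, , drop = FALSE]
}

#' Per-clade gene prevalence over retained genomes
#'
#' For every (clade, gene) pair, the fraction of the clade's retained
#' genomes that carry the gene, with the prevalence class from
#' [classify_prevalence()]. Clades with at most `min_genomes` retained
#' genomes are excluded (strict `>`). Computed at the rank given by
#' `clade_col` (genus by default; pass `"species"` for conspecific
#' prevalence from the same presence calls).
#'
#' @param presence Presence pairs from [call_presence()].
#' @param genomes Retained genome tibble (after [filter_genomes()]).
#' @param genes Character vector of gene/family ids to report (defaults to
#'   the genes observed in `presence`).
#' @param min_genomes Strict lower bound on clade size (default 100).
#' @param clade_col Genome column holding the clade label.
#' @param core_min,accessory_low Classification bounds (see
#'   [classify_prevalence()]).
#' @return Tibble of class `rpksm_prevalence`: `clade`, `gene`,
#'   `n_genomes`, `n_carrying`, `prevalence`, `class`.
#' @export
clade_prevalence <- function(presence, genomes, genes = NULL,
                             min_genomes = 100, clade_col = "genus",
                             core_min = 0.80, accessory_low = 0.20) {
  if (is.null(genes)) genes <- sort(unique(presence$profile_id))
  sizes <- genomes |>
    dplyr::count(clade = .data[[clade_col]], name = "n_genomes") |>
    dplyr::filter(.data$n_genomes > .env$min_genomes)
  if (!nrow(sizes)) {
    out <- tibble::tibble(clade = character(), gene = character(),
                          n_genomes = integer(), n_carrying = integer(),
                          prevalence = numeric(), class = character())
    class(out) <- c("rpksm_prevalence", class(out))
    return(out)
  }
  carry <- presence |>
    dplyr::inner_join(
      genomes |> dplyr::select(replicon_id = "genome_id",
                               clade = dplyr::all_of(clade_col)),
      by = "replicon_id") |>
    dplyr::distinct(.data$clade, gene = .data$profile_id,
                    .data$replicon_id) |>
    dplyr::count(.data$clade, .data$gene, name = "n_carrying")
  out <- tidyr::expand_grid(sizes, gene = genes) |>
    dplyr::left_join(carry, by = c("clade", "gene")) |>
    dplyr::mutate(
      n_carrying = dplyr::coalesce(.data$n_carrying, 0L),
      prevalence = .data$n_carrying / .data$n_genomes,
      class = classify_prevalence(.data$prevalence, core_min,
                                  accessory_low)
    )
  class(out) <- c("rpksm_prevalence", class(out))
  out
}

#' Classify a prevalence fraction
#'
#' Core above 80% (strict), accessory in the closed 20-80% bracket, highly
#' accessory strictly between 0 and 20%, absent at exactly zero.
#'
#' @param p Prevalence fraction(s) in `[0, 1]`.
#' @param core_min Strict lower bound of the core class (default 0.80).
#' @param accessory_low Inclusive lower bound of the accessory bracket
#'   (default 0.20).
#' @return Character vector: `"core"`, `"accessory"`,
#'   `"highly_accessory"` or `"absent"`.
#' @export
#' @examples
#' classify_prevalence(c(0.85, 0.80, 0.20, 0.1, 0))
classify_prevalence <- function(p, core_min = 0.80, accessory_low = 0.20) {
  if (any(p < 0 | p > 1)) abort("prevalence must lie in [0, 1]")
  dplyr::case_when(
    p > core_min ~ "core",
    p >= accessory_low ~ "accessory",
    p > 0 ~ "highly_accessory",
    TRUE ~ "absent"
  )
}

#' Curate a plasmid collection
#'
#' Drops partial sequences, plasmids without a host assignment, and
#' sequencing internal controls.
#'
#' @param plasmids Plasmid metadata tibble with `host_assignment`,
#'   `partial_flag`, `control_flag`.
#' @return The curated plasmid tibble.
#' @export
curate_plasmids <- function(plasmids) {
  stopifnot(nrow(plasmids) >= 1)
  plasmids |>
    dplyr::filter(
      !.data$partial_flag,
      !.data$control_flag,
      !is.na(.data$host_assignment),
      tolower(.data$host_assignment) != "unassigned"
    )
}

#' Count distinct curated plasmids carrying each gene
#'
#' A plasmid counts once per gene regardless of copy number; only plasmids
#' in the curated set count.
#'
#' @param presence Presence pairs from [call_presence()] on the scan table.
#' @param curated Curated plasmid tibble (see [curate_plasmids()]).
#' @param genes Genes to report (defaults to those observed).
#' @return Tibble `gene`, `n_plasmids`.
#' @export
plasmid_gene_counts <- function(presence, curated, genes = NULL) {
  if (is.null(genes)) genes <- sort(unique(presence$profile_id))
  counts <- presence |>
    dplyr::filter(.data$replicon_id %in% curated$plasmid_id) |>
    dplyr::distinct(gene = .data$profile_id, .data$replicon_id) |>
    dplyr::count(.data$gene, name = "n_plasmids")
  tibble::tibble(gene = genes) |>
    dplyr::left_join(counts, by = "gene") |>
    dplyr::mutate(n_plasmids = dplyr::coalesce(.data$n_plasmids, 0L))
}

#' Heatmap-ready prevalence matrix
#'
#' Pivots a prevalence table to a clade-by-gene tibble of class labels,
#' the layout of a class-coded prevalence heatmap.
#'
#' @param prevalence An [clade_prevalence()] tibble.
#' @return Wide tibble, first column `clade`, one column per gene.
#' @export
prevalence_matrix <- function(prevalence) {
  prevalence |>
    dplyr::select("clade", "gene", "class") |>
    tidyr::pivot_wider(names_from = "gene", values_from = "class",
                       values_fill = "absent")
}
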