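ALN_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
              "gapopen", "qstart", "qend", "sstart", "send",
              "evalue", "bitscore")

#' Parse a 12-column tabular alignment file
#'
#' Reads the standard tab-separated protein-alignment dialect (qseqid,
#' sseqid, pident, length, mismatch, gapopen, qstart, qend, sstart, send,
#' evalue, bitscore), one hit per row. Rows with the wrong number of fields
#' are rejected with their line number.
#'
#' @param path File path.
#' @return Tibble with the 12 standard columns, E-values as doubles.
#' @export
parse_alignment_table <- function(path) {
  if (!file.exists(path)) abort(paste0("no such alignment file: ", path))
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(tibble::as_tibble(setNames(
      c(rep(list(character()), 2), rep(list(numeric()), 10)), ALN_COLS)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12)) {
    bad <- which(nf != 12)[1]
    abort(sprintf("line %d has %d columns, expected 12", bad, nf[bad]))
  }
  m <- matrix(unlist(fields), ncol = 12, byrow = TRUE)
  tibble::tibble(
    qseqid = m[, 1], sseqid = m[, 2],
    pident = as.numeric(m[, 3]), length = as.integer(m[, 4]),
    mismatch = as.integer(m[, 5]), gapopen = as.integer(m[, 6]),
    qstart = as.integer(m[, 7]), qend = as.integer(m[, 8]),
    sstart = as.integer(m[, 9]), send = as.integer(m[, 10]),
    evalue = as.numeric(m[, 11]), bitscore = as.numeric(m[, 12])
  )
}

#' Retain one best hit per read
#'
#' Discards hits at or above the E-value threshold (strict `< e_max`), then
#' keeps exactly one hit per read: lowest E-value, ties broken by highest
#' bit score, then by lexicographically smallest subject id so the result is
#' deterministic.
#'
#' @param hits Alignment tibble (needs `qseqid`, `sseqid`, `evalue`,
#'   `bitscore`).
#' @param e_max Strict E-value cutoff (default 1e-10).
#' @return Tibble with one row per surviving read.
#' @export
best_hit_filter <- function(hits, e_max = 1e-10) {
  hits |>
    dplyr::filter(.data$evalue < e_max) |>
    dplyr::arrange(.data$qseqid, .data$evalue,
                   dplyr::desc(.data$bitscore), .data$sseqid) |>
    dplyr::distinct(.data$qseqid, .keep_all = TRUE)
}

#' Count best hits per gene family
#'
#' Each retained read increments exactly one family — the family of its
#' single best gene. Reads whose best gene maps to no family are tallied in
#' an `"unassigned"` bucket so that family counts plus unassigned always
#' equal the number of retained reads.
#'
#' @param best_hits Output of [best_hit_filter()] for one sample.
#' @param members Tibble mapping `member_id` to `family_id`; a gene in two
#'   families is an error.
#' @return Tibble `family_id`, `count` including an `"unassigned"` row
#'   (count may be 0) and a zero row for families with no members hit.
#' @export
assign_reads_to_families <- function(best_hits, members) {
  if (anyDuplicated(members$member_id)) {
    dup <- members$member_id[duplicated(members$member_id)][1]
    abort(paste0("gene '", dup, "' maps to more than one family"))
  }
  if (anyDuplicated(best_hits$qseqid)) {
    abort("duplicate read ids after best-hit filtering")
  }
  counted <- best_hits |>
    dplyr::left_join(members |> dplyr::select("member_id", "family_id"),
                     by = c(sseqid = "member_id")) |>
    dplyr::mutate(family_id = dplyr::coalesce(.data$family_id,
                                              "unassigned")) |>
    dplyr::count(.data$family_id, name = "count")
  tibble::tibble(family_id = c(unique(members$family_id), "unassigned")) |>
    dplyr::left_join(counted, by = "family_id") |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L))
}

#' Reads per kilobase per family size per million reads
#'
#' The package's abundance statistic: a read count normalized by the
#' family's gene length in kilobases, its size `S` (number of member genes),
#' and the sample's library size in millions —
#' `RPKSM = count / (Lkb * S * library_size / 1e6)`. By default `Lkb` is
#' the mean member gene length (nucleotides / 1000); the `"total"` basis
#' uses the summed member length instead, which penalizes family size a
#' second time and is provided for comparison only.
#'
#' @param count Nonnegative read count(s).
#' @param mean_length_nt Mean member gene length in nucleotides (> 0).
#'   Amino-acid lengths must be converted (x 3) before calling.
#' @param S Family size, number of member genes (>= 1).
#' @param library_size Total reads in the sample (> 0).
#' @param length_basis `"mean"` (default) or `"total"`.
#' @return Nonnegative RPKSM value(s); 0 exactly when `count` is 0.
#' @export
#' @examples
#' compute_rpksm(100, 1000, 1, 1e6)         # 100
#' compute_rpksm(50, 500, 4, 2e6)           # 12.5
compute_rpksm <- function(count, mean_length_nt, S, library_size,
                          length_basis = c("mean", "total")) {
  length_basis <- match.arg(length_basis)
  if (any(S < 1) || any(mean_length_nt <= 0)) {
    abort("family size and mean length must be positive")
  }
  if (any(library_size <= 0)) abort("library_size must be positive")
  l_kb <- mean_length_nt / 1000
  if (length_basis == "total") l_kb <- l_kb * S
  count / (l_kb * S * library_size / 1e6)
}

#' Build a family-by-sample abundance table
#'
#' Runs E-value filtering, best-hit selection, family assignment and RPKSM
#' normalization for every sample and assembles the long count/RPKSM table.
#' Families with no hits in a sample get zero rows, so the table is always
#' complete over families x samples.
#'
#' @param hits Either a named list of alignment tibbles (names are sample
#'   ids), a named character vector of file paths, or a directory containing
#'   `<sample_id>.aln.tsv` files.
#' @param families Per-family tibble with `family_id`, `S`,
#'   `mean_length_nt`.
#' @param members Tibble mapping `member_id` to `family_id`.
#' @param samples Sample tibble with `sample_id` and `library_size`.
#' @param e_max Strict E-value cutoff for read hits.
#' @param length_basis See [compute_rpksm()].
#' @return Long tibble of class `rpksm_abundance`: `family_id`,
#'   `sample_id`, `count`, `rpksm`, `library_size`, with the per-sample
#'   unassigned counts in the `"unassigned"` attribute and the family table
#'   in the `"families"` attribute.
#' @export
build_abundance_table <- function(hits, families, members, samples,
                                  e_max = 1e-10,
                                  length_basis = c("mean", "total")) {
  length_basis <- match.arg(length_basis)
  if (is.character(hits) && length(hits) == 1 && dir.exists(hits)) {
    paths <- file.path(hits, paste0(samples$sample_id, ".aln.tsv"))
    names(paths) <- samples$sample_id
    hits <- paths
  }
  if (is.character(hits)) {
    missing_files <- samples$sample_id[!samples$sample_id %in% names(hits) |
                                         !file.exists(hits[samples$sample_id])]
    if (length(missing_files)) {
      abort(paste0("missing alignment file(s) for sample(s): ",
                   paste(missing_files, collapse = ", ")))
    }
  } else {
    absent <- setdiff(samples$sample_id, names(hits))
    if (length(absent)) {
      abort(paste0("missing hits for sample(s): ",
                   paste(absent, collapse = ", ")))
    }
  }
  per_sample <- lapply(samples$sample_id, function(sid) {
    tab <- if (is.character(hits)) parse_alignment_table(hits[[sid]]) else
      hits[[sid]]
    assign_reads_to_families(best_hit_filter(tab, e_max), members) |>
      dplyr::mutate(sample_id = sid)
  })
  long <- dplyr::bind_rows(per_sample) |>
    dplyr::left_join(samples |> dplyr::select("sample_id", "library_size"),
                     by = "sample_id")
  unassigned <- long |>
    dplyr::filter(.data$family_id == "unassigned") |>
    dplyr::select("sample_id", "count")
  out <- long |>
    dplyr::filter(.data$family_id != "unassigned") |>
    dplyr::left_join(families |>
                       dplyr::select("family_id", "S", "mean_length_nt"),
                     by = "family_id") |>
    dplyr::mutate(rpksm = compute_rpksm(.data$count, .data$mean_length_nt,
                                        .data$S, .data$library_size,
                                        length_basis)) |>
    dplyr::select("family_id", "sample_id", "count", "rpksm",
                  "library_size")
  attr(out, "unassigned") <- unassigned
  attr(out, "families") <- families
  class(out) <- c("rpksm_abundance", class(out))
  out
}

#' Write counts and RPKSM matrices
#'
#' Serialises an abundance table as two wide TSVs (families as rows,
#' samples as columns): `counts.tsv` and `rpksm.tsv`.
#'
#' @param abundance An `rpksm_abundance` tibble.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the two paths, invisibly.
#' @export
write_abundance_table <- function(abundance, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  widen <- function(value) {
    abundance |>
      dplyr::select("family_id", "sample_id", dplyr::all_of(value)) |>
      tidyr::pivot_wider(names_from = "sample_id",
                         values_from = dplyr::all_of(value))
  }
  paths <- c(counts = file.path(dir, "counts.tsv"),
             rpksm = file.path(dir, "rpksm.tsv"))
  readr::write_tsv(widen("count"), paths[["counts"]], progress = FALSE)
  readr::write_tsv(widen("rpksm"), paths[["rpksm"]], progress = FALSE)
  invisible(paths)
}
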