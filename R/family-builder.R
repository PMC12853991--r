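#' Read a protein FASTA into a candidate tibble
#'
#' @param path FASTA file path.
#' @return Tibble with columns `id` (first header token), `header` (full
#'   header line without `>`), `sequence`.
#' @export
read_fasta_candidates <- function(path) {
  if (!file.exists(path)) abort(paste0("cannot read FASTA: ", path))
  x <- Biostrings::readAAStringSet(path)
  fasta_tibble(setNames(as.character(x), names(x)))
}

fasta_tibble <- function(seqs) {
  headers <- names(seqs)
  tibble::tibble(
    id = vapply(strsplit(headers, "\\s+"), `[`, character(1), 1),
    header = headers,
    sequence = unname(seqs)
  )
}

#' Extract candidate records by header pattern
#'
#' Keeps FASTA records whose header matches at least one include pattern and
#' no exclude pattern. Matching is case-insensitive regular-expression
#' matching; exclusion takes precedence, so spurious near-matches (e.g. a
#' "kinase 2" paralog caught by a "kinase" include) can be negatively
#' matched away.
#'
#' @param fasta A FASTA path, or a tibble with `header` and `sequence`
#'   columns (an `id` column is derived if absent).
#' @param include_patterns Character vector, at least one.
#' @param exclude_patterns Character vector, possibly empty.
#' @return Tibble of class `rpksm_candidates` (`id`, `header`, `sequence`).
#'   Zero matches yield an empty tibble with a warning.
#' @export
#' @examples
#' recs <- tibble::tibble(
#'   header = c("g1 butyrate kinase", "g2 butyrate kinase 2",
#'              "g3 hypothetical"),
#'   sequence = c("MKV", "MKL", "MQP"))
#' extract_candidates(recs, "butyrate kinase", "kinase 2")$id
extract_candidates <- function(fasta, include_patterns,
                               exclude_patterns = character()) {
  if (length(include_patterns) < 1) {
    abort("at least one include pattern is required")
  }
  recs <- if (is.character(fasta) && length(fasta) == 1) {
    read_fasta_candidates(fasta)
  } else {
    stopifnot(is.data.frame(fasta),
              all(c("header", "sequence") %in% names(fasta)))
    r <- tibble::as_tibble(fasta)
    if (!"id" %in% names(r)) {
      r$id <- vapply(strsplit(r$header, "\\s+"), `[`, character(1), 1)
    }
    dplyr::select(r, "id", "header", "sequence")
  }
  match_any <- function(patterns) {
    if (!length(patterns) || !nrow(recs)) {
      return(rep(FALSE, nrow(recs)))
    }
    Reduce(`|`, lapply(patterns, function(p) {
      grepl(p, recs$header, ignore.case = TRUE)
    }))
  }
  keep <- match_any(include_patterns) & !match_any(exclude_patterns)
  out <- recs[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    warn("no records matched the include/exclude patterns")
  }
  if (anyDuplicated(out$id)) abort("duplicate record ids in candidate set")
  class(out) <- c("rpksm_candidates", class(out))
  out
}

#' Filter candidates by length relative to a reference
#'
#' Keeps sequences whose length lies within `[min_frac, max_frac]` times the
#' reference length, bounds inclusive. Removes fragments and fused/run-on
#' records before alignment.
#'
#' @param candidates Candidate tibble (`sequence` column).
#' @param reference_length Reference protein length (residues), positive.
#' @param min_frac,max_frac Inclusive fractional bounds (defaults 0.5, 1.5).
#' @return The filtered candidate tibble.
#' @export
filter_by_length <- function(candidates, reference_length,
                             min_frac = 0.5, max_frac = 1.5) {
  stopifnot(reference_length > 0, min_frac > 0, min_frac <= max_frac)
  len <- nchar(candidates$sequence)
  candidates[len >= min_frac * reference_length &
               len <= max_frac * reference_length, , drop = FALSE]
}

# global pairwise alignment of one sequence onto fixed target coordinates:
# returns the query with '-' at target positions it does not cover
# (insertions relative to the target are dropped)
project_onto <- function(query, target) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(target),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global"
  )
  p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  paste(p[s != "-"], collapse = "")
}

#' Star-align candidates onto an anchor sequence
#'
#' Desk-scale multiple alignment: every candidate is globally aligned to the
#' anchor (BLOSUM62) and projected onto the anchor's columns, so all rows
#' share the anchor's coordinate system and insertions relative to the
#' anchor are dropped. Adequate for point-substitution divergence; not a
#' general progressive aligner.
#'
#' @param candidates Candidate tibble (`id`, `sequence`).
#' @param anchor_id Id of the row to use as the column anchor; default the
#'   longest sequence.
#' @return Tibble of class `rpksm_msa` (`id`, `aligned`, `gap_frac`) with
#'   attributes `n_col`, `anchor_id`, `reference_id` (NA until
#'   [anchor_reference()] is applied or the anchor is declared reference).
#' @export
align_msa <- function(candidates, anchor_id = NULL) {
  stopifnot(nrow(candidates) >= 1)
  if (is.null(anchor_id)) {
    anchor_id <- candidates$id[which.max(nchar(candidates$sequence))]
  }
  stopifnot(anchor_id %in% candidates$id)
  target <- candidates$sequence[candidates$id == anchor_id]
  aligned <- vapply(candidates$sequence, function(s) {
    if (identical(s, target)) target else project_onto(s, target)
  }, character(1), USE.NAMES = FALSE)
  new_msa(tibble::tibble(id = candidates$id, aligned = aligned),
          anchor_id = anchor_id)
}

new_msa <- function(tbl, anchor_id = NA_character_,
                    reference_id = NA_character_) {
  n_col <- unique(nchar(tbl$aligned))
  if (length(n_col) != 1) abort("alignment rows have unequal lengths")
  tbl$gap_frac <- vapply(strsplit(tbl$aligned, ""), function(x) {
    mean(x == "-")
  }, numeric(1))
  structure(tbl, n_col = n_col, anchor_id = anchor_id,
            reference_id = reference_id,
            class = c("rpksm_msa", class(tibble::tibble())))
}

#' Remove gappy rows from an alignment
#'
#' Rows whose gap fraction is at or above `max_gap_frac` are removed (the
#' boundary itself is excluded: a row at exactly 30% gaps goes). Surviving
#' rows are unchanged.
#'
#' @param msa An `rpksm_msa`.
#' @param max_gap_frac Exclusive upper bound on the per-row gap fraction.
#' @param family_id Optional label used in the all-removed error message.
#' @return The filtered `rpksm_msa`.
#' @export
gap_filter <- function(msa, max_gap_frac = 0.30, family_id = NULL) {
  stopifnot(inherits(msa, "rpksm_msa"))
  keep <- msa$gap_frac < max_gap_frac
  if (!any(keep)) {
    abort(paste0("gap filter removed every sequence",
                 if (!is.null(family_id)) paste0(" of family ", family_id)))
  }
  out <- msa[keep, , drop = FALSE]
  new_msa(out[, c("id", "aligned")], anchor_id = attr(msa, "anchor_id"),
          reference_id = attr(msa, "reference_id"))
}

#' Anchor an alignment to a validated reference enzyme
#'
#' Adds the reference sequence into the existing alignment columns by a
#' profile-to-sequence step: the reference is globally aligned to the
#' column-consensus of the alignment and projected onto its coordinates.
#' The reference id is recorded so downstream delimitation knows the anchor.
#'
#' @param msa An `rpksm_msa`.
#' @param reference_id Id for the reference row (must not collide).
#' @param reference_seq Nonempty amino-acid sequence. If `reference_id`
#'   already names a row of the alignment and `reference_seq` is `NULL`,
#'   that row is flagged as the reference instead of being re-added.
#' @return The `rpksm_msa` with the reference present and flagged.
#' @export
anchor_reference <- function(msa, reference_id, reference_seq = NULL) {
  stopifnot(inherits(msa, "rpksm_msa"))
  if (is.null(reference_seq)) {
    if (!reference_id %in% msa$id) {
      abort("reference_id not in alignment and no reference_seq given")
    }
    return(new_msa(msa[, c("id", "aligned")],
                   anchor_id = attr(msa, "anchor_id"),
                   reference_id = reference_id))
  }
  if (!nzchar(reference_seq)) abort("empty reference sequence")
  if (reference_id %in% msa$id) {
    abort(paste0("reference id '", reference_id,
                 "' collides with an existing alignment row"))
  }
  cons <- msa_consensus(msa)
  projected <- project_onto(reference_seq, cons)
  new_msa(
    tibble::tibble(id = c(msa$id, reference_id),
                   aligned = c(msa$aligned, projected)),
    anchor_id = attr(msa, "anchor_id"), reference_id = reference_id
  )
}

msa_consensus <- function(msa) {
  m <- do.call(rbind, strsplit(msa$aligned, ""))
  apply(m, 2, function(col) {
    col <- col[col != "-"]
    if (!length(col)) return("A")
    names(sort(table(col), decreasing = TRUE))[1]
  }) |> paste(collapse = "")
}

#' Pairwise p-distances over an alignment
#'
#' Proportion of differing residues among columns where neither row has a
#' gap. Row pairs with no shared gap-free column get distance 1.
#'
#' @param msa An `rpksm_msa`.
#' @return Symmetric numeric matrix with the alignment ids as dimnames.
#' @export
p_distance_matrix <- function(msa) {
  m <- do.call(rbind, strsplit(msa$aligned, ""))
  rownames(m) <- msa$id
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(msa$id, msa$id))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- m[i, ] != "-" & m[j, ] != "-"
      d[i, j] <- d[j, i] <- if (!any(ok)) 1 else
        mean(m[i, ok] != m[j, ok])
    }
  }
  d
}

#' Neighbor-joining tree from alignment p-distances
#'
#' Desk-scale substitute for full maximum-likelihood reconstruction: the
#' family-delimitation contract downstream is distance-based, so a
#' neighbor-joining tree on p-distances carries the same information at a
#' fraction of the cost. Negative branch lengths produced by NJ are clamped
#' to zero.
#'
#' @param msa An `rpksm_msa` with at least three rows.
#' @return An [ape::phylo] tree whose tips are the alignment ids.
#' @export
build_distance_tree <- function(msa) {
  stopifnot(inherits(msa, "rpksm_msa"))
  if (nrow(msa) < 3) abort("need at least 3 sequences to build a tree")
  d <- p_distance_matrix(msa)
  tree <- ape::nj(as.dist(d))
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Delimit a gene family around its reference
#'
#' Midpoint-roots the tree and takes the largest clade containing the
#' reference leaf in which every leaf's path distance to the reference is at
#' most `d_max`. The reference is removed from the returned membership and
#' the family size `S` recomputed.
#'
#' @param tree An [ape::phylo] tree containing `reference_id` as a tip.
#' @param reference_id The anchored reference tip.
#' @param d_max Maximum leaf-to-reference path distance (default 0.6).
#' @param family_id Optional family label.
#' @return List of class `rpksm_family`: `family_id`, `member_ids`,
#'   `reference_id`, `S`. An empty family (only the reference qualifies)
#'   triggers a warning.
#' @export
delimit_family <- function(tree, reference_id, d_max = 0.6,
                           family_id = NA_character_) {
  if (!reference_id %in% tree$tip.label) {
    abort("reference_id is not a leaf of the tree")
  }
  rooted <- phangorn::midpoint(tree)
  dmat <- cophenetic(rooted)
  ref_d <- dmat[reference_id, ]
  ref_tip <- which(rooted$tip.label == reference_id)
  anc <- c(ref_tip, phangorn::Ancestors(rooted, ref_tip, type = "all"))
  best <- character()
  for (node in anc) {
    leaves <- if (node <= length(rooted$tip.label)) {
      rooted$tip.label[node]
    } else {
      rooted$tip.label[unlist(phangorn::Descendants(rooted, node,
                                                    type = "tips"))]
    }
    if (all(ref_d[leaves] <= d_max)) {
      if (length(leaves) > length(best)) best <- leaves
    } else {
      break  # larger clades only add leaves; once violated, stay violated
    }
  }
  members <- setdiff(best, reference_id)
  if (!length(members)) {
    warn(paste0("family ", family_id,
                ": only the reference lies within d_max; empty family"))
  }
  structure(
    list(family_id = family_id, member_ids = members,
         reference_id = reference_id, S = length(members)),
    class = "rpksm_family"
  )
}

#' Build one gene family end to end
#'
#' Runs the full extraction procedure for a single family: header-pattern
#' extraction, fractional length filter against the reference, star
#' alignment anchored on the reference, gap filter, distance tree and
#' reference-anchored delimitation. With fewer than three aligned rows no
#' tree can be built and membership falls back to direct p-distance to the
#' reference.
#'
#' @param fasta FASTA path or record tibble (see [extract_candidates()]).
#' @param include_patterns,exclude_patterns Header patterns.
#' @param reference_id,reference_seq The validated reference; if
#'   `reference_id` is among the extracted records, its own sequence is
#'   used.
#' @param config A [pipeline_config()] supplying `length_frac_bounds`,
#'   `gap_max` and `d_max`.
#' @param family_id Family label carried into the result.
#' @return An `rpksm_family` (see [delimit_family()]).
#' @export
build_family <- function(fasta, include_patterns,
                         exclude_patterns = character(),
                         reference_id, reference_seq = NULL,
                         config = pipeline_config(),
                         family_id = NA_character_) {
  cand <- extract_candidates(fasta, include_patterns, exclude_patterns)
  if (reference_id %in% cand$id) {
    reference_seq <- cand$sequence[cand$id == reference_id]
  } else {
    stopifnot(!is.null(reference_seq))
    cand <- dplyr::bind_rows(
      cand, tibble::tibble(id = reference_id, header = reference_id,
                           sequence = reference_seq))
  }
  cand <- filter_by_length(cand, nchar(reference_seq),
                           config$length_frac_bounds[1],
                           config$length_frac_bounds[2])
  msa <- align_msa(cand, anchor_id = reference_id)
  msa <- gap_filter(msa, config$gap_max, family_id = family_id)
  msa <- anchor_reference(msa, reference_id)
  if (nrow(msa) < 3) {
    d <- p_distance_matrix(msa)
    members <- setdiff(msa$id[d[reference_id, msa$id] <= config$d_max],
                       reference_id)
    return(structure(
      list(family_id = family_id, member_ids = members,
           reference_id = reference_id, S = length(members)),
      class = "rpksm_family"))
  }
  tree <- build_distance_tree(msa)
  delimit_family(tree, reference_id, d_max = config$d_max,
                 family_id = family_id)
}
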