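# Alignment-quality metrics. The pairwise metrics (RMSD, structurally
# equivalent residues) are computed for every structure pair after a single
# common superposition onto the longest structure, then averaged over all
# unordered pairs.

#' Gap-less alignment positions
#'
#' @param msa a `MultipleAlignment`.
#' @return list with `count` and `ratio` (fraction of columns).
#' @export
gapless_positions <- function(msa) {
  occ <- vapply(msa$rows, function(r) !is.na(r), logical(msa$column_count))
  occ <- matrix(occ, nrow = msa$column_count)
  gp <- rowSums(occ) == length(msa$rows)
  list(count = sum(gp), ratio = sum(gp) / msa$column_count,
       which = which(gp))
}

# residue-index tuple keys of the gap-less columns, in a fixed id order
gapless_column_keys <- function(msa, ids) {
  gp <- gapless_positions(msa)$which
  if (!length(gp)) return(character(0L))
  mat <- vapply(ids, function(id) msa$rows[[id]][gp], integer(length(gp)))
  mat <- matrix(mat, nrow = length(gp))
  apply(mat, 1L, paste, collapse = ",")
}

#' Equivalence score against a reference alignment
#'
#' Percentage of the test alignment's gap-less columns that appear in the
#' reference alignment, i.e. for which the reference pairs exactly the same
#' residue index in every structure. Used to score alignments against a
#' curated reference.
#'
#' @param msa,reference_msa `MultipleAlignment`s over the same structures
#'   (same ids, same per-structure residue counts - a mismatch indicates the
#'   alignments came from different sequences and raises an error).
#' @return percentage in [0, 100]; `NA` if the test alignment has no gap-less
#'   columns.
#' @export
equivalence_score <- function(msa, reference_msa) {
  ids <- sort(names(msa$rows))
  if (!setequal(ids, names(reference_msa$rows)))
    stop("alignments cover different structure ids")
  for (id in ids) {
    n1 <- sum(!is.na(msa$rows[[id]]))
    n2 <- sum(!is.na(reference_msa$rows[[id]]))
    if (n1 != n2)
      stop("sequence mismatch for '", id, "': ", n1, " vs ", n2, " residues")
  }
  test_keys <- gapless_column_keys(msa, ids)
  if (!length(test_keys)) return(NA_real_)
  ref_keys <- gapless_column_keys(reference_msa, ids)
  100 * sum(test_keys %in% ref_keys) / length(test_keys)
}

#' Superpose all structures onto the longest one
#'
#' The common-reference superposition used by the pairwise quality metrics:
#' the longest structure (ties: first by id) is the reference, and every
#' other structure is Kabsch-fitted on the alpha carbons of the alignment's
#' gap-less columns.
#'
#' @param msa a `MultipleAlignment`.
#' @param structures list of the aligned `ProteinStructure`s.
#' @return named list of N x 3 transformed alpha-carbon coordinate sets (the
#'   reference is returned unchanged).
#' @export
superpose_to_reference <- function(msa, structures) {
  names(structures) <- vapply(structures, `[[`, character(1L), "id")
  structures <- structures[names(msa$rows)]
  lens <- vapply(structures, n_residues, integer(1L))
  ref_id <- names(structures)[order(-lens, names(structures))][1L]
  gp <- gapless_positions(msa)$which
  if (length(gp) < 3L)
    stop("need at least 3 gap-less columns for reference superposition")
  ref_idx <- msa$rows[[ref_id]][gp]
  ref_ca <- structures[[ref_id]]$ca_coords
  out <- list()
  for (id in names(structures)) {
    ca <- structures[[id]]$ca_coords
    if (id == ref_id) { out[[id]] <- ca; next }
    idx <- msa$rows[[id]][gp]
    tr <- kabsch(ca[idx, , drop = FALSE], ref_ca[ref_idx, , drop = FALSE])
    out[[id]] <- apply_transform(tr, ca)
  }
  out
}

pair_columns <- function(msa, id1, id2) {
  r1 <- msa$rows[[id1]]; r2 <- msa$rows[[id2]]
  shared <- !is.na(r1) & !is.na(r2)
  list(i = r1[shared], j = r2[shared])
}

#' Mean pairwise RMSD of a superposed multiple alignment
#'
#' For each unordered structure pair, the RMSD over alignment columns where
#' both have residues; averaged over all pairs.
#'
#' @param msa a `MultipleAlignment`.
#' @param coords named list of transformed alpha-carbon coordinates, as from
#'   [superpose_to_reference()].
#' @return mean RMSD in angstrom.
#' @export
pairwise_rmsd <- function(msa, coords) {
  ids <- names(msa$rows)
  vals <- c()
  for (a in seq_along(ids)[-length(ids)]) {
    for (b in (a + 1L):length(ids)) {
      pc <- pair_columns(msa, ids[a], ids[b])
      if (!length(pc$i)) next
      vals <- c(vals, coord_rmsd(coords[[ids[a]]][pc$i, , drop = FALSE],
                                 coords[[ids[b]]][pc$j, , drop = FALSE]))
    }
  }
  mean(vals)
}

#' Structurally equivalent residues
#'
#' Residues in the same alignment column of a structure pair that lie within
#' `cutoff` angstrom of each other after the common superposition; reported
#' as the mean count and mean fraction (of mutually aligned columns) over all
#' unordered pairs.
#'
#' @inheritParams pairwise_rmsd
#' @param cutoff distance cutoff in angstrom (default 4).
#' @return list with `mean_count` and `mean_fraction`.
#' @export
structurally_equivalent <- function(msa, coords, cutoff = 4) {
  ids <- names(msa$rows)
  counts <- fracs <- c()
  for (a in seq_along(ids)[-length(ids)]) {
    for (b in (a + 1L):length(ids)) {
      pc <- pair_columns(msa, ids[a], ids[b])
      if (!length(pc$i)) { counts <- c(counts, 0); fracs <- c(fracs, 0); next }
      d <- sqrt(rowSums((coords[[ids[a]]][pc$i, , drop = FALSE] -
                           coords[[ids[b]]][pc$j, , drop = FALSE])^2))
      counts <- c(counts, sum(d <= cutoff))
      fracs <- c(fracs, mean(d <= cutoff))
    }
  }
  list(mean_count = mean(counts), mean_fraction = mean(fracs))
}

#' Full alignment-quality report
#'
#' @param msa a `MultipleAlignment`.
#' @param structures list of the aligned `ProteinStructure`s.
#' @param reference_msa optional reference `MultipleAlignment` for the
#'   equivalence score.
#' @param cutoff structural-equivalence cutoff, angstrom.
#' @return an `AlignmentQuality` list: `gapless_count`, `gapless_ratio`,
#'   `equivalence_score` (NA without a reference), `mean_pairwise_rmsd`,
#'   `mean_equivalent_count`, `mean_equivalent_fraction`.
#' @export
alignment_quality <- function(msa, structures, reference_msa = NULL,
                              cutoff = 4) {
  gp <- gapless_positions(msa)
  coords <- superpose_to_reference(msa, structures)
  se <- structurally_equivalent(msa, coords, cutoff)
  base::structure(list(
    gapless_count = gp$count,
    gapless_ratio = gp$ratio,
    equivalence_score = if (is.null(reference_msa)) NA_real_
      else equivalence_score(msa, reference_msa),
    mean_pairwise_rmsd = pairwise_rmsd(msa, coords),
    mean_equivalent_count = se$mean_count,
    mean_equivalent_fraction = se$mean_fraction
  ), class = "AlignmentQuality")
}

#' @export
print.AlignmentQuality <- function(x, ...) {
  cat("<AlignmentQuality>\n")
  for (nm in names(x)) cat(sprintf("  %-25s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Write an alignment-quality report
#'
#' @param quality an `AlignmentQuality`.
#' @param path output path.
#' @param format `"json"` or `"tsv"`.
#' @export
write_quality_report <- function(quality, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(unclass(quality), path, auto_unbox = TRUE,
                         digits = NA, na = "null")
  } else {
    utils::write.table(
      data.frame(metric = names(quality),
                 value = vapply(quality, as.numeric, numeric(1L))),
      path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
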