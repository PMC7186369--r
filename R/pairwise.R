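#' Alignment parameters
#'
#' @param gamma RBF kernel width for the coordinate score, 1/angstrom^2.
#'   The default 0.03 gives a score of ~0.62 at the common 4 angstrom
#'   structural-equivalence cutoff and drops to near zero by 8 angstrom.
#' @param coord_penalties gap penalties for the coordinate-score alignment
#'   (default open 1, extend 0.01).
#' @param sec_penalties gap penalties for the secondary-structure alignment
#'   (default open 1, extend 0 - that score works in unit increments).
#' @param consensus_weight weight (cw) given to each aligned residue when the
#'   consensus row of a progressive-alignment node is built; 0 disables the
#'   consensus feedback entirely.
#' @param segment_length distance-signal segment length in residues. When a
#'   structure pair is shorter than this, the pairwise aligner shrinks the
#'   segment length to `max(10, floor(min(N1, N2) / 2))` so short chains stay
#'   alignable.
#' @param refine_iterations maximum number of post-selection refinement
#'   rounds (Kabsch on the current aligned pairs, then re-alignment);
#'   refinement stops early when the alignment score stops improving by more
#'   than 1e-6.
#' @return an `AlignmentParams` object.
#' @export
alignment_params <- function(gamma = 0.03,
                             coord_penalties = gap_penalties(1, 0.01),
                             sec_penalties = gap_penalties(1, 0),
                             consensus_weight = 1,
                             segment_length = 30L,
                             refine_iterations = 1L) {
  if (gamma <= 0) stop("gamma must be positive")
  if (consensus_weight < 0) stop("consensus_weight must be >= 0")
  structure(list(gamma = gamma, coord_penalties = coord_penalties,
                 sec_penalties = sec_penalties,
                 consensus_weight = consensus_weight,
                 segment_length = as.integer(segment_length),
                 refine_iterations = as.integer(refine_iterations)),
            class = "AlignmentParams")
}

#' Gaussian (RBF) coordinate similarity
#'
#' `exp(-gamma * sum((a - b)^2))`: 1 for coincident points, decaying with
#' squared Euclidean distance. Inputs are plain 3-D coordinates, or 4-D
#' vectors when a consensus component has been concatenated to the
#' coordinates during progressive alignment.
#'
#' @param a,b numeric vectors of equal length.
#' @param gamma kernel width (1/angstrom^2).
#' @return similarity in (0, 1].
#' @export
score_coords <- function(a, b, gamma = 0.03) {
  if (length(a) != length(b)) stop("coordinate vectors differ in length")
  exp(-gamma * sum((a - b)^2))
}

# Dense RBF score matrix between two row-wise coordinate sets.
coord_score_matrix <- function(A, B, gamma) exp(-gamma * cross_sqdist(A, B))

# Core aligner shared by structure-level and node-level alignment.
# ca1/ca2: 3-D coordinates; sec1/sec2: code character vectors; aug1/aug2:
# optional extra column (consensus) used only in the coordinate score, never
# in the geometric superposition steps.
align_coords_core <- function(ca1, ca2, sec1, sec2, params,
                              aug1 = NULL, aug2 = NULL) {
  n1 <- nrow(ca1); n2 <- nrow(ca2)
  seg_len <- params$segment_length
  if (min(n1, n2) < seg_len) seg_len <- max(10L, min(n1, n2) %/% 2L)

  evaluate <- function(tr) {
    ca1t <- apply_transform(tr, ca1)
    A <- if (is.null(aug1)) ca1t else cbind(ca1t, aug1)
    B <- if (is.null(aug2)) ca2 else cbind(ca2, aug2)
    S <- coord_score_matrix(A, B, params$gamma)
    aln <- affine_dp_align(S, params$coord_penalties)
    ap <- aligned_pairs(aln)
    eq_score <- sum(S[ap])
    list(alignment = aln, transform = tr, score = eq_score, n_pairs = nrow(ap))
  }

  # candidate coarse superpositions, in tie-breaking precedence order
  candidates <- list(
    signal_first = function() signal_superpose_coords(ca1, ca2, "first", seg_len),
    signal_last = function() signal_superpose_coords(ca1, ca2, "last", seg_len),
    secondary = function()
      secondary_superpose_coords(ca1, ca2, sec1, sec2, params$sec_penalties)
  )
  best <- NULL
  errors <- character(0L)
  for (nm in names(candidates)) {
    res <- tryCatch({
      tr <- candidates[[nm]]()
      out <- evaluate(tr)
      out$strategy <- nm
      out
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) { errors <- c(errors, paste0(nm, ": ", res)); next }
    if (is.null(best) || res$score > best$score + 1e-9) best <- res
  }
  if (is.null(best))
    stop("all superposition strategies failed: ", paste(errors, collapse = "; "))

  for (k in seq_len(params$refine_iterations)) {
    ap <- aligned_pairs(best$alignment)
    if (nrow(ap) < 3L) break
    tr2 <- tryCatch(kabsch(ca1[ap[, 1L], , drop = FALSE],
                           ca2[ap[, 2L], , drop = FALSE]),
                    error = function(e) NULL)
    if (is.null(tr2)) break
    res2 <- evaluate(tr2)
    res2$strategy <- best$strategy
    if (res2$score > best$score + 1e-6) best <- res2 else {
      if (res2$score > best$score) best <- res2
      break
    }
  }
  best$alignment$score <- best$score  # summed pair similarity, gap-cost free
  best
}

#' Pairwise structure alignment
#'
#' Runs the full pairwise procedure: three candidate coarse superpositions
#' (distance-signal with first-residue anchors, with last-residue anchors,
#' and secondary-structure based), each followed by an affine-gap DP
#' alignment of the superposed alpha carbons under the Gaussian coordinate
#' score; the candidate with the highest summed pair similarity wins (ties
#' broken in the order just given), and is then refined by re-superposing on
#' its aligned pairs and re-aligning.
#'
#' The reported `score` is the summed coordinate similarity over aligned
#' pairs (gap costs excluded), so a structure aligned with an exact rigid
#' copy of itself scores its residue count. Because every ingredient depends
#' only on internal or post-superposition distances, the score is invariant
#' under rigid-body motion of either input.
#'
#' @param s1,s2 `ProteinStructure`s.
#' @param params an [alignment_params()] object.
#' @return a `PairwiseAlignment`: list with `alignment` (an `IndexAlignment`
#'   whose `score` is the summed pair similarity), `transform` (the
#'   `RigidTransform` taking `s1` onto `s2`), `score`, `n_pairs`, and the
#'   winning `strategy`.
#' @export
pairwise_align <- function(s1, s2, params = alignment_params()) {
  res <- align_coords_core(s1$ca_coords, s2$ca_coords,
                           sec_chars(s1), sec_chars(s2), params)
  res$ids <- c(s1$id, s2$id)
  class(res) <- "PairwiseAlignment"
  res
}

#' @export
print.PairwiseAlignment <- function(x, ...) {
  cat(sprintf("<PairwiseAlignment %s/%s: %d pairs, score %.3f, strategy %s>\n",
              x$ids[1L], x$ids[2L], x$n_pairs, x$score, x$strategy))
  invisible(x)
}

#' Length-normalized alignment score
#'
#' The summed pair similarity divided by the number of aligned pairs; 1 for a
#' perfect self-alignment, decreasing towards 0 as aligned residues drift
#' apart. Used as the similarity feeding guide-tree construction.
#'
#' @param aln a `PairwiseAlignment`, or an `IndexAlignment` whose `score` is
#'   the summed pair similarity.
#' @return score in [0, 1].
#' @export
tree_score <- function(aln) {
  if (inherits(aln, "PairwiseAlignment")) aln <- aln$alignment
  np <- nrow(aligned_pairs(aln))
  if (np == 0L) stop("alignment has no aligned pairs")
  aln$score / np
}
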