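#' Rigid-body transform
#'
#' @param rotation 3 x 3 orthonormal matrix with determinant +1.
#' @param translation length-3 translation vector (angstrom).
#' @export
rigid_transform <- function(rotation, translation) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L))) stop("rotation must be 3 x 3")
  if (abs(det(rotation) - 1) > 1e-6 ||
      max(abs(crossprod(rotation) - diag(3L))) > 1e-6)
    stop("rotation must be orthonormal with determinant +1")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "RigidTransform")
}

#' Apply a rigid transform to row-wise coordinates
#'
#' @param transform a `RigidTransform`.
#' @param coords k x 3 matrix (or length-3 vector).
#' @return transformed coordinates, same shape.
#' @export
apply_transform <- function(transform, coords) {
  single <- is.null(dim(coords))
  m <- if (single) matrix(coords, 1L, 3L) else as.matrix(coords)
  out <- m %*% t(transform$rotation)
  out <- sweep(out, 2L, transform$translation, `+`)
  if (single) drop(out) else out
}

#' Compose two rigid transforms
#'
#' `compose_transforms(b, a)` is the transform applying `a` first, then `b`.
#' @param b,a `RigidTransform`s.
#' @export
compose_transforms <- function(b, a) {
  rigid_transform(b$rotation %*% a$rotation,
                  as.numeric(b$rotation %*% a$translation) + b$translation)
}

#' Optimal rigid superposition (Kabsch)
#'
#' Returns the rotation/translation minimizing the RMSD between the
#' transformed `x` and `y`, via SVD of the cross-covariance with the usual
#' determinant correction so the result is always a proper rotation (never a
#' reflection), including for degenerate (e.g. planar or collinear) inputs.
#'
#' @param x,y k x 3 matrices of corresponded coordinates, k >= 3.
#' @return a `RigidTransform` `t` with `apply_transform(t, x)` optimally
#'   superposed onto `y`.
#' @export
kabsch <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) != nrow(y) || ncol(x) != 3L || ncol(y) != 3L)
    stop("x and y must be k x 3 with equal k")
  if (nrow(x) < 3L) stop("at least 3 point pairs are required")
  cx <- colMeans(x); cy <- colMeans(y)
  xc <- sweep(x, 2L, cx); yc <- sweep(y, 2L, cy)
  s <- svd(crossprod(xc, yc))       # H = Xc' Yc = U D V'
  d <- sign(det(tcrossprod(s$v, s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rigid_transform(R, cy - as.numeric(R %*% cx))
}

# -- distance-signal segments -------------------------------------------------

make_segments_coords <- function(ca, anchor, segment_length) {
  n <- nrow(ca)
  L <- as.integer(segment_length)
  if (L < 2L) stop("segment_length must be >= 2")
  if (n < L) stop("structure too short for segment length ", L,
                  " (", n, " residues)")
  lapply(seq_len(n - L + 1L), function(s) {
    idx <- s:(s + L - 1L)
    a <- if (anchor == "first") s else s + L - 1L
    sig <- sqrt(rowSums(sweep(ca[idx, , drop = FALSE], 2L, ca[a, ])^2))
    base::structure(list(start = s, anchor = anchor, signal = sig),
                    class = "SignalSegment")
  })
}

#' Rotation-invariant distance-signal segments
#'
#' Represents each overlapping `segment_length`-residue stretch of a
#' structure by the Euclidean distances of every alpha carbon in the stretch
#' to the stretch's anchor alpha carbon (first or last residue). Distances
#' are invariant under rigid motion, which is what lets two arbitrarily
#' oriented structures be compared before any superposition exists.
#'
#' @param structure a `ProteinStructure`.
#' @param anchor `"first"` or `"last"`: which residue of the segment the
#'   distances are measured to.
#' @param segment_length segment length in residues (default 30); one segment
#'   starts at every position (stride 1).
#' @return list of `SignalSegment`s: `start` (1-based start index), `anchor`,
#'   `signal` (length `segment_length` distance vector).
#' @export
make_segments <- function(structure, anchor = c("first", "last"),
                          segment_length = 30L) {
  anchor <- match.arg(anchor)
  make_segments_coords(structure$ca_coords, anchor, segment_length)
}

#' Similarity of two distance signals
#'
#' Median over signal positions of `exp(-(d_i - d_j)^2 / 10)`; 1 for
#' identical signals, approaching 0 as the segments diverge.
#'
#' @param a,b `SignalSegment`s with equal signal lengths.
#' @return similarity in [0, 1].
#' @export
score_signal <- function(a, b) {
  if (length(a$signal) != length(b$signal)) stop("signal length mismatch")
  stats::median(exp(-(a$signal - b$signal)^2 / 10))
}

signal_score_matrix <- function(segs1, segs2) {
  S1 <- do.call(rbind, lapply(segs1, `[[`, "signal"))
  S2 <- do.call(rbind, lapply(segs2, `[[`, "signal"))
  M <- matrix(0, nrow(S1), nrow(S2))
  for (i in seq_len(nrow(S1))) {
    d <- exp(-(sweep(S2, 2L, S1[i, ]))^2 / 10)
    M[i, ] <- apply(d, 1L, stats::median)
  }
  M
}

signal_superpose_coords <- function(ca1, ca2, anchor, segment_length) {
  segs1 <- make_segments_coords(ca1, anchor, segment_length)
  segs2 <- make_segments_coords(ca2, anchor, segment_length)
  if (length(segs1) < 3L || length(segs2) < 3L)
    stop("too few segments for signal superposition")
  aln <- affine_dp_align(signal_score_matrix(segs1, segs2),
                         gap_penalties(0, 0))
  ap <- aligned_pairs(aln)
  if (nrow(ap) < 3L) stop("fewer than 3 aligned segment pairs")
  off <- if (anchor == "first") 0L else as.integer(segment_length) - 1L
  i1 <- vapply(segs1[ap[, 1L]], `[[`, integer(1L), "start") + off
  i2 <- vapply(segs2[ap[, 2L]], `[[`, integer(1L), "start") + off
  kabsch(ca1[i1, , drop = FALSE], ca2[i2, , drop = FALSE])
}

#' Coarse superposition from rotation-invariant distance signals
#'
#' Aligns the two structures' overlapping distance-signal segments by
#' dynamic time warping (the affine DP engine with zero gap penalties, for
#' leniency while the structures are still arbitrarily oriented), then runs
#' Kabsch over the anchor-residue alpha carbons of the aligned segment
#' pairs.
#'
#' @param s1,s2 `ProteinStructure`s; both must yield at least 3 segments at
#'   the given segment length.
#' @inheritParams make_segments
#' @return a `RigidTransform` taking `s1` onto `s2`.
#' @export
signal_superpose <- function(s1, s2, anchor = c("first", "last"),
                             segment_length = 30L) {
  anchor <- match.arg(anchor)
  signal_superpose_coords(s1$ca_coords, s2$ca_coords, anchor, segment_length)
}

# Secondary-structure code similarity: 0 if either code unassigned, +1 for
# equal codes, -1 for unequal.
sec_score_matrix <- function(codes1, codes2) {
  M <- outer(codes1, codes2, function(a, b) ifelse(a == b, 1, -1))
  M[codes1 == "-", ] <- 0
  M[, codes2 == "-"] <- 0
  M
}

secondary_superpose_coords <- function(ca1, ca2, sec1, sec2, penalties) {
  M <- sec_score_matrix(sec1, sec2)
  aln <- affine_dp_align(M, penalties)
  ap <- aligned_pairs(aln)
  if (nrow(ap) < 3L)
    stop("fewer than 3 aligned residue pairs from secondary structure")
  kabsch(ca1[ap[, 1L], , drop = FALSE], ca2[ap[, 2L], , drop = FALSE])
}

#' Coarse superposition from secondary-structure codes
#'
#' Aligns the two code strings with the affine DP engine (match +1, mismatch
#' -1, unassigned 0; gap open 1, gap extend 0) and superposes the aligned
#' residues' alpha carbons with Kabsch. Fails (with an error the pairwise
#' driver treats as "skip this strategy") when fewer than 3 residue pairs
#' align, e.g. an all-coil chain against an all-helix chain.
#'
#' @param s1,s2 `ProteinStructure`s with assigned `sec_codes`.
#' @return a `RigidTransform` taking `s1` onto `s2`.
#' @export
secondary_superpose <- function(s1, s2) {
  secondary_superpose_coords(s1$ca_coords, s2$ca_coords,
                             sec_chars(s1), sec_chars(s2),
                             gap_penalties(1, 0))
}
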