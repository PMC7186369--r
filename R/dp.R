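#' Affine gap penalties
#'
#' A gap run of length L costs `open + (L - 1) * extend` (in score units);
#' terminal gaps are penalized like internal ones. Switching gap direction
#' (a gap in one sequence immediately followed by a gap in the other) starts
#' a new run.
#'
#' @param open non-negative gap opening penalty.
#' @param extend non-negative gap extension penalty; must not exceed `open`.
#' @export
gap_penalties <- function(open, extend) {
  if (open < 0 || extend < 0) stop("gap penalties must be non-negative")
  if (open < extend) stop("gap open penalty must be >= extend penalty")
  structure(list(open = open, extend = extend), class = "GapPenalties")
}

#' Global alignment with affine gap costs (Gotoh)
#'
#' Maximizes the sum of `score_matrix[i, j]` over aligned pairs minus affine
#' gap costs, over all global alignments of the two index sets. The
#' three-state (match / gap-in-rows / gap-in-columns) recursion guarantees
#' correctness of the affine cost model in O(nm). With zero penalties the
#' result is an unconstrained monotone best path - the dynamic-time-warping
#' regime used when aligning rotation-invariant distance signals.
#'
#' Traceback ties are broken deterministically: match is preferred over a gap
#' consuming a row index, which is preferred over a gap consuming a column
#' index.
#'
#' @param score_matrix n x m numeric matrix of pair scores (finite).
#' @param penalties a [gap_penalties()] object.
#' @return an `IndexAlignment`: list with `pairs` (two-column integer matrix
#'   of 1-based row/column indices, `NA` marking a gap) and `score` (the
#'   maximized objective).
#' @export
affine_dp_align <- function(score_matrix, penalties) {
  S <- as.matrix(score_matrix)
  n <- nrow(S); m <- ncol(S)
  if (n < 1L || m < 1L) stop("empty score matrix")
  if (!all(is.finite(S))) stop("score matrix must be finite")
  go <- penalties$open; ge <- penalties$extend
  NEG <- -Inf
  M <- Ix <- Iy <- matrix(NEG, n + 1L, m + 1L)
  # pointer codes: 1 = from M, 2 = from Ix, 3 = from Iy
  Pm <- Px <- Py <- matrix(0L, n + 1L, m + 1L)
  M[1L, 1L] <- 0
  if (n >= 1L) { Ix[2:(n + 1L), 1L] <- -(go + (seq_len(n) - 1L) * ge); Px[2:(n + 1L), 1L] <- 2L; Px[2L, 1L] <- 1L }
  if (m >= 1L) { Iy[1L, 2:(m + 1L)] <- -(go + (seq_len(m) - 1L) * ge); Py[1L, 2:(m + 1L)] <- 3L; Py[1L, 2L] <- 1L }
  for (i in seq_len(n)) {
    Mi1 <- M[i, ]; Ixi1 <- Ix[i, ]; Iyi1 <- Iy[i, ]
    Mi <- M[i + 1L, ]; Ixi <- Ix[i + 1L, ]; Iyi <- Iy[i + 1L, ]
    Pmi <- Pm[i + 1L, ]; Pxi <- Px[i + 1L, ]; Pyi <- Py[i + 1L, ]
    # Ix (gap consuming row index i) is column-independent within the row
    cand1 <- Mi1 - go; cand2 <- Ixi1 - ge; cand3 <- Iyi1 - go
    for (j in seq_len(m)) {
      # M: diagonal move
      v <- c(Mi1[j], Ixi1[j], Iyi1[j])
      k <- which.max(v)
      Mi[j + 1L] <- v[k] + S[i, j]
      Pmi[j + 1L] <- k
      # Ix: vertical move (row i aligned to a gap)
      v <- c(cand1[j + 1L], cand2[j + 1L], cand3[j + 1L])
      k <- which.max(v)
      Ixi[j + 1L] <- v[k]
      Pxi[j + 1L] <- k
      # Iy: horizontal move (column j aligned to a gap)
      v <- c(Mi[j] - go, Ixi[j] - go, Iyi[j] - ge)
      k <- which.max(v)
      Iyi[j + 1L] <- v[k]
      Pyi[j + 1L] <- k
    }
    M[i + 1L, ] <- Mi; Ix[i + 1L, ] <- Ixi; Iy[i + 1L, ] <- Iyi
    Pm[i + 1L, ] <- Pmi; Px[i + 1L, ] <- Pxi; Py[i + 1L, ] <- Pyi
  }
  finals <- c(M[n + 1L, m + 1L], Ix[n + 1L, m + 1L], Iy[n + 1L, m + 1L])
  state <- which.max(finals)
  score <- finals[state]

  # traceback
  pairs <- matrix(NA_integer_, 0L, 2L)
  i <- n; j <- m
  steps <- vector("list", n + m)
  ns <- 0L
  while (i > 0L || j > 0L) {
    ns <- ns + 1L
    if (state == 1L) {
      steps[[ns]] <- c(i, j)
      state <- Pm[i + 1L, j + 1L]
      i <- i - 1L; j <- j - 1L
    } else if (state == 2L) {
      steps[[ns]] <- c(i, NA_integer_)
      state <- Px[i + 1L, j + 1L]
      i <- i - 1L
    } else {
      steps[[ns]] <- c(NA_integer_, j)
      state <- Py[i + 1L, j + 1L]
      j <- j - 1L
    }
  }
  pairs <- do.call(rbind, rev(steps[seq_len(ns)]))
  structure(list(pairs = pairs, score = score), class = "IndexAlignment")
}

#' @export
print.IndexAlignment <- function(x, ...) {
  np <- sum(stats::complete.cases(x$pairs))
  cat(sprintf("<IndexAlignment: %d columns, %d aligned pairs, score %.4f>\n",
              nrow(x$pairs), np, x$score))
  invisible(x)
}

# Aligned (gap-free) pairs of an IndexAlignment as a two-column matrix.
aligned_pairs <- function(aln) {
  p <- aln$pairs
  p[stats::complete.cases(p), , drop = FALSE]
}
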