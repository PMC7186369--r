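#' Backbone hydrogen-bond energies (Kabsch-Sander)
#'
#' Electrostatic hydrogen-bond energy between the C=O group of an acceptor
#' residue i and the N-H group of a donor residue j:
#' `E = 0.084 * (1/r(ON) + 1/r(CH) - 1/r(OH) - 1/r(CN)) * 332` kcal/mol.
#' The amide hydrogen is reconstructed at 1 angstrom from N along the
#' direction of the preceding residue's C=O bond (O -> C), which requires a
#' continuous chain: donors after a chain break (C(j-1)-N(j) > 2.5 angstrom)
#' or with missing atoms get no bonds.
#'
#' @param structure a `ProteinStructure`.
#' @return N x N matrix `E[i, j]` = energy of the bond donated by residue j's
#'   N-H to residue i's C=O, in kcal/mol; `Inf` where undefined. Pairs with
#'   `|i - j| < 2` are excluded.
#' @export
ks_hbond_matrix <- function(structure) {
  bb <- structure$backbone
  n <- n_residues(structure)
  E <- matrix(Inf, n, n)
  if (n < 3L) return(E)
  # reconstructed H position per donor residue
  H <- matrix(NA_real_, n, 3L)
  for (j in 2:n) {
    cprev <- bb$c[j - 1L, ]; oprev <- bb$o[j - 1L, ]; nj <- bb$n[j, ]
    if (anyNA(c(cprev, oprev, nj))) next
    if (vnorm(cprev - nj) > 2.5) next  # chain break
    H[j, ] <- nj + unitv(cprev - oprev)
  }
  const <- 0.084 * 332
  for (i in seq_len(n)) {
    ci <- bb$c[i, ]; oi <- bb$o[i, ]
    if (anyNA(c(ci, oi))) next
    for (j in seq_len(n)) {
      if (abs(i - j) < 2L || anyNA(H[j, ])) next
      nj <- bb$n[j, ]; hj <- H[j, ]
      rON <- vnorm(oi - nj); rCH <- vnorm(ci - hj)
      rOH <- vnorm(oi - hj); rCN <- vnorm(ci - nj)
      if (min(rON, rCH, rOH, rCN) < 0.5) { E[i, j] <- -9.9; next }
      E[i, j] <- const * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
    }
  }
  E
}

#' Assign secondary structure from backbone geometry
#'
#' A compact three-state assignment driven by Kabsch-Sander hydrogen-bond
#' energies (bond when E < -0.5 kcal/mol):
#' \itemize{
#'   \item `H` - residues covered by two or more consecutive i -> i+4
#'     hydrogen bonds (the alpha-helical turn pattern);
#'   \item `E` - members of parallel or antiparallel bridges (the standard
#'     two-bond bridge patterns between non-adjacent residues);
#'   \item `C` - any other residue with a complete N/CA/C backbone;
#'   \item `-` - residues whose backbone is incomplete (e.g. CA-only input).
#' }
#' The similarity score used in secondary-structure based superposition only
#' tests code equality, so the three-state collapse coarsens but never breaks
#' that score. The assignment depends only on internal distances, hence is
#' invariant under rigid motion of the structure.
#'
#' @param structure a `ProteinStructure`.
#' @return length-N code string over `H`, `E`, `C`, `-`.
#' @export
assign_secondary <- function(structure) {
  n <- n_residues(structure)
  bb <- structure$backbone
  complete <- stats::complete.cases(bb$n) & stats::complete.cases(bb$ca) &
    stats::complete.cases(bb$c)
  codes <- ifelse(complete, "C", "-")
  # anything other than coil needs a run of >= 5 complete residues
  r <- rle(complete)
  if (!any(r$values & r$lengths >= 5L) || n < 5L)
    return(paste(codes, collapse = ""))

  E <- ks_hbond_matrix(structure)
  hb <- is.finite(E) & E < -0.5

  # helix: runs of >= 2 consecutive i -> i+4 turns cover residues i+1 .. i+5
  turn4 <- rep(FALSE, n)
  if (n >= 5L) for (i in seq_len(n - 4L)) turn4[i] <- hb[i, i + 4L]
  helix <- rep(FALSE, n)
  if (n >= 6L) {
    for (i in seq_len(n - 5L)) {
      if (turn4[i] && turn4[i + 1L]) helix[(i + 1L):(i + 4L)] <- TRUE
    }
  }

  # bridges: standard parallel / antiparallel double-bond patterns
  strand <- rep(FALSE, n)
  for (i in 2:(n - 1L)) {
    for (j in seq_len(n)) {
      if (abs(i - j) < 3L) next
      par <- (hb[j, i - 1L] && hb[i + 1L, j]) ||
        (j > 1L && j < n && hb[i, j - 1L] && hb[j + 1L, i])
      anti <- (hb[j, i] && hb[i, j]) ||
        (j < n && j > 1L && i > 1L && i < n &&
           hb[j + 1L, i - 1L] && hb[i + 1L, j - 1L])
      if (par || anti) { strand[i] <- TRUE; strand[j] <- TRUE }
    }
  }

  codes[strand & complete] <- "E"
  codes[helix & complete] <- "H"
  paste(codes, collapse = "")
}
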