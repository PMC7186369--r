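#' Protein structure container
#'
#' A single-chain protein structure reduced to the per-residue information the
#' alignment and feature machinery needs: alpha-carbon and beta-carbon
#' coordinates, backbone N/CA/C/O coordinates, the one-letter sequence and a
#' secondary-structure code string.
#'
#' For glycine (no beta carbon) the alpha-carbon coordinate is reused as the
#' beta-carbon coordinate, so `cb_coords` is always fully populated.
#'
#' @param id character identifier.
#' @param sequence one-letter amino-acid string of length N.
#' @param ca_coords N x 3 matrix of alpha-carbon coordinates (angstrom).
#' @param backbone list with N x 3 matrices `n`, `ca`, `c`, `o`; rows of `o`
#'   (and, for partial input, `n`/`c`) may be NA when the atom is absent.
#' @param cb_coords N x 3 matrix of beta-carbon coordinates; defaults to the
#'   alpha carbons where missing.
#' @param chain one-letter chain identifier.
#' @param sec_codes length-N secondary structure string over `H`, `E`, `C`,
#'   `-` (`-` = unassigned). If `NULL` it is assigned from the backbone via
#'   [assign_secondary()].
#' @return an object of class `ProteinStructure`.
#' @export
protein_structure <- function(id, sequence, ca_coords, backbone,
                              cb_coords = NULL, chain = "A",
                              sec_codes = NULL) {
  ca_coords <- as.matrix(ca_coords)
  n <- nrow(ca_coords)
  if (n < 1L) stop("structure must contain at least one residue")
  if (ncol(ca_coords) != 3L) stop("ca_coords must be N x 3")
  if (!all(is.finite(ca_coords))) stop("non-finite alpha-carbon coordinates")
  if (nchar(sequence) != n) stop("sequence length does not match coordinates")
  for (nm in c("n", "ca", "c", "o")) {
    if (is.null(backbone[[nm]])) backbone[[nm]] <- matrix(NA_real_, n, 3L)
    backbone[[nm]] <- as.matrix(backbone[[nm]])
    if (nrow(backbone[[nm]]) != n) stop("backbone arrays must have N rows")
  }
  if (is.null(cb_coords)) cb_coords <- ca_coords
  cb_coords <- as.matrix(cb_coords)
  if (nrow(cb_coords) != n) stop("cb_coords must have N rows")
  seq_chars <- strsplit(sequence, "")[[1L]]
  gly <- seq_chars == "G"
  cb_coords[gly, ] <- ca_coords[gly, ]
  x <- structure(list(
    id = as.character(id), chain = chain, sequence = sequence,
    ca_coords = ca_coords, cb_coords = cb_coords, backbone = backbone,
    sec_codes = sec_codes %||% NULL
  ), class = "ProteinStructure")
  if (is.null(sec_codes)) x$sec_codes <- assign_secondary(x)
  if (nchar(x$sec_codes) != n) stop("sec_codes length does not match N")
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ProteinStructure <- function(x, ...) {
  cat(sprintf("<ProteinStructure %s chain %s: %d residues>\n",
              x$id, x$chain, n_residues(x)))
  cat(" sequence:", abbreviate_string(x$sequence), "\n")
  cat(" secondary:", abbreviate_string(x$sec_codes), "\n")
  invisible(x)
}

abbreviate_string <- function(s, width = 60L) {
  if (nchar(s) <= width) s else paste0(substr(s, 1L, width - 3L), "...")
}

#' Number of residues in a structure
#' @param structure a `ProteinStructure`.
#' @export
n_residues <- function(structure) nrow(structure$ca_coords)

sec_chars <- function(structure) strsplit(structure$sec_codes, "")[[1L]]

#' Apply a rigid transform to every atom of a structure
#'
#' @param structure a `ProteinStructure`.
#' @param transform a `RigidTransform` (see [kabsch()]).
#' @return the transformed `ProteinStructure` (secondary structure codes are
#'   unchanged: they only depend on internal distances).
#' @export
transform_structure <- function(structure, transform) {
  structure$ca_coords <- apply_transform(transform, structure$ca_coords)
  structure$cb_coords <- apply_transform(transform, structure$cb_coords)
  for (nm in names(structure$backbone)) {
    m <- structure$backbone[[nm]]
    ok <- stats::complete.cases(m)
    if (any(ok)) m[ok, ] <- apply_transform(transform, m[ok, , drop = FALSE])
    structure$backbone[[nm]] <- m
  }
  structure
}

#' Keep a subset of residues
#'
#' Subsets every per-residue array, preserving order. Useful for building
#' deletion variants of synthetic structures. Secondary structure is
#' re-assigned because deletions can break hydrogen-bond patterns.
#'
#' @param structure a `ProteinStructure`.
#' @param keep integer vector of residue indices to keep (1-based, increasing).
#' @export
subset_residues <- function(structure, keep) {
  keep <- sort(unique(as.integer(keep)))
  if (any(keep < 1L | keep > n_residues(structure)))
    stop("residue indices out of range")
  seq_chars <- strsplit(structure$sequence, "")[[1L]]
  protein_structure(
    id = structure$id, chain = structure$chain,
    sequence = paste(seq_chars[keep], collapse = ""),
    ca_coords = structure$ca_coords[keep, , drop = FALSE],
    cb_coords = structure$cb_coords[keep, , drop = FALSE],
    backbone = lapply(structure$backbone, function(m) m[keep, , drop = FALSE])
  )
}
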