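# Small 3-D geometry helpers shared across modules. All angles in degrees.

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Angle between two vectors
#' @param a,b numeric 3-vectors.
#' @return angle in degrees in [0, 180].
#' @keywords internal
vec_angle <- function(a, b) {
  ca <- sum(a * b) / (vnorm(a) * vnorm(b))
  acos(max(-1, min(1, ca))) * 180 / pi
}

#' Torsion (dihedral) angle of four points
#'
#' Signed dihedral p1-p2-p3-p4 using the IUPAC convention (trans = 180).
#'
#' @param p1,p2,p3,p4 numeric 3-vectors.
#' @return angle in degrees in (-180, 180].
#' @keywords internal
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unitv(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

# NeRF atom placement: position D bonded to C, given the three preceding
# atoms A-B-C, a bond length |C-D|, the bond angle B-C-D and the dihedral
# A-B-C-D. Used to grow ideal backbones.
place_atom <- function(a, b, c, bond, angle, dihedral) {
  th <- angle * pi / 180
  chi <- dihedral * pi / 180
  bc <- unitv(c - b)
  n <- unitv(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- bond * c(-cos(th), sin(th) * cos(chi), -sin(th) * sin(chi))
  c + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}

#' Root mean square deviation between two coordinate sets
#'
#' @param x,y k x 3 matrices of corresponded coordinates (angstrom).
#' @return RMSD in angstrom.
#' @export
coord_rmsd <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(all(dim(x) == dim(y)))
  sqrt(mean(rowSums((x - y)^2)))
}

# Squared-Euclidean cross-distance between the rows of two matrices.
cross_sqdist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

# Run code with a private RNG state: seeds deterministically, then restores
# whatever random state the caller had. Keeps generators pure in their seed.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
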