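# Per-residue structural feature extraction and alignment-indexed feature
# matrices for downstream machine learning.

zero_mode_tol <- 1e-8

eig_modes <- function(mat) {
  e <- eigen(mat, symmetric = TRUE)
  # ascending order; identify near-zero modes relative to the spectrum
  vals <- rev(e$values)
  vecs <- e$vectors[, rev(seq_along(e$values)), drop = FALSE]
  nzero <- sum(abs(vals) < zero_mode_tol * max(abs(vals)))
  list(values = vals, vectors = vecs, n_zero = nzero)
}

connected_components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(0L, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Gaussian network model square fluctuations
#'
#' Builds the Kirchhoff (connectivity) matrix from the alpha-carbon contact
#' graph (`-1` for pairs within `cutoff`, diagonal = contact degree) and sums
#' `u_ki^2 / lambda_k` over the `n_modes` smallest nonzero modes. With all
#' `N - 1` modes this equals the diagonal of the Moore-Penrose pseudo-inverse
#' of the Kirchhoff matrix (up to the conventional kT/spring-constant scale,
#' which is taken as 1).
#'
#' @param ca_coords N x 3 alpha-carbon coordinates, N >= 3.
#' @param cutoff contact cutoff in angstrom (default 10).
#' @param n_modes number of low-frequency modes to sum (default 50).
#' @return length-N non-negative fluctuation vector.
#' @export
gnm_fluctuations <- function(ca_coords, cutoff = 10, n_modes = 50L) {
  ca <- as.matrix(ca_coords)
  n <- nrow(ca)
  if (n < 3L) stop("at least 3 residues are required")
  D <- as.matrix(stats::dist(ca))
  contact <- D <= cutoff & upper.tri(D, diag = FALSE)
  contact <- contact | t(contact)
  K <- -1 * contact
  diag(K) <- rowSums(contact)
  em <- eig_modes(K)
  if (em$n_zero > 1L) {
    comp <- connected_components(contact)
    stop("contact graph is disconnected into ", max(comp), " components: ",
         paste(vapply(split(seq_len(n), comp),
                      function(ix) sprintf("[%d..%d]", min(ix), max(ix)),
                      character(1L)), collapse = " "))
  }
  k <- min(n_modes, n - 1L)
  sel <- (em$n_zero + 1L):(em$n_zero + k)
  U <- em$vectors[, sel, drop = FALSE]
  as.numeric((U^2) %*% (1 / em$values[sel]))
}

#' Anisotropic network model square fluctuations
#'
#' Builds the 3N x 3N Hessian from the standard pairwise super-elements
#' `-(d d^T) / |d|^2` for contacts within `cutoff` (unit spring constant) and
#' sums, for each residue, the squared x/y/z mode components divided by the
#' eigenvalue over the `n_modes` smallest nonzero modes. With all `3N - 6`
#' modes this equals the trace of the residue's 3 x 3 diagonal block of the
#' Hessian pseudo-inverse. Depends only on inter-residue distances, hence is
#' invariant under rigid motion of the input.
#'
#' @param ca_coords N x 3 alpha-carbon coordinates, N >= 4.
#' @param cutoff contact cutoff in angstrom (default 15).
#' @param n_modes number of low-frequency modes to sum (default 50).
#' @return length-N non-negative fluctuation vector.
#' @export
anm_fluctuations <- function(ca_coords, cutoff = 15, n_modes = 50L) {
  ca <- as.matrix(ca_coords)
  n <- nrow(ca)
  if (n < 4L) stop("at least 4 residues are required")
  H <- matrix(0, 3L * n, 3L * n)
  D <- as.matrix(stats::dist(ca))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (D[i, j] > cutoff || D[i, j] < 1e-9) next
      d <- ca[j, ] - ca[i, ]
      block <- -tcrossprod(d) / sum(d^2)
      ii <- (3L * i - 2L):(3L * i); jj <- (3L * j - 2L):(3L * j)
      H[ii, jj] <- block
      H[jj, ii] <- block
      H[ii, ii] <- H[ii, ii] - block
      H[jj, jj] <- H[jj, jj] - block
    }
  }
  em <- eig_modes(H)
  if (em$n_zero > 6L)
    stop("Hessian has ", em$n_zero, " near-zero modes (> 6): ",
         "degenerate or disconnected geometry")
  k <- min(n_modes, 3L * n - em$n_zero)
  sel <- (em$n_zero + 1L):(em$n_zero + k)
  U <- em$vectors[, sel, drop = FALSE]
  w <- (U^2) %*% (1 / em$values[sel])
  as.numeric(rowSums(matrix(w, n, 3L, byrow = TRUE)))
}

# -- solvent accessibility and depth ------------------------------------------

vdw_radius <- c(N = 1.55, C = 1.70, O = 1.52)

# Rotate centered coordinates into their principal-axes frame with a
# deterministic sign convention (positive third moment along each axis), so
# that sampling-based surface features are invariant under rigid motion of
# the input (up to eigen-solver precision; exactly symmetric point sets have
# no unique frame, but their features are not orientation-sensitive either).
canonical_orient <- function(coords) {
  x <- sweep(coords, 2L, colMeans(coords))
  ev <- eigen(stats::cov(x), symmetric = TRUE)$vectors
  y <- x %*% ev
  for (k in 1:3) if (sum(y[, k]^3) < 0) y[, k] <- -y[, k]
  y
}

# Deterministic near-uniform points on the unit sphere (golden spiral).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Flat atom table for a structure: one row per present N/CA/C/O/CB atom.
structure_atoms <- function(structure) {
  seq_chars <- strsplit(structure$sequence, "")[[1L]]
  bb <- structure$backbone
  rows <- list()
  for (i in seq_len(n_residues(structure))) {
    add <- function(name, elem, xyz) {
      if (all(is.finite(xyz)))
        rows[[length(rows) + 1L]] <<-
          data.frame(residue = i, atom = name, elem = elem,
                     x = xyz[1L], y = xyz[2L], z = xyz[3L])
    }
    add("N", "N", bb$n[i, ])
    add("CA", "C", structure$ca_coords[i, ])
    add("C", "C", bb$c[i, ])
    add("O", "O", bb$o[i, ])
    if (seq_chars[i] != "G" &&
        any(structure$cb_coords[i, ] != structure$ca_coords[i, ]))
      add("CB", "C", structure$cb_coords[i, ])
  }
  at <- do.call(rbind, rows)
  at$radius <- vdw_radius[at$elem]
  at
}

#' Solvent-accessible surface area per atom (Shrake-Rupley)
#'
#' Samples `n_points` near-uniform points on each atom's solvent-expanded
#' sphere (van der Waals radius + probe) and counts the fraction not buried
#' inside any neighboring atom's expanded sphere.
#'
#' @param coords k x 3 atom coordinates.
#' @param radii length-k van der Waals radii, angstrom.
#' @param probe probe radius, angstrom (default 1.4, water).
#' @param n_points sample points per atom.
#' @return length-k areas in angstrom^2.
#' @export
atom_sasa <- function(coords, radii, probe = 1.4, n_points = 256L) {
  coords <- as.matrix(coords)
  k <- nrow(coords)
  pts <- sphere_points(n_points)
  er <- radii + probe
  out <- numeric(k)
  D2 <- cross_sqdist(coords, coords)
  for (i in seq_len(k)) {
    nb <- which(D2[i, ] < (er[i] + er)^2 & seq_len(k) != i)
    p <- sweep(pts * er[i], 2L, coords[i, ], `+`)
    if (length(nb)) {
      d2 <- cross_sqdist(p, coords[nb, , drop = FALSE])
      buried <- rowSums(d2 < matrix(er[nb]^2, n_points, length(nb),
                                    byrow = TRUE)) > 0L
    } else buried <- rep(FALSE, n_points)
    out[i] <- mean(!buried) * 4 * pi * er[i]^2
  }
  out
}

#' Residue depth below the solvent-accessible surface
#'
#' The solvent-accessible surface is sampled as the set of points on the
#' atoms' expanded spheres (radius + probe) not contained in any other atom's
#' expanded sphere; each residue's depth is the mean distance of its atoms to
#' the nearest retained surface point. A sampled-surface approximation whose
#' accuracy is bounded by `sphere_points`.
#'
#' @param structure a `ProteinStructure` (N/CA/C/O/CB atoms are used).
#' @param probe probe radius, angstrom.
#' @param sphere_points surface sample points per atom.
#' @return length-N depths in angstrom.
#' @export
residue_depth <- function(structure, probe = 1.4, sphere_points = 256L) {
  at <- structure_atoms(structure)
  if (nrow(at) < 4L) stop("at least 4 atoms are required")
  coords <- canonical_orient(as.matrix(at[, c("x", "y", "z")]))
  er <- at$radius + probe
  pts <- sphere_points(sphere_points)
  surface <- list()
  D2 <- cross_sqdist(coords, coords)
  for (i in seq_len(nrow(at))) {
    nb <- which(D2[i, ] < (er[i] + er)^2 & seq_len(nrow(at)) != i)
    p <- sweep(pts * er[i], 2L, coords[i, ], `+`)
    if (length(nb)) {
      d2 <- cross_sqdist(p, coords[nb, , drop = FALSE])
      keep <- rowSums(d2 < matrix((er[nb] - 1e-6)^2, nrow(p), length(nb),
                                  byrow = TRUE)) == 0L
      p <- p[keep, , drop = FALSE]
    }
    surface[[i]] <- p
  }
  surf <- do.call(rbind, surface)
  depth_atom <- numeric(nrow(at))
  chunk <- 2000L
  for (s in seq(1L, nrow(surf), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(surf))
    d2 <- cross_sqdist(coords, surf[s:e, , drop = FALSE])
    mins <- sqrt(apply(d2, 1L, min))
    depth_atom <- if (s == 1L) mins else pmin(depth_atom, mins)
  }
  as.numeric(tapply(depth_atom, at$residue, mean)[
    as.character(seq_len(n_residues(structure)))])
}

# -- backbone geometry features ----------------------------------------------

#' Backbone geometry and hydrogen-bond features
#'
#' Per-residue record of: best (most negative) hydrogen-bond energies of the
#' residue as donor and as acceptor (kcal/mol, Kabsch-Sander formula),
#' solvent accessibility (angstrom^2, summed atom SASA), the alpha virtual
#' torsion (CA i-1..i+2), the kappa bend angle at CA i between residues i-2
#' and i+2, phi/psi backbone torsions, and tco (cosine of the angle between
#' the C=O bonds of residues i and i-1). Angles in degrees. Undefined values
#' (chain termini, missing atoms) are `NA`.
#'
#' @param structure a `ProteinStructure`.
#' @param probe,n_points accessibility sampling parameters.
#' @return data.frame with N rows and columns `hbond_donor_energy`,
#'   `hbond_acceptor_energy`, `accessibility`, `alpha`, `kappa`, `phi`,
#'   `psi`, `tco`.
#' @export
backbone_features <- function(structure, probe = 1.4, n_points = 256L) {
  n <- n_residues(structure)
  bb <- structure$backbone
  ca <- structure$ca_coords
  out <- data.frame(hbond_donor_energy = rep(NA_real_, n),
                    hbond_acceptor_energy = NA_real_, accessibility = NA_real_,
                    alpha = NA_real_, kappa = NA_real_, phi = NA_real_,
                    psi = NA_real_, tco = NA_real_)
  E <- ks_hbond_matrix(structure)
  for (i in seq_len(n)) {
    don <- E[, i][is.finite(E[, i])]
    acc <- E[i, ][is.finite(E[i, ])]
    if (length(don)) out$hbond_donor_energy[i] <- min(don)
    if (length(acc)) out$hbond_acceptor_energy[i] <- min(acc)
    if (i >= 2L && i <= n - 2L)
      out$alpha[i] <- tryCatch(dihedral_angle(ca[i - 1L, ], ca[i, ],
                                              ca[i + 1L, ], ca[i + 2L, ]),
                               error = function(e) NA_real_)
    if (i >= 3L && i <= n - 2L)
      out$kappa[i] <- tryCatch(vec_angle(ca[i, ] - ca[i - 2L, ],
                                         ca[i + 2L, ] - ca[i, ]),
                               error = function(e) NA_real_)
    if (i >= 2L && !anyNA(c(bb$c[i - 1L, ], bb$n[i, ], bb$ca[i, ], bb$c[i, ])))
      out$phi[i] <- dihedral_angle(bb$c[i - 1L, ], bb$n[i, ], bb$ca[i, ],
                                   bb$c[i, ])
    if (i <= n - 1L && !anyNA(c(bb$n[i, ], bb$ca[i, ], bb$c[i, ],
                                bb$n[i + 1L, ])))
      out$psi[i] <- dihedral_angle(bb$n[i, ], bb$ca[i, ], bb$c[i, ],
                                   bb$n[i + 1L, ])
    if (i >= 2L && !anyNA(c(bb$c[i, ], bb$o[i, ], bb$c[i - 1L, ],
                            bb$o[i - 1L, ]))) {
      v1 <- bb$o[i, ] - bb$c[i, ]
      v0 <- bb$o[i - 1L, ] - bb$c[i - 1L, ]
      out$tco[i] <- sum(v1 * v0) / (vnorm(v1) * vnorm(v0))
    }
  }
  at <- structure_atoms(structure)
  sasa <- atom_sasa(canonical_orient(as.matrix(at[, c("x", "y", "z")])),
                    at$radius,
                    probe = probe, n_points = n_points)
  acc_by_res <- tapply(sasa, at$residue, sum)
  out$accessibility <- as.numeric(acc_by_res[as.character(seq_len(n))])
  out
}

#' Full per-residue feature table for one structure
#'
#' Combines elastic-network fluctuations (computed on the alpha carbons),
#' backbone geometry features, and the atom-level features (accessibility and
#' depth) reduced to alpha-carbon, beta-carbon and residue-mean columns.
#'
#' @param structure a `ProteinStructure`.
#' @param gnm_cutoff,anm_cutoff,n_modes elastic-network parameters.
#' @param probe,sasa_points,depth_points sampling parameters for
#'   accessibility and depth.
#' @return numeric matrix, N residues x named features.
#' @export
extract_features <- function(structure, gnm_cutoff = 10, anm_cutoff = 15,
                             n_modes = 50L, probe = 1.4, sasa_points = 256L,
                             depth_points = 128L) {
  n <- n_residues(structure)
  bbf <- backbone_features(structure, probe = probe, n_points = sasa_points)
  at <- structure_atoms(structure)
  sasa <- atom_sasa(canonical_orient(as.matrix(at[, c("x", "y", "z")])),
                    at$radius,
                    probe = probe, n_points = sasa_points)
  depth <- residue_depth(structure, probe = probe,
                         sphere_points = depth_points)
  pick_atom <- function(values, name) {
    v <- rep(NA_real_, n)
    sel <- at$atom == name
    v[at$residue[sel]] <- values[sel]
    v
  }
  res_mean <- function(values)
    as.numeric(tapply(values, at$residue, mean)[as.character(seq_len(n))])
  # depth is computed per residue from atom depths; recover CA/CB atoms
  # directly for the atom-level variants
  coords <- as.matrix(at[, c("x", "y", "z")])
  acc_ca <- pick_atom(sasa, "CA")
  acc_cb <- pick_atom(sasa, "CB")
  acc_cb[is.na(acc_cb)] <- acc_ca[is.na(acc_cb)]  # Gly: CA stands in for CB
  m <- cbind(
    gnm_fluctuation = gnm_fluctuations(structure$ca_coords,
                                       cutoff = gnm_cutoff, n_modes = n_modes),
    anm_fluctuation = anm_fluctuations(structure$ca_coords,
                                       cutoff = anm_cutoff, n_modes = n_modes),
    phi = bbf$phi, psi = bbf$psi, alpha = bbf$alpha, kappa = bbf$kappa,
    tco = bbf$tco,
    hbond_donor_energy = bbf$hbond_donor_energy,
    hbond_acceptor_energy = bbf$hbond_acceptor_energy,
    accessibility_ca = acc_ca,
    accessibility_cb = acc_cb,
    accessibility_mean = res_mean(sasa),
    depth_mean = depth
  )
  rownames(m) <- NULL
  m
}

# -- alignment-indexed feature matrix -----------------------------------------

#' Scatter per-structure features into alignment columns
#'
#' @param msa a `MultipleAlignment`.
#' @param per_structure_features named list (one entry per structure id in
#'   the alignment) of numeric matrices with one row per residue and a common
#'   set of named feature columns, as from [extract_features()].
#' @return a `FeatureMatrix`: 3-D array `structures x columns x features`
#'   with `NA` exactly at gap cells.
#' @export
aligned_feature_matrix <- function(msa, per_structure_features) {
  ids <- names(msa$rows)
  feats <- per_structure_features[ids]
  if (any(vapply(feats, is.null, logical(1L))))
    stop("missing features for: ",
         paste(ids[vapply(feats, is.null, logical(1L))], collapse = ", "))
  fnames <- colnames(feats[[1L]])
  arr <- array(NA_real_, dim = c(length(ids), msa$column_count, length(fnames)),
               dimnames = list(ids, NULL, fnames))
  for (id in ids) {
    f <- as.matrix(feats[[id]])
    row <- msa$rows[[id]]
    if (nrow(f) != sum(!is.na(row)))
      stop("feature rows for '", id, "' (", nrow(f),
           ") do not match its residue count (", sum(!is.na(row)), ")")
    cols <- which(!is.na(row))
    arr[id, cols, ] <- f[row[cols], fnames, drop = FALSE]
  }
  base::structure(list(values = arr, feature_names = fnames,
                       structure_ids = ids,
                       column_count = msa$column_count),
                  class = "FeatureMatrix")
}

#' @export
print.FeatureMatrix <- function(x, ...) {
  cat(sprintf("<FeatureMatrix: %d structures x %d columns x %d features>\n",
              length(x$structure_ids), x$column_count,
              length(x$feature_names)))
  invisible(x)
}

#' Drop alignment columns containing any gap
#'
#' The usual preprocessing before feeding aligned features to a learner:
#' only columns where every structure has a residue are kept.
#'
#' @param fm a `FeatureMatrix`.
#' @return a `FeatureMatrix` restricted to gap-free columns.
#' @export
drop_gap_columns <- function(fm) {
  keep <- apply(!is.na(fm$values[, , 1L, drop = FALSE]), 2L, all)
  fm$values <- fm$values[, keep, , drop = FALSE]
  fm$column_count <- sum(keep)
  fm
}

#' Write / read a feature matrix as TSV
#'
#' Long format: one row per structure x column, one column per feature;
#' missing cells written as `NaN`. The round trip preserves values and
#' missingness.
#'
#' @param fm a `FeatureMatrix`.
#' @param path file path.
#' @export
write_feature_tsv <- function(fm, path) {
  long <- do.call(rbind, lapply(fm$structure_ids, function(id) {
    data.frame(structure = id, column = seq_len(fm$column_count),
               fm$values[id, , , drop = TRUE], check.names = FALSE)
  }))
  for (f in fm$feature_names) long[[f]][is.na(long[[f]])] <- NaN
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_tsv
#' @export
read_feature_tsv <- function(path) {
  long <- utils::read.table(path, sep = "\t", header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE)
  ids <- unique(long$structure)
  fnames <- setdiff(colnames(long), c("structure", "column"))
  ncol_aln <- max(long$column)
  arr <- array(NA_real_, dim = c(length(ids), ncol_aln, length(fnames)),
               dimnames = list(ids, NULL, fnames))
  for (id in ids) {
    sub <- long[long$structure == id, , drop = FALSE]
    arr[id, sub$column, ] <- as.matrix(sub[, fnames, drop = FALSE])
  }
  base::structure(list(values = arr, feature_names = fnames,
                       structure_ids = ids, column_count = ncol_aln),
                  class = "FeatureMatrix")
}
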