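#' Synthetic protein backbone fixtures
#'
#' Generates idealized single-chain backbones (helix / strand / loop blocks)
#' with full N, CA, C, O, CB atoms, so that every stage of the alignment and
#' feature pipeline - including hydrogen-bond based secondary structure
#' assignment and backbone torsions - can be exercised without real data.
#'
#' Backbones are grown residue-by-residue from ideal internal coordinates
#' (bond lengths N-CA 1.458, CA-C 1.525, C-N 1.329, C-O 1.231 angstrom; trans
#' peptide, omega = 180), with per-block torsions: alpha helix phi/psi =
#' -57/-47, extended strand -139/135, and seeded random coil torsions for
#' loops. Trans peptides give consecutive CA-CA distances of ~3.8 angstrom,
#' and loop torsions are re-sampled when a new alpha carbon would clash
#' (< 4 angstrom) with an earlier one, approximating a self-avoiding walk.
#'
#' @param blocks ordered list of `c(kind, length)` pairs or a data.frame with
#'   columns `kind` (`"helix"`, `"strand"`, `"loop"`) and `length`.
#' @param noise_sd per-atom isotropic Gaussian coordinate noise, angstrom.
#' @param seed integer seed controlling loop torsions and noise.
#' @param transform_seed optional integer; when given, the finished structure
#'   is moved by a random rigid-body transform drawn from this seed.
#' @param sequence optional one-letter sequence (default: poly-alanine).
#' @param id structure identifier.
#' @return a `FixtureSpec` (for [fixture_spec()]) or a `ProteinStructure`
#'   (for [make_structure()]).
#' @export
fixture_spec <- function(blocks, noise_sd = 0, seed = 1L,
                         transform_seed = NULL, sequence = NULL,
                         id = "fixture") {
  if (is.data.frame(blocks)) {
    blocks <- Map(function(k, l) list(kind = k, length = as.integer(l)),
                  blocks$kind, blocks$length)
  }
  blocks <- lapply(blocks, function(b) {
    b <- as.list(b)
    names(b) <- c("kind", "length")[seq_along(b)]
    b$kind <- match.arg(b$kind, c("helix", "strand", "loop"))
    b$length <- as.integer(b$length)
    if (b$length < 1L) stop("block lengths must be >= 1")
    b
  })
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(blocks = blocks, noise_sd = noise_sd, seed = as.integer(seed),
                 transform_seed = transform_seed, sequence = sequence,
                 id = id),
            class = "FixtureSpec")
}

block_torsions <- function(kind, len) {
  if (kind == "helix") {
    cbind(phi = rep(-57, len), psi = rep(-47, len))
  } else if (kind == "strand") {
    cbind(phi = rep(-139, len), psi = rep(135, len))
  } else {
    # coil: broad left-half Ramachandran region, drawn from the current RNG
    cbind(phi = stats::runif(len, -160, -50),
          psi = stats::runif(len, -75, 170))
  }
}

#' Build a synthetic structure from a fixture specification
#'
#' @param spec a `FixtureSpec` from [fixture_spec()].
#' @return a `ProteinStructure`; deterministic for a fixed spec.
#' @seealso [perturb()], [random_rigid()]
#' @export
make_structure <- function(spec) {
  stopifnot(inherits(spec, "FixtureSpec"))
  n <- sum(vapply(spec$blocks, function(b) b$length, integer(1)))
  sequence <- spec$sequence %||% strrep("A", n)
  if (nchar(sequence) != n) stop("sequence length must match total block length")
  with_seed(spec$seed, {
    tor <- do.call(rbind, lapply(spec$blocks,
                                 function(b) block_torsions(b$kind, b$length)))
    bb <- grow_backbone(tor)
    if (spec$noise_sd > 0) {
      for (nm in names(bb)) {
        bb[[nm]] <- bb[[nm]] +
          matrix(stats::rnorm(length(bb[[nm]]), sd = spec$noise_sd),
                 nrow(bb[[nm]]), 3L)
      }
    }
    st <- protein_structure(
      id = spec$id, sequence = sequence, ca_coords = bb$ca,
      cb_coords = bb$cb, backbone = bb[c("n", "ca", "c", "o")]
    )
    if (!is.null(spec$transform_seed)) st <- random_rigid(st, spec$transform_seed)
    st
  })
}

# Grow N/CA/C/O/CB coordinates for the given phi/psi rows (degrees).
# Loop torsions are re-sampled on CA-CA clash (< 4 A to residues i-4 and
# earlier), up to 40 attempts per residue.
grow_backbone <- function(torsions) {
  n <- nrow(torsions)
  N <- CA <- C <- O <- CB <- matrix(NA_real_, n, 3L)
  N[1L, ] <- c(0, 0, 0)
  CA[1L, ] <- c(1.458, 0, 0)
  C[1L, ] <- CA[1L, ] + 1.525 * c(cos(pi * (180 - 111.2) / 180),
                                  sin(pi * (180 - 111.2) / 180), 0)
  for (i in seq_len(n)[-1L]) {
    attempt <- 0L
    repeat {
      attempt <- attempt + 1L
      psi_prev <- torsions[i - 1L, "psi"]
      phi_i <- torsions[i, "phi"]
      ni <- place_atom(N[i - 1L, ], CA[i - 1L, ], C[i - 1L, ],
                       1.329, 116.2, psi_prev)
      cai <- place_atom(CA[i - 1L, ], C[i - 1L, ], ni, 1.458, 121.7, 180)
      ci <- place_atom(C[i - 1L, ], ni, cai, 1.525, 111.2, phi_i)
      clash <- FALSE
      if (i > 4L) {
        d2 <- rowSums(sweep(CA[seq_len(i - 4L), , drop = FALSE], 2L, cai)^2)
        clash <- any(d2 < 16)
      }
      if (!clash || attempt >= 40L) {
        N[i, ] <- ni; CA[i, ] <- cai; C[i, ] <- ci
        break
      }
      # only loops are random; re-draw this residue's torsions
      torsions[i - 1L, "psi"] <- stats::runif(1, -75, 170)
      torsions[i, "phi"] <- stats::runif(1, -160, -50)
    }
  }
  for (i in seq_len(n)) {
    psi_i <- if (i < n) torsions[i, "psi"] else torsions[i, "psi"]
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], 1.231, 120.8, psi_i + 180)
    CB[i, ] <- place_atom(N[i, ], C[i, ], CA[i, ], 1.521, 110.4, 122.55)
  }
  list(n = N, ca = CA, c = C, o = O, cb = CB)
}

#' Add Gaussian coordinate noise to a structure
#'
#' Each atom is displaced by an independent isotropic Gaussian; the expected
#' CA RMSD to the original is `noise_sd * sqrt(3)`. Secondary structure is
#' re-assigned afterwards since large noise can break hydrogen bonds.
#'
#' @param structure a `ProteinStructure`.
#' @param noise_sd standard deviation per coordinate axis, angstrom.
#' @param seed integer seed.
#' @export
perturb <- function(structure, noise_sd, seed) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (noise_sd == 0) return(structure)
  with_seed(seed, {
    jitter3 <- function(m) {
      ok <- stats::complete.cases(m)
      m[ok, ] <- m[ok, , drop = FALSE] +
        matrix(stats::rnorm(3L * sum(ok), sd = noise_sd), sum(ok), 3L)
      m
    }
    bb <- lapply(structure$backbone, jitter3)
    protein_structure(
      id = structure$id, chain = structure$chain,
      sequence = structure$sequence, ca_coords = bb$ca,
      cb_coords = jitter3(structure$cb_coords), backbone = bb
    )
  })
}

#' Move a structure by a random rigid-body transform
#'
#' Rotation drawn uniformly from SO(3) (quaternion method), translation
#' uniform in a [-50, 50] angstrom box.
#'
#' @param structure a `ProteinStructure`.
#' @param seed integer seed.
#' @export
random_rigid <- function(structure, seed) {
  tr <- with_seed(seed, {
    q <- stats::rnorm(4L)
    q <- q / vnorm(q)
    rigid_transform(quaternion_rotation(q), stats::runif(3L, -50, 50))
  })
  transform_structure(structure, tr)
}

quaternion_rotation <- function(q) {
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3L, 3L, byrow = TRUE)
}

#' Noise-seeded groups for runtime scaling experiments
#'
#' For each seed structure, builds one group per requested size whose members
#' are noisy copies of the seed - the protocol used to measure how alignment
#' runtime scales with the number and length of structures. Timings are
#' informational; nothing in the test suite asserts on them.
#'
#' @param n_seeds number of seed structures.
#' @param sizes group sizes (number of members per group).
#' @param lengths residue lengths cycled over the seed structures.
#' @param noise_sd coordinate noise for the members, angstrom.
#' @param seed master seed.
#' @return nested list: `result[[seed]][[size]]` is a list of
#'   `ProteinStructure`s.
#' @export
scaling_benchmark_groups <- function(n_seeds = 25L, sizes = seq(13L, 93L, 30L),
                                     lengths = c(60L, 120L, 200L),
                                     noise_sd = 0.5, seed = 1L) {
  lengths <- rep_len(lengths, n_seeds)
  out <- vector("list", n_seeds)
  for (s in seq_len(n_seeds)) {
    len <- lengths[s]
    base <- make_structure(fixture_spec(
      list(c("helix", max(4L, len %/% 3L)),
           c("loop", max(2L, len %/% 6L)),
           c("strand", max(3L, len %/% 4L)),
           c("loop", len - max(4L, len %/% 3L) - max(2L, len %/% 6L) -
               max(3L, len %/% 4L))),
      seed = seed * 1000L + s, id = sprintf("seed%02d", s)
    ))
    groups <- lapply(sizes, function(k) {
      lapply(seq_len(k), function(j) {
        st <- perturb(base, noise_sd, seed * 100000L + s * 1000L + j)
        st$id <- sprintf("%s_m%03d", base$id, j)
        st
      })
    })
    names(groups) <- as.character(sizes)
    out[[s]] <- groups
  }
  names(out) <- sprintf("seed%02d", seq_len(n_seeds))
  out
}
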