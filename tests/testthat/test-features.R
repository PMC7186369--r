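test_that("GNM fluctuations match the pseudo-inverse oracle with all modes", {
  skip_if_not_installed("MASS")
  s <- base_structure()
  ca <- s$ca_coords
  n <- nrow(ca)
  fl <- gnm_fluctuations(ca, cutoff = 10, n_modes = n - 1)
  D <- as.matrix(dist(ca))
  K <- -(D <= 10) * 1
  diag(K) <- 0
  diag(K) <- -rowSums(K)
  oracle <- diag(MASS::ginv(K))
  expect_equal(fl, oracle, tolerance = 1e-6)
  expect_true(all(fl >= 0))
  # a linear chain's termini are its most mobile residues
  hx <- make_structure(fixture_spec(list(c("helix", 40)), seed = 2))
  f2 <- gnm_fluctuations(hx$ca_coords)
  expect_true(which.max(f2) %in% c(1, 40))
})

test_that("GNM errors on a disconnected contact graph", {
  ca <- rbind(matrix(rnorm(15), 5, 3), matrix(rnorm(15), 5, 3) + 100)
  expect_error(gnm_fluctuations(ca, cutoff = 10), "disconnected")
})

test_that("ANM fluctuations match the pseudo-inverse oracle and are
           rigid-motion invariant", {
  skip_if_not_installed("MASS")
  s <- make_structure(fixture_spec(list(c("helix", 12), c("loop", 8)),
                                   seed = 3))
  ca <- s$ca_coords
  n <- nrow(ca)
  fl <- anm_fluctuations(ca, cutoff = 15, n_modes = 3 * n - 6)
  # oracle: trace of the 3x3 diagonal blocks of the Hessian pseudo-inverse
  H <- matrix(0, 3 * n, 3 * n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- ca[j, ] - ca[i, ]
    if (sqrt(sum(d^2)) > 15) next
    blk <- -outer(d, d) / sum(d^2)
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    H[ii, jj] <- blk; H[jj, ii] <- blk
    H[ii, ii] <- H[ii, ii] - blk; H[jj, jj] <- H[jj, jj] - blk
  }
  Hp <- MASS::ginv(H)
  oracle <- vapply(1:n, function(i) sum(diag(Hp)[(3 * i - 2):(3 * i)]),
                   numeric(1))
  expect_equal(fl, oracle, tolerance = 1e-6)
  expect_true(all(fl >= 0))

  moved <- random_rigid(s, 8)
  expect_equal(anm_fluctuations(moved$ca_coords, cutoff = 15, n_modes = 10),
               anm_fluctuations(ca, cutoff = 15, n_modes = 10),
               tolerance = 1e-8)
})

test_that("backbone features read ideal torsions back from the fixture", {
  hx <- make_structure(fixture_spec(list(c("helix", 20)), seed = 1))
  bf <- backbone_features(hx)
  interior <- 3:18
  expect_lt(abs(mean(bf$phi[interior]) - (-57)), 10)
  expect_lt(abs(mean(bf$psi[interior]) - (-47)), 10)
  expect_true(is.na(bf$phi[1]))    # no preceding C
  expect_true(is.na(bf$psi[20]))   # no following N
  expect_true(is.na(bf$tco[1]))
  expect_true(all(abs(bf$tco[2:20]) <= 1 + 1e-9))
  expect_true(all(bf$kappa[3:18] >= 0 & bf$kappa[3:18] <= 180))
  # helix hydrogen bonds are strong
  expect_lt(min(bf$hbond_acceptor_energy, na.rm = TRUE), -1)
})

test_that("a fully enclosed atom has ~zero accessible surface", {
  # two-shell construction: one atom at the origin surrounded by a tight shell
  shell <- structmsa:::sphere_points(60) * 3
  coords <- rbind(c(0, 0, 0), shell)
  radii <- rep(1.7, nrow(coords))
  sasa <- atom_sasa(coords, radii, probe = 1.4, n_points = 128)
  expect_equal(sasa[1], 0)
  expect_true(mean(sasa[-1]) > 5)  # shell atoms keep outward-facing surface
})

test_that("residue depth is larger in the core and rigid-motion invariant", {
  s <- make_structure(fixture_spec(list(c("loop", 40)), seed = 12))
  d <- residue_depth(s, sphere_points = 64)
  expect_true(all(is.finite(d)))
  # a single isolated residue sits right under its own surface
  one <- subset_residues(s, 20)
  d1 <- residue_depth(one, sphere_points = 128)
  expect_lte(d1, 1.4 + 1.7 + 0.5)

  moved <- random_rigid(s, 4)
  expect_equal(residue_depth(moved, sphere_points = 64), d, tolerance = 1e-6)
})

test_that("depth separates a buried center from surface residues", {
  # a dense ball of CA pseudo-atoms: residue 1 at the center, the rest
  # filling a sphere around it on a 3-angstrom grid
  g <- as.matrix(expand.grid(x = seq(-6, 6, 3), y = seq(-6, 6, 3),
                             z = seq(-6, 6, 3)))
  g <- g[order(rowSums(g^2)), ]
  g <- g[sqrt(rowSums(g^2)) <= 6.5, ]
  n <- nrow(g)
  st <- protein_structure(id = "ball", sequence = strrep("G", n),
                          ca_coords = g, backbone = list(ca = g))
  d <- residue_depth(st, sphere_points = 64)
  boundary <- which(sqrt(rowSums(g^2)) > 5.9)
  expect_gt(d[1], max(d[boundary]))
})

test_that("feature matrices scatter to columns with missing exactly at gaps", {
  fam <- noisy_family(base_structure(), 3, noise_sd = 0.3, seed = 21)
  fam[[2]] <- subset_residues(fam[[2]], setdiff(1:60, 30:32))
  fam[[2]]$id <- "base_m1"
  msa <- multiple_align(fam)
  feats <- lapply(fam, function(st) {
    m <- cbind(x = seq_len(n_residues(st)), y = rep(1, n_residues(st)))
    m
  })
  names(feats) <- vapply(fam, `[[`, character(1), "id")
  fm <- aligned_feature_matrix(msa, feats)
  for (id in names(msa$rows)) {
    row <- msa$rows[[id]]
    expect_identical(which(is.na(fm$values[id, , "x"])), which(is.na(row)))
    expect_identical(unname(fm$values[id, !is.na(row), "x"]),
                     as.numeric(seq_len(sum(!is.na(row)))))
  }
  # dropping gapped columns leaves a dense matrix
  dense <- drop_gap_columns(fm)
  expect_false(anyNA(dense$values))
  expect_equal(dense$column_count, gapless_positions(msa)$count)

  bad <- feats
  bad[[2]] <- bad[[2]][-1, ]
  expect_error(aligned_feature_matrix(msa, bad), "base_m1")
})

test_that("feature TSV round-trips losslessly including missing cells", {
  fam <- noisy_family(base_structure(), 2, noise_sd = 0.2, seed = 31)
  fam[[2]] <- subset_residues(fam[[2]], 1:55)
  fam[[2]]$id <- "short"
  msa <- multiple_align(fam)
  feats <- lapply(fam, function(st)
    cbind(a = rnorm(n_residues(st)), b = rnorm(n_residues(st))))
  names(feats) <- vapply(fam, `[[`, character(1), "id")
  fm <- aligned_feature_matrix(msa, feats)
  path <- tempfile(fileext = ".tsv")
  write_feature_tsv(fm, path)
  back <- read_feature_tsv(path)
  expect_equal(back$values[fm$structure_ids, , fm$feature_names], fm$values,
               tolerance = 1e-12)
})

test_that("extract_features returns a complete named per-residue table", {
  s <- make_structure(fixture_spec(list(c("helix", 14), c("loop", 10)),
                                   seed = 5))
  m <- extract_features(s, sasa_points = 64, depth_points = 48)
  expect_equal(nrow(m), 24)
  expect_true(all(c("gnm_fluctuation", "anm_fluctuation", "phi", "psi",
                    "accessibility_ca", "accessibility_cb",
                    "accessibility_mean", "depth_mean") %in% colnames(m)))
  expect_true(all(m[, "accessibility_ca"] >= 0))
})
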