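test_that("gap-less positions are counted correctly", {
  rows <- list(a = c(1L, 2L, 3L, NA, 4L), b = c(1L, NA, 2L, 3L, 4L))
  msa <- structmsa:::new_multiple_alignment(rows, 5L)
  gp <- gapless_positions(msa)
  expect_equal(gp$count, 3)
  expect_equal(gp$ratio, 0.6)
  expect_equal(gp$which, c(1L, 3L, 5L))

  dense <- structmsa:::new_multiple_alignment(
    list(a = 1:4, b = 1:4), 4L)
  expect_equal(gapless_positions(dense)$ratio, 1.0)

  sparse <- structmsa:::new_multiple_alignment(
    list(a = c(1L, NA), b = c(NA, 1L)), 2L)
  expect_equal(gapless_positions(sparse)$count, 0)
})

test_that("equivalence score is 100 against itself and 0 after a row shift", {
  fam <- noisy_family(base_structure(), 3, noise_sd = 0.4, seed = 15)
  msa <- multiple_align(fam)
  expect_equal(equivalence_score(msa, msa), 100)

  # a reference in which one structure is shifted by one residue shares no
  # column with the unshifted alignment
  test_msa <- structmsa:::new_multiple_alignment(list(a = 1:5, b = 1:5), 5L)
  ref <- structmsa:::new_multiple_alignment(
    list(a = c(1:5, NA), b = c(NA, 1:5)), 6L)
  expect_equal(equivalence_score(test_msa, ref), 0)
})

test_that("equivalence score matches a brute-force column-set oracle", {
  # hand-built alignments over three structures
  test_rows <- list(a = c(1L, 2L, 3L, 4L), b = c(1L, 2L, 3L, 4L),
                    c = c(1L, 2L, NA, 3L))
  ref_rows <- list(a = c(1L, 2L, NA, 3L, 4L), b = c(1L, NA, 2L, 3L, 4L),
                   c = c(1L, NA, 2L, 3L, NA))
  msa <- structmsa:::new_multiple_alignment(test_rows, 4L)
  ref <- structmsa:::new_multiple_alignment(ref_rows, 5L)
  # oracle: enumerate gap-less columns of both as index tuples and intersect
  tuples <- function(rows, cols) {
    ids <- sort(names(rows))
    apply(vapply(ids, function(id) rows[[id]][cols], integer(length(cols))),
          1, paste, collapse = "/")
  }
  gl_test <- which(Reduce(`&`, lapply(test_rows, function(r) !is.na(r))))
  gl_ref <- which(Reduce(`&`, lapply(ref_rows, function(r) !is.na(r))))
  expected <- 100 * mean(tuples(test_rows, gl_test) %in% tuples(ref_rows, gl_ref))
  expect_equal(equivalence_score(msa, ref), expected)
})

test_that("equivalence score rejects mismatched structure sets", {
  msa <- structmsa:::new_multiple_alignment(list(a = 1:3, b = 1:3), 3L)
  other <- structmsa:::new_multiple_alignment(list(a = 1:3, c = 1:3), 3L)
  expect_error(equivalence_score(msa, other), "different structure ids")
  short <- structmsa:::new_multiple_alignment(
    list(a = c(1L, 2L, NA), b = 1:3), 3L)
  expect_error(equivalence_score(msa, short), "sequence mismatch")
})

test_that("reference superposition recovers rigid motions", {
  fam <- noisy_family(base_structure(), 3, noise_sd = 0, seed = 16)
  msa <- multiple_align(fam)
  coords <- superpose_to_reference(msa, fam)
  ref <- coords[[1]]
  for (id in names(coords))
    expect_lt(coord_rmsd(coords[[id]], ref), 1e-6)
})

test_that("pairwise RMSD matches the direct formula and is order-invariant", {
  rows <- list(a = 1:3, b = 1:3)
  msa <- structmsa:::new_multiple_alignment(rows, 3L)
  c1 <- matrix(c(0, 0, 0, 1, 0, 0, 2, 0, 0), 3, byrow = TRUE)
  c2 <- c1
  c2[, 2] <- c2[, 2] + 2   # uniform 2-angstrom offset
  coords <- list(a = c1, b = c2)
  expect_equal(pairwise_rmsd(msa, coords), 2)

  fam <- noisy_family(base_structure(), 4, noise_sd = 0.7, seed = 17)
  msa <- multiple_align(fam)
  coords <- superpose_to_reference(msa, fam)
  got <- pairwise_rmsd(msa, coords)
  # brute-force recomputation over all unordered pairs
  ids <- names(msa$rows)
  vals <- c()
  for (a in 1:(length(ids) - 1)) for (b in (a + 1):length(ids)) {
    ra <- msa$rows[[ids[a]]]; rb <- msa$rows[[ids[b]]]
    sh <- !is.na(ra) & !is.na(rb)
    d2 <- rowSums((coords[[ids[a]]][ra[sh], ] - coords[[ids[b]]][rb[sh], ])^2)
    vals <- c(vals, sqrt(mean(d2)))
  }
  expect_equal(got, mean(vals), tolerance = 1e-12)
  # permutation invariance
  msa_r <- msa
  msa_r$rows <- rev(msa_r$rows)
  expect_equal(pairwise_rmsd(msa_r, coords), got, tolerance = 1e-12)
})

test_that("structurally equivalent residues respect the 4-angstrom cutoff", {
  fam <- noisy_family(base_structure(), 3, noise_sd = 0, seed = 18)
  msa <- multiple_align(fam)
  coords <- superpose_to_reference(msa, fam)
  se <- structurally_equivalent(msa, coords)
  expect_equal(se$mean_fraction, 1.0)
  expect_equal(se$mean_count, 60)

  # displace one set rigidly by 5 angstrom, deliberately skipping superposition
  rows <- list(a = 1:3, b = 1:3)
  small <- structmsa:::new_multiple_alignment(rows, 3L)
  c1 <- matrix(rnorm(9), 3, 3)
  off <- list(a = c1, b = c1 + 5 / sqrt(3))
  se2 <- structurally_equivalent(small, off)
  expect_equal(se2$mean_fraction, 0)

  # mixed case against a brute-force distance check
  fam2 <- noisy_family(base_structure(), 3, noise_sd = 1.5, seed = 19)
  msa2 <- multiple_align(fam2)
  coords2 <- superpose_to_reference(msa2, fam2)
  se3 <- structurally_equivalent(msa2, coords2)
  ids <- names(msa2$rows)
  fr <- c()
  for (a in 1:2) for (b in (a + 1):3) {
    ra <- msa2$rows[[ids[a]]]; rb <- msa2$rows[[ids[b]]]
    sh <- !is.na(ra) & !is.na(rb)
    d <- sqrt(rowSums((coords2[[ids[a]]][ra[sh], ] -
                         coords2[[ids[b]]][rb[sh], ])^2))
    fr <- c(fr, mean(d <= 4))
  }
  expect_equal(se3$mean_fraction, mean(fr), tolerance = 1e-12)
})

test_that("equivalent fraction does not increase with noise", {
  s <- base_structure()
  frac <- vapply(c(0.3, 1.2, 3), function(sd) {
    mean(vapply(1:3, function(r) {
      fam <- noisy_family(s, 3, noise_sd = sd, seed = 100 * sd + r)
      msa <- multiple_align(fam)
      structurally_equivalent(msa, superpose_to_reference(msa, fam))$mean_fraction
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(frac) <= 1e-9))
})

test_that("quality reports serialize to JSON and TSV", {
  fam <- noisy_family(base_structure(), 3, noise_sd = 0.4, seed = 20)
  msa <- multiple_align(fam)
  q <- alignment_quality(msa, fam, reference_msa = msa)
  expect_equal(q$equivalence_score, 100)
  expect_true(q$mean_pairwise_rmsd >= 0)
  jp <- tempfile(fileext = ".json")
  write_quality_report(q, jp)
  back <- jsonlite::read_json(jp)
  expect_equal(back$gapless_count, q$gapless_count)
  tp <- tempfile(fileext = ".tsv")
  write_quality_report(q, tp, format = "tsv")
  tab <- read.delim(tp)
  expect_true("mean_pairwise_rmsd" %in% tab$metric)
})
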