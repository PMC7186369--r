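# Shared fixture builders. Everything is generated in code; nothing is read
# from disk except files the tests themselves write to tempdir().

# A 60-residue mixed-topology backbone used throughout the suite.
base_structure <- function(seed = 7, id = "base") {
  make_structure(fixture_spec(
    list(c("helix", 20), c("loop", 8), c("strand", 12), c("loop", 6),
         c("helix", 14)),
    seed = seed, id = id
  ))
}

# k noisy, rigidly moved copies of a structure (the first is the original).
noisy_family <- function(base, k, noise_sd = 0.5, seed = 1) {
  c(list(base), lapply(seq_len(k - 1L), function(i) {
    st <- perturb(base, noise_sd, seed * 100 + i)
    st <- random_rigid(st, seed * 100 + i + 50)
    st$id <- sprintf("%s_m%d", base$id, i)
    st
  }))
}

# Random proper rotation drawn from a seed.
random_rotation <- function(seed) {
  with_seed_test(seed, {
    q <- rnorm(4)
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(
      1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
      2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
      2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
    ), 3, 3, byrow = TRUE)
  })
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# Brute-force oracle for global affine-gap alignment: enumerates every
# monotone global alignment of n x m indices and scores it with the shared
# gap-cost convention (a run of L same-direction gaps costs
# open + (L - 1) * extend; terminal gaps count). Independent of the DP code.
brute_force_best <- function(S, open, extend) {
  n <- nrow(S); m <- ncol(S)
  best <- -Inf
  # steps: 1 = diagonal (i,j), 2 = gap consuming i, 3 = gap consuming j
  recurse <- function(i, j, score, last_step, run_extra) {
    if (i == n && j == m) {
      if (score > best) best <<- score
      return(invisible())
    }
    if (i < n && j < m)
      recurse(i + 1, j + 1, score + S[i + 1, j + 1], 1L, 0)
    if (i < n) {
      cost <- if (last_step == 2L) extend else open
      recurse(i + 1, j, score - cost, 2L, 0)
    }
    if (j < m) {
      cost <- if (last_step == 3L) extend else open
      recurse(i, j + 1, score - cost, 3L, 0)
    }
  }
  recurse(0L, 0L, 0, 0L, 0)
  best
}

# Recompute the affine-gap objective of a returned alignment from scratch.
alignment_objective <- function(aln, S, open, extend) {
  p <- aln$pairs
  score <- 0
  last <- 0L
  for (r in seq_len(nrow(p))) {
    i <- p[r, 1]; j <- p[r, 2]
    if (!is.na(i) && !is.na(j)) {
      score <- score + S[i, j]
      last <- 1L
    } else if (!is.na(i)) {
      score <- score - if (last == 2L) extend else open
      last <- 2L
    } else {
      score <- score - if (last == 3L) extend else open
      last <- 3L
    }
  }
  score
}
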