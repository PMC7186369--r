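test_that("guide tree merges the most similar pair first", {
  S <- matrix(c(1, 0.9, 0.2,
                0.9, 1, 0.2,
                0.2, 0.2, 1), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- build_guide_tree(S)
  expect_equal(nrow(tree$merge_order), 2)
  expect_equal(sort(c(tree$merge_order$left[1], tree$merge_order$right[1])),
               c("A", "B"))
})

test_that("identical structures give a deterministic zero-height tree", {
  ids <- c("d", "b", "a", "c")
  S <- matrix(1, 4, 4, dimnames = list(ids, ids))
  tree <- build_guide_tree(S)
  expect_equal(nrow(tree$merge_order), 3)   # 4 leaves -> 3 merges
  expect_true(all(tree$merge_order$height == 0))
  expect_equal(c(tree$merge_order$left[1], tree$merge_order$right[1]),
               c("a", "b"))
  tree2 <- build_guide_tree(S)
  expect_identical(tree$merge_order, tree2$merge_order)
  expect_error(build_guide_tree(S[1, 1, drop = FALSE]), "at least 2")
})

test_that("newick export is a valid rooted binary tree", {
  skip_if_not_installed("ape")
  fam <- noisy_family(base_structure(), 4, noise_sd = 0.4, seed = 3)
  msa <- multiple_align(fam)
  nwk <- guide_tree_newick(attr(msa, "tree"))
  tr <- ape::read.tree(text = nwk)
  expect_equal(sort(tr$tip.label),
               sort(vapply(fam, `[[`, character(1), "id")))
  expect_true(ape::is.binary(tr))
})

test_that("combining two copies of a structure keeps every column doubly
           occupied with averaged coordinates", {
  s <- base_structure()
  copy <- random_rigid(s, 6)
  copy$id <- "copy"
  params <- alignment_params()
  node <- combine_nodes(structmsa:::leaf_node(s, params),
                        structmsa:::leaf_node(copy, params), params)
  expect_equal(nrow(node$coords), 60)
  expect_true(all(node$counts == 2L))
  expect_equal(node$consensus, rep(2, 60))
  expect_equal(node$n_structures, 2L)
  expect_equal(node$coords, copy$ca_coords, tolerance = 1e-5,
               ignore_attr = TRUE)
})

test_that("a loop deletion yields singly-occupied columns in the merged node", {
  s <- base_structure()                                 # N = 60
  short <- subset_residues(s, setdiff(1:60, 24:28))     # N = 55
  short$id <- "short"
  params <- alignment_params()
  node <- combine_nodes(structmsa:::leaf_node(s, params),
                        structmsa:::leaf_node(short, params), params)
  expect_equal(nrow(node$coords), 60)
  expect_equal(sum(node$counts == 2L), 55)
  expect_equal(sum(node$counts == 1L), 5)
  expect_equal(node$consensus, node$counts * params$consensus_weight)
})

test_that("identical structures align gap-free for several family sizes", {
  s <- base_structure()
  for (k in c(2, 4)) {
    fam <- lapply(seq_len(k), function(i) {
      st <- random_rigid(s, 300 + i)
      st$id <- paste0("c", i)
      st
    })
    msa <- multiple_align(fam)
    expect_equal(msa$column_count, 60)
    expect_equal(gapless_positions(msa)$count, 60)
  }
})

test_that("rows always read out each structure's full index sequence", {
  fam <- noisy_family(base_structure(), 4, noise_sd = 0.8, seed = 10)
  fam[[3]] <- subset_residues(fam[[3]], setdiff(1:60, 25:27))
  fam[[3]]$id <- "base_m2"
  msa <- multiple_align(fam)
  for (st in fam) {
    row <- msa$rows[[st$id]]
    expect_identical(as.integer(row[!is.na(row)]), seq_len(n_residues(st)))
  }
})

test_that("an insertion in one member localizes to contiguous gap columns", {
  long <- base_structure()                              # the 'insertion' carrier
  core <- subset_residues(long, setdiff(1:60, 25:30))   # 6 residues shorter
  fam <- lapply(1:3, function(i) {
    st <- random_rigid(core, 400 + i)
    st$id <- paste0("core", i)
    st
  })
  ins <- random_rigid(long, 404)
  ins$id <- "withloop"
  msa <- multiple_align(c(fam, list(ins)))
  occ <- sapply(msa$rows, function(r) !is.na(r))
  gap_cols <- which(rowSums(!occ) > 0)
  expect_length(gap_cols, 6)
  expect_identical(diff(gap_cols), rep(1L, 5))
  # the gaps are carried by the three shorter members
  expect_true(all(is.na(msa$rows[["core1"]][gap_cols])))
  expect_true(all(!is.na(msa$rows[["withloop"]][gap_cols])))
})

test_that("input order of identical structures affects neither width nor gaps", {
  s <- base_structure()
  fam <- lapply(1:4, function(i) {
    st <- random_rigid(s, 500 + i)
    st$id <- paste0("c", i)
    st
  })
  msa1 <- multiple_align(fam)
  msa2 <- multiple_align(rev(fam))
  expect_equal(msa1$column_count, msa2$column_count)
  expect_equal(gapless_positions(msa1)$count, gapless_positions(msa2)$count)
})

test_that("consensus weighting never loses gap-free columns on a mixed family", {
  s <- base_structure()
  fam <- c(
    lapply(1:6, function(i) {
      st <- random_rigid(perturb(s, 0.3, 600 + i), 700 + i)
      st$id <- paste0("sim", i)
      st
    }),
    lapply(1:2, function(i) {
      st <- random_rigid(perturb(s, 2.5, 800 + i), 900 + i)
      st$id <- paste0("div", i)
      st
    })
  )
  g1 <- gapless_positions(multiple_align(fam, alignment_params(consensus_weight = 1)))$count
  g0 <- gapless_positions(multiple_align(fam, alignment_params(consensus_weight = 0)))$count
  expect_gte(g1, g0)
})

test_that("root bookkeeping is consistent", {
  fam <- noisy_family(base_structure(), 4, noise_sd = 0.5, seed = 44)
  msa <- multiple_align(fam)
  root <- attr(msa, "root_node")
  expect_equal(root$n_structures, 4L)
  expect_true(all(root$counts >= 1L & root$counts <= 4L))
  occ <- sapply(msa$rows, function(r) !is.na(r))
  expect_equal(as.integer(rowSums(occ)), root$counts)
})
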