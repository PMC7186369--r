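#' Guide tree from pairwise similarity scores
#'
#' Agglomerates structures on the distance `d = 1 - tree_score` with
#' complete (maximum) linkage: the distance from a merged node to any other
#' node is the maximum over its members, so the most mutually similar groups
#' merge first and progression towards distant structures is as smooth as the
#' data allow. Ties are broken by lexicographic node id, making the merge
#' order deterministic (in particular for sets of identical structures).
#'
#' @param score_table symmetric numeric matrix of length-normalized pairwise
#'   alignment scores in [0, 1], with structure ids as dimnames.
#' @return a `GuideTree`: list with `merge_order` (data.frame with columns
#'   `left`, `right`, `new_id`, `height`) and `leaf_ids`.
#' @export
build_guide_tree <- function(score_table) {
  D <- 1 - as.matrix(score_table)
  ids <- rownames(D)
  if (is.null(ids)) stop("score_table needs structure ids as dimnames")
  k <- length(ids)
  if (k < 2L) stop("at least 2 structures are required")
  if (any(D < -1e-9 | D > 1 + 1e-9)) stop("scores must lie in [0, 1]")
  dimnames(D) <- list(ids, ids)
  active <- ids
  merges <- vector("list", k - 1L)
  for (step in seq_len(k - 1L)) {
    # find the minimum-distance active pair; ties -> lexicographically first
    best <- NULL
    for (a in seq_along(active)) {
      for (b in seq_along(active)) {
        if (b <= a) next
        pair <- sort(c(active[a], active[b]))
        d <- D[active[a], active[b]]
        if (is.null(best) || d < best$d - 1e-12 ||
            (abs(d - best$d) <= 1e-12 &&
             (pair[1L] < best$pair[1L] ||
              (pair[1L] == best$pair[1L] && pair[2L] < best$pair[2L])))) {
          best <- list(d = d, pair = pair)
        }
      }
    }
    new_id <- sprintf("node%d", step)
    merges[[step]] <- data.frame(left = best$pair[1L], right = best$pair[2L],
                                 new_id = new_id, height = best$d,
                                 stringsAsFactors = FALSE)
    rest <- setdiff(active, best$pair)
    newrow <- if (length(rest))
      pmax(D[best$pair[1L], rest], D[best$pair[2L], rest]) else numeric(0L)
    D <- rbind(cbind(D, 0), 0)
    rownames(D)[nrow(D)] <- colnames(D)[ncol(D)] <- new_id
    if (length(rest)) {
      D[new_id, rest] <- newrow
      D[rest, new_id] <- newrow
    }
    active <- c(rest, new_id)
  }
  structure(list(merge_order = do.call(rbind, merges), leaf_ids = ids),
            class = "GuideTree")
}

#' @export
print.GuideTree <- function(x, ...) {
  cat(sprintf("<GuideTree: %d leaves>\n", length(x$leaf_ids)))
  print(x$merge_order)
  invisible(x)
}

#' Newick export of a guide tree
#'
#' Ultrametric branch lengths derived from the merge heights (each node sits
#' at half its merge distance).
#'
#' @param tree a `GuideTree`.
#' @return a Newick string (terminated by `;`).
#' @export
guide_tree_newick <- function(tree) {
  height <- stats::setNames(rep(0, length(tree$leaf_ids)), tree$leaf_ids)
  label <- stats::setNames(tree$leaf_ids, tree$leaf_ids)
  mo <- tree$merge_order
  for (r in seq_len(nrow(mo))) {
    h <- mo$height[r] / 2
    l <- mo$left[r]; rt <- mo$right[r]
    label[mo$new_id[r]] <- sprintf("(%s:%.6f,%s:%.6f)",
                                   label[l], max(h - height[l], 0),
                                   label[rt], max(h - height[rt], 0))
    height[mo$new_id[r]] <- h
  }
  paste0(label[mo$new_id[nrow(mo)]], ";")
}

# -- alignment nodes ----------------------------------------------------------

# A progressive-alignment node: a stack of aligned structures collapsed to
# averaged coordinates plus the consensus bookkeeping that feeds back into
# each pairwise step.
leaf_node <- function(structure, params) {
  n <- n_residues(structure)
  base::structure(list(
    coords = structure$ca_coords,
    sec = sec_chars(structure),
    counts = rep(1L, n),
    consensus = rep(params$consensus_weight, n),
    n_structures = 1L,
    members = stats::setNames(list(seq_len(n)), structure$id)
  ), class = "AlignmentNode")
}

#' @export
print.AlignmentNode <- function(x, ...) {
  cat(sprintf("<AlignmentNode: %d structures, %d columns>\n",
              x$n_structures, nrow(x$coords)))
  invisible(x)
}

#' Combine two progressive-alignment nodes
#'
#' The consensus feedback step: before alignment each node's consensus row is
#' multiplied by half the number of structures in the other node, and the
#' result is concatenated to the 3-D coordinates as a fourth component that
#' enters only the Gaussian coordinate score (the geometric superposition
#' steps always see plain 3-D points). Columns whose consensus values match
#' in both nodes contribute nothing to the score exponent and so keep
#' scoring highly, which protects well-aligned core columns from gap
#' insertion as progressive alignment proceeds.
#'
#' After alignment the new node carries: averaged coordinates at columns
#' aligned in both nodes (the present node's coordinates at gap columns),
#' the first node's secondary code where both are aligned (otherwise the
#' non-gap node's code), summed per-column residue counts, the stored
#' consensus `counts * cw`, and member rows extended with the new gaps.
#'
#' @param a,b `AlignmentNode`s.
#' @param params an [alignment_params()] object.
#' @return the combined `AlignmentNode`.
#' @export
combine_nodes <- function(a, b, params = alignment_params()) {
  cw <- params$consensus_weight
  wc_a <- a$consensus * (b$n_structures / 2)
  wc_b <- b$consensus * (a$n_structures / 2)
  res <- align_coords_core(a$coords, b$coords, a$sec, b$sec, params,
                           aug1 = wc_a, aug2 = wc_b)
  p <- res$alignment$pairs
  i <- p[, 1L]; j <- p[, 2L]
  a_t <- apply_transform(res$transform, a$coords)
  L <- nrow(p)
  coords <- matrix(NA_real_, L, 3L)
  both <- !is.na(i) & !is.na(j)
  only_a <- !is.na(i) & is.na(j)
  only_b <- is.na(i) & !is.na(j)
  coords[both, ] <- (a_t[i[both], , drop = FALSE] +
                       b$coords[j[both], , drop = FALSE]) / 2
  coords[only_a, ] <- a_t[i[only_a], , drop = FALSE]
  coords[only_b, ] <- b$coords[j[only_b], , drop = FALSE]
  sec <- character(L)
  sec[both | only_a] <- a$sec[i[both | only_a]]
  sec[only_b] <- b$sec[j[only_b]]
  counts <- ifelse(is.na(i), 0L, a$counts[ifelse(is.na(i), 1L, i)]) +
    ifelse(is.na(j), 0L, b$counts[ifelse(is.na(j), 1L, j)])
  members <- c(
    lapply(a$members, function(row) ifelse(is.na(i), NA_integer_, row[i])),
    lapply(b$members, function(row) ifelse(is.na(j), NA_integer_, row[j]))
  )
  base::structure(list(
    coords = coords, sec = sec, counts = as.integer(counts),
    consensus = counts * cw,
    n_structures = a$n_structures + b$n_structures,
    members = members, score = res$score, strategy = res$strategy
  ), class = "AlignmentNode")
}

# -- multiple alignment -------------------------------------------------------

new_multiple_alignment <- function(rows, column_count) {
  column_count <- as.integer(column_count)
  for (id in names(rows)) {
    row <- rows[[id]]
    if (length(row) != column_count) stop("ragged row for '", id, "'")
    idx <- row[!is.na(row)]
    if (length(idx) && (any(diff(idx) <= 0L) ||
                        !identical(as.integer(idx), seq_along(idx))))
      stop("row for '", id, "' is not a complete increasing index sequence")
  }
  base::structure(list(rows = rows, column_count = column_count),
                  class = "MultipleAlignment")
}

#' @export
print.MultipleAlignment <- function(x, ...) {
  gp <- gapless_positions(x)
  cat(sprintf("<MultipleAlignment: %d structures, %d columns, %d gap-less>\n",
              length(x$rows), x$column_count, gp$count))
  invisible(x)
}

#' Progressive multiple structure alignment
#'
#' The full pipeline: all-vs-all pairwise alignment, guide-tree construction
#' from the length-normalized scores, and a fold of [combine_nodes()] over
#' the merge order. Gaps inserted into an intermediate node's columns are
#' propagated into every member row beneath it, so each structure's row of
#' the final alignment reads out its complete residue index sequence.
#'
#' @param structures list of two or more `ProteinStructure`s with unique ids.
#' @param params an [alignment_params()] object.
#' @return a `MultipleAlignment`: named per-structure rows of residue indices
#'   (`NA` = gap) over shared columns, with the guide tree and pairwise score
#'   table attached as attributes `tree` and `pairwise_scores`.
#' @export
multiple_align <- function(structures, params = alignment_params()) {
  if (length(structures) < 2L) stop("at least 2 structures are required")
  ids <- vapply(structures, `[[`, character(1L), "id")
  if (anyDuplicated(ids)) stop("structure ids must be unique")
  names(structures) <- ids

  k <- length(ids)
  scores <- matrix(1, k, k, dimnames = list(ids, ids))
  for (a in seq_len(k - 1L)) {
    for (b in (a + 1L):k) {
      pw <- tryCatch(
        pairwise_align(structures[[a]], structures[[b]], params),
        error = function(e) stop("pairwise alignment of '", ids[a], "' and '",
                                 ids[b], "' failed: ", conditionMessage(e))
      )
      scores[a, b] <- scores[b, a] <- tree_score(pw)
    }
  }

  tree <- build_guide_tree(scores)
  nodes <- new.env(parent = emptyenv())
  for (id in ids) assign(id, leaf_node(structures[[id]], params), envir = nodes)
  mo <- tree$merge_order
  for (r in seq_len(nrow(mo))) {
    merged <- tryCatch(
      combine_nodes(get(mo$left[r], envir = nodes),
                    get(mo$right[r], envir = nodes), params),
      error = function(e) stop("progressive merge of '", mo$left[r],
                               "' and '", mo$right[r], "' failed: ",
                               conditionMessage(e))
    )
    assign(mo$new_id[r], merged, envir = nodes)
  }
  root <- get(mo$new_id[nrow(mo)], envir = nodes)
  msa <- new_multiple_alignment(root$members[ids], nrow(root$coords))
  attr(msa, "tree") <- tree
  attr(msa, "pairwise_scores") <- scores
  attr(msa, "root_node") <- root
  msa
}
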