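#' Read a protein chain from a PDB file
#'
#' Parses a PDB file (first model only), selects one chain and optionally an
#' inclusive author-numbering residue range, and reduces it to the
#' per-residue representation used throughout the package. Residues lacking
#' an alpha carbon are dropped; alternate locations are resolved to the
#' highest-occupancy copy (ties: first encountered); insertion-coded residues
#' are kept in file order. Secondary structure is assigned internally from
#' backbone hydrogen-bond geometry unless precomputed codes are supplied.
#'
#' @param path path to a PDB file.
#' @param chain one-letter chain identifier; default: the first chain in the
#'   file.
#' @param start,end optional inclusive residue-number (PDB `resSeq`) range.
#' @param id structure identifier; defaults to the file base name.
#' @param sec_codes optional precomputed secondary-structure string (e.g.
#'   externally computed DSSP codes collapsed to H/E/C); length must match
#'   the number of residues kept.
#' @return a [protein_structure()].
#' @export
read_pdb <- function(path, chain = NULL, start = NULL, end = NULL,
                     id = NULL, sec_codes = NULL) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in ", path)
  if (is.null(chain)) chain <- at$chain[1L]
  if (!chain %in% at$chain) stop("chain '", chain, "' not found in ", path)
  at <- at[at$chain == chain, , drop = FALSE]
  if (!is.null(start)) at <- at[at$resno >= start, , drop = FALSE]
  if (!is.null(end)) at <- at[at$resno <= end, , drop = FALSE]
  if (nrow(at) == 0L) stop("empty selection: no residues left after filtering")

  # resolve altlocs: keep the highest-occupancy copy of each atom (ties:
  # first encountered), then restore file order
  at$alt[is.na(at$alt)] <- ""
  file_ord <- seq_len(nrow(at))
  key <- paste(at$resno, at$insert, at$elety, sep = "|")
  occ <- at$o
  occ[is.na(occ)] <- 1
  ord <- order(key, -occ, file_ord)
  keep <- ord[!duplicated(key[ord])]
  at <- at[sort(keep), , drop = FALSE]

  res_key <- paste(at$resno, at$insert, sep = "|")
  res_ids <- unique(res_key)
  get_atom <- function(rk, name) {
    row <- at[res_key == rk & at$elety == name, , drop = FALSE]
    if (nrow(row) == 0L) rep(NA_real_, 3L)
    else c(row$x[1L], row$y[1L], row$z[1L])
  }
  ca <- t(vapply(res_ids, get_atom, numeric(3L), name = "CA"))
  has_ca <- stats::complete.cases(ca)
  res_ids <- res_ids[has_ca]
  if (length(res_ids) == 0L) stop("empty selection: no residues with a CA atom")
  ca <- ca[has_ca, , drop = FALSE]
  nn <- t(vapply(res_ids, get_atom, numeric(3L), name = "N"))
  cc <- t(vapply(res_ids, get_atom, numeric(3L), name = "C"))
  oo <- t(vapply(res_ids, get_atom, numeric(3L), name = "O"))
  cb <- t(vapply(res_ids, get_atom, numeric(3L), name = "CB"))
  miss_cb <- !stats::complete.cases(cb)
  cb[miss_cb, ] <- ca[miss_cb, , drop = FALSE]
  dimnames(ca) <- dimnames(nn) <- dimnames(cc) <- dimnames(oo) <-
    dimnames(cb) <- NULL
  resid3 <- vapply(res_ids, function(rk) at$resid[res_key == rk][1L],
                   character(1L))
  seq1 <- bio3d::aa321(resid3)
  seq1[is.na(seq1) | seq1 == ""] <- "X"

  protein_structure(
    id = id %||% sub("\\.(pdb|ent)$", "", basename(path), ignore.case = TRUE),
    chain = chain, sequence = paste(seq1, collapse = ""),
    ca_coords = ca, cb_coords = cb,
    backbone = list(n = nn, ca = ca, c = cc, o = oo),
    sec_codes = sec_codes
  )
}

#' Write a structure to a PDB file
#'
#' Writes N/CA/C/O/CB ATOM records (CB omitted for glycine, O omitted when
#' absent) with sequential numbering. Coordinates keep the standard 3-decimal
#' PDB precision.
#'
#' @param structure a `ProteinStructure`.
#' @param path output file path.
#' @export
write_pdb <- function(structure, path) {
  seq_chars <- strsplit(structure$sequence, "")[[1L]]
  res3 <- bio3d::aa123(seq_chars)
  res3[is.na(res3)] <- "UNK"
  lines <- character(0L)
  serial <- 0L
  emit <- function(name, elem, res_i, xyz) {
    serial <<- serial + 1L
    sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial, paste0(" ", formatC(name, width = -3)), res3[res_i],
            structure$chain, res_i, xyz[1L], xyz[2L], xyz[3L], 1, 0, elem)
  }
  bb <- structure$backbone
  for (i in seq_len(n_residues(structure))) {
    if (all(is.finite(bb$n[i, ]))) lines <- c(lines, emit("N", "N", i, bb$n[i, ]))
    lines <- c(lines, emit("CA", "C", i, structure$ca_coords[i, ]))
    if (all(is.finite(bb$c[i, ]))) lines <- c(lines, emit("C", "C", i, bb$c[i, ]))
    if (all(is.finite(bb$o[i, ]))) lines <- c(lines, emit("O", "O", i, bb$o[i, ]))
    if (seq_chars[i] != "G" &&
        any(structure$cb_coords[i, ] != structure$ca_coords[i, ]))
      lines <- c(lines, emit("CB", "C", i, structure$cb_coords[i, ]))
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}
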