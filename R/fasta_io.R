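#' Write a multiple alignment as aligned FASTA
#'
#' One record per structure, record ids equal to structure ids, `-` at gap
#' columns. Round-trips through [read_fasta_alignment()].
#'
#' @param msa a `MultipleAlignment`.
#' @param structures list of `ProteinStructure`s providing the sequences;
#'   must contain every id in the alignment.
#' @param path output file path.
#' @export
write_fasta_alignment <- function(msa, structures, path) {
  stopifnot(inherits(msa, "MultipleAlignment"))
  if (length(msa$rows) == 0L) stop("empty alignment")
  seqs <- gapped_sequences(msa, structures)
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Gapped sequence strings of an alignment
#'
#' @inheritParams write_fasta_alignment
#' @return named character vector of equal-length gapped sequences.
#' @export
gapped_sequences <- function(msa, structures) {
  names(structures) <- vapply(structures, `[[`, character(1L), "id")
  vapply(names(msa$rows), function(id) {
    st <- structures[[id]]
    if (is.null(st)) stop("no structure with id '", id, "'")
    chars <- strsplit(st$sequence, "")[[1L]]
    row <- msa$rows[[id]]
    if (length(row) != msa$column_count) stop("ragged alignment row: ", id)
    paste(ifelse(is.na(row), "-", chars[row]), collapse = "")
  }, character(1L))
}

#' Read an aligned FASTA file
#'
#' @param path path to an aligned FASTA file.
#' @return named character vector of gapped sequences (all the same length).
#' @export
read_fasta_alignment <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no records in ", path)
  w <- Biostrings::width(set)
  if (length(unique(w)) != 1L)
    stop("ragged alignment: records have differing lengths")
  stats::setNames(as.character(set), names(set))
}

#' Build a MultipleAlignment from gapped sequences
#'
#' Residue indices are recovered from the order of non-gap characters, so any
#' aligner's aligned-FASTA output (e.g. a curated reference alignment) can be
#' scored with the package's quality metrics.
#'
#' @param gapped named character vector of equal-length gapped sequences.
#' @return a `MultipleAlignment`.
#' @export
msa_from_gapped <- function(gapped) {
  if (length(gapped) == 0L) stop("empty alignment")
  w <- unique(nchar(gapped))
  if (length(w) != 1L) stop("ragged alignment rows")
  rows <- lapply(gapped, function(s) {
    chars <- strsplit(s, "")[[1L]]
    idx <- rep(NA_integer_, length(chars))
    idx[chars != "-"] <- seq_len(sum(chars != "-"))
    idx
  })
  new_multiple_alignment(rows, w)
}
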