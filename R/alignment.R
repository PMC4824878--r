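#' Aligned sequence set
#'
#' A light container for an alignment over `{A,C,G,T,-,N}` plus IUPAC
#' ambiguity codes: named character vector of equal-length strings. Used for
#' the mtDNA control-region fragment (~406 bp) and the microsatellite
#' flanking-region fragment (~190 bp). Gap runs are allowed (the flanking
#' alignment carries a 10 bp indel); `N` counts as missing.
#'
#' @param sequences named character vector of sequences.
#' @param marker `"CR"` or `"flanking"` (free-form allowed).
#' @return object of class `seq_alignment`.
#' @export
seq_alignment <- function(sequences, marker = NA_character_) {
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("sequences must have unique names")
  sequences <- stats::setNames(toupper(as.character(sequences)), names(sequences))
  len <- unique(nchar(sequences))
  if (length(len) != 1)
    stop("unequal sequence lengths: input is not an alignment")
  structure(list(sequences = sequences, length = len, marker = marker),
            class = "seq_alignment")
}

#' @export
print.seq_alignment <- function(x, ...) {
  cat(sprintf("<seq_alignment> %d records x %d positions (marker: %s)\n",
              length(x$sequences), x$length, x$marker))
  invisible(x)
}

#' @export
length.seq_alignment <- function(x) length(x$sequences)

#' Alignment as a character matrix (records x positions)
#' @param aln a [seq_alignment()].
#' @return character matrix with rownames = record IDs.
#' @export
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$sequences, ""))
  rownames(m) <- names(aln$sequences)
  m
}

#' Read an aligned FASTA file
#'
#' Thin wrapper over [Biostrings::readBStringSet()] that enforces unique IDs
#' and equal lengths (the downstream operations are alignment-based).
#'
#' @param path file path.
#' @param marker stored marker tag.
#' @return a [seq_alignment()].
#' @export
read_fasta <- function(path, marker = NA_character_) {
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) stop("duplicate record IDs in FASTA")
  seqs <- stats::setNames(as.character(ss), ids)
  seq_alignment(seqs, marker = marker)
}

#' Write an alignment as FASTA (60-column wrap)
#'
#' @param aln a [seq_alignment()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(aln, path) {
  ss <- Biostrings::BStringSet(aln$sequences)
  Biostrings::writeXStringSet(ss, path, width = 60)
  invisible(path)
}

#' Subset an alignment by record ID
#' @param aln a [seq_alignment()].
#' @param ids record names to keep (order respected).
#' @return a [seq_alignment()].
#' @export
subset_alignment <- function(aln, ids) {
  miss <- setdiff(ids, names(aln$sequences))
  if (length(miss)) stop("unknown record ID(s): ", paste(miss, collapse = ", "))
  seq_alignment(aln$sequences[ids], marker = aln$marker)
}
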