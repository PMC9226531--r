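#' FASTA and genome-index helpers
#'
#' Thin wrappers over \pkg{Biostrings} for sequence I/O, plus a reader for
#' \code{.fai}-style genome index files (used for genome lengths).
#'
#' @param path File path.
#' @return \code{read_fasta()}: named character vector of sequences;
#'   \code{read_genome_index()}: named numeric vector of sequence lengths.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  out <- as.character(set)
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' @rdname read_fasta
#' @export
read_genome_index <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  stats::setNames(as.numeric(raw[[2L]]), as.character(raw[[1L]]))
}
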