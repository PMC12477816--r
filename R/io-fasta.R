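#' Read a FASTA file
#'
#' Sequences are returned as a [Biostrings::DNAStringSet]; names are the full
#' FASTA identifiers (first whitespace-delimited token plus description).
#'
#' @param path Path to a FASTA file.
#' @return A `DNAStringSet`.
#' @export
read_fasta <- function(path) {
  Biostrings::readDNAStringSet(path, format = "fasta")
}

#' Write sequences to FASTA
#'
#' @param seqs A `DNAStringSet`, or a named character vector of sequences.
#' @param path Output path.
#' @param width Line width used when wrapping sequence lines.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  if (is.character(seqs)) {
    seqs <- Biostrings::DNAStringSet(seqs)
  }
  Biostrings::writeXStringSet(seqs, filepath = path, format = "fasta", width = width)
  invisible(path)
}

#' Chromosome lengths of a genome
#'
#' @param genome A `DNAStringSet` (e.g. from [read_fasta()]).
#' @return Named integer vector of sequence lengths.
#' @export
chrom_lengths <- function(genome) {
  stats::setNames(BiocGenerics::width(genome), names(genome))
}

#' Write a table as TSV with provenance header comments
#'
#' @param table A data.frame.
#' @param path Output path.
#' @param comments Optional character vector written as leading `#` lines
#'   (used to echo analysis parameters into every output).
#' @return Invisibly, `path`.
#' @export
write_tsv <- function(table, path, comments = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(comments)) {
    writeLines(paste0("# ", comments), con)
  }
  utils::write.table(table, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()] (leading `#` comments skipped)
#'
#' @param path Input path.
#' @return A data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
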