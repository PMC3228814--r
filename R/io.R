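#' Read a FASTA file as a named character vector
#'
#' Thin wrapper over Biostrings' FASTA reader: IDs are taken up to the
#' first whitespace, sequences are uppercased except the lowercase "n" pad
#' symbol, and an empty file yields an empty vector with a warning.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) {
    warning("empty FASTA file: ", path)
    return(setNames(character(0), character(0)))
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e)))
  seqs <- as.character(set)
  if (any(!nzchar(seqs))) stop("malformed FASTA in ", path,
                               ": record with empty sequence")
  ids <- sub("\\s.*$", "", names(set))
  # uppercase, preserving "n" pads
  seqs <- chartr("acgt", "ACGT", seqs)
  setNames(unname(seqs), ids)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line-wrap width (default 70).
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Write a table as TSV
#'
#' @param table Data frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_tsv <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#'
#' @param path Input path.
#' @return Data frame.
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
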