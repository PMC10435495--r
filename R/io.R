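# Readers and writers for the plain-text interchange formats: TSV tables
# with a header row, one-identifier-per-line gene sets, FASTA via
# Biostrings, and JSON truth records.

#' Read a gene set
#'
#' Accepts either a one-identifier-per-line text file or a two-column TSV
#' (`set_label`, `gene`); the two-column form returns a named list of sets.
#'
#' @param path File path.
#' @return Character vector, or a named list of character vectors for the
#'   two-column form.
#' @export
read_gene_set <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) {
    d <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("set_label", "gene"),
                           stringsAsFactors = FALSE)
    return(lapply(split(d$gene, d$set_label), clean_ids))
  }
  clean_ids(readLines(path))
}

#' Write a gene set (one identifier per line)
#' @param genes Character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_set <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}

#' Read a differential-expression table
#'
#' TSV with header columns `gene`, `log2fc`, `fdr` ('.' decimal separator).
#'
#' @param path File path.
#' @return Data.frame with those three columns.
#' @export
read_de_table <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  names(d) <- tolower(names(d))
  req <- c("gene", "log2fc", "fdr")
  if (!all(req %in% names(d)))
    stop_invalid("DE table %s must have columns %s", path,
                 paste(req, collapse = ", "))
  d[, req]
}

#' Write a TSV table (header row, no quoting, '.' decimal)
#' @param x Data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV table written by [write_tsv()]
#' @param path File path.
#' @return Data.frame.
#' @export
read_tsv <- function(path)
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)

#' Write named sequences as FASTA
#' @param seqs Named character vector or `DNAStringSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#' @param path File path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write a truth record (or any list) as JSON
#' @param truth List, typically the `truth` element of a generator.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}
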