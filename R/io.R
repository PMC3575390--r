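# Thin FASTQ/TSV wrappers. FASTQ goes through Biostrings; identifiers keep
# their description field, which is where the simulator stores truth labels.

#' Read amplicon reads from FASTQ
#'
#' @param path FASTQ file.
#' @return tibble with `id` (first token of the identifier line), `desc`
#'   (full identifier line) and `seq`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  desc <- names(x)
  tibble(id = sub("\\s.*$", "", desc), desc = desc, seq = as.character(x))
}

#' Write reads to FASTQ
#'
#' Qualities are constant (the pipeline's filters are length-based); truth or
#' annotation fields already present in `desc` are preserved.
#'
#' @param reads tibble with at least `id` and `seq`; an optional `desc`
#'   column replaces `id` as the identifier line.
#' @param path output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$desc %||% reads$id
  Biostrings::writeXStringSet(x, path, format = "fastq")
  invisible(path)
}

write_tsv_ <- function(x, path) {
  x <- as.data.frame(x)
  list_cols <- vapply(x, is.list, logical(1))
  x[list_cols] <- lapply(x[list_cols], function(col) {
    vapply(col, function(v) paste(unlist(v), collapse = ","), character(1))
  })
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_ <- function(path) {
  as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
}
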