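#' @importFrom rlang .data abort warn %||%
#' @import dplyr
#' @importFrom tibble tibble as_tibble
NULL

DNA_BASES <- c("A", "C", "G", "T")

# vectorised reverse complement of plain character sequences
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Hamming distance between each element of `x` and a single reference of the
# same length; positions compared one by one so mixed-case never sneaks in.
str_hamming <- function(x, ref) {
  k <- nchar(ref)
  d <- integer(length(x))
  for (i in seq_len(k)) {
    d <- d + (substr(x, i, i) != substr(ref, i, i))
  }
  d[nchar(x) != k] <- NA_integer_
  d
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# substitute `base` at 1-based position `pos` of `seq`
subst_base <- function(seq, pos, base) {
  substr(seq, pos, pos) <- base
  seq
}

# intervals are length-2 integer vectors c(start, end), 1-based inclusive
int_len <- function(iv) {
  if (is.null(iv) || iv[2] < iv[1]) 0L else as.integer(iv[2] - iv[1] + 1L)
}

int_intersect <- function(a, b) {
  s <- max(a[1], b[1])
  e <- min(a[2], b[2])
  if (s > e) NULL else c(s, e)
}

check_interval <- function(start, end, what = "interval") {
  if (any(start < 1L) || any(start > end)) {
    abort(sprintf("invalid %s: need 1 <= start <= end", what))
  }
  invisible(TRUE)
}

# translate a single in-frame codon via the standard genetic code
translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) NA_character_ else aa
}

# union-find used by the ambiguity engines
uf_new <- function(n) seq_len(n)

uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i)
  rj <- uf_find(parent, j)
  if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  parent
}

uf_classes <- function(parent) {
  vapply(seq_along(parent), function(i) uf_find(parent, i), integer(1))
}
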