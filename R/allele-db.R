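#' Build a reference allele database
#'
#' A reference database is a tibble with one row per allele: the parsed name,
#' the nucleotide sequence actually deposited for that allele, and the
#' interval of the consensus open reading frame the sequence covers (its
#' "known" interval, 1-based inclusive). Alleles deposited only over part of
#' the ORF — the exon-2/3-only class I and exon-2-only DRB records that
#' dominate real repositories — simply carry a proper sub-interval.
#'
#' @param name character vector of allele names (see [parse_allele_name()]).
#' @param seq nucleotide sequences over `A,C,G,T`; `nchar(seq)` must equal the
#'   known-interval length. Gaps and ambiguity codes are rejected: the
#'   100%-identity matching contract is only defined over concrete bases.
#' @param known_start,known_end known interval in consensus coordinates.
#' @param consensus_length declared length of the consensus frame; defaults to
#'   `max(known_end)`.
#' @return a tibble of class `csbt_db` with columns `name`, `locus`,
#'   `fields`, `suffix`, `seq`, `known_start`, `known_end`.
#' @export
allele_db <- function(name, seq, known_start, known_end,
                      consensus_length = max(known_end)) {
  if (anyDuplicated(name)) {
    abort(sprintf("duplicate allele names: %s",
                  paste(unique(name[duplicated(name)]), collapse = ", ")))
  }
  check_interval(known_start, known_end, "known interval")
  seq <- toupper(seq)
  bad <- grepl("[^ACGT]", seq)
  if (any(bad)) {
    abort(sprintf("allele %s: sequence contains gaps or ambiguity codes",
                  name[which(bad)[1]]))
  }
  len_ok <- nchar(seq) == (known_end - known_start + 1L)
  if (!all(len_ok)) {
    abort(sprintf(
      "allele %s: sequence length %d does not match known interval %d-%d",
      name[!len_ok][1], nchar(seq[!len_ok][1]),
      known_start[!len_ok][1], known_end[!len_ok][1]))
  }
  if (any(known_end > consensus_length)) {
    abort("known interval extends past the declared consensus range")
  }
  parsed <- parse_allele_name(name)
  db <- tibble(
    name = parsed$text, locus = parsed$locus, fields = parsed$fields,
    suffix = parsed$suffix, seq = seq,
    known_start = as.integer(known_start), known_end = as.integer(known_end)
  ) |>
    arrange(.data$locus, .data$name)
  attr(db, "consensus_length") <- as.integer(consensus_length)
  class(db) <- c("csbt_db", class(db))
  db
}

#' Load a reference allele database from FASTA
#'
#' Headers are `NAME known=START-END`; alternatively a sidecar TSV with
#' columns `name`, `start`, `end` supplies the known intervals. A record with
#' neither is assumed full-length over `1..nchar(seq)`.
#'
#' @param path FASTA file of allele sequences.
#' @param coords optional sidecar TSV path or a data frame with columns
#'   `name`, `start`, `end`.
#' @param consensus_length optional declared consensus length.
#' @return a `csbt_db` tibble; loading is order-independent (records are
#'   sorted by locus and name).
#' @export
load_allele_fasta <- function(path, coords = NULL, consensus_length = NULL) {
  x <- Biostrings::readDNAStringSet(path)
  headers <- names(x)
  seqs <- unname(as.character(x))
  name <- sub("\\s.*$", "", headers)
  ks <- rep(NA_integer_, length(x))
  ke <- rep(NA_integer_, length(x))
  m <- regmatches(headers, regexec("known=([0-9]+)-([0-9]+)", headers))
  has <- lengths(m) == 3
  ks[has] <- as.integer(vapply(m[has], `[`, character(1), 2))
  ke[has] <- as.integer(vapply(m[has], `[`, character(1), 3))
  if (!is.null(coords)) {
    side <- if (is.character(coords)) {
      utils::read.delim(coords, stringsAsFactors = FALSE)
    } else {
      as.data.frame(coords)
    }
    idx <- match(name, side$name)
    take <- !is.na(idx) & is.na(ks)
    ks[take] <- as.integer(side$start[idx[take]])
    ke[take] <- as.integer(side$end[idx[take]])
  }
  full <- is.na(ks)
  ks[full] <- 1L
  ke[full] <- nchar(seqs)[full]
  allele_db(name, seqs, ks, ke,
            consensus_length = consensus_length %||% max(ke))
}

#' Write a reference database to FASTA
#'
#' Known intervals are carried in the headers as `known=START-END`, the same
#' convention [load_allele_fasta()] reads.
#'
#' @param db a `csbt_db` tibble.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_allele_fasta <- function(db, path) {
  x <- Biostrings::DNAStringSet(db$seq)
  names(x) <- sprintf("%s known=%d-%d", db$name, db$known_start, db$known_end)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Restrict every allele to a consensus-coordinate region
#'
#' For each allele, returns the subsequence over the intersection of `region`
#' with the allele's known interval — the primitive behind in-silico
#' resolution analysis and expected match-matrix computation. An allele whose
#' known interval misses the region entirely yields an empty subsequence and
#' is flagged.
#'
#' @param db a `csbt_db` tibble.
#' @param start,end the region, 1-based inclusive consensus coordinates.
#' @return tibble with `name`, `locus`, `start`, `end` (the intersection, NA
#'   when empty), `seq` (possibly empty string) and `empty` flag.
#' @export
restrict_to_interval <- function(db, start, end) {
  check_interval(start, end, "region")
  s <- pmax(db$known_start, start)
  e <- pmin(db$known_end, end)
  empty <- s > e
  sub <- ifelse(empty, "",
                substr(db$seq, s - db$known_start + 1L, e - db$known_start + 1L))
  tibble(
    name = db$name, locus = db$locus,
    start = ifelse(empty, NA_integer_, as.integer(s)),
    end = ifelse(empty, NA_integer_, as.integer(e)),
    seq = sub, empty = empty
  )
}

#' @export
print.csbt_db <- function(x, ...) {
  cat(sprintf("<csbt_db> %d alleles, %d loci, consensus length %d\n",
              nrow(x), dplyr::n_distinct(x$locus),
              attr(x, "consensus_length")))
  NextMethod()
}

# subset a db keeping class/attributes
db_subset <- function(db, keep) {
  out <- db[keep, , drop = FALSE]
  attr(out, "consensus_length") <- attr(db, "consensus_length")
  class(out) <- class(db)
  out
}
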