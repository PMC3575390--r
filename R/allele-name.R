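#' Parse HLA-style allele names
#'
#' Allele names follow the WHO nomenclature `LOCUS*ff:ff[:ff[:ff]][suffix]`:
#' a locus symbol, then one to four colon-separated numeric name fields
#' (serological group, protein, synonymous coding change, non-coding change),
#' optionally followed by a single expression-suffix letter such as `N`.
#' Resolution in "digits" is twice the number of name fields, so `C*08:56`
#' is a four-digit (high-resolution, protein-level) name and
#' `B*18:01:01:01` an eight-digit one.
#'
#' @param text character vector of allele names.
#' @return A tibble with one row per name: `text` (canonical rendering),
#'   `locus`, `fields` (list-column of integer vectors), `suffix`
#'   (`NA` when absent) and `resolution` (digits).
#' @examples
#' parse_allele_name(c("C*08:56", "B*18:01:01:01", "C*04:09N"))
#' @export
parse_allele_name <- function(text) {
  if (length(text) == 0) {
    return(tibble(text = character(), locus = character(),
                  fields = list(), suffix = character(),
                  resolution = integer()))
  }
  if (any(is.na(text) | !nzchar(text))) {
    abort("allele names must be non-empty strings")
  }
  parts <- purrr::map(text, parse_one_name)
  tibble(
    text = vapply(parts, `[[`, character(1), "text"),
    locus = vapply(parts, `[[`, character(1), "locus"),
    fields = purrr::map(parts, "fields"),
    suffix = vapply(parts, `[[`, character(1), "suffix"),
    resolution = vapply(parts, `[[`, integer(1), "resolution")
  )
}

parse_one_name <- function(x) {
  x <- gsub(" ", "", x, fixed = TRUE)
  star <- regexpr("*", x, fixed = TRUE)
  if (star < 0) {
    abort(sprintf("malformed allele name '%s': missing '*'", x))
  }
  locus <- substr(x, 1, star - 1)
  rest <- substr(x, star + 1, nchar(x))
  if (!nzchar(locus) || !nzchar(rest)) {
    abort(sprintf("malformed allele name '%s'", x))
  }
  suffix <- NA_character_
  if (grepl("[A-Za-z]$", rest)) {
    suffix <- toupper(substr(rest, nchar(rest), nchar(rest)))
    rest <- substr(rest, 1, nchar(rest) - 1)
  }
  toks <- strsplit(rest, ":", fixed = TRUE)[[1]]
  if (length(toks) < 1 || length(toks) > 4) {
    abort(sprintf("allele name '%s' must have 1-4 name fields", x))
  }
  bad <- toks[!grepl("^[0-9]+$", toks)]
  if (length(bad)) {
    abort(sprintf("allele name '%s': non-numeric field '%s'", x, bad[1]))
  }
  fields <- as.integer(toks)
  list(text = render_allele_name(locus, fields, suffix),
       locus = locus, fields = fields, suffix = suffix,
       resolution = 2L * length(fields))
}

#' Render an allele name from its parts
#'
#' Inverse of [parse_allele_name()]: fields are zero-padded to two digits and
#' colon-joined, and the optional expression suffix is appended.
#'
#' @param locus locus symbol, e.g. `"C"` or `"DRB1"`.
#' @param fields integer vector of 1-4 name fields.
#' @param suffix single expression letter or `NA`.
#' @return canonical allele-name string.
#' @export
render_allele_name <- function(locus, fields, suffix = NA_character_) {
  body <- paste(sprintf("%02d", as.integer(fields)), collapse = ":")
  out <- paste0(locus, "*", body)
  if (!is.na(suffix) && nzchar(suffix)) out <- paste0(out, suffix)
  out
}

# truncate a parsed-name tibble to the given resolution; used when deciding
# whether ambiguity-group members are name-distinct at 4 or 6 digits
name_at_resolution <- function(names, digits, ignore_suffix = FALSE) {
  p <- parse_allele_name(names)
  k <- digits %/% 2L
  out <- purrr::pmap_chr(list(p$locus, p$fields, p$suffix), function(l, f, s) {
    f <- f[seq_len(min(k, length(f)))]
    render_allele_name(l, f, if (ignore_suffix) NA_character_ else s)
  })
  out
}
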