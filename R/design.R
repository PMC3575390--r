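#' Per-position variability profile of an aligned allele set
#'
#' Computes, for every alignment column, the depth of coverage (number of
#' alleles with a non-gap base) and the percentage of covering alleles whose
#' base differs from the modal base — the profile used to locate conserved
#' primer-binding regions in highly polymorphic gene families. Modal-base
#' ties are broken lexicographically.
#'
#' @param aligned character vector (optionally named) of equal-length aligned
#'   sequences; `-` and `.` are gaps.
#' @return tibble of class `csbt_profile` with columns `position`, `depth`,
#'   `variability` (percent, 0-100) and `consensus` (modal base, `NA` at
#'   depth-0 columns); attribute `n_alleles`.
#' @export
variability_profile <- function(aligned) {
  if (length(aligned) == 0) abort("no sequences supplied")
  aligned <- toupper(aligned)
  lens <- nchar(aligned)
  if (length(unique(lens)) != 1) {
    abort("ragged alignment: sequences differ in length")
  }
  mat <- matrix(unlist(strsplit(aligned, "", fixed = TRUE)),
                nrow = length(aligned), byrow = TRUE)
  mat[mat %in% c("-", ".")] <- NA_character_
  ncol_ <- ncol(mat)
  depth <- integer(ncol_)
  modal <- character(ncol_)
  varia <- numeric(ncol_)
  for (j in seq_len(ncol_)) {
    col <- mat[, j]
    col <- col[!is.na(col)]
    depth[j] <- length(col)
    if (depth[j] == 0) {
      modal[j] <- NA_character_
      varia[j] <- 0
      next
    }
    tab <- table(col)
    best <- sort(names(tab)[tab == max(tab)])[1]
    modal[j] <- best
    varia[j] <- 100 * sum(col != best) / depth[j]
  }
  out <- tibble(position = seq_len(ncol_), depth = depth,
                variability = varia, consensus = modal)
  attr(out, "n_alleles") <- length(aligned)
  class(out) <- c("csbt_profile", class(out))
  out
}

#' Find conserved windows in a variability profile
#'
#' Returns the maximal runs of alignment columns, at least `window_len` long,
#' in which every column is conserved (variability at or below
#' `max_variability`) and covered deeply enough (`depth >=
#' min_depth_fraction * n_alleles`) — candidate pan-locus primer sites.
#'
#' @param profile a `csbt_profile`.
#' @param window_len minimum window length in nt (default 18, a typical
#'   gene-specific primer length).
#' @param max_variability maximum per-column variability in percent
#'   (default 1).
#' @param min_depth_fraction minimum depth as a fraction of the allele count
#'   (default 0.5).
#' @param n_alleles allele count; taken from the profile attribute when
#'   omitted.
#' @return tibble with `start`, `end`, `length`, sorted by `start`.
#' @export
find_conserved_windows <- function(profile, window_len = 18L,
                                   max_variability = 1,
                                   min_depth_fraction = 0.5,
                                   n_alleles = attr(profile, "n_alleles")) {
  stopifnot(window_len >= 1)
  ok <- profile$variability <= max_variability &
    profile$depth >= min_depth_fraction * n_alleles
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= window_len
  tibble(start = profile$position[starts[keep]],
         end = profile$position[ends[keep]]) |>
    mutate(length = .data$end - .data$start + 1L) |>
    arrange(.data$start)
}

#' Define a genotyping amplicon
#'
#' An amplicon is a pair of primer sites on the consensus frame plus the
#' insert they delimit (`fwd.start .. rev.end`, so a forward primer at 61-79
#' and a reverse primer at 707-727 delimit a 667 nt insert). The final
#' sequencing-library product adds fixed fusion overhead at each end
#' (platform adapter plus MID barcode; default 25 + 10 = 35 nt per end).
#'
#' @param name amplicon name, e.g. `"HLA-1"`.
#' @param fwd_interval,rev_interval length-2 vectors `c(start, end)` of the
#'   primer sites in consensus coordinates; they must not overlap.
#' @param aligned optional named vector of aligned sequences on the same
#'   frame, used to derive the primer-site consensus sequence and per-allele
#'   primer mismatch counts.
#' @param fwd_seq,rev_seq optional explicit primer-site consensus sequences
#'   (used when no alignment is supplied, e.g. in config-driven runs).
#' @param adapter_overhead fusion overhead per end in nt (adapter + MID).
#' @param group_fwd,group_rev read-group labels for the two read directions
#'   (e.g. `"2F"`, `"2R"`).
#' @param locus_class `"I"` or `"II"`; decides which match-matrix join the
#'   genotyper applies downstream.
#' @param loci loci this amplicon amplifies (used to pick reference subsets).
#' @return an object of class `csbt_amplicon`: a list with the primer sites
#'   (each `start`, `end`, `seq`, `per_allele_mismatches`), `insert`
#'   (`start`, `end`, `length`) and `product_length`.
#' @export
define_amplicon <- function(name, fwd_interval, rev_interval, aligned = NULL,
                            adapter_overhead = 35L,
                            group_fwd = paste0(name, "-F"),
                            group_rev = paste0(name, "-R"),
                            locus_class = c("I", "II"), loci = NULL,
                            fwd_seq = NULL, rev_seq = NULL) {
  locus_class <- match.arg(locus_class)
  check_interval(fwd_interval[1], fwd_interval[2], "forward primer interval")
  check_interval(rev_interval[1], rev_interval[2], "reverse primer interval")
  if (fwd_interval[2] >= rev_interval[1]) {
    abort("primer intervals overlap or are out of order")
  }
  site <- function(iv, given = NULL) {
    consensus <- given %||% NA_character_
    mism <- NULL
    if (!is.null(given) && nchar(given) != iv[2] - iv[1] + 1L) {
      abort("primer sequence length does not match its interval")
    }
    if (is.null(given) && !is.null(aligned)) {
      prof <- variability_profile(aligned)
      consensus <- paste(prof$consensus[iv[1]:iv[2]], collapse = "")
      sub <- substr(aligned, iv[1], iv[2])
      mm <- str_hamming(sub, consensus)
      mism <- tibble(name = names(aligned) %||% as.character(seq_along(aligned)),
                     mismatches = as.integer(mm))
    }
    list(start = as.integer(iv[1]), end = as.integer(iv[2]),
         seq = consensus, per_allele_mismatches = mism)
  }
  insert_len <- as.integer(rev_interval[2] - fwd_interval[1] + 1L)
  structure(list(
    name = name,
    fwd = site(fwd_interval, fwd_seq),
    rev = site(rev_interval, rev_seq),
    insert = list(start = as.integer(fwd_interval[1]),
                  end = as.integer(rev_interval[2]),
                  length = insert_len),
    adapter_overhead = as.integer(adapter_overhead),
    product_length = insert_len + 2L * as.integer(adapter_overhead),
    group_fwd = group_fwd, group_rev = group_rev,
    locus_class = locus_class, loci = loci
  ), class = "csbt_amplicon")
}

#' @export
print.csbt_amplicon <- function(x, ...) {
  cat(sprintf(
    "<csbt_amplicon> %s: insert %d-%d (%d nt), product %d nt, groups %s/%s\n",
    x$name, x$insert$start, x$insert$end, x$insert$length,
    x$product_length, x$group_fwd, x$group_rev))
  invisible(x)
}

#' Predict in-silico typing resolution over a coverage region
#'
#' Partitions each locus's alleles into classes indistinguishable over the
#' assayed coverage (sequences compared only where both alleles are known)
#' and reports the classes that contain two or more alleles with distinct
#' names at the requested resolution — the residual ambiguity a typing assay
#' with that coverage cannot resolve.
#'
#' Classes are built by transitive closure of the pairwise relation, since
#' with heterogeneous known intervals "identical where both known" is not
#' transitive. Allele pairs whose known intervals overlap the coverage by
#' fewer than `min_overlap` shared positions are declared incomparable and
#' never joined (a warning is emitted when this happens).
#'
#' @param db a `csbt_db`.
#' @param coverage a list of `c(start, end)` intervals (or a single such
#'   vector) describing the assayed region.
#' @param digits name resolution at which members must differ (4 or 6).
#' @param count_suffix_distinct should names differing only by an expression
#'   suffix (e.g. `N`) count as distinct? Default `TRUE`.
#' @param min_overlap minimum number of jointly known, covered positions for
#'   two alleles to be comparable (default 1).
#' @return tibble with `locus`, `group` (index within locus), `members`
#'   (slash-joined sorted names), `n_members`, deterministically ordered.
#' @export
in_silico_resolution <- function(db, coverage, digits = 4L,
                                 count_suffix_distinct = TRUE,
                                 min_overlap = 1L) {
  if (is.numeric(coverage)) coverage <- list(coverage)
  if (length(coverage) == 0) abort("coverage must be non-empty")
  out <- list()
  incomparable <- 0L
  for (loc in sort(unique(db$locus))) {
    sub <- db[db$locus == loc, , drop = FALSE]
    n <- nrow(sub)
    if (n < 2) next
    parent <- uf_new(n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        cmpr <- compare_over_coverage(sub[i, ], sub[j, ], coverage)
        if (cmpr$n_compared < min_overlap) {
          incomparable <- incomparable + 1L
          next
        }
        if (cmpr$identical) parent <- uf_union(parent, i, j)
      }
    }
    cls <- uf_classes(parent)
    for (cid in unique(cls)) {
      members <- sort(sub$name[cls == cid])
      if (length(members) < 2) next
      keys <- name_at_resolution(members, digits,
                                 ignore_suffix = !count_suffix_distinct)
      if (dplyr::n_distinct(keys) < 2) next
      n_mem <- length(members)
      out[[length(out) + 1L]] <- tibble(locus = loc,
                                        members = paste(members, collapse = "/"),
                                        n_members = n_mem)
    }
  }
  if (incomparable > 0) {
    warn(sprintf(
      "%d allele pair(s) had no jointly known covered positions and were treated as incomparable",
      incomparable))
  }
  if (length(out) == 0) {
    return(tibble(locus = character(), group = integer(),
                  members = character(), n_members = integer()))
  }
  bind_rows(out) |>
    arrange(.data$locus, .data$members) |>
    group_by(.data$locus) |>
    mutate(group = dplyr::row_number()) |>
    ungroup() |>
    select("locus", "group", "members", "n_members")
}

# compare two db rows over coverage intervals, only where both are known
compare_over_coverage <- function(a, b, coverage) {
  n_compared <- 0L
  same <- TRUE
  both <- int_intersect(c(a$known_start, a$known_end),
                        c(b$known_start, b$known_end))
  if (!is.null(both)) {
    for (iv in coverage) {
      ov <- int_intersect(both, c(iv[1], iv[2]))
      if (is.null(ov)) next
      n_compared <- n_compared + int_len(ov)
      sa <- substr(a$seq, ov[1] - a$known_start + 1L, ov[2] - a$known_start + 1L)
      sb <- substr(b$seq, ov[1] - b$known_start + 1L, ov[2] - b$known_start + 1L)
      if (sa != sb) same <- FALSE
    }
  }
  list(identical = same && n_compared > 0, n_compared = n_compared)
}
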