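#' Genotype-calling policy
#'
#' @param mode `"stringent"` (every expected read group needs
#'   `min_reads` supporting reads) or `"low_stringency"` (any number of
#'   allele-specific reads per group suffices; calls that would fail the
#'   stringent threshold are downgraded to `low_stringency` confidence).
#' @param min_reads stringent per-group read minimum (default 3).
#' @param anchor minimum perfect overlap for extension matches, in nt.
#' @param hom_fraction read-share threshold above which a single-allele locus
#'   is reported homozygous-consistent rather than flagged for review.
#' @param novel_min_cluster minimum identical-read cluster size for a novel
#'   candidate.
#' @param novel_max_snps maximum SNPs to the nearest reference for a novel
#'   candidate.
#' @return list of class `csbt_call_policy`.
#' @export
call_policy <- function(mode = c("stringent", "low_stringency"),
                        min_reads = 3L, anchor = 30L, hom_fraction = 0.8,
                        novel_min_cluster = 3L, novel_max_snps = 3L) {
  mode <- match.arg(mode)
  structure(list(mode = mode, min_reads = as.integer(min_reads),
                 anchor = as.integer(anchor), hom_fraction = hom_fraction,
                 novel_min_cluster = as.integer(novel_min_cluster),
                 novel_max_snps = as.integer(novel_max_snps)),
            class = "csbt_call_policy")
}

#' Call genotypes from a match matrix
#'
#' An allele is called when its observed condition row equals its expected
#' row and every non-`NONE` group carries at least `min_reads` supporting
#' reads (stringent) or at least one (low stringency, with confidence
#' downgraded). Called alleles that are indistinguishable over the assayed
#' region — the union of the read-group windows actually supported for that
#' sample, so dropout narrows rather than widens the claimed resolution —
#' are merged into an ambiguity set with slash-joined names. Alleles
#' supported by amplicon-1 evidence but absent from the key group are
#' reported with `amplicon_discordant` confidence; sample/locus combinations
#' with nothing to report are `not_detected`. More than two protein-distinct
#' calls at one locus raises a warning and flags the rows.
#'
#' @param matrix a `csbt_matrix` from [build_match_matrix_classI()] /
#'   [build_match_matrix_classII()].
#' @param db the `csbt_db` the matrix was mapped against (used for
#'   ambiguity merging).
#' @param windows read-group windows from [group_windows()].
#' @param policy a [call_policy()].
#' @param samples optional character vector of all samples expected (so
#'   samples with no matches still yield `not_detected` rows).
#' @param group_totals optional tibble `(sample, locus, group, total)` of all
#'   mapped read counts, used for the homozygosity read-share triage.
#' @return tibble of class `csbt_calls`: `sample`, `locus`, `call`
#'   (slash-joined allele names), `members` (list-column), `n_members`,
#'   `resolution` (digits), `confidence`, `support` (total reads),
#'   `min_group_reads`, `homozygous`, `flag_multi`.
#' @export
call_genotype <- function(matrix, db, windows, policy = call_policy(),
                          samples = NULL, group_totals = NULL) {
  expected <- attr(matrix, "expected")
  groups <- attr(matrix, "groups")
  minreq <- if (policy$mode == "stringent") policy$min_reads else 1L

  qual <- matrix |>
    left_join(expected, by = c("allele", "locus", "group")) |>
    group_by(.data$sample, .data$locus, .data$allele) |>
    summarise(
      row_match = all(.data$condition == .data$expected),
      min_reads_nonnone = ifelse(any(.data$expected != "NONE"),
                                 min(.data$reads[.data$expected != "NONE"]),
                                 0L),
      support = sum(.data$reads),
      .groups = "drop") |>
    mutate(called = .data$row_match & .data$min_reads_nonnone >= minreq,
           stringent_ok = .data$row_match &
             .data$min_reads_nonnone >= policy$min_reads)

  called <- qual |> filter(.data$called)

  calls <- list()
  for (key in unique(paste(called$sample, called$locus, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    smp <- parts[1]; loc <- parts[2]
    sub <- called |> filter(.data$sample == smp, .data$locus == loc)
    # windows with any read support for this sample/locus
    supp_groups <- matrix |>
      filter(.data$sample == smp, .data$locus == loc, .data$reads > 0) |>
      pull(.data$group) |>
      unique()
    cov <- windows |>
      filter(.data$group %in% supp_groups)
    cov_list <- purrr::map2(cov$start, cov$end, c)
    classes <- ambiguity_classes(db, sub$allele, cov_list)
    for (cl in classes) {
      mem <- sort(cl)
      msub <- sub[sub$allele %in% mem, ]
      calls[[length(calls) + 1L]] <- tibble(
        sample = smp, locus = loc,
        call = paste(mem, collapse = "/"),
        members = list(mem),
        n_members = length(mem),
        resolution = set_resolution(mem),
        confidence = if (any(msub$stringent_ok)) {
          if (length(mem) > 1) "ambiguous_set" else "unambiguous"
        } else "low_stringency",
        support = sum(msub$support),
        min_group_reads = min(msub$min_reads_nonnone)
      )
    }
  }
  calls <- bind_rows(calls)

  # key-amplicon dropout candidates not already inside a call
  disc <- attr(matrix, "discordant")
  if (!is.null(disc) && nrow(disc) > 0) {
    already <- if (nrow(calls) > 0) {
      calls |>
        select("sample", "members") |>
        tidyr::unnest_longer("members", values_to = "allele")
    } else {
      tibble(sample = character(), allele = character())
    }
    disc_rows <- disc |>
      anti_join(already, by = c("sample", "allele")) |>
      transmute(sample = .data$sample, locus = .data$locus,
                call = .data$allele, members = purrr::map(.data$allele, identity),
                n_members = 1L,
                resolution = parse_allele_name(.data$allele)$resolution,
                confidence = "amplicon_discordant",
                support = .data$reads, min_group_reads = 0L)
    calls <- bind_rows(calls, disc_rows)
  }

  # not-detected grid
  all_samples <- sort(unique(c(samples, matrix$sample)))
  all_loci <- sort(unique(expected$locus))
  grid <- tidyr::expand_grid(sample = all_samples, locus = all_loci)
  seen <- calls |> distinct(.data$sample, .data$locus)
  nd <- grid |>
    anti_join(seen, by = c("sample", "locus")) |>
    mutate(call = NA_character_, members = list(character(0)),
           n_members = 0L, resolution = NA_integer_,
           confidence = "not_detected", support = 0L, min_group_reads = 0L)
  calls <- bind_rows(calls, nd) |>
    arrange(.data$sample, .data$locus, .data$call)

  # >2 protein-distinct calls per classical locus: calls (not set members)
  # are counted, merging calls that share a 4-digit protein key
  calls <- calls |>
    group_by(.data$sample, .data$locus) |>
    mutate(flag_multi = protein_distinct_count(.data$members) > 2) |>
    ungroup()
  if (any(calls$flag_multi)) {
    bad <- calls |> filter(.data$flag_multi) |>
      distinct(.data$sample, .data$locus)
    warn(sprintf(">2 protein-distinct calls at: %s",
                 paste(paste(bad$sample, bad$locus), collapse = "; ")))
  }

  # homozygosity triage for single-call loci
  calls <- calls |>
    group_by(.data$sample, .data$locus) |>
    mutate(n_calls = sum(.data$confidence %in%
                           c("unambiguous", "ambiguous_set", "low_stringency"))) |>
    ungroup() |>
    mutate(homozygous = NA)
  if (!is.null(group_totals)) {
    hom_idx <- which(calls$n_calls == 1 &
                       calls$confidence %in%
                       c("unambiguous", "ambiguous_set", "low_stringency"))
    for (i in hom_idx) {
      first <- calls$members[[i]][1]
      rows <- matrix |>
        filter(.data$sample == calls$sample[i], .data$allele == first,
               .data$reads > 0)
      tot <- group_totals |>
        filter(.data$sample == calls$sample[i],
               .data$locus == calls$locus[i], .data$group %in% rows$group)
      share <- if (sum(tot$total) > 0) sum(rows$reads) / sum(tot$total) else 0
      calls$homozygous[i] <- share >= policy$hom_fraction
    }
  }
  calls <- calls |> select(-"n_calls")
  class(calls) <- c("csbt_calls", class(calls))
  calls
}

# partition alleles into classes indistinguishable over the given intervals
ambiguity_classes <- function(db, alleles, coverage) {
  idx <- match(alleles, db$name)
  n <- length(alleles)
  if (n == 0) return(list())
  if (n == 1 || length(coverage) == 0) return(as.list(alleles))
  parent <- uf_new(n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      cmpr <- compare_over_coverage(db[idx[i], ], db[idx[j], ], coverage)
      if (cmpr$identical) parent <- uf_union(parent, i, j)
    }
  }
  cls <- uf_classes(parent)
  lapply(unique(cls), function(cid) alleles[cls == cid])
}

# achieved name resolution of a call: the deepest field truncation at which
# all members agree
set_resolution <- function(members) {
  p <- parse_allele_name(members)
  maxd <- 2L * min(lengths(p$fields))
  for (d in seq(maxd, 2L, by = -2L)) {
    if (dplyr::n_distinct(name_at_resolution(members, d)) == 1) return(d)
  }
  0L
}

protein_distinct_count <- function(members_list) {
  keysets <- lapply(members_list, function(m) {
    m <- m[!is.na(m)]
    if (length(m) == 0) NULL else unique(name_at_resolution(m, 4L))
  })
  keysets <- keysets[!vapply(keysets, is.null, logical(1))]
  n <- length(keysets)
  if (n <= 1) return(n)
  parent <- uf_new(n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (length(intersect(keysets[[i]], keysets[[j]])) > 0) {
        parent <- uf_union(parent, i, j)
      }
    }
  }
  length(unique(uf_classes(parent)))
}
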