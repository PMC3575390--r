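#' Expected match-condition matrix
#'
#' Derived purely from interval geometry: for each allele and read group, the
#' group's genomic window is intersected with the allele's known interval.
#' Full containment gives an expected `FULL` ("1"); an overlap of at least
#' `anchor` nt with the window running past the known interval gives `EXTEND`
#' ("0", `EXTEND_BOTH` when it runs past both ends); anything shorter gives
#' `NONE` (".": no read match expected because the reference lacks the
#' region). Full-length alleles therefore expect all-`FULL` rows, and
#' exon-2/3-only class I alleles expect `(1F:0, 1R:0, 2F:1, 2R:.)`.
#'
#' @param db `csbt_db`.
#' @param amplicons named list of `csbt_amplicon`.
#' @param policy trim policy (sets window lengths).
#' @param anchor minimum overlap for an `EXTEND` expectation (default 30).
#' @return tibble `(allele, locus, group, expected)`.
#' @export
expected_matrix <- function(db, amplicons, policy, anchor = 30L) {
  win <- group_windows(amplicons, policy)
  rows <- list()
  for (a in amplicons) {
    w <- win[win$amplicon == a$name, ]
    sub <- db[db$locus %in% a$loci, , drop = FALSE]
    if (nrow(sub) == 0) next
    for (g in seq_len(nrow(w))) {
      ws <- w$start[g]; we <- w$end[g]
      ovs <- pmax(ws, sub$known_start)
      ove <- pmin(we, sub$known_end)
      ovlen <- ove - ovs + 1L
      full <- ws >= sub$known_start & we <= sub$known_end
      both <- ws < sub$known_start & we > sub$known_end
      expected <- ifelse(full, "FULL",
                         ifelse(ovlen >= anchor,
                                ifelse(both, "EXTEND_BOTH", "EXTEND"),
                                "NONE"))
      rows[[length(rows) + 1L]] <- tibble(allele = sub$name,
                                          locus = sub$locus,
                                          group = w$group[g],
                                          expected = expected)
    }
  }
  bind_rows(rows)
}

# shared machinery: per-(sample, allele, group) observed condition and count
summarize_matches <- function(matches) {
  matches |>
    group_by(.data$sample, .data$allele, .data$locus, .data$group) |>
    summarise(
      condition = names(sort(table(.data$condition), decreasing = TRUE))[1],
      reads = dplyr::n(), .groups = "drop"
    )
}

build_matrix <- function(matches, expected, key_group, required_groups,
                         optional_groups, discordant_from = matches) {
  groups <- c(key_group, required_groups, optional_groups)
  obs <- summarize_matches(matches)
  keyed <- obs |>
    filter(.data$group == key_group) |>
    distinct(.data$sample, .data$allele, .data$locus)

  # inner join: a kept row needs support in every required group unless the
  # expected condition there is NONE (geometry says no read can exist)
  exp_wide <- expected |>
    filter(.data$group %in% groups)
  req_ok <- keyed
  for (g in required_groups) {
    has_g <- obs |>
      filter(.data$group == g) |>
      distinct(.data$sample, .data$allele) |>
      mutate(has = TRUE)
    none_g <- exp_wide |>
      filter(.data$group == g, .data$expected == "NONE") |>
      distinct(.data$allele) |>
      mutate(exp_none = TRUE)
    req_ok <- req_ok |>
      left_join(has_g, by = c("sample", "allele")) |>
      left_join(none_g, by = "allele") |>
      filter(!is.na(.data$has) | !is.na(.data$exp_none)) |>
      select("sample", "allele", "locus")
  }

  mat <- tidyr::expand_grid(req_ok, group = groups) |>
    left_join(obs, by = c("sample", "allele", "locus", "group")) |>
    mutate(condition = dplyr::coalesce(.data$condition, "NONE"),
           reads = dplyr::coalesce(.data$reads, 0L))

  # discordant candidates: supported in every required (amplicon 1) group but
  # absent from the key — the signature of key-amplicon dropout
  discordant <- tibble(sample = character(), allele = character(),
                       locus = character(), reads = integer())
  if (length(required_groups) > 0) {
    cand <- summarize_matches(discordant_from) |>
      filter(.data$group %in% required_groups) |>
      group_by(.data$sample, .data$allele, .data$locus) |>
      summarise(n_groups = dplyr::n_distinct(.data$group),
                reads = sum(.data$reads), .groups = "drop") |>
      filter(.data$n_groups == length(required_groups)) |>
      anti_join(keyed, by = c("sample", "allele")) |>
      select("sample", "allele", "locus", "reads")
    discordant <- cand
  }

  structure(mat, expected = exp_wide, discordant = discordant,
            groups = groups, key_group = key_group,
            class = c("csbt_matrix", class(mat)))
}

#' Build the class I match matrix
#'
#' Mirrors the published join strategy: the 2F dataset is the key; rows are
#' kept only with qualifying 1F and 1R support (inner joins), while 2R is
#' attached where present and recorded as `NONE` otherwise (outer join),
#' accommodating short reference alleles with null 2R conditions. Alleles
#' supported in both amplicon-1 groups but absent from the 2F key are
#' returned in the `discordant` attribute — the signature of an
#' amplicon-specific primer mismatch.
#'
#' @param matches match tibble from [map_reads_exact()] covering groups
#'   2F, 1F, 1R, 2R.
#' @param expected tibble from [expected_matrix()].
#' @param key_group,inner_groups,outer_groups read-group roles.
#' @param discordant_from match tibble used for discordance screening; pass
#'   the unrestricted (full-database) matches so alleles dropped by the key
#'   restriction can still surface as `amplicon_discordant`.
#' @return a `csbt_matrix` tibble `(sample, locus, allele, group, condition,
#'   reads)` with attributes `expected`, `discordant`, `groups`, `key_group`.
#' @export
build_match_matrix_classI <- function(matches, expected, key_group = "2F",
                                      inner_groups = c("1F", "1R"),
                                      outer_groups = "2R",
                                      discordant_from = matches) {
  build_matrix(matches, expected, key_group, inner_groups, outer_groups,
               discordant_from = discordant_from)
}

#' Build the class II match matrix
#'
#' Forward reads are the key (admitting `FULL`, `EXTEND` and — against
#' exon-2-only references — `EXTEND_BOTH` conditions); reverse reads are
#' evaluated only against forward-matching alleles and outer-joined, so
#' reverse-only support never creates a row.
#'
#' @param matches match tibble covering the forward and reverse groups.
#' @param expected tibble from [expected_matrix()].
#' @param key_group,reverse_groups read-group roles.
#' @return a `csbt_matrix` (see [build_match_matrix_classI()]).
#' @export
build_match_matrix_classII <- function(matches, expected,
                                       key_group = "DRB-F",
                                       reverse_groups = "DRB-R") {
  build_matrix(matches, expected, key_group, character(0), reverse_groups)
}
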