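# Read-group geometry ---------------------------------------------------

#' Genomic windows of the trimmed read groups
#'
#' A forward read, after MID and primer clipping, starts at the base after the
#' forward primer and runs `target` nt downstream; a reverse read ends at the
#' base before the reverse primer and runs `target` nt upstream. These
#' windows, intersected with each allele's known interval, determine the
#' expected match condition for every (allele, read group) pair.
#'
#' @param amplicons named list of `csbt_amplicon`.
#' @param policy trim policy tibble (the `target` column sets window length).
#' @return tibble `(group, amplicon, direction, start, end)`.
#' @export
group_windows <- function(amplicons, policy) {
  bind_rows(lapply(amplicons, function(a) {
    tf <- policy$target[match(a$group_fwd, policy$group)]
    tr <- policy$target[match(a$group_rev, policy$group)]
    tibble(group = c(a$group_fwd, a$group_rev),
           amplicon = a$name,
           direction = c("forward", "reverse"),
           start = c(a$fwd$end + 1L, a$rev$start - tr),
           end = c(a$fwd$end + tf, a$rev$start - 1L))
  }))
}

# Exact mapping ----------------------------------------------------------

#' Map trimmed reads against reference alleles at 100% identity
#'
#' Each read is placed at its expected offset on the consensus frame (fixed
#' by its amplicon and direction; reverse reads are reverse-complemented
#' first) and compared base-for-base against each allele over the
#' intersection of the read window with the allele's known interval.
#' The match condition is:
#'
#' * `FULL` — the window lies inside the known interval and the read is an
#'   exact substring of the reference there ("type 1");
#' * `EXTEND` — the overlap is at least `anchor` nt, matches with zero
#'   mismatches, and the read extends past one end of the known interval
#'   ("type 0": the read carries positions unknown to the reference);
#' * `EXTEND_BOTH` — as above but the read extends past both ends (the
#'   class II forward-read case against exon-2-only references).
#'
#' Reads matching no allele produce no entry and feed novel-allele detection.
#'
#' @param reads tibble of trimmed demultiplexed reads (`id, sample, amplicon,
#'   direction, group, seq`).
#' @param db `csbt_db` of candidate alleles (must be non-empty).
#' @param amplicons named list of `csbt_amplicon`.
#' @param anchor minimum perfect overlap in nt for an `EXTEND` match
#'   (default 30).
#' @return tibble `(id, sample, group, allele, locus, condition)`.
#' @export
map_reads_exact <- function(reads, db, amplicons, anchor = 30L) {
  if (nrow(db) == 0) abort("empty reference subset: upstream restriction failed")
  if (nrow(reads) == 0) {
    return(tibble(id = character(), sample = character(), group = character(),
                  allele = character(), locus = character(),
                  condition = character()))
  }
  keys <- reads |>
    distinct(.data$amplicon, .data$direction, .data$group, .data$seq)
  hits <- vector("list", nrow(keys))
  for (k in seq_len(nrow(keys))) {
    amp <- amplicons[[keys$amplicon[k]]]
    len <- nchar(keys$seq[k])
    if (keys$direction[k] == "forward") {
      ws <- amp$fwd$end + 1L
      we <- ws + len - 1L
      oriented <- keys$seq[k]
    } else {
      we <- amp$rev$start - 1L
      ws <- we - len + 1L
      oriented <- revcomp(keys$seq[k])
    }
    sub <- db[db$locus %in% amp$loci, , drop = FALSE]
    if (nrow(sub) == 0) next
    ovs <- pmax(ws, sub$known_start)
    ove <- pmin(we, sub$known_end)
    ovlen <- ove - ovs + 1L
    valid <- ovlen >= anchor
    if (!any(valid)) next
    read_sub <- substring(oriented, ovs - ws + 1L, ove - ws + 1L)
    ref_sub <- substr(sub$seq, ovs - sub$known_start + 1L,
                      ove - sub$known_start + 1L)
    eq <- valid & read_sub == ref_sub
    if (!any(eq)) next
    cond <- ifelse(ovlen == len, "FULL",
                   ifelse(ws < sub$known_start & we > sub$known_end,
                          "EXTEND_BOTH", "EXTEND"))
    hits[[k]] <- tibble(amplicon = keys$amplicon[k],
                        direction = keys$direction[k],
                        group = keys$group[k], seq = keys$seq[k],
                        allele = sub$name[eq], locus = sub$locus[eq],
                        condition = cond[eq])
  }
  hits <- bind_rows(hits)
  if (nrow(hits) == 0) {
    return(tibble(id = character(), sample = character(), group = character(),
                  allele = character(), locus = character(),
                  condition = character()))
  }
  reads |>
    select(any_of(c("id", "sample", "amplicon", "direction", "group", "seq"))) |>
    inner_join(hits, by = c("amplicon", "direction", "group", "seq"),
               relationship = "many-to-many") |>
    select(any_of(c("id", "sample")), "group", "allele", "locus", "condition")
}

#' Restrict the reference set from forward-key matches
#'
#' The key read group (class I: the 2F reads, which all named alleles cover;
#' class II: the forward reads) dictates the candidate allele set for all
#' subsequent mapping: only alleles with at least one perfect key-group match
#' are carried forward. An empty candidate set is not an error — the sample
#' is flagged not-detected downstream.
#'
#' @param matches match tibble from [map_reads_exact()].
#' @param db full `csbt_db`.
#' @param key_group key read-group label (e.g. `"2F"`).
#' @return list with `db` (the restricted `csbt_db`), `alleles` and
#'   `detected` (FALSE when no key matches exist).
#' @export
restrict_references <- function(matches, db, key_group) {
  alleles <- unique(matches$allele[matches$group == key_group])
  list(db = db_subset(db, db$name %in% alleles),
       alleles = alleles,
       detected = length(alleles) > 0)
}
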