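#' Trim policy
#'
#' Per-read-group target length and acceptance window. The published assay
#' trimmed every read group to a standardized length between 300 and 350 nt;
#' the default policy trims to 320 nt and accepts 300-350.
#'
#' @param groups read-group labels.
#' @param target target trimmed length in nt (recycled).
#' @param min,max acceptance window in nt (recycled).
#' @return tibble `(group, target, min, max)`.
#' @export
trim_policy <- function(groups, target = 320L, min = 300L, max = 350L) {
  stopifnot(all(min > 0), all(min <= target), all(target <= max))
  tibble(group = groups, target = as.integer(target),
         min = as.integer(min), max = as.integer(max))
}

#' Default trim policy for an amplicon panel
#'
#' @param amplicons named list of `csbt_amplicon`.
#' @inheritParams trim_policy
#' @return tibble `(group, target, min, max)` covering both directions of
#'   every amplicon.
#' @export
default_trim_policy <- function(amplicons, target = 320L, min = 300L,
                                max = 350L) {
  groups <- unlist(lapply(amplicons, function(a) c(a$group_fwd, a$group_rev)))
  trim_policy(unname(groups), target, min, max)
}

#' Demultiplex reads by MID and amplicon primer
#'
#' A read is assigned if and only if its 5' prefix matches exactly one MID
#' (within `max_mid_mismatch`) and the following bases match exactly one
#' amplicon primer (within `max_primer_mismatch`), which identifies the
#' amplicon and the read direction. MID and primer are clipped from assigned
#' reads; every input read lands in exactly one bin (assigned or unassigned
#' with a reason code), so demultiplexing is a partition.
#'
#' @param reads tibble with `id`, `seq` (e.g. from [read_fastq()] or a
#'   simulator), or a FASTQ path.
#' @param manifest tibble `(sample, mid_id, mid)`.
#' @param amplicons named list of `csbt_amplicon` whose primer sites carry
#'   consensus sequences.
#' @param max_mid_mismatch allowed MID mismatches (default 0; simulated tags
#'   have pairwise distance >= 3 so 1 is also safe).
#' @param max_primer_mismatch allowed primer mismatches (default 2).
#' @return list with `assigned` (tibble `id, sample, amplicon, direction,
#'   group, seq` — seq clipped of MID and primer) and `unassigned`
#'   (tibble `id, seq, reason`).
#' @export
demultiplex <- function(reads, manifest, amplicons,
                        max_mid_mismatch = 0L, max_primer_mismatch = 2L) {
  if (is.character(reads)) reads <- read_fastq(reads)
  mid_len <- unique(nchar(manifest$mid))
  if (length(mid_len) != 1) abort("MID tags must have uniform length")

  prefix <- substr(reads$seq, 1L, mid_len)
  n <- nrow(reads)
  sample_hit <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)

  if (max_mid_mismatch == 0L) {
    idx <- match(prefix, manifest$mid)
    sample_hit <- manifest$sample[idx]
    reason[is.na(idx)] <- "unknown_mid"
  } else {
    dists <- vapply(manifest$mid, function(m) str_hamming(prefix, m),
                    integer(n))
    dists <- matrix(dists, nrow = n)
    hits <- dists <= max_mid_mismatch
    nhit <- rowSums(hits)
    one <- nhit == 1
    sample_hit[one] <- manifest$sample[apply(hits[one, , drop = FALSE], 1,
                                             which)]
    reason[nhit == 0] <- "unknown_mid"
    reason[nhit > 1] <- "ambiguous_mid"
  }

  # primer table: one row per (amplicon, direction); reverse reads start with
  # the reverse complement of the reverse primer site
  prim <- bind_rows(lapply(amplicons, function(a) {
    tibble(amplicon = a$name,
           direction = c("forward", "reverse"),
           group = c(a$group_fwd, a$group_rev),
           primer = c(a$fwd$seq, revcomp(a$rev$seq)))
  }))
  if (any(is.na(prim$primer))) {
    abort("amplicon primer consensus sequences are required for demultiplexing")
  }

  rest <- substr(reads$seq, mid_len + 1L, nchar(reads$seq))
  pd <- vapply(prim$primer, function(p) {
    d <- str_hamming(substr(rest, 1L, nchar(p)), p)
    ifelse(is.na(d), nchar(p), d)  # too-short reads never match
  }, integer(n))
  pd <- matrix(pd, nrow = n)
  phits <- pd <= max_primer_mismatch
  nphit <- rowSums(phits)
  amp_idx <- rep(NA_integer_, n)
  amp_idx[nphit == 1] <- apply(phits[nphit == 1, , drop = FALSE], 1, which)
  pr_reason <- ifelse(nphit == 0, "unknown_primer",
                      ifelse(nphit > 1, "ambiguous_primer", NA_character_))
  reason <- dplyr::coalesce(reason, pr_reason)

  ok <- !is.na(sample_hit) & !is.na(amp_idx)
  plen <- nchar(prim$primer)[amp_idx[ok]]
  assigned <- tibble(
    id = reads$id[ok],
    sample = sample_hit[ok],
    amplicon = prim$amplicon[amp_idx[ok]],
    direction = prim$direction[amp_idx[ok]],
    group = prim$group[amp_idx[ok]],
    seq = substr(rest[ok], plen + 1L, nchar(rest[ok]))
  )
  unassigned <- tibble(id = reads$id[!ok], seq = reads$seq[!ok],
                       reason = reason[!ok])
  list(assigned = assigned, unassigned = unassigned)
}

#' Length-filter and trim demultiplexed reads
#'
#' Reads shorter than their group's minimum are discarded; reads at least as
#' long as the target are truncated to the target, anchored at the 5' end
#' (post MID/primer clipping). Reads between minimum and target are kept
#' untrimmed. Trimming is idempotent.
#'
#' @param reads assigned-read tibble from [demultiplex()].
#' @param policy tibble from [trim_policy()]; must cover every group present.
#' @return list with `reads` (kept, trimmed) and `stats` (per group: `input`,
#'   `kept`, `discarded`, `retention`).
#' @export
trim_filter <- function(reads, policy) {
  missing <- setdiff(unique(reads$group), policy$group)
  if (length(missing)) {
    abort(sprintf("no trim policy for group(s): %s",
                  paste(missing, collapse = ", ")))
  }
  x <- reads |>
    left_join(policy, by = "group") |>
    mutate(len = nchar(.data$seq))
  kept <- x |>
    filter(.data$len >= .data$min) |>
    mutate(seq = ifelse(.data$len >= .data$target,
                        substr(.data$seq, 1L, .data$target), .data$seq)) |>
    select(-"len", -"target", -"min", -"max")
  stats <- x |>
    group_by(.data$group) |>
    summarise(input = dplyr::n(),
              kept = sum(.data$len >= .data$min),
              .groups = "drop") |>
    mutate(discarded = .data$input - .data$kept,
           retention = .data$kept / .data$input)
  list(reads = kept, stats = stats)
}
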