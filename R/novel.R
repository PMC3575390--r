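#' Annotate a coding substitution
#'
#' The consensus frame is in frame with the open reading frame (codon 1
#' begins at consensus position 1), so a substitution at consensus position
#' `p` falls in codon `ceiling(p / 3)` — position 587 is in codon 196. The
#' reference and alternate codons are translated with the standard genetic
#' code and classified.
#'
#' @param ref_seq the reference allele's deposited sequence.
#' @param known_start consensus position of the first base of `ref_seq`.
#' @param position consensus position of the substitution; its whole codon
#'   must lie inside the known interval.
#' @param alt alternate base.
#' @return one-row tibble: `position`, `codon` (index), `ref_base`,
#'   `alt_base`, `ref_aa`, `alt_aa`, `consequence` (`identity`,
#'   `synonymous`, `missense` or `nonsense`).
#' @examples
#' # a Pro -> Leu change at the second codon position
#' annotate_variant(strrep("CCG", 4), known_start = 1, position = 5, alt = "T")
#' @export
annotate_variant <- function(ref_seq, known_start, position, alt) {
  known_end <- known_start + nchar(ref_seq) - 1L
  if (position < known_start || position > known_end) {
    abort(sprintf("position %d outside known interval %d-%d",
                  position, known_start, known_end))
  }
  codon_idx <- ceiling(position / 3)
  c_start <- 3L * codon_idx - 2L
  c_end <- 3L * codon_idx
  if (c_start < known_start || c_end > known_end) {
    abort(sprintf("codon %d (positions %d-%d) not fully inside known interval",
                  codon_idx, c_start, c_end))
  }
  ref_codon <- substr(ref_seq, c_start - known_start + 1L,
                      c_end - known_start + 1L)
  ref_base <- substr(ref_seq, position - known_start + 1L,
                     position - known_start + 1L)
  off <- position - c_start + 1L
  alt_codon <- ref_codon
  substr(alt_codon, off, off) <- alt
  ref_aa <- translate_codon(ref_codon)
  alt_aa <- translate_codon(alt_codon)
  consequence <- if (alt == ref_base) "identity"
    else if (ref_aa == alt_aa) "synonymous"
    else if (alt_aa == "*") "nonsense"
    else "missense"
  tibble(position = as.integer(position), codon = as.integer(codon_idx),
         ref_base = ref_base, alt_base = alt, ref_aa = ref_aa,
         alt_aa = alt_aa, consequence = consequence)
}

#' Detect putative novel alleles from unmatched reads
#'
#' Identical unmatched reads are clustered per (sample, read group); clusters
#' of at least `min_cluster` reads are placed at their expected frame offset
#' and compared to every reference by Hamming distance over the aligned
#' overlap with the known interval. A cluster within `max_snps` of its
#' nearest reference becomes a candidate carrying the SNP list (consensus
#' coordinates) and per-SNP protein consequences; when several references are
#' equidistant, all nearest are reported. Consistent clusters from different
#' read groups of the same sample against the same nearest reference are
#' merged into one consensus candidate.
#'
#' @param unmatched tibble of trimmed reads with no match entries
#'   (`id, sample, amplicon, direction, group, seq`).
#' @param db `csbt_db`.
#' @param amplicons named list of `csbt_amplicon`.
#' @param policy a [call_policy()] (`novel_min_cluster`, `novel_max_snps`,
#'   `anchor` are used).
#' @return tibble of class `csbt_novel`: `sample`, `locus`, `nearest_allele`,
#'   `n_snps`, `snps` (list-column of annotation tibbles), `support`,
#'   `groups`, `consensus_seq`.
#' @export
detect_novel <- function(unmatched, db, amplicons, policy = call_policy()) {
  empty <- tibble(sample = character(), locus = character(),
                  nearest_allele = character(), n_snps = integer(),
                  snps = list(), support = integer(), groups = character(),
                  consensus_seq = character())
  if (nrow(unmatched) == 0) {
    class(empty) <- c("csbt_novel", class(empty))
    return(empty)
  }
  clusters <- unmatched |>
    count(.data$sample, .data$amplicon, .data$direction, .data$group,
          .data$seq, name = "support") |>
    filter(.data$support >= policy$novel_min_cluster)
  cands <- list()
  for (k in seq_len(nrow(clusters))) {
    cl <- clusters[k, ]
    amp <- amplicons[[cl$amplicon]]
    len <- nchar(cl$seq)
    if (cl$direction == "forward") {
      ws <- amp$fwd$end + 1L; we <- ws + len - 1L
      oriented <- cl$seq
    } else {
      we <- amp$rev$start - 1L; ws <- we - len + 1L
      oriented <- revcomp(cl$seq)
    }
    sub <- db[db$locus %in% amp$loci, , drop = FALSE]
    ovs <- pmax(ws, sub$known_start)
    ove <- pmin(we, sub$known_end)
    ovlen <- ove - ovs + 1L
    valid <- which(ovlen >= policy$anchor)
    if (length(valid) == 0) next
    d <- rep(NA_integer_, nrow(sub))
    for (i in valid) {
      rs <- substr(oriented, ovs[i] - ws + 1L, ove[i] - ws + 1L)
      fs <- substr(sub$seq[i], ovs[i] - sub$known_start[i] + 1L,
                   ove[i] - sub$known_start[i] + 1L)
      d[i] <- str_hamming(rs, fs)
    }
    dmin <- min(d, na.rm = TRUE)
    if (dmin < 1 || dmin > policy$novel_max_snps) next
    for (i in which(!is.na(d) & d == dmin)) {
      rs <- strsplit(substr(oriented, ovs[i] - ws + 1L, ove[i] - ws + 1L),
                     "")[[1]]
      fs <- strsplit(substr(sub$seq[i], ovs[i] - sub$known_start[i] + 1L,
                            ove[i] - sub$known_start[i] + 1L), "")[[1]]
      diffpos <- which(rs != fs)
      snps <- bind_rows(lapply(diffpos, function(p) {
        pos <- ovs[i] + p - 1L
        annotate_variant(sub$seq[i], sub$known_start[i], pos, rs[p])
      }))
      cands[[length(cands) + 1L]] <- tibble(
        sample = cl$sample, locus = sub$locus[i],
        nearest_allele = sub$name[i], group = cl$group,
        support = cl$support, snps = list(snps)
      )
    }
  }
  if (length(cands) == 0) {
    class(empty) <- c("csbt_novel", class(empty))
    return(empty)
  }
  cands <- bind_rows(cands)

  # merge consistent clusters across read groups
  out <- list()
  keys <- cands |> distinct(.data$sample, .data$locus, .data$nearest_allele)
  for (k in seq_len(nrow(keys))) {
    sub <- cands |>
      filter(.data$sample == keys$sample[k], .data$locus == keys$locus[k],
             .data$nearest_allele == keys$nearest_allele[k])
    snps <- bind_rows(sub$snps) |> distinct()
    consistent <- !anyDuplicated(snps$position)
    if (!consistent) {
      # conflicting alternates at one position: report clusters separately
      for (r in seq_len(nrow(sub))) {
        out[[length(out) + 1L]] <- candidate_row(sub[r, ], sub$snps[[r]], db)
      }
    } else {
      merged <- sub[1, ]
      merged$support <- sum(sub$support)
      out[[length(out) + 1L]] <- candidate_row(
        merged, snps |> arrange(.data$position), db,
        groups = paste(sort(unique(sub$group)), collapse = ","))
    }
  }
  res <- bind_rows(out) |>
    arrange(.data$sample, .data$locus, .data$nearest_allele)
  class(res) <- c("csbt_novel", class(res))
  res
}

candidate_row <- function(row, snps, db, groups = row$group) {
  i <- match(row$nearest_allele, db$name)
  cons <- db$seq[i]
  for (r in seq_len(nrow(snps))) {
    cons <- subst_base(cons, snps$position[r] - db$known_start[i] + 1L,
                       snps$alt_base[r])
  }
  tibble(sample = row$sample, locus = row$locus,
         nearest_allele = row$nearest_allele,
         n_snps = nrow(snps), snps = list(snps),
         support = row$support, groups = groups, consensus_seq = cons)
}
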