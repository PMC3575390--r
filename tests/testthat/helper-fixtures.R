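# shared fixture builders — everything is generated in code, no files

# small hand-built database on a 1..120 consensus frame
tiny_db <- function() {
  set.seed(42)
  base <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
                collapse = "")
  a2 <- base; substr(a2, 30, 30) <- "A"; substr(a2, 31, 31) <- "C"
  allele_db(
    name = c("A*01:01", "A*01:02", "A*02:01"),
    seq = c(base, a2, substr(base, 20, 90)),
    known_start = c(1L, 1L, 20L),
    known_end = c(120L, 120L, 90L),
    consensus_length = 120L
  )
}

# random full-length toy database for property tests: alleles are a shared
# backbone with sparse substitutions, so indistinguishable pairs are common
random_full_db <- function(n_alleles, len = 80L, n_snp_positions = 6L) {
  backbone <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                    collapse = "")
  pos <- sort(sample(seq_len(len), n_snp_positions))
  seqs <- vapply(seq_len(n_alleles), function(i) {
    s <- backbone
    for (p in sample(pos, sample(0:2, 1))) {
      substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                        substr(s, p, p)), 1)
    }
    s
  }, character(1))
  # unique names, some sharing the 2-digit group
  names_ <- sprintf("X*%02d:%02d", (seq_len(n_alleles) - 1) %/% 3 + 1,
                    (seq_len(n_alleles) - 1) %% 3 + 1)
  allele_db(names_, seqs, rep(1L, n_alleles), rep(len, n_alleles),
            consensus_length = len)
}

# independent all-pairs comparator for in_silico_resolution: returns the set
# of name-distinct-at-`digits` pairs identical over the coverage
brute_force_ambiguous_pairs <- function(db, coverage, digits = 4L) {
  if (is.numeric(coverage)) coverage <- list(coverage)
  pairs <- character(0)
  for (loc in unique(db$locus)) {
    sub <- db[db$locus == loc, ]
    n <- nrow(sub)
    if (n < 2) next
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        compared <- 0L
        same <- TRUE
        for (iv in coverage) {
          lo <- max(iv[1], sub$known_start[i], sub$known_start[j])
          hi <- min(iv[2], sub$known_end[i], sub$known_end[j])
          if (lo > hi) next
          for (p in lo:hi) {
            compared <- compared + 1L
            bi <- substr(sub$seq[i], p - sub$known_start[i] + 1,
                         p - sub$known_start[i] + 1)
            bj <- substr(sub$seq[j], p - sub$known_start[j] + 1,
                         p - sub$known_start[j] + 1)
            if (bi != bj) same <- FALSE
          }
        }
        if (compared == 0 || !same) next
        k <- digits %/% 2L
        short <- function(nm) {
          p <- parse_allele_name(nm)
          paste(p$locus[1], paste(p$fields[[1]][seq_len(min(k, length(p$fields[[1]])))],
                                  collapse = ":"))
        }
        if (short(sub$name[i]) != short(sub$name[j])) {
          pairs <- c(pairs, paste(sort(c(sub$name[i], sub$name[j])),
                                  collapse = "|"))
        }
      }
    }
  }
  sort(unique(pairs))
}

# expand resolution groups into their name-distinct member pairs
groups_to_pairs <- function(groups, digits = 4L) {
  if (nrow(groups) == 0) return(character(0))
  out <- character(0)
  for (g in seq_len(nrow(groups))) {
    members <- strsplit(groups$members[g], "/", fixed = TRUE)[[1]]
    k <- digits %/% 2L
    for (i in seq_len(length(members) - 1)) {
      for (j in (i + 1):length(members)) {
        pi <- parse_allele_name(members[i])
        pj <- parse_allele_name(members[j])
        ki <- paste(pi$fields[[1]][seq_len(min(k, length(pi$fields[[1]])))], collapse = ":")
        kj <- paste(pj$fields[[1]][seq_len(min(k, length(pj$fields[[1]])))], collapse = ":")
        if (ki != kj) {
          out <- c(out, paste(sort(c(members[i], members[j])), collapse = "|"))
        }
      }
    }
  }
  sort(unique(out))
}

# independent mapper: fixed-substring full scan (FULL anywhere in the
# reference) plus per-base overlap comparison at the expected offset
oracle_map <- function(reads, db, amplicons, anchor = 30L) {
  out <- list()
  for (r in seq_len(nrow(reads))) {
    amp <- amplicons[[reads$amplicon[r]]]
    len <- nchar(reads$seq[r])
    if (reads$direction[r] == "forward") {
      ws <- amp$fwd$end + 1L; we <- ws + len - 1L
      oriented <- reads$seq[r]
    } else {
      we <- amp$rev$start - 1L; ws <- we - len + 1L
      oriented <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(reads$seq[r])))
    }
    rvec <- strsplit(oriented, "")[[1]]
    for (a in seq_len(nrow(db))) {
      if (!db$locus[a] %in% amp$loci) next
      ks <- db$known_start[a]; ke <- db$known_end[a]
      lo <- max(ws, ks); hi <- min(we, ke)
      ov <- hi - lo + 1L
      if (ov < anchor) next
      fvec <- strsplit(db$seq[a], "")[[1]]
      mism <- 0L
      for (p in lo:hi) {
        if (rvec[p - ws + 1L] != fvec[p - ks + 1L]) { mism <- 1L; break }
      }
      if (mism > 0L) next
      cond <- if (ov == len) {
        # cross-check with a naive full-substring scan
        stopifnot(grepl(oriented, db$seq[a], fixed = TRUE))
        "FULL"
      } else if (ws < ks && we > ke) "EXTEND_BOTH" else "EXTEND"
      out[[length(out) + 1L]] <- tibble::tibble(
        id = reads$id[r], group = reads$group[r],
        allele = db$name[a], condition = cond)
    }
  }
  dplyr::bind_rows(out)
}

# tiny simulated world used by several mapping tests
small_world <- function(seed = 7L, n_samples = 2L, reads = 40L, ...) {
  cfg <- sim_config(seed = seed, class1_loci = "A", alleles_per_locus = 6L,
                    n_samples = n_samples, reads_per_amplicon = reads, ...)
  sim <- simulate_database(cfg)
  gt <- simulate_genotypes(sim, n_samples)
  sr <- simulate_reads(sim, gt)
  list(sim = sim, gt = gt, sr = sr)
}

prep_reads <- function(world) {
  dm <- demultiplex(world$sr$reads, world$sr$manifest, world$sim$amplicons)
  tr <- trim_filter(dm$assigned, default_trim_policy(world$sim$amplicons))
  tr$reads
}

# does every truth allele at (sample, locus) appear inside some call, and
# does every positive call contain at least one truth allele?
check_truth_recovery <- function(calls, genotypes) {
  ok_recovered <- TRUE
  ok_no_false <- TRUE
  for (r in seq_len(nrow(genotypes))) {
    truth <- unique(c(genotypes$allele1[r], genotypes$allele2[r]))
    sub <- calls[calls$sample == genotypes$sample[r] &
                   calls$locus == genotypes$locus[r] &
                   calls$confidence %in% c("unambiguous", "ambiguous_set",
                                           "low_stringency"), ]
    called_sets <- sub$members
    for (al in truth) {
      if (!any(vapply(called_sets, function(m) al %in% m, logical(1)))) {
        ok_recovered <- FALSE
      }
    }
    for (m in called_sets) {
      if (!any(truth %in% m)) ok_no_false <- FALSE
    }
  }
  list(recovered = ok_recovered, no_false = ok_no_false)
}
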