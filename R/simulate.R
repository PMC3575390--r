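#' Simulation configuration
#'
#' Describes the synthetic world the fixture generator emulates: a multi-locus
#' allele database with heterogeneous known-sequence extent, diploid samples,
#' two tiled class I amplicons plus one DRB amplicon, MID tagging, pooling
#' ratios, optional substitution errors and per-allele amplicon dropout.
#'
#' Defaults mirror the published assay: two overlapping class I amplicons
#' with inserts 50-725 (676 nt) and 145-1069 (925 nt) on an ~1.1 kb ORF
#' frame, a DRB amplicon 61-727 (667 nt), three amplicons pooled 3:6:1,
#' 10 nt MIDs, reads trimmed to 300-350 nt, and a reference set in which a
#' quarter of the alleles are deposited only over an exon-2/3-like
#' sub-interval.
#'
#' @param seed integer seed; every downstream draw is reproducible from it.
#' @param class1_loci,drb_loci locus names for the class I frame and the DRB
#'   frame.
#' @param alleles_per_locus alleles simulated per locus (min 4).
#' @param consensus_length_classI,consensus_length_drb frame lengths in nt.
#' @param snp_rate per-base probability of an inter-allele substitution.
#' @param fraction_partial fraction of alleles deposited only over the
#'   partial interval (class I analog 104-620, DRB analog 100-380).
#' @param n_samples number of diploid samples.
#' @param reads_per_amplicon base read count per sample; each amplicon's
#'   expectation is this times its pooling multiplier.
#' @param pool_ratio named positive multipliers per amplicon.
#' @param error_rate per-base substitution error probability in reads.
#' @param mid_length MID barcode length in nt.
#' @param dropout optional tibble `(sample, allele, amplicon)`: combinations
#'   yielding zero reads (models allele-specific primer incompatibility).
#' @param starve optional tibble `(sample, allele, keep)`: cap that allele's
#'   reads at `keep` per (amplicon, direction) — models poorly amplifying
#'   alleles that only a low-stringency pipeline recovers.
#' @return a list of class `csbt_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       class1_loci = c("A", "B"),
                       drb_loci = "DRB1",
                       alleles_per_locus = 20L,
                       consensus_length_classI = 1100L,
                       consensus_length_drb = 750L,
                       snp_rate = 0.01,
                       fraction_partial = 0.25,
                       n_samples = 10L,
                       reads_per_amplicon = 300L,
                       pool_ratio = c("HLA-1" = 3, "HLA-2" = 6, "DRB" = 1),
                       error_rate = 0,
                       mid_length = 10L,
                       dropout = NULL,
                       starve = NULL) {
  stopifnot(alleles_per_locus >= 4,
            snp_rate >= 0, snp_rate <= 1,
            fraction_partial >= 0, fraction_partial <= 1,
            error_rate >= 0, error_rate <= 1,
            all(pool_ratio > 0))
  structure(as.list(environment()), class = "csbt_sim_config")
}

# fixed geometry of the simulated assay (printed design coordinates)
sim_geometry <- function(cfg) {
  list(
    classI = list(
      frame_len = cfg$consensus_length_classI,
      coverage = c(50L, 1069L),
      partial_known = c(104L, 620L),
      amplicons = list(
        `HLA-1` = list(fwd = c(50L, 68L), rev = c(707L, 725L),
                       gf = "1F", gr = "1R"),
        `HLA-2` = list(fwd = c(145L, 163L), rev = c(1051L, 1069L),
                       gf = "2F", gr = "2R")
      )
    ),
    drb = list(
      frame_len = cfg$consensus_length_drb,
      coverage = c(61L, 727L),
      partial_known = c(100L, 380L),
      amplicons = list(
        DRB = list(fwd = c(61L, 79L), rev = c(707L, 727L),
                   gf = "DRB-F", gr = "DRB-R")
      )
    )
  )
}

#' Simulate a reference allele database
#'
#' Generates, reproducibly from the seed, per-locus allele sets on two
#' coordinate frames (class I analog and DRB analog). Each allele carries a
#' private substitution plus Binomial(`snp_rate`) extra substitutions, all
#' placed outside the conserved primer windows so the universal primers stay
#' universal. The last two alleles of each locus are a designed ambiguous
#' pair: they differ only outside the assayed coverage, so any method reading
#' only the amplified region cannot separate them. A `fraction_partial`
#' subset of alleles is deposited only over the partial interval, emulating
#' exon-2/3-only (class I) and exon-2-only (DRB) records.
#'
#' @param cfg a [sim_config()].
#' @return list of class `csbt_sim` with elements `db` (a `csbt_db` holding
#'   the deposited sequences), `truth` (tibble of full underlying sequences:
#'   `name`, `locus`, `full_seq`, `known_start`, `known_end`, `partial`),
#'   `amplicons` (named list of `csbt_amplicon`), `ambiguous_pairs` (tibble of
#'   the designed pairs) and `config`.
#' @export
simulate_database <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  geoms <- sim_geometry(cfg)
  truth <- list()
  pairs <- list()

  gen_frame <- function(geom, loci) {
    L <- geom$frame_len
    if (cfg$alleles_per_locus * length(loci) > 4^6) {
      abort("infeasible config: more alleles than sequence space")
    }
    primer_pos <- unlist(lapply(geom$amplicons,
                                function(a) c(a$fwd[1]:a$fwd[2], a$rev[1]:a$rev[2])))
    master <- random_dna(L)
    cov <- geom$coverage
    in_pool <- setdiff(seq(cov[1], cov[2]), primer_pos)
    out_pool <- setdiff(seq_len(L), seq(cov[1], cov[2]))
    for (loc in loci) {
      cons <- master
      # locus-distinguishing substitutions, inside coverage
      for (p in sample(in_pool, 3)) {
        cons <- subst_base(cons, p, sample(setdiff(DNA_BASES, substr(cons, p, p)), 1))
      }
      m <- cfg$alleles_per_locus
      n_partial <- floor(cfg$fraction_partial * m)
      # alleles 2..(m-2) are eligible for partial deposition; the designed
      # ambiguous pair (m-1, m) and allele 1 stay full-length
      partial_idx <- if (n_partial > 0) {
        sample(setdiff(seq_len(m - 2), 1L), min(n_partial, m - 3))
      } else integer(0)
      priv_pos <- sample(in_pool, m)
      seqs <- character(m)
      for (i in seq_len(m)) {
        s <- cons
        p <- priv_pos[i]
        if (i %in% partial_idx) {
          # keep the private SNP inside the deposited interval
          pk <- intersect(in_pool, seq(geom$partial_known[1] + 5L,
                                       geom$partial_known[2] - 5L))
          p <- sample(pk, 1)
        }
        s <- subst_base(s, p, sample(setdiff(DNA_BASES, substr(s, p, p)), 1))
        k <- stats::rbinom(1, L, cfg$snp_rate)
        if (k > 0) {
          for (q in sample(in_pool, min(k, length(in_pool)))) {
            s <- subst_base(s, q, sample(setdiff(DNA_BASES, substr(s, q, q)), 1))
          }
        }
        seqs[i] <- s
      }
      # designed ambiguous pair: identical inside coverage, one SNP apart
      # outside it
      seqs[m] <- seqs[m - 1]
      po <- sample(out_pool, 1)
      seqs[m] <- subst_base(seqs[m], po,
                            sample(setdiff(DNA_BASES, substr(seqs[m], po, po)), 1))
      names_ <- allele_names_for(loc, m)
      ks <- rep(1L, m); ke <- rep(L, m)
      ks[partial_idx] <- geom$partial_known[1]
      ke[partial_idx] <- geom$partial_known[2]
      truth[[length(truth) + 1L]] <<- tibble(
        name = names_, locus = loc, full_seq = seqs,
        known_start = ks, known_end = ke,
        partial = seq_len(m) %in% partial_idx
      )
      pairs[[length(pairs) + 1L]] <<- tibble(
        locus = loc, allele1 = names_[m - 1], allele2 = names_[m],
        position = po
      )
    }
  }

  gen_frame(geoms$classI, cfg$class1_loci)
  gen_frame(geoms$drb, cfg$drb_loci)
  truth <- bind_rows(truth)

  db <- allele_db(
    truth$name,
    substr(truth$full_seq, truth$known_start, truth$known_end),
    truth$known_start, truth$known_end,
    consensus_length = max(truth$known_end)
  )

  amplicons <- build_sim_amplicons(truth, geoms, cfg)
  structure(list(db = db, truth = truth, amplicons = amplicons,
                 ambiguous_pairs = bind_rows(pairs), config = cfg),
            class = "csbt_sim")
}

# systematic names: groups of five protein variants; the first two alleles of
# each locus also carry a synonymous (6-digit) field, the last two are the
# designed ambiguous pair "98:01"/"98:02"
allele_names_for <- function(locus, m) {
  nm <- character(m)
  for (i in seq_len(m - 2)) {
    g <- (i - 1) %/% 5 + 1L
    p <- (i - 1) %% 5 + 1L
    f <- c(g, p)
    if (i <= 2) f <- c(f, 1L)
    nm[i] <- render_allele_name(locus, f)
  }
  nm[m - 1] <- render_allele_name(locus, c(98L, 1L))
  nm[m] <- render_allele_name(locus, c(98L, 2L))
  nm
}

build_sim_amplicons <- function(truth, geoms, cfg) {
  out <- list()
  frames <- list(list(geom = geoms$classI, loci = cfg$class1_loci, cls = "I"),
                 list(geom = geoms$drb, loci = cfg$drb_loci, cls = "II"))
  for (fr in frames) {
    sub <- truth[truth$locus %in% fr$loci, ]
    aligned <- stats::setNames(sub$full_seq, sub$name)
    for (an in names(fr$geom$amplicons)) {
      a <- fr$geom$amplicons[[an]]
      out[[an]] <- define_amplicon(an, a$fwd, a$rev, aligned = aligned,
                                   adapter_overhead = 25L + cfg$mid_length,
                                   group_fwd = a$gf, group_rev = a$gr,
                                   locus_class = fr$cls, loci = fr$loci)
    }
  }
  out
}

#' Simulate diploid genotypes
#'
#' @param sim a `csbt_sim` from [simulate_database()].
#' @param n_samples number of samples (default from the config).
#' @param seed seed (default `config$seed + 1`).
#' @return tibble `(sample, locus, allele1, allele2)`; homozygotes arise by
#'   sampling with replacement.
#' @export
simulate_genotypes <- function(sim, n_samples = sim$config$n_samples,
                               seed = sim$config$seed + 1L) {
  set.seed(seed)
  samples <- sprintf("S%02d", seq_len(n_samples))
  loci <- unique(sim$db$locus)
  tidyr::expand_grid(sample = samples, locus = loci) |>
    rowwise() |>
    mutate(pick = list(sample(sim$db$name[sim$db$locus == .data$locus],
                              2, replace = TRUE))) |>
    ungroup() |>
    mutate(allele1 = purrr::map_chr(.data$pick, 1),
           allele2 = purrr::map_chr(.data$pick, 2)) |>
    select(-"pick")
}

#' Generate MID barcodes
#'
#' Fixed-length multiplex identifiers with pairwise Hamming distance of at
#' least `min_dist` (default 3), generated greedily.
#'
#' @param n number of tags.
#' @param length tag length in nt (default 10).
#' @param min_dist minimum pairwise Hamming distance.
#' @param seed optional seed.
#' @return tibble `(mid_id, mid)`.
#' @export
make_mids <- function(n, length = 10L, min_dist = 3L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tags <- character(0)
  tries <- 0L
  while (base::length(tags) < n) {
    cand <- random_dna(length)
    if (base::length(tags) == 0 ||
        all(str_hamming(tags, cand) >= min_dist)) {
      tags <- c(tags, cand)
    }
    tries <- tries + 1L
    if (tries > 1000L * n) abort("could not generate enough distinct MIDs")
  }
  tibble(mid_id = sprintf("MID%02d", seq_len(n)), mid = tags)
}

#' Simulate MID-tagged amplicon reads
#'
#' Each read is a 5' MID barcode followed by the full amplicon insert of one
#' of the sample's alleles, forward or reverse-complemented with equal
#' probability. Per-sample read counts across amplicons are multinomial with
#' probabilities proportional to the pooling ratio and total
#' `reads_per_amplicon * sum(pool_ratio)`. Substitution errors are applied at
#' `error_rate` per base; `dropout` triples yield zero reads; `starve` caps
#' an allele's reads per (amplicon, direction). Deterministic given the seed.
#'
#' @param sim a `csbt_sim`.
#' @param genotypes tibble from [simulate_genotypes()] (or same shape). Any
#'   allele present in `extra_alleles` may also be used — that is how novel
#'   (not-in-database) alleles enter a sample.
#' @param mids optional MID table from [make_mids()]; generated when `NULL`.
#' @param extra_alleles optional tibble like `sim$truth` with additional
#'   underlying sequences (e.g. from [inject_novel()]).
#' @param seed seed (default `config$seed + 2`).
#' @return list of class `csbt_simreads`: `reads` (tibble `id, desc, seq`
#'   plus truth columns `sample, locus, allele, amplicon, direction`),
#'   `manifest` (`sample, mid_id, mid`), `genotypes`.
#' @export
simulate_reads <- function(sim, genotypes, mids = NULL, extra_alleles = NULL,
                           seed = sim$config$seed + 2L) {
  cfg <- sim$config
  set.seed(seed)
  truth <- bind_rows(sim$truth, extra_alleles)
  missing <- setdiff(unique(c(genotypes$allele1, genotypes$allele2)), truth$name)
  if (length(missing)) {
    abort(sprintf("genotype alleles not in database/extras: %s",
                  paste(missing, collapse = ", ")))
  }
  samples <- sort(unique(genotypes$sample))
  mids <- mids %||% make_mids(length(samples), length = cfg$mid_length)
  if (nrow(mids) < length(samples)) abort("not enough MIDs for samples")
  manifest <- tibble(sample = samples,
                     mid_id = mids$mid_id[seq_along(samples)],
                     mid = mids$mid[seq_along(samples)])

  amp_names <- names(sim$amplicons)
  ratio <- cfg$pool_ratio[amp_names]
  total <- round(cfg$reads_per_amplicon * sum(ratio))
  full_seq <- stats::setNames(truth$full_seq, truth$name)
  locus_of <- stats::setNames(truth$locus, truth$name)

  rows <- list()
  for (smp in samples) {
    counts <- stats::rmultinom(1, total, ratio / sum(ratio))[, 1]
    gts <- genotypes[genotypes$sample == smp, ]
    for (ai in seq_along(amp_names)) {
      amp <- sim$amplicons[[amp_names[ai]]]
      pool <- gts |>
        filter(.data$locus %in% amp$loci)
      alleles_pool <- c(pool$allele1, pool$allele2)
      n <- counts[ai]
      if (n == 0 || length(alleles_pool) == 0) next
      al <- sample(alleles_pool, n, replace = TRUE)
      dir <- sample(c("forward", "reverse"), n, replace = TRUE)
      rows[[length(rows) + 1L]] <- tibble(
        sample = smp, amplicon = amp_names[ai], allele = al, direction = dir
      )
    }
  }
  reads <- bind_rows(rows)

  if (!is.null(cfg$dropout) && nrow(cfg$dropout) > 0) {
    reads <- anti_join(reads, cfg$dropout,
                       by = c("sample", "allele", "amplicon"))
  }
  if (!is.null(cfg$starve) && nrow(cfg$starve) > 0) {
    reads <- reads |>
      left_join(cfg$starve, by = c("sample", "allele")) |>
      group_by(.data$sample, .data$allele, .data$amplicon, .data$direction) |>
      mutate(.rk = dplyr::row_number()) |>
      ungroup() |>
      filter(is.na(.data$keep) | .data$.rk <= .data$keep) |>
      select(-"keep", -".rk")
  }

  mid_of <- stats::setNames(manifest$mid, manifest$sample)
  insert_of <- function(amp_name, allele) {
    amp <- sim$amplicons[[amp_name]]
    substr(full_seq[allele], amp$insert$start, amp$insert$end)
  }
  reads <- reads |>
    mutate(locus = unname(locus_of[.data$allele]),
           insert = purrr::map2_chr(.data$amplicon, .data$allele, insert_of),
           body = ifelse(.data$direction == "forward",
                         .data$insert, revcomp(.data$insert)),
           seq = paste0(unname(mid_of[.data$sample]), .data$body)) |>
    select(-"insert", -"body")

  if (cfg$error_rate > 0) {
    reads$seq <- apply_errors(reads$seq, cfg$error_rate)
  }

  reads <- reads |>
    mutate(id = sprintf("read%06d", dplyr::row_number()),
           desc = sprintf("%s sample=%s locus=%s allele=%s amplicon=%s dir=%s",
                          .data$id, .data$sample, .data$locus, .data$allele,
                          .data$amplicon, .data$direction)) |>
    select("id", "desc", "seq", "sample", "locus", "allele",
           "amplicon", "direction")

  structure(list(reads = reads, manifest = manifest, genotypes = genotypes),
            class = "csbt_simreads")
}

apply_errors <- function(seqs, rate) {
  for (i in seq_along(seqs)) {
    n <- nchar(seqs[i])
    k <- stats::rbinom(1, n, rate)
    if (k == 0) next
    s <- seqs[i]
    for (p in sample.int(n, k)) {
      s <- subst_base(s, p, sample(setdiff(DNA_BASES, substr(s, p, p)), 1))
    }
    seqs[i] <- s
  }
  seqs
}

#' Inject a novel allele
#'
#' Derives an underlying sequence `n_snps` substitutions away from a database
#' allele, placed inside the base allele's known interval and the assayed
#' windows (never in a primer site), and returns it as a truth row for
#' [simulate_reads()] plus the injected SNP table. The database itself is
#' left untouched: the pipeline sees reads from an allele it does not know.
#'
#' @param sim a `csbt_sim`.
#' @param base_allele name of the database allele to mutate.
#' @param n_snps 1-3 substitutions.
#' @param seed seed.
#' @param name name given to the novel truth allele.
#' @return list with `truth` (one-row tibble shaped like `sim$truth`) and
#'   `snps` (tibble `position, ref, alt`).
#' @export
inject_novel <- function(sim, base_allele, n_snps = 1L,
                         seed = sim$config$seed + 9L,
                         name = NULL) {
  set.seed(seed)
  row <- sim$truth[sim$truth$name == base_allele, ]
  if (nrow(row) != 1) abort(sprintf("unknown base allele '%s'", base_allele))
  geoms <- sim_geometry(sim$config)
  geom <- if (row$locus %in% sim$config$class1_loci) geoms$classI else geoms$drb
  primer_pos <- unlist(lapply(geom$amplicons,
                              function(a) c(a$fwd[1]:a$fwd[2], a$rev[1]:a$rev[2])))
  # candidate positions: inside the deposited interval, inside the assayed
  # read windows, outside primer sites
  windows <- group_windows_for_geom(geom)
  win_pos <- unique(unlist(lapply(windows, function(w) seq(w[1], w[2]))))
  pool <- setdiff(intersect(seq(row$known_start, row$known_end), win_pos),
                  primer_pos)
  pos <- sort(sample(pool, n_snps))
  s <- row$full_seq
  snps <- tibble(position = integer(0), ref = character(0), alt = character(0))
  for (p in pos) {
    ref <- substr(s, p, p)
    alt <- sample(setdiff(DNA_BASES, ref), 1)
    s <- subst_base(s, p, alt)
    snps <- bind_rows(snps, tibble(position = p, ref = ref, alt = alt))
  }
  nm <- name %||% render_allele_name(row$locus, c(97L, n_snps))
  list(truth = tibble(name = nm, locus = row$locus, full_seq = s,
                      known_start = row$known_start, known_end = row$known_end,
                      partial = row$partial),
       snps = snps, base = base_allele)
}

# target-length read windows for a raw geometry (target 320 nt)
group_windows_for_geom <- function(geom, target = 320L) {
  out <- list()
  for (a in geom$amplicons) {
    out[[a$gf]] <- c(a$fwd[2] + 1L, a$fwd[2] + target)
    out[[a$gr]] <- c(a$rev[1] - target, a$rev[1] - 1L)
  }
  out
}

#' Write a simulated read set to disk
#'
#' @param simreads a `csbt_simreads`.
#' @param dir output directory (created if needed).
#' @return named list of the paths written (`fastq`, `manifest`, `truth`).
#' @export
write_simulation <- function(simreads, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(fastq = file.path(dir, "reads.fastq"),
                manifest = file.path(dir, "manifest.tsv"),
                truth = file.path(dir, "truth_genotypes.tsv"))
  write_fastq(simreads$reads, paths$fastq)
  write_tsv_(simreads$manifest, paths$manifest)
  write_tsv_(simreads$genotypes, paths$truth)
  paths
}
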