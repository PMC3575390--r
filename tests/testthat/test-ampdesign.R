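test_that("variability profile counts depth and modal divergence per column", {
  aligned <- c("AAAA", "AAAC", "ACA-", "ACC-")
  p <- variability_profile(aligned)
  expect_equal(p$depth, c(4L, 4L, 4L, 2L))
  expect_equal(p$variability[1], 0)            # all agree
  expect_equal(p$variability[2], 50)           # A,A,C,C: tie broken to "A"
  expect_equal(p$consensus[2], "A")
  expect_equal(p$variability[4], 50)           # A,C,-,-: depth 2
  expect_equal(p$depth[4], 2L)
  # gap-only contributions never count towards depth
  p2 <- variability_profile(c("A-", "A-", "--", "--"))
  expect_equal(p2$depth, c(2L, 0L))
  expect_equal(p2$variability, c(0, 0))
  expect_error(variability_profile(c("AA", "AAA")), "ragged")
})

test_that("conserved windows are maximal runs above depth and below variability", {
  seqs <- rep(strrep("A", 100), 4)
  p <- variability_profile(seqs)
  expect_equal(find_conserved_windows(p, window_len = 19),
               tibble::tibble(start = 1L, end = 100L, length = 100L))
  # one variable column at 50 splits the run
  seqs2 <- c(rep(strrep("A", 100), 2),
             paste0(strrep("A", 49), "C", strrep("A", 50)),
             paste0(strrep("A", 49), "G", strrep("A", 50)))
  p2 <- variability_profile(seqs2)
  w <- find_conserved_windows(p2, window_len = 19, max_variability = 1)
  expect_equal(w$start, c(1L, 51L))
  expect_equal(w$end, c(49L, 100L))
  # no run long enough
  expect_equal(nrow(find_conserved_windows(p2, window_len = 60)), 0L)
})

test_that("amplicon spans reproduce printed insert arithmetic", {
  drb <- define_amplicon("DRB", c(61, 79), c(707, 727), locus_class = "II")
  expect_equal(drb$insert$length, 667L)
  hla1 <- define_amplicon("HLA-1", c(50, 68), c(707, 725))
  expect_equal(hla1$insert$length, 676L)
  expect_error(define_amplicon("bad", c(50, 80), c(70, 90)), "overlap")
})

test_that("per-allele primer mismatches are counted against the consensus", {
  base <- strrep("ACGT", 25)  # 100 nt
  mut <- base
  substr(mut, 15, 15) <- "A"  # inside the forward site 10-28
  aligned <- c(X1 = base, X2 = base, X3 = mut)
  amp <- define_amplicon("T", c(10, 28), c(60, 78), aligned = aligned)
  mm <- amp$fwd$per_allele_mismatches
  expect_equal(mm$mismatches[mm$name == "X3"], 1L)
  expect_equal(mm$mismatches[mm$name == "X1"], 0L)
  expect_equal(amp$rev$per_allele_mismatches$mismatches, c(0L, 0L, 0L))
})

test_that("in-silico resolution finds pairs hidden outside the coverage", {
  # five alleles; two differ only at position 95, outside coverage [1,80]
  base <- strrep("ACGT", 25)
  s2 <- base; substr(s2, 40, 40) <- "A"
  s3 <- base; substr(s3, 95, 95) <- "A"
  s4 <- base; substr(s4, 10, 10) <- "T"; substr(s4, 95, 95) <- "C"
  db <- allele_db(c("A*01:01", "A*01:02", "A*01:03", "A*02:01", "B*01:01"),
                  c(base, s2, s3, s4, base),
                  rep(1L, 5), rep(100L, 5), consensus_length = 100L)
  res <- in_silico_resolution(db, c(1, 80), digits = 4)
  expect_equal(nrow(res), 1L)
  expect_equal(res$members, "A*01:01/A*01:03")
  expect_equal(res$n_members, 2L)
  # the pair is resolved once coverage includes the distinguishing site
  expect_equal(nrow(in_silico_resolution(db, c(1, 100), digits = 4)), 0L)
  # single-allele locus contributes nothing
  expect_false(any(res$locus == "B"))
})

test_that("resolution engine agrees with the all-pairs brute-force comparator", {
  set.seed(31)
  for (rep in 1:12) {
    db <- random_full_db(sample(4:10, 1))
    cov <- sort(sample(1:80, 2))
    got <- suppressWarnings(in_silico_resolution(db, cov, digits = 4))
    expect_equal(groups_to_pairs(got, digits = 4),
                 brute_force_ambiguous_pairs(db, cov, digits = 4),
                 info = sprintf("rep %d coverage %d-%d", rep, cov[1], cov[2]))
  }
})

test_that("enlarging coverage never increases ambiguous pairs", {
  set.seed(77)
  for (rep in 1:8) {
    db <- random_full_db(8)
    n_prev <- Inf
    for (hi in c(20, 40, 60, 80)) {
      n <- length(groups_to_pairs(
        suppressWarnings(in_silico_resolution(db, c(1, hi), digits = 4))))
      expect_lte(n, n_prev)
      n_prev <- n
    }
  }
})

test_that("alleles with disjoint known regions are incomparable, with warning", {
  db <- allele_db(c("A*01:01", "A*01:02"),
                  c(strrep("A", 30), strrep("A", 30)),
                  c(1L, 60L), c(30L, 89L), consensus_length = 100L)
  expect_warning(res <- in_silico_resolution(db, c(1, 100)), "incomparable")
  expect_equal(nrow(res), 0L)
})
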