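test_that("database simulation is byte-identical given a seed", {
  sim1 <- simulate_database(sim_config(seed = 5, alleles_per_locus = 6))
  sim2 <- simulate_database(sim_config(seed = 5, alleles_per_locus = 6))
  f1 <- tempfile(); f2 <- tempfile()
  write_allele_fasta(sim1$db, f1)
  write_allele_fasta(sim2$db, f2)
  expect_identical(readLines(f1), readLines(f2))
  # different seed, different world
  sim3 <- simulate_database(sim_config(seed = 6, alleles_per_locus = 6))
  expect_false(identical(sim1$db$seq, sim3$db$seq))
})

test_that("the partial-allele fraction is honoured", {
  sim <- simulate_database(sim_config(alleles_per_locus = 10,
                                      fraction_partial = 0.5))
  per_locus <- tapply(sim$truth$partial, sim$truth$locus, sum)
  expect_true(all(per_locus == 5L))
  # partial class I records carry the exon-2/3 analog interval
  pA <- sim$truth[sim$truth$locus == "A" & sim$truth$partial, ]
  expect_true(all(pA$known_start == 104L & pA$known_end == 620L))
  pD <- sim$truth[sim$truth$locus == "DRB1" & sim$truth$partial, ]
  expect_true(all(pD$known_start == 100L & pD$known_end == 380L))
})

test_that("the designed ambiguous pair is exactly what the resolver finds", {
  sim <- simulate_database(sim_config(seed = 3, class1_loci = "A",
                                      alleles_per_locus = 8))
  pair <- sim$ambiguous_pairs[sim$ambiguous_pairs$locus == "A", ]
  # direct comparison: identical inside coverage, different outside
  t1 <- sim$truth[sim$truth$name == pair$allele1, ]
  t2 <- sim$truth[sim$truth$name == pair$allele2, ]
  expect_identical(substr(t1$full_seq, 50, 1069), substr(t2$full_seq, 50, 1069))
  expect_false(identical(t1$full_seq, t2$full_seq))
  res <- suppressWarnings(
    in_silico_resolution(sim$db[sim$db$locus == "A", ], c(50, 1069)))
  expect_equal(res$members, paste(sort(c(pair$allele1, pair$allele2)),
                                  collapse = "/"))
})

test_that("error-free reads are MID plus exact amplicon substrings", {
  sim <- simulate_database(sim_config(seed = 9, class1_loci = "A",
                                      alleles_per_locus = 6, error_rate = 0))
  gt <- tibble::tibble(sample = "S01", locus = "A",
                       allele1 = "A*01:01:01", allele2 = "A*01:01:01")
  sr <- simulate_reads(sim, gt)
  mid <- sr$manifest$mid[1]
  mol <- sim$truth$full_seq[sim$truth$name == "A*01:01:01"]
  for (r in sample(seq_len(nrow(sr$reads)), 50)) {
    read <- sr$reads[r, ]
    amp <- sim$amplicons[[read$amplicon]]
    insert <- substr(mol, amp$insert$start, amp$insert$end)
    if (read$direction == "reverse") {
      insert <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(insert)))
    }
    expect_identical(read$seq, paste0(mid, insert))
  }
})

test_that("read counts follow the 3:6:1 pooling ratio", {
  sim <- simulate_database(sim_config(seed = 2, reads_per_amplicon = 100,
                                      alleles_per_locus = 6, n_samples = 4))
  gt <- simulate_genotypes(sim, 4)
  sr <- simulate_reads(sim, gt)
  counts <- table(sr$reads$amplicon) / 4  # per sample
  # multinomial with expectation 300/600/100 per sample
  expect_equal(unname(counts[["HLA-1"]]), 300, tolerance = 0.12)
  expect_equal(unname(counts[["HLA-2"]]), 600, tolerance = 0.12)
  expect_equal(unname(counts[["DRB"]]), 100, tolerance = 0.25)
  expect_equal(sum(table(sr$reads$amplicon)), 4 * 1000)
})

test_that("dropout triples produce zero reads for that combination", {
  drop <- tibble::tibble(sample = "S01", allele = "A*01:03",
                         amplicon = "HLA-2")
  sim <- simulate_database(sim_config(seed = 4, class1_loci = "A",
                                      alleles_per_locus = 6, dropout = drop))
  gt <- tibble::tibble(sample = c("S01", "S02"), locus = "A",
                       allele1 = "A*01:03", allele2 = "A*01:04")
  sr <- simulate_reads(sim, gt)
  hit <- sr$reads[sr$reads$sample == "S01" & sr$reads$allele == "A*01:03" &
                    sr$reads$amplicon == "HLA-2", ]
  expect_equal(nrow(hit), 0L)
  # the same allele still yields HLA-2 reads in the unaffected sample
  other <- sr$reads[sr$reads$sample == "S02" & sr$reads$allele == "A*01:03" &
                      sr$reads$amplicon == "HLA-2", ]
  expect_gt(nrow(other), 0L)
})

test_that("MID tags are uniform length with pairwise distance >= 3", {
  mids <- make_mids(24, length = 10, seed = 8)
  expect_true(all(nchar(mids$mid) == 10))
  for (i in seq_len(nrow(mids) - 1)) {
    d <- vapply(mids$mid[(i + 1):nrow(mids)], function(m) {
      sum(strsplit(m, "")[[1]] != strsplit(mids$mid[i], "")[[1]])
    }, integer(1))
    expect_true(all(d >= 3))
  }
})

test_that("substitution errors appear at roughly the configured rate", {
  sim <- simulate_database(sim_config(seed = 12, class1_loci = "A",
                                      alleles_per_locus = 6,
                                      error_rate = 0.01,
                                      reads_per_amplicon = 30))
  gt <- tibble::tibble(sample = "S01", locus = "A",
                       allele1 = "A*01:01:01", allele2 = "A*01:01:01")
  sr <- simulate_reads(sim, gt)
  mid <- sr$manifest$mid[1]
  mol <- sim$truth$full_seq[sim$truth$name == "A*01:01:01"]
  mism <- 0L; total <- 0L
  for (r in seq_len(nrow(sr$reads))) {
    read <- sr$reads[r, ]
    amp <- sim$amplicons[[read$amplicon]]
    insert <- substr(mol, amp$insert$start, amp$insert$end)
    if (read$direction == "reverse") {
      insert <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(insert)))
    }
    clean <- paste0(mid, insert)
    a <- strsplit(read$seq, "")[[1]]; b <- strsplit(clean, "")[[1]]
    mism <- mism + sum(a != b); total <- total + length(a)
  }
  expect_equal(mism / total, 0.01, tolerance = 0.3)
})
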