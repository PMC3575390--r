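make_prepped <- function(world) {
  dm <- demultiplex(world$sr$reads, world$sr$manifest, world$sim$amplicons)
  trim_filter(dm$assigned, default_trim_policy(world$sim$amplicons))$reads
}

test_that("exact mapping assigns FULL / EXTEND / no-entry correctly", {
  world <- small_world(seed = 13)
  sim <- world$sim
  reads <- make_prepped(world)
  cdb <- sim$db[sim$db$locus == "A", ]
  attr(cdb, "consensus_length") <- attr(sim$db, "consensus_length")
  class(cdb) <- class(sim$db)
  amps <- sim$amplicons[c("HLA-1", "HLA-2")]
  m <- map_reads_exact(reads[reads$amplicon %in% names(amps), ], cdb, amps)

  # every truth read maps FULL to its own allele when the allele is
  # full-length, and with the partial-row pattern otherwise
  truth <- world$sr$reads
  full_alleles <- sim$truth$name[!sim$truth$partial & sim$truth$locus == "A"]
  joined <- merge(m, truth[, c("id", "allele")], by = "id",
                  suffixes = c("", ".truth"))
  own <- joined[joined$allele == joined$allele.truth, ]
  expect_true(all(own$condition[own$allele %in% full_alleles] == "FULL"))
  partials <- setdiff(unique(truth$allele[truth$locus == "A"]), full_alleles)
  if (length(partials)) {
    po <- own[own$allele %in% partials, ]
    expect_setequal(unique(po$condition[po$group %in% c("1F", "1R")]), "EXTEND")
    expect_true(all(po$condition[po$group == "2F"] == "FULL"))
    expect_false(any(po$group == "2R"))
  }

  # a read one mismatch away from everything yields no entries
  bad <- reads[reads$group == "2F", ][1, ]
  substr(bad$seq, 100, 100) <- setdiff(c("A", "C", "G", "T"),
                                       substr(bad$seq, 100, 100))[1]
  bad$id <- "mutant"
  expect_equal(nrow(map_reads_exact(bad, cdb, amps)), 0L)

  expect_error(map_reads_exact(reads[1, ], cdb[0, ], amps), "empty reference")
})

test_that("mapping agrees with the independent per-base oracle", {
  for (seed in c(3, 14)) {
    world <- small_world(seed = seed, n_samples = 1, reads = 15)
    sim <- world$sim
    reads <- make_prepped(world)
    m <- map_reads_exact(reads, sim$db, sim$amplicons)
    o <- oracle_map(reads, sim$db, sim$amplicons)
    key <- function(x) sort(paste(x$id, x$allele, x$condition))
    expect_identical(key(m), key(o))
  }
})

test_that("key restriction is sound and flags key-less samples", {
  world <- small_world(seed = 17)
  sim <- world$sim
  reads <- make_prepped(world)
  cdb <- sim$db[sim$db$locus == "A", ]
  attr(cdb, "consensus_length") <- attr(sim$db, "consensus_length")
  class(cdb) <- class(sim$db)
  amps <- sim$amplicons[c("HLA-1", "HLA-2")]
  m <- map_reads_exact(reads[reads$amplicon %in% names(amps), ], cdb, amps)
  rr <- restrict_references(m, cdb, key_group = "2F")
  expect_true(rr$detected)
  # soundness: restriction never removes an allele unrestricted mapping keeps
  non_key <- unique(m$allele[m$group != "2F"])
  m_restricted <- map_reads_exact(
    reads[reads$amplicon %in% names(amps) & reads$group != "2F", ],
    rr$db, amps)
  # alleles in the candidate set keep identical non-key matches
  in_cand <- m[m$group != "2F" & m$allele %in% rr$alleles, ]
  expect_setequal(paste(m_restricted$id, m_restricted$allele),
                  paste(in_cand$id, in_cand$allele))
  # candidate set contains at least the truth alleles
  truth_a <- unique(world$sr$reads$allele[world$sr$reads$locus == "A"])
  expect_true(all(truth_a %in% rr$alleles))
  # no key reads at all
  rr0 <- restrict_references(m[m$group == "1F", ], cdb, key_group = "2F")
  expect_false(rr0$detected)
  expect_equal(nrow(rr0$db), 0L)
})

test_that("expected matrix reproduces the published condition patterns", {
  L <- 1100L
  db <- allele_db(c("A*01:01", "A*01:02"),
                  c(strrep("A", L), strrep("A", 517)),
                  c(1L, 104L), c(L, 620L), consensus_length = L)
  amps <- list(
    `HLA-1` = define_amplicon("HLA-1", c(50, 68), c(707, 725),
                              group_fwd = "1F", group_rev = "1R",
                              loci = "A"),
    `HLA-2` = define_amplicon("HLA-2", c(145, 163), c(1051, 1069),
                              group_fwd = "2F", group_rev = "2R", loci = "A"))
  pol <- default_trim_policy(amps)
  em <- expected_matrix(db, amps, pol)
  wide <- tidyr::pivot_wider(em, names_from = "group",
                             values_from = "expected")
  fl <- wide[wide$allele == "A*01:01", ]
  expect_equal(unlist(fl[c("1F", "1R", "2F", "2R")], use.names = FALSE),
               rep("FULL", 4))
  # exon-2/3-only analog: (1F:0, 1R:0, 2F:1, 2R:.)
  px <- wide[wide$allele == "A*01:02", ]
  expect_equal(unlist(px[c("1F", "1R", "2F", "2R")], use.names = FALSE),
               c("EXTEND", "EXTEND", "FULL", "NONE"))
})

test_that("class I matrix keeps inner-join rows and outer-joins 2R", {
  world <- small_world(seed = 23, n_samples = 2, reads = 60)
  sim <- world$sim
  reads <- make_prepped(world)
  cdb <- sim$db[sim$db$locus == "A", ]
  attr(cdb, "consensus_length") <- attr(sim$db, "consensus_length")
  class(cdb) <- class(sim$db)
  amps <- sim$amplicons[c("HLA-1", "HLA-2")]
  pol <- default_trim_policy(amps)
  m <- map_reads_exact(reads[reads$amplicon %in% names(amps), ], cdb, amps)
  em <- expected_matrix(cdb, amps, pol)
  mat <- build_match_matrix_classI(m, em)
  # truth alleles have rows matching their expected pattern
  truth <- unique(world$sr$reads[world$sr$reads$locus == "A",
                                 c("sample", "allele")])
  for (r in seq_len(nrow(truth))) {
    row <- mat[mat$sample == truth$sample[r] & mat$allele == truth$allele[r], ]
    expect_equal(nrow(row), 4L)
    exp_row <- attr(mat, "expected")
    exp_row <- exp_row[exp_row$allele == truth$allele[r], ]
    cmp <- merge(row, exp_row, by = c("allele", "locus", "group"))
    expect_equal(cmp$condition, cmp$expected)
    expect_true(all(cmp$reads[cmp$expected != "NONE"] > 0))
    expect_true(all(cmp$reads[cmp$expected == "NONE"] == 0))
  }
})

test_that("an allele with 2F support but no 1F reads is dropped by the inner join", {
  drop <- tibble::tibble(sample = "S01", allele = "A*01:03",
                         amplicon = "HLA-1")
  cfg <- sim_config(seed = 25, class1_loci = "A", alleles_per_locus = 6,
                    reads_per_amplicon = 60, dropout = drop)
  sim <- simulate_database(cfg)
  gt <- tibble::tibble(sample = "S01", locus = c("A", "DRB1"),
                       allele1 = c("A*01:03", "DRB1*01:01:01"),
                       allele2 = c("A*01:04", "DRB1*01:01:01"))
  sr <- simulate_reads(sim, gt)
  dm <- demultiplex(sr$reads, sr$manifest, sim$amplicons)
  reads <- trim_filter(dm$assigned, default_trim_policy(sim$amplicons))$reads
  cdb <- sim$db[sim$db$locus == "A", ]
  attr(cdb, "consensus_length") <- attr(sim$db, "consensus_length")
  class(cdb) <- class(sim$db)
  amps <- sim$amplicons[c("HLA-1", "HLA-2")]
  m <- map_reads_exact(reads[reads$amplicon %in% names(amps), ], cdb, amps)
  em <- expected_matrix(cdb, amps, default_trim_policy(amps))
  mat <- build_match_matrix_classI(m, em)
  expect_false("A*01:03" %in% mat$allele[mat$sample == "S01"])
  expect_true("A*01:04" %in% mat$allele[mat$sample == "S01"])
})

test_that("class II forward reads key the matrix; reverse-only gives no row", {
  world <- small_world(seed = 29, n_samples = 2, reads = 60,
                       fraction_partial = 0.4)
  sim <- world$sim
  reads <- make_prepped(world)
  ddb <- sim$db[sim$db$locus == "DRB1", ]
  attr(ddb, "consensus_length") <- attr(sim$db, "consensus_length")
  class(ddb) <- class(sim$db)
  amps <- sim$amplicons["DRB"]
  pol <- default_trim_policy(amps)
  em <- expected_matrix(ddb, amps, pol)
  # exon-2-only analog expects EXTEND_BOTH forward, NONE reverse
  part <- sim$truth$name[sim$truth$locus == "DRB1" & sim$truth$partial][1]
  expect_equal(em$expected[em$allele == part & em$group == "DRB-F"],
               "EXTEND_BOTH")
  expect_equal(em$expected[em$allele == part & em$group == "DRB-R"], "NONE")
  m <- map_reads_exact(reads[reads$amplicon == "DRB", ], ddb, amps)
  mat <- build_match_matrix_classII(m, em)
  # full-length truth alleles show (F:1, R:1)
  full_truth <- intersect(
    unique(world$sr$reads$allele[world$sr$reads$locus == "DRB1"]),
    sim$truth$name[!sim$truth$partial])
  for (al in full_truth) {
    row <- mat[mat$allele == al & mat$reads > 0, ]
    expect_setequal(unique(row$condition), "FULL")
  }
  # reverse-only support cannot create a row
  m_revonly <- m[m$group == "DRB-R", ]
  mat2 <- build_match_matrix_classII(m_revonly, em)
  expect_equal(nrow(mat2), 0L)
})

test_that("codon annotation classifies substitutions", {
  # third-position wobble in a 4-codon toy ORF: CTT -> CTG is still Leu
  toy <- "ATGCTTGGGTAA"
  a <- annotate_variant(toy, 1, 6, "G")
  expect_equal(a$consequence, "synonymous")
  expect_equal(a$codon, 2L)
  expect_equal(a$ref_aa, "L")
  # identity
  expect_equal(annotate_variant(toy, 1, 6, "T")$consequence, "identity")
  # missense and nonsense
  expect_equal(annotate_variant(toy, 1, 7, "T")$consequence, "missense")
  expect_equal(annotate_variant("ATGTGTGGG", 1, 6, "A")$consequence,
               "nonsense")
  # position 587 sits in codon 196 regardless of sequence content
  L <- strrep("CCG", 400)
  a587 <- annotate_variant(L, 1, 587, "T")
  expect_equal(a587$codon, 196L)
  expect_error(annotate_variant(toy, 1, 99, "A"), "outside")
  # partial reference: codon must be fully known
  expect_error(annotate_variant(substr(toy, 2, 12), 2, 3, "A"),
               "not fully inside")
})

test_that("novel alleles are recovered with exact SNP coordinates", {
  cfg <- sim_config(seed = 33, class1_loci = "A", alleles_per_locus = 6,
                    reads_per_amplicon = 40)
  sim <- simulate_database(cfg)
  nv <- inject_novel(sim, "A*01:04", n_snps = 2, seed = 101)
  gt <- tibble::tibble(sample = "S01", locus = c("A", "DRB1"),
                       allele1 = c(nv$truth$name, "DRB1*01:01:01"),
                       allele2 = c("A*01:01:01", "DRB1*01:01:01"))
  sr <- simulate_reads(sim, gt, extra_alleles = nv$truth)
  run <- run_pipeline(sim$db, sr$reads, sr$manifest, sim$amplicons)
  expect_gt(nrow(run$novel), 0L)
  hit <- run$novel[run$novel$nearest_allele == "A*01:04", ]
  expect_equal(nrow(hit), 1L)
  got <- hit$snps[[1]]
  expect_setequal(got$position, nv$snps$position)
  expect_equal(got$alt_base[order(got$position)], nv$snps$alt)
  expect_equal(got$ref_base[order(got$position)], nv$snps$ref)
  # the partner allele is still called normally
  calls <- run$genotypes
  expect_true(any(vapply(calls$members[calls$sample == "S01" &
                                         calls$locus == "A"],
                         function(m) "A*01:01:01" %in% m, logical(1))))
})

test_that("clusters below the minimum size are not reported", {
  world <- small_world(seed = 35, n_samples = 1, reads = 30)
  sim <- world$sim
  amps <- sim$amplicons[c("HLA-1", "HLA-2")]
  # two identical unmatched reads < min_cluster of 3
  mol <- sim$truth$full_seq[sim$truth$name == "A*01:04"]
  s <- substr(mol, 164, 483)
  substr(s, 50, 50) <- setdiff(c("A", "C", "G", "T"), substr(s, 50, 50))[1]
  um <- tibble::tibble(id = c("u1", "u2"), sample = "S01",
                       amplicon = "HLA-2", direction = "forward",
                       group = "2F", seq = s)
  nv <- detect_novel(um, sim$db, amps, policy = call_policy())
  expect_equal(nrow(nv), 0L)
  # with three copies the cluster qualifies
  um3 <- dplyr::bind_rows(um, dplyr::mutate(um[1, ], id = "u3"))
  nv3 <- detect_novel(um3, sim$db, amps, policy = call_policy())
  expect_gt(nrow(nv3), 0L)
  expect_equal(nv3$n_snps[1], 1L)
})
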