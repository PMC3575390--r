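#' Run the full cSBT genotyping pipeline
#'
#' Executes demultiplex -> trim -> map -> match matrix -> genotype call ->
#' novel detection. Mapping is forward-keyed per locus class: the key read
#' group (class I: the amplicon-2 forward reads; class II: the forward reads)
#' is mapped against the full reference set, and for each sample the key
#' matches dictate the candidate allele subset evaluated for the remaining
#' read groups.
#'
#' @param db a `csbt_db` or FASTA path.
#' @param reads read tibble (`id`, `seq`) or FASTQ path.
#' @param manifest MID manifest tibble (`sample, mid_id, mid`) or TSV path.
#' @param amplicons named list of `csbt_amplicon`.
#' @param policy a [call_policy()].
#' @param trim a trim-policy tibble; defaults to
#'   [default_trim_policy()] over `amplicons`.
#' @param max_mid_mismatch,max_primer_mismatch demultiplexing tolerances.
#' @param outdir optional output directory; when given, genotype/matrix/novel
#'   TSVs, a JSON run summary and a run log are written there.
#' @return an object of class `csbt_run`: list with `genotypes`
#'   (`csbt_calls`), `matrix` (long match-matrix tibble), `matches`,
#'   `novel`, `demux_stats`, `trim_stats`, `accounting` (per-read terminal
#'   categories), `log` (per-stage counts) and the inputs used.
#' @export
run_pipeline <- function(db, reads, manifest, amplicons,
                         policy = call_policy(),
                         trim = default_trim_policy(amplicons),
                         max_mid_mismatch = 0L, max_primer_mismatch = 2L,
                         outdir = NULL) {
  if (is.character(db)) db <- load_allele_fasta(db)
  if (is.character(reads)) reads <- read_fastq(reads)
  if (is.character(manifest)) manifest <- read_tsv_(manifest)

  log <- list()
  note <- function(stage, count) {
    log[[length(log) + 1L]] <<- tibble(stage = stage, count = as.integer(count))
  }
  note("input_reads", nrow(reads))

  dm <- demultiplex(reads, manifest, amplicons,
                    max_mid_mismatch = max_mid_mismatch,
                    max_primer_mismatch = max_primer_mismatch)
  note("assigned", nrow(dm$assigned))
  note("unassigned", nrow(dm$unassigned))

  tr <- trim_filter(dm$assigned, trim)
  note("trimmed_kept", nrow(tr$reads))
  note("length_rejected", nrow(dm$assigned) - nrow(tr$reads))

  samples <- sort(unique(manifest$sample))
  windows <- group_windows(amplicons, trim)

  classes <- split(amplicons,
                   vapply(amplicons, `[[`, character(1), "locus_class"))
  all_matches <- list()
  all_matrix <- list()
  all_calls <- list()
  all_unmatched <- list()
  all_novel <- list()

  for (cls in names(classes)) {
    amps <- classes[[cls]]
    names(amps) <- vapply(amps, `[[`, character(1), "name")
    loci <- unique(unlist(lapply(amps, `[[`, "loci")))
    cdb <- db_subset(db, db$locus %in% loci)
    key_amp <- pick_key_amplicon(amps, cdb)
    key_group <- key_amp$group_fwd
    creads <- tr$reads |>
      filter(.data$amplicon %in% names(amps))
    key_reads <- creads |> filter(.data$group == key_group)
    other_reads <- creads |> filter(.data$group != key_group)

    key_matches <- map_reads_exact(key_reads, cdb, amps,
                                   anchor = policy$anchor)
    other_matches <- if (nrow(other_reads) > 0) {
      map_reads_exact(other_reads, cdb, amps, anchor = policy$anchor)
    } else {
      key_matches[0, ]
    }
    # per-sample restriction: non-key matches only count against that
    # sample's key-matching candidate set; the unrestricted matches are kept
    # for amplicon-discordance screening
    cand <- key_matches |>
      distinct(.data$sample, .data$allele)
    matches_all <- bind_rows(key_matches, other_matches)
    other_matches <- other_matches |>
      semi_join(cand, by = c("sample", "allele"))
    matches <- bind_rows(key_matches, other_matches)

    expd <- expected_matrix(cdb, amps, trim, anchor = policy$anchor)
    mat <- if (cls == "I") {
      inner <- setdiff(unlist(lapply(amps, function(a)
        if (a$name != key_amp$name) c(a$group_fwd, a$group_rev))), NULL)
      build_match_matrix_classI(matches, expd, key_group = key_group,
                                inner_groups = inner,
                                outer_groups = key_amp$group_rev,
                                discordant_from = matches_all)
    } else {
      build_match_matrix_classII(matches, expd, key_group = key_group,
                                 reverse_groups = key_amp$group_rev)
    }

    totals <- matches |>
      distinct(.data$id, .data$sample, .data$locus, .data$group) |>
      count(.data$sample, .data$locus, .data$group, name = "total")
    calls <- call_genotype(mat, cdb, windows, policy = policy,
                           samples = samples, group_totals = totals)

    unmatched <- creads |>
      anti_join(matches |> distinct(.data$id), by = "id")
    # reads in a group where a called allele expects NONE are extension reads
    # beyond a partial reference, not novel-allele evidence
    called_alleles <- calls |>
      filter(!.data$confidence %in% c("not_detected", "amplicon_discordant")) |>
      select("sample", "members") |>
      tidyr::unnest_longer("members", values_to = "allele")
    ext_groups <- called_alleles |>
      inner_join(expd |> filter(.data$expected == "NONE"),
                 by = "allele", relationship = "many-to-many") |>
      distinct(.data$sample, .data$group)
    nov <- detect_novel(unmatched |> anti_join(ext_groups,
                                               by = c("sample", "group")),
                        cdb, amps, policy = policy)

    all_matches[[cls]] <- matches
    all_matrix[[cls]] <- as_tibble(mat)
    all_calls[[cls]] <- calls
    all_unmatched[[cls]] <- unmatched
    all_novel[[cls]] <- nov
  }

  matches <- bind_rows(all_matches)
  genotypes <- bind_rows(all_calls) |>
    arrange(.data$sample, .data$locus, .data$call)
  class(genotypes) <- c("csbt_calls", class(genotypes))
  novel <- bind_rows(all_novel)
  unmatched <- bind_rows(all_unmatched)

  note("matched_reads", dplyr::n_distinct(matches$id))
  note("unmatched_reads", nrow(unmatched))
  note("genotype_calls", sum(!genotypes$confidence %in% "not_detected"))
  note("novel_candidates", nrow(novel))

  # terminal accounting: every input read lands in exactly one category
  accounting <- bind_rows(
    tibble(id = dm$unassigned$id, category = "unassigned"),
    dm$assigned |>
      anti_join(tr$reads, by = "id") |>
      transmute(id = .data$id, category = "length_rejected"),
    matches |> distinct(.data$id) |>
      mutate(category = "called_supporting"),
    unmatched |> transmute(id = .data$id, category = "unmatched_novel")
  )

  run <- structure(list(
    genotypes = genotypes,
    matrix = bind_rows(all_matrix),
    matches = matches,
    novel = novel,
    demux_stats = dm,
    trim_stats = tr$stats,
    trimmed_reads = tr$reads,
    accounting = accounting,
    log = bind_rows(log),
    db = db, amplicons = amplicons, policy = policy, trim = trim,
    samples = samples
  ), class = "csbt_run")

  if (!is.null(outdir)) write_run(run, outdir)
  run
}

# the key amplicon is the one whose forward window lies inside the most
# alleles' known intervals (ties broken by later window start) — for the
# published design that is HLA-2, whose 2F reads cover the exon 2/3 region
# every named allele deposits
pick_key_amplicon <- function(amps, db) {
  if (length(amps) == 1) return(amps[[1]])
  score <- vapply(amps, function(a) {
    ws <- a$fwd$end + 1L
    sum(db$known_start <= ws)  # alleles whose known region reaches the window
  }, numeric(1))
  starts <- vapply(amps, function(a) a$fwd$end, numeric(1))
  amps[[order(-score, -starts)[1]]]
}

#' Write a run's report bundle
#'
#' @param run a `csbt_run`.
#' @param outdir output directory.
#' @return `outdir`, invisibly.
#' @export
write_run <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  g <- run$genotypes |>
    mutate(members = purrr::map_chr(.data$members, paste, collapse = "/")) |>
    select(-"flag_multi")
  write_tsv_(g, file.path(outdir, "genotypes.tsv"))
  write_tsv_(run$matrix, file.path(outdir, "match_matrix.tsv"))
  if (nrow(run$novel) > 0) {
    nv <- run$novel |> select(-"snps")
    write_tsv_(nv, file.path(outdir, "novel_candidates.tsv"))
    write_tsv_(run$novel |>
                 select("sample", "nearest_allele", "snps") |>
                 tidyr::unnest("snps"),
               file.path(outdir, "novel_snps.tsv"))
    fa <- Biostrings::DNAStringSet(run$novel$consensus_seq)
    names(fa) <- sprintf("%s_novel_near_%s", run$novel$sample,
                         run$novel$nearest_allele)
    Biostrings::writeXStringSet(fa, file.path(outdir, "novel_candidates.fasta"))
  }
  write_tsv_(run$log, file.path(outdir, "run_log.tsv"))
  jsonlite::write_json(as.list(glance(run)),
                       file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' Per-sample and per-amplicon read metrics
#'
#' Mean and sample (n-1) standard deviation of assigned reads per sample,
#' overall and per amplicon, plus per-stage totals. A single sample reports
#' sd 0 with a note; an empty run reports zeros.
#'
#' @param run a `csbt_run`.
#' @return tibble `(metric, n, mean, sd, total, note)`.
#' @export
summarize_run <- function(run) {
  assigned <- run$demux_stats$assigned
  per_sample <- assigned |> count(.data$sample, name = "reads")
  per_amp <- assigned |> count(.data$sample, .data$amplicon, name = "reads")
  row <- function(metric, x) {
    n <- length(x)
    tibble(metric = metric, n = n,
           mean = if (n == 0) 0 else mean(x),
           sd = if (n >= 2) stats::sd(x) else 0,
           total = sum(x),
           note = if (n == 1) "single sample: sd reported as 0"
                  else NA_character_)
  }
  out <- row("reads_per_sample", per_sample$reads)
  for (amp in sort(unique(per_amp$amplicon))) {
    out <- bind_rows(out, row(sprintf("reads_per_sample[%s]", amp),
                              per_amp$reads[per_amp$amplicon == amp]))
  }
  stage <- run$log |>
    mutate(metric = paste0("stage_total[", .data$stage, "]"),
           n = NA_integer_, mean = NA_real_, sd = NA_real_,
           total = .data$count, note = NA_character_) |>
    select("metric", "n", "mean", "sd", "total", "note")
  bind_rows(out, stage)
}

# broom-style accessors -------------------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a pipeline run into its genotype table
#'
#' @param x a `csbt_run`.
#' @param ... unused.
#' @return the genotype call tibble with `members` flattened to a string.
#' @method tidy csbt_run
#' @export
tidy.csbt_run <- function(x, ...) {
  x$genotypes |>
    mutate(members = purrr::map_chr(.data$members, paste, collapse = "/")) |>
    as_tibble()
}

#' One-row summary of a pipeline run
#'
#' @param x a `csbt_run`.
#' @param ... unused.
#' @return one-row tibble of run-level counts.
#' @method glance csbt_run
#' @export
glance.csbt_run <- function(x, ...) {
  g <- x$genotypes
  tibble(
    n_reads = x$log$count[x$log$stage == "input_reads"],
    n_assigned = x$log$count[x$log$stage == "assigned"],
    n_trimmed = x$log$count[x$log$stage == "trimmed_kept"],
    n_samples = length(x$samples),
    n_loci = dplyr::n_distinct(x$db$locus),
    n_calls = sum(!g$confidence %in% "not_detected"),
    n_unambiguous = sum(g$confidence == "unambiguous"),
    n_ambiguous_set = sum(g$confidence == "ambiguous_set"),
    n_low_stringency = sum(g$confidence == "low_stringency"),
    n_amplicon_discordant = sum(g$confidence == "amplicon_discordant"),
    n_not_detected = sum(g$confidence == "not_detected"),
    n_novel = nrow(x$novel)
  )
}

#' @export
print.csbt_run <- function(x, ...) {
  cat("<csbt_run>\n")
  print(glance(x))
  invisible(x)
}

# plotting ---------------------------------------------------------------

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a variability profile
#'
#' Depth of coverage as a grey area with percent variability overlaid in red,
#' the display used to locate conserved primer windows.
#'
#' @param object a `csbt_profile`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot csbt_profile
#' @export
autoplot.csbt_profile <- function(object, ...) {
  n <- attr(object, "n_alleles")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position)) +
    ggplot2::geom_area(ggplot2::aes(y = 100 * .data$depth / n),
                       fill = "grey70") +
    ggplot2::geom_line(ggplot2::aes(y = .data$variability), colour = "red") +
    ggplot2::labs(x = "consensus position",
                  y = "depth (% of alleles, grey) / variability (%, red)") +
    ggplot2::theme_minimal()
}

confidence_colors <- c(
  unambiguous = "#2c7bb6", ambiguous_set = "#1a9641",
  low_stringency = "#fdae61", amplicon_discordant = "#f1b6da",
  putative_novel = "#7b3294", not_detected = "grey80"
)

#' Plot genotype calls as a confidence-coloured table
#'
#' One tile per (sample, locus, call), coloured by the confidence category —
#' the genotyping-table display with blue unambiguous calls, green ambiguity
#' sets, orange low-stringency recoveries, pink amplicon-discordant alleles
#' and grey not-detected cells.
#'
#' @param calls a `csbt_calls` tibble.
#' @return a ggplot.
#' @export
plot_genotype_calls <- function(calls) {
  d <- calls |>
    group_by(.data$sample, .data$locus) |>
    mutate(slot = dplyr::row_number()) |>
    ungroup() |>
    mutate(label = dplyr::coalesce(.data$call, ""))
  ggplot2::ggplot(d, ggplot2::aes(x = interaction(.data$locus, .data$slot),
                                  y = .data$sample,
                                  fill = .data$confidence)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 2.5) +
    ggplot2::scale_fill_manual(values = confidence_colors) +
    ggplot2::labs(x = "locus / call slot", y = "sample") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname plot_genotype_calls
#' @param object a `csbt_calls` tibble.
#' @param ... unused.
#' @method autoplot csbt_calls
#' @export
autoplot.csbt_calls <- function(object, ...) plot_genotype_calls(object)

#' @param object a `csbt_run`.
#' @param ... unused.
#' @rdname plot_genotype_calls
#' @method autoplot csbt_run
#' @export
autoplot.csbt_run <- function(object, ...) plot_genotype_calls(object$genotypes)

# config-driven entry point ----------------------------------------------

#' Run the pipeline from a YAML configuration
#'
#' The configuration carries the input paths (`db`, `reads`, `manifest`,
#' `outdir`), the amplicon definitions (`name`, `fwd: [start, end]`,
#' `rev: [start, end]`, `fwd_seq`, `rev_seq`, `group_fwd`, `group_rev`,
#' `locus_class`, `loci`, optional `adapter_overhead`) and optional `trim`
#' (`target`, `min`, `max`) and `calling` (`mode`, `min_reads`, `anchor`,
#' `hom_fraction`, `novel_min_cluster`, `novel_max_snps`) blocks. Every value
#' is validated before any stage runs, so a run is reproducible from its
#' config plus inputs.
#'
#' @param config YAML path or an equivalent nested list.
#' @return a `csbt_run` (see [run_pipeline()]).
#' @export
run_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (key in c("db", "reads", "manifest", "amplicons")) {
    if (is.null(config[[key]])) abort(sprintf("config is missing '%s'", key))
  }
  amps <- list()
  for (a in config$amplicons) {
    amps[[a$name]] <- define_amplicon(
      a$name, unlist(a$fwd), unlist(a$rev),
      adapter_overhead = a$adapter_overhead %||% 35L,
      group_fwd = a$group_fwd %||% paste0(a$name, "-F"),
      group_rev = a$group_rev %||% paste0(a$name, "-R"),
      locus_class = a$locus_class %||% "I",
      loci = unlist(a$loci),
      fwd_seq = a$fwd_seq, rev_seq = a$rev_seq)
  }
  trim_cfg <- config$trim %||% list()
  trim <- default_trim_policy(amps,
                              target = trim_cfg$target %||% 320L,
                              min = trim_cfg$min %||% 300L,
                              max = trim_cfg$max %||% 350L)
  cc <- config$calling %||% list()
  policy <- call_policy(mode = cc$mode %||% "stringent",
                        min_reads = cc$min_reads %||% 3L,
                        anchor = cc$anchor %||% 30L,
                        hom_fraction = cc$hom_fraction %||% 0.8,
                        novel_min_cluster = cc$novel_min_cluster %||% 3L,
                        novel_max_snps = cc$novel_max_snps %||% 3L)
  run_pipeline(config$db, config$reads, config$manifest, amps,
               policy = policy, trim = trim,
               max_mid_mismatch = config$max_mid_mismatch %||% 0L,
               max_primer_mismatch = config$max_primer_mismatch %||% 2L,
               outdir = config$outdir)
}
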