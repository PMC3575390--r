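---
title: "cSBT: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cSBT: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csbt)
```

## The genotyping model

cSBT genotypes the classical HLA loci from cDNA amplicon reads mapped at
100% identity. The decisive modelling fact is that reference alleles are
deposited over *heterogeneous extents* of the open reading frame: a minority
are full-length, the majority cover only exons 2–3 (class I) or exon 2
(DRB). A read therefore has a *typed* relationship with each reference, not
just a hit/miss:

* `FULL` ("1") — the read's genomic window lies inside the allele's known
  interval and the read equals the reference there, base for base;
* `EXTEND` ("0") — the read matches perfectly over the overlap but carries
  positions the reference does not know (one side; `EXTEND_BOTH` when the
  read overhangs both ends, the normal case for class II forward reads
  against exon-2-only references);
* `NONE` (".") — the window misses the known interval (below the anchor
  minimum), so no match can be expected.

Every allele's expected row over the read groups (class I: 1F, 1R, 2F, 2R;
class II: F, R) is computed from interval geometry alone
(`expected_matrix()`), never hard-coded per allele class, so arbitrary
partial alleles are handled. A full-length class I allele expects
`(1,1,1,1)`; an exon-2/3-only allele expects `(0,0,1,.)`.

Mapping is keyed: class I analysis starts from the 2F reads because the 2F
window lies inside every named allele's deposited sequence; alleles with at
least one perfect 2F match form the candidate set for all other groups. The
key admits any 0-mismatch condition (`FULL` or `EXTEND`), which coincides
with `FULL` whenever references cover the key window — the published
behaviour — while remaining defined for degenerate databases. In the
original workflow the restriction cut BLAT time from thousands of references
to hundreds; here it is also what gives `amplicon_discordant` its meaning:
an allele supported by both amplicon-1 groups but absent from the key is
reported as a flagged candidate rather than silently missed (the documented
forward-primer-mismatch failure mode of a key amplicon).

An allele is *called* when its observed row equals its expected row and each
expected group carries enough reads. Called alleles that are
indistinguishable over the region actually assayed for that sample are
merged into a slash-joined ambiguity set. The comparison region is the union
of read-group windows with observed support, so amplicon dropout narrows —
never widens — the claimed resolution.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `min_reads` (stringent) | 3 | reads/group | smallest count clearly separable from carry-over noise; the source data's per-group means ranged from ~900 down to ~90 reads and no threshold was published, so it is configurable |
| low-stringency minimum | 1 | reads/group | the published "allele-specific read groups of any number" rescue mode; confidence is downgraded |
| `anchor` | 30 | nt | minimum perfect overlap for an `EXTEND` call; short anchors make coincidental perfect overlaps likely (4^30 >> database size), long anchors would void legitimate partial matches |
| trim target / window | 320 / 300–350 | nt | the published standardized trimmed-read lengths ("between 300 and 350 bp depending on the amplicon") |
| MID mismatches | 0 | nt | generated tags have pairwise Hamming distance ≥ 3, so exact matching is safe; 1 is allowed for real tag sets |
| primer mismatches | 2 | nt | tolerates the documented single-base primer-site variants (e.g. the DRB3 C74G class) without misrouting reads |
| `hom_fraction` | 0.8 | fraction | a single-allele locus is reported homozygous-consistent when the allele holds ≥ 80% of that locus's mapped reads; below it the locus is flagged for review, codifying what was previously manual interrogation |
| `novel_min_cluster` / `novel_max_snps` | 3 / 3 | reads / SNPs | a novel candidate needs ≥ 3 identical unmatched reads and a nearest reference within 3 substitutions |
| conserved-window search | 18 nt, ≤ 1% variability, ≥ 50% depth | — | typical gene-specific primer length; no parameters were published for the profile scan, these are exposed as arguments |

Coordinates are 1-based inclusive throughout, so printed spans verify by
arithmetic: an insert from 50 to 725 has length 676; with 35 nt of fusion
overhead per end (25 nt platform adapter + 10 nt MID) the final products of
the three amplicons are 746, 995 and 737 nt.

## What the simulator emulates — and what it does not

`simulate_database()` / `simulate_reads()` generate the structural
properties the pipeline's logic depends on: multiple loci on two coordinate
frames; alleles as a shared consensus with private plus Binomial(per-base
rate 0.01) substitutions placed outside the conserved primer windows; a
configurable fraction (default 0.25) of alleles deposited only over
exon-analog sub-intervals (class I 104–620, DRB 100–380); a designed
ambiguous pair per locus differing only outside the assayed coverage;
diploid genotypes; 10 nt MIDs at pairwise distance ≥ 3; full-length amplicon
reads pooled 3:6:1 across the three amplicons (multinomial per sample);
optional uniform substitution errors, per-(sample, allele, amplicon) dropout
and per-allele read starvation.

It deliberately does **not** model: pyrosequencing homopolymer indels or any
quality-score structure (qualities are constant; the pipeline's filters are
length-based), emulsion-PCR bead kinetics, chimeric/abortive products, or
the real IMGT allele-frequency landscape. A green end-to-end test therefore
establishes that the *logic* — demultiplexing, trimming, condition typing,
joins, calling, novel detection — is correct on reads with the stated
structure; it says nothing about error tolerance beyond the substitution
model, and the published concordance percentages from real instrument runs
are not reproducible at desk scale and are not asserted.

## Numerical and procedural choices

* **Variability** is the percentage of covering (non-gap) alleles differing
  from the modal base; modal ties break lexicographically (A < C < G < T).
  Depth-0 columns report 0 variability.
* **Ambiguity classes** (`in_silico_resolution()`, and call-time merging)
  are built by union–find over the pairwise "identical where both known"
  relation. With heterogeneous known intervals the relation is not
  transitive, so classes are its transitive closure; pairs with no jointly
  known covered position are incomparable and never joined (a warning
  reports how many). For full-length databases this reduces to exact
  partitioning, which is what the brute-force oracle checks.
* **Exact matching replaces BLAT**: the published criterion is 100%
  identity, so substring comparison at the expected frame offset (fixed by
  amplicon and direction after MID/primer clipping) is the whole algorithm;
  no alignment scoring is reproduced.
* **Reads between the minimum and the target length** are kept untrimmed;
  reads at or above the target are truncated at the target, anchored 5′
  (the anchor was unstated; 5′ is the only end with a fixed frame offset
  after clipping). Trimming is idempotent.
* **Variant annotation is direction-agnostic.** The source's printed
  example (a T→C at position 587 said to cause proline→leucine) is
  internally inconsistent — T→C at a second codon position is Leu→Pro —
  so `annotate_variant()` simply reports ref/alt amino acids for whichever
  direction is supplied; position 587 is codon 196 either way.
* **Novel-candidate triage**: unmatched reads from a group where a *called*
  allele expects `NONE` are extension reads beyond a partial reference
  (useful for extending the database, not evidence of a new allele) and are
  excluded before clustering. Clusters equidistant from several references
  report all nearest references rather than choosing arbitrarily;
  consistent clusters across read groups merge into one candidate whose
  consensus is the nearest reference with the SNPs applied.
* **Read-metric standard deviations** use the sample (n−1) form; a single
  sample reports sd 0 with an explicit note; an empty run reports zeros.
* **Degenerate inputs**: an empty key-group match set flags the sample
  `not_detected` instead of erroring; an empty reference subset passed to
  the mapper is an error (it means upstream restriction was skipped);
  ambiguous MID or primer hits land in the unassigned bin with a reason
  code, preserving the partition invariant.

## Known limitations

* Indel variants cannot be detected: both mapping and novel-candidate
  scoring are substitution-only, matching the 100%-identity contract.
* Novel alleles whose every distinguishing SNP lies in a primer site or
  outside all read windows are invisible, as in the real assay.
* Phasing across amplicons relies on shared allele identity; true
  haplotype phasing is out of scope.
* The in-silico resolution of a real database release depends on that
  release's content; the package computes, it does not ship, reference data.
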