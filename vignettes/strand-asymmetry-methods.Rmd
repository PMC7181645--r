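---
title: "Measuring transcriptional strand asymmetry of indels at repeat tracts"
author: "indelstrand"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring transcriptional strand asymmetry of indels at repeat tracts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(indelstrand)
```

## The problem

Small insertions and deletions (indels) in somatic genomes arise mostly at
mono- and dinucleotide repeat tracts, where polymerase slippage produces
insertion/deletion loops that mismatch repair (MMR) normally removes.
Substitutions have long been oriented relative to transcription — excess
mutation on the coding (non-template) strand of expressed genes is the
classic footprint of transcription-coupled nucleotide excision repair
(TC-NER), which preferentially clears lesions from the template strand —
but indels resisted this analysis because a single indel has no obvious
strand of its own.

The trick this package implements is to orient the *repeat tract* instead
of the indel. A polyT run inside a gene on the `+` reference strand reads
T on the non-template strand; the same run inside a `-` gene reads A on
the non-template strand (equivalently, T on the template strand). Every
indel overlapping an oriented tract inherits that orientation, and strand
asymmetry of indel burden becomes measurable.

## The statistic

Repeat tracts are not placed symmetrically in the reference genome (polyT
runs favour the non-template strand), so raw hit counts are confounded.
The package therefore works with per-strand mutational *densities*:

- `A` = (indel hits on non-template tracts) / (non-template tract count)
- `B` = (indel hits on template tracts) / (template tract count)
- strand bias = `A / (A + B)`, 0.5 meaning no asymmetry,
- percentage excess = `(A/B - 1) * 100`.

Scaling one strand's hit and motif counts by a common factor leaves the
bias unchanged, which is exactly the background correction required; the
test suite asserts this invariance, together with the complementarity
identity `bias(U) = 1 - bias(revcomp(U))` on identical data.

Dispersion comes from a gene-level bootstrap: genes are resampled with
replacement, the four counts are summed over each resample and the bias
recomputed (1000 iterations by default; undefined resamples are redrawn
and counted, with a warning above a 1% redraw rate). Significance comes
from an exact binomial test of the non-template hit count with null
probability equal to the non-template share of motif occurrences — the
motif-share null keeps the test calibrated over a skewed reference.
A `null = "half"` mode reproduces the uncorrected test against 0.5; the
corrected null is the default because every headline analysis is meant to
be background-corrected. Group contrasts (MSI vs MSS, expression tiers)
use rank tests (Mann–Whitney, Kruskal–Wallis, Wilcoxon signed-rank) with
an explicit Bonferroni family size — the family is always stated by the
caller, never inferred.

For a focal sample with very few indels, a down-sampling comparison is
provided: the focal number of hits is drawn repeatedly (10,000 times by
default) from a reference cohort's pooled hits, the bias recomputed per
draw with the cohort's motif denominators, and the focal bias expressed
as a z-score and empirical two-sided tail probability on that
distribution. Drawing labels with replacement from the pool is
equivalent to a binomial draw at the pool's non-template proportion, and
the implementation uses that identity for speed.

## The atlas

Homopolymer tracts are maximal single-base runs; N breaks a run. Runs
longer than the 10 bp cap are kept with their true length but flagged
`over_max` and pooled into a single "over" stratum in length-stratified
output, rather than silently truncated or dropped. Dinucleotide tracts
cover the eight orientable units (GT/TG/AC/CA/CT/TC/AG/GA): palindromic
units (AT/TA/GC/CG) read the same on both strands and cannot be oriented,
and double-base units are homopolymers. Dinucleotide phase ambiguity is
resolved by a greedy leftmost-longest scan — at each position the longest
run of complete units starting there is emitted and the scan jumps past
it — which guarantees non-overlapping tracts and is checked exactly
against an independently implemented oracle.

Orientation requires a tract to lie fully inside the annotated gene body
(start to end, introns included); tracts straddling a boundary are
dropped from genic analyses, and a tract inside two overlapping genes is
counted once per gene. Indel–tract overlap is positional, following the
intersection rule: any deleted base inside the tract, or an insertion
point inside the tract or immediately at either boundary. The inserted
or deleted sequence is *not* required to match the tract unit by default
(`require_base_match = TRUE` enables the stricter mode for sensitivity
analysis). Indels are left-aligned to their lowest-coordinate equivalent
placement on read; within a homopolymer every equivalent placement hits
the same tract, so this matters only at tract edges, and the operation is
asserted idempotent and equivalence-preserving against a brute-force
placement enumerator.

Reference-genome description uses the same orientation machinery:
occurrence ratios per tract length with an occurrence-weighted average
across lengths, metagene profiles over 14 bins (10 equal body bins plus
two 10 kb flank bins at each end, bin 1 being 5'-most in transcription
direction; a tract is assigned to the bin containing its start so it is
never double-counted), TSS/TES density profiles in 100 bp intervals with
gene-bootstrap standard errors, and GC/AT skew `(G - C)/(G + C)` per
100 bp window read on the non-template strand.

## Stratification

Expression tiers split protein-coding genes at the 33rd and 66th RPKM
percentiles into low/medium/high; zero-RPKM genes fall into "low" (a
separate zero tier is available by flag) and ties go to the lower tier.
Stratified counts restrict both numerators and denominators to the
stratum, so strata sum exactly to the pooled analysis — an identity the
tests assert.

Replication timing is smoothed with a 50 kb moving average (configurable);
the central first difference gives replication direction (sign) with a
transition band below the 5th percentile of |slope| by default, and the
second difference flags initiation/termination zones. Which reference
strand is the lagging-strand template in a right-replicating region is a
convention the signal cannot identify; it is exposed as
`rep_convention` with `"right_lagging_plus"` as the documented default,
and only convention-independent properties are asserted. The
leading/lagging partition of a motif is by the replication role of the
strand the unit is read on (the reference strand carries the unit exactly
when the tract's reference reading equals the target unit). Under this
definition a purely replication-coupled process shifts indel totals
between partitions but leaves the within-partition transcriptional bias
at 0.5, while a purely transcription-coupled process gives equal bias in
both partitions — both directions are exercised on generated data. Gene
timing is the length-weighted mean of overlapping bins, and timing
quantiles are near-equal rank-based groups.

## The synthetic-data generator

The generator defines the study conditions under which every claim is
tested, and its defaults are chosen once to emulate the structure of the
cohort data the method targets:

- a background genome with runs longer than 2 bp suppressed, so planted
  tracts are the only tracts of length >= 3 and atlas assertions can be
  exact;
- non-overlapping 2 kb genes on random strands; 4 planted tracts per
  gene with lengths from a truncated geometric on 3–10 bp;
- a reference-strand placement skew `q` (probability a tract reads its
  unit on the host gene's non-template strand); `q = 0.6` reproduces the
  observed-scale polyT skew, giving an expected occurrence ratio
  `q/(1-q) = 1.5`;
- a planted bias `beta`, the target non-template share of indel density
  after motif correction. Tract selection weights are proportional to
  `length_slope^(length-1) * tier_multiplier * s(beta)` with `s(beta)`
  equal to `beta` on non-template-reading tracts and `1-beta` otherwise,
  which makes the planted value exactly the estimand. Separate
  `beta_ins`/`beta_del` (insertions = 0.36 of indels by default,
  matching the observed deletion predominance) and per-tier values are
  supported;
- MSI samples get a tract-rate multiplier against a configurable
  background indel rate, so the MSI/MSS enrichment ratio has the closed
  form `(m/(m+b)) / (1/(1+b))`;
- deletions remove one repeat unit at a unit boundary and insertions add
  one unit at an interior insertion point, so with zero background rate
  every indel hits exactly one planted tract — enabling exact hit-count
  assertions;
- a sawtooth replication-timing track with per-bin orientation truth,
  and an optional replication-driven placement mode (`rep_beta`) used to
  verify that the transcriptional statistic does not absorb a
  replication signal.

Each stage derives its RNG stream from `seed` plus a fixed offset, so
outputs are byte-identical under a fixed configuration.

What the generator does not emulate — real base composition, chromatin
context, signature-specific indel spectra, caller artefacts — bounds what
green tests mean: they establish that the estimator, tests and
stratifications are correct and calibrated under known truth, not that
any particular biological dataset will show a given effect size.

## Numerical choices and problem sizes

Tests and the acceptance script run the full pipeline at 250–2000 genes
and a few thousand indels per run: large enough that binomial sampling
error on the bias is below 0.01–0.02 and closed-form recoveries are
sharp, small enough to keep the whole suite comfortably reproducible on a
single CPU. Oracle-equivalence checks use 1000 random 10 kb sequences
(exact set equality) and 10,000 random indels against 5,000 tracts
(interval index vs all-pairs). Bootstrap intervals are percentile-based;
bias estimates whose denominators vanish are flagged rather than coerced;
ties in expression quantiles go to the lower tier; undefined bootstrap
resamples are redrawn and counted. When an analysis is restricted to
length strata, the motif denominators are restricted identically — mixing
hit-free strata into the denominators would undo the background
correction, which is why generator-based analyses use strata 3–10.

## Known limitations

- The replication annotation is a parameterised stand-in validated on
  synthetic sawtooth signals; real Repli-seq requires tuning the
  smoothing and threshold, and the leading/lagging convention must be
  supplied.
- Complex indels and multi-nucleotide substitutions are skipped at the
  VCF boundary with a logged count.
- An insertion point falling exactly between two adjacent tracts is
  counted for both (the positional rule's boundary case); the rate is
  negligible away from tract-dense regions but is not zero.
- Tri-nucleotide and longer repeat units, exon/intron substructure and
  signature decomposition are out of scope.
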