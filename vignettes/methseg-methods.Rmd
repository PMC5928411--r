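---
title: "Methylome segmentation with methseg: models, parameters and design"
author: "methseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylome segmentation with methseg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`methseg` analyses whole-genome bisulfite sequencing (WGBS) methylomes
with a focus on the contrast between germline (sperm) and somatic
samples. This vignette explains the statistical models behind each
stage, the tunable parameters and their defaults, what the synthetic
data generator does and does not emulate, and the design choices made
where the methods left room for interpretation.

## Data model and coordinate conventions

A `Methylome` wraps a sorted `GRanges` of cytosines with metadata
columns `n_meth`, `n_unmeth` and `context` (`CpG`, `CHG`, `CHH`). As
everywhere in Bioconductor, ranges are 1-based and closed; the on-disk
dialects keep their native conventions (Bismark-style cytosine reports
are 1-based, BED is 0-based half-open) and are converted at I/O.
Because the two cytosines of a CpG dyad are strand-symmetric copies of
one methylation state, `mergeCpGDyads()` sums the `+` record at p and
the `-` record at p+1 into one site at p by default, doubling
effective coverage; merging is idempotent and can be skipped.

Two notions of a region's methylation level exist in the literature.
`methseg` reports the coverage-weighted (pooled) ratio
$\sum_i m_i / \sum_i (m_i+u_i)$ by default — the convention behind
whole-genome summary levels — and exposes the unweighted mean of site
levels as an option. Sites below the coverage filter are ignored; a
region where nothing passes has an *undefined* (NA) level, which is
deliberately distinct from zero methylation.

Coverage filters follow the two-tier convention of region- versus
site-level analysis: **≥ 5×** per CpG for regional summaries (windows,
PMDs, HMRs, elements) and **≥ 10×** in *every* sample for site-level
comparisons (common-CpG matrix, DMCs). The source descriptions of
these filters mix "at least" and "greater than" phrasings; the package
standardises on inclusive thresholds (≥ 5, ≥ 10) and both are
configurable, so the strict reading is one argument away.

## PMD segmentation

Partially methylated domains are large (≥ ~60 kb here) spans of
intermediate methylation against a highly methylated background. The
detector follows the window-binarisation + HMM recipe:

1. tile each autosome into non-overlapping 20-kb windows and compute
   the weighted level over CpGs with ≥ 5× coverage;
2. label a window 1 if its level is strictly greater than 60% and 0
   otherwise (a tie at exactly 60% is assigned 0 — only the strict
   inequalities are defined by the rule, so the tie needed a
   documented convention);
3. decode a two-state HMM (PMD, background) over each chromosome's
   label sequence with Viterbi and report maximal runs of PMD-state
   windows;
4. intersect across samples: a consensus PMD is a maximal run of
   windows supported by ≥ 3 samples, at least 3 windows long.

The HMM's parameters are not dictated by the method's description, so
fixed, hand-verifiable defaults are used: stay probability 0.9 in both
states and emission probabilities P(0 | PMD) = 0.9,
P(0 | background) = 0.1, uniform initial distribution. These are
symmetric, which gives a clean decision rule: an isolated run of k
zero-windows flips to the PMD state exactly when the emission gain
(2·log 9 per window) beats the two transition penalties, i.e. when
k ≥ 3 — matching the ≥ 3-window consensus filter. Viterbi ties break
toward background so an ambiguous window never seeds a PMD. Optional
Baum–Welch refinement (≤ 100 iterations, tolerance 1e-6 on the
log-likelihood) is deterministic given its starting values and off by
default; run-of-zeros detection is insensitive to the exact
parameters, and fixed values keep runs bitwise reproducible.

Windows with fewer than 10 covered CpGs (at ~6× coverage a 20-kb
window typically holds ~150–200 usable CpGs, so this only removes
assembly gaps and deserts) are excluded and *split* the HMM sequence
rather than being imputed: a PMD cannot bridge a region with no data.
Consensus support is counted per window, not by reciprocal interval
overlap, which makes the consensus order-independent and monotone —
adding a sample can only grow it.

## HMR calling

Hypomethylated regions are short (~0.5–1 kb) promoter/CGI-scale
intervals where at least 80% of covered CpGs have level < 20%. The
caller is seed-and-extend: 200-bp seeds slide at 50-bp offsets; a seed
qualifies with ≥ 3 covered CpGs and a hypomethylated fraction ≥ 0.8 (a
CpG-free window is vacuously "80% hypomethylated", hence the explicit
seed minimum); qualifying seeds extend rightward in 50-bp steps while
the fraction holds. Leftward extension is implied by seeds starting
earlier, and overlapping or book-ended calls merge, so the simpler
one-direction semantics covers the same space. Each merged call is
trimmed to its outermost hypomethylated CpGs — without trimming, call
edges would float in CpG deserts — and the final filter requires ≥ 5
covered CpGs and re-checks the 80% fraction, so **every emitted HMR
satisfies its own definition**; this is asserted post-hoc in the test
suite on every run.

Group-level HMR sets can be formed as union (default), intersection
or majority of the replicate calls. Nesting of a somatic HMR inside
the broader sperm HMR around the same promoter is classified with a
50-bp margin (one extension step) per edge, distinguishing genuine
nesting from coincident boundaries. TSS metaprofiles pool
coverage-weighted methylation into strand-oriented offset bins.

## Differential methylation

The site-level test pools counts within each group and applies a
two-sided exact conditional test to the 2×2 table
(methylated/unmethylated × group), with the standard convention that
all tables at most as probable as the observed one (relative tolerance
1 + 1e-7) contribute to p. q-values are Benjamini–Hochberg; a DMC
requires |pooled level difference| > 30% and q < 0.01, on autosomes.
The exact test was chosen over replicate-aware regression because a
two-replicate design gives exact tests more stable behaviour, the test
is fully specified and verifiable against brute-force hypergeometric
enumeration (the suite checks every table with total ≤ 60), and
replicate variability is instead handled at the gene level: genes in
PMDs are compared by a two-sample Student t test on per-sample
weighted gene-body levels (reported at |Δ| > 20%, FDR < 0.01, with
hypo- (< 20%) and hyper- (> 80%) methylation flags).

Element-level methylation applies a detection filter before any level
is reported: elements with more than 50 CpGs need ≥ 10% of them
detected, elements with at most 50 CpGs need ≥ 5 detected; failures
are flagged, not errored, and carry no level.

## Enrichment statistics

O/E enrichment is base-pair density based: observed = feature bp per
region bp, expected = feature bp per autosomal bp. "Density" is not
given units in the source description; bp density was chosen because
it is invariant to how the annotation happens to fragment a feature
(records are merged first), and the suite checks the statistic
exactly against a per-base counting oracle. Sex chromosomes and
spike-in contigs are excluded whenever the expectation is autosomal.
TSS-proximity enrichment divides the fraction of elements hitting
TSS ± 2 kb windows by the fraction of autosomal bp those windows
occupy — the uniform-placement expectation.

## Repeat analysis

RepeatMasker's milliDiv (substitutions per 1000 bp against the family
consensus) proxies element age. Hypomethylated elements are those
below 20% in at least one sample passing the detection filter. The
young-SINE selection keeps hypomethylated SINEs with divergence below
50; the threshold's unit is interpreted as **milliDiv** (< 5%
substitutions) by default because that is what "young" means for
recently expanded SINE families whose copies sit at 90–100% of
consensus length, but a percent-substitution interpretation is
selectable (`unit = "percent"`) since divergence axes are often
drawn in percent. CpG density of an element is computed from the CpG
site index rather than genome sequence, so the pipeline runs without
a FASTA.

## The synthetic-data generator

`simConfig()`/`simulateGenome()`/`simulateMethylomes()` generate a
genome, annotation and multi-sample methylomes with planted,
fully-known structure. Defaults mirror the emulated study design:

- 3 chromosomes × 5 Mb; 4 sperm + 6 somatic samples (two replicates
  each of three tissues); CpG coverage ~ Poisson(6);
- background methylation Beta-distributed around 0.78 (concentration
  30), drawn once per site and shared across samples so replicates
  carry the same biology;
- 10 planted PMDs of 100–500 kb at level 0.35 in the sperm group;
- planted promoter HMRs at level 0.05 (shared and group-specific),
  sitting inside CGI blocks whose CpG density is 10× background —
  roughly 1 CpG per 10 bp, the density real CGIs have;
- satellite blocks (pericentromeric plus interstitial) at level 0.15
  in sperm and 0.85 in somatic samples, with modestly elevated CpG
  density;
- a repeat catalogue whose scattered old elements follow the
  background, plus young SINEs (BOV-A2-named with probability 0.95,
  milliDiv 5–45, consensus fraction 0.9–1.0) planted within 2 kb of
  TSS and hypomethylated in sperm;
- planted single-CpG DMCs (sperm 0.05 vs somatic 0.95) and an
  unmethylated lambda-like spike-in contig with a 0.5% conversion
  error.

Each replicate draws its level as a Beta around the group truth
(concentration 100) before binomial sampling; pure binomial noise
understates replicate variance, and the jitter gives the DMC and
t-test stages realistic overdispersion. Random streams are split per
(sample, stage) from the master seed, so adding a sample never
perturbs the others and all outputs are byte-identical across runs
with the same seed (R's default Mersenne-Twister RNG).

What the generator does **not** emulate: sequence composition beyond
CpG placement rates, read-level artefacts (mapping bias, M-bias,
incomplete conversion outside the spike-in), non-CpG methylation
structure, copy-number variation, and correlated coverage (coverage is
independent Poisson per site, while real WGBS coverage is locally
autocorrelated and GC-biased). Passing the planted-recovery tests
therefore demonstrates that the algorithms are correct and calibrated
under the stated noise model, not that their thresholds are optimal
for any particular real dataset.

## Numerical and degenerate-input conventions

- Undefined quantities are `NA` with a flag, never silently 0 or
  infinite: a region with no covered CpG, an O/E with zero expected
  density, a correlation over a zero-variance vector.
- Zero-variance t-test inputs with equal means return t = 0, p = 1
  (flagged degenerate); unequal constant means return p = 0.
- The exact test reproduces the conventional 1 + 1e-7 relative
  tolerance when summing table probabilities, so its p-values agree
  with `stats::fisher.test` to machine precision.
- Site-level validation scales: the test-suite simulations use 1.5–5
  Mb chromosomes and 20,000-site DMC panels, sizes at which every
  recovery statistic is stable across seeds while the whole suite
  stays interactive.

## Known limitations

The exact DMC test pools replicates and therefore tests the pooled
difference, not a replicate-level model; biological replicate variance
enters only at the gene level. The HMR extension rule can overshoot
into a CpG desert before trimming pulls the boundary back to the last
hypomethylated CpG, so a boundary is only ever as precise as the local
CpG spacing. PMD boundaries are window-quantised (± 1 window). The
consensus PMD statistic records support counts but not per-sample
boundary variance. None of the downstream biology (GO enrichment,
motif scanning, co-expression) is in scope; the tables the pipeline
writes are the hand-off points.
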