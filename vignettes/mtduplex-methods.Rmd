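---
title: "Dual-strand mtDNA heteroplasmy analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-strand mtDNA heteroplasmy analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtduplex)
library(dplyr)
```

## The problem

Human mitochondrial DNA is a circular, 16,569-bp genome present in hundreds
to thousands of copies per cell. A variant may be *homoplasmic* (carried by
essentially all copies, at or near 100% allele frequency — the inherited
germline state that defines a maternal haplogroup) or *heteroplasmic* (a
mixture of mutant and wild-type copies, quantified by the fraction of reads
supporting the variant). Heteroplasmies below a few percent are
biologically meaningful but sit at the same frequency scale as two nuisance
processes: sequencing error and post-extraction DNA modification (for
example cytosine deamination), which produces apparent C>T / G>A changes.

The analysis implemented here exploits a dual-strand amplicon design: two
complementary primer pools interrogate the two strands of the molecule
independently. A real variant is present in the template and must appear in
the reads of *both* pools; a chemical modification lesion lives on one
strand only and appears in one pool. The package implements that rule as a
pipeline — simulate or ingest strand-resolved pileups, call candidate
variants per pool, intersect the pools, classify what survives, aggregate
across samples, and test cohort-level carrier patterns.

## Per-pool variant calling

For each pool, position and alternate base, the caller records the
alternate count $k$ out of depth $n$ and scores it against a uniform error
model: errors occur at rate $e$ per base (default $e = 0.001$) and are
spread evenly over the three non-reference bases, so a specific alternate
base accumulates errors at rate $e/3$. The quality score is the
Phred-scaled upper binomial tail,

$$\mathrm{QUAL} = \min\!\left(100,\; -10\log_{10} P\!\left[X \ge k\right]\right),
\qquad X \sim \mathrm{Binomial}(n, e/3),$$

computed in log space so deep tails do not underflow, and capped at 100 by
convention. A call PASSes when frequency $k/n \ge$ `min_maf` (default 0.01),
depth $n \ge$ `min_depth` (default 1,000) and QUAL $\ge$ `min_qual`
(default 30). Records between `min_maf/2` and `min_maf` are emitted with a
`low_maf` flag rather than dropped, so the concordance stage can report
*why* a key failed, not merely that it did. The caller is deliberately
minimal — no realignment, recalibration or within-pool strand modelling —
because the downstream concordance rule, not caller subtlety, carries the
artifact filtering.

## Both-strand concordance

`concord()` intersects the two pools' calls by (position, ref, alt). A key
with a qualifying call in both pools becomes a *true variant*; everything
else is rejected with a reason. The combined frequency is the
depth-weighted mean

$$\hat f = \frac{f_A n_A + f_B n_B}{n_A + n_B},$$

the minimum-variance unbiased combination of two binomial proportions;
`combine = "min"` gives a conservative alternative. Strict mode (default)
demands PASS in both pools. A lenient mode (`require_pass = FALSE`)
accepts PASS in one pool plus any emitted sub-threshold record in the
other, for near-threshold asymmetry between pools; it is off by default
because the strict reading is the cleaner operationalisation of the
both-strands rule.

Why the rule works: a single-strand artifact at fraction $a$ produces an
expected frequency $a$ in its pool but only $e/3 \approx 0.03\%$ in the
other pool, far below the 1% floor, so it cannot qualify twice. A true
heteroplasmy is sampled binomially in both pools and qualifies in each as
long as its frequency clears the floor.

## Classification

* **Substitution class** — transitions stay within purines (A↔G) or within
  pyrimidines (C↔T); the other eight ordered pairs are transversions.
  Transitions are the signature of replication error, transversions of
  oxidative damage, which is what makes the partition biologically
  informative.
* **Zygosity** — homoplasmy iff combined frequency ≥ `homoplasmy_min`
  (default 0.85). The observed data are strongly bimodal (homoplasmies at
  or above ~0.90, heteroplasmies at or below ~0.60), and 85–90% is the
  burden at which point-mutation pathogenicity is reached, so 0.85
  separates the modes with margin on both sides. The `< 40%`
  low-frequency flag (`low_frequency_max = 0.40`) is a *reporting* flag,
  not the heteroplasmy definition: samples do contain heteroplasmies above
  40% and they remain heteroplasmies.
* **Category** — a variant on the assigned haplogroup's root-to-node path
  is haplogroup-defining; otherwise, if present in the packaged annotation
  set, private; otherwise unique. "Unique" is relative to the packaged
  annotation set (hot-spot annotations plus germline SNPs); there are no
  network lookups.

## Haplogroup assignment

The packaged mini-tree stores root-to-leaf paths whose accumulated defining
SNPs are the three study subjects' homoplasmy sets, with decoy branches so
that scoring is non-trivial. Each node is scored with a symmetric
(Kulczynski-style) match fraction,

$$s = \tfrac12\left(\frac{m}{|\mathrm{path}|} + \frac{m}{|\mathrm{observed}|}\right),$$

where $m$ counts observed homoplasmies on the node's path. The best score
wins; ties break to the shallowest node, then lexicographically; an empty
homoplasmy set returns the root (the reference haplogroup, since the
reference sequence itself belongs to haplogroup H). This is a deliberate
simplification of full phylogenetic classifiers — adequate here because
fixture tests pin the three subjects' labels and simulation tests measure
recovery across the whole tree.

One modelling note: position 263A>G appears on both the H and the U
branches of the mini-tree. The I-lineage subject's printed homoplasmy set
lacks it while both other subjects carry it, so the mini-tree encodes it as
a homoplasy rather than forcing it onto a shared trunk.

## The synthetic-data generator

The generator emulates exactly the statistical structure the analysis
assumes, per tissue sample and pool:

* **Depth** — drawn per position from
  $d = d_{\min} (d_{\max}/d_{\min})^{u^{g}}$ with $u \sim U(0,1)$: a
  log-uniform body over the 1,000–100,000 range, tilted by an exponent $g$
  solved once (by `uniroot` on the quadrature mean) so the mean equals
  30,000. This keeps every draw inside the stated range without
  truncation, at the stated mean; only the mean and range are specified by
  the study design, so the body shape is a package choice.
* **Base error** — each non-reference base is Binomial$(d, e/3)$, default
  $e = 0.001$. At event sites the alternate base is drawn at
  $\mathrm{maf} + (1-\mathrm{maf})\,e/3$: the error channel feeds the
  alternate base there too, keeping event and non-event sites under one
  error model. The reference count takes the remainder, so counts sum to
  the drawn depth.
* **Events** — germline homoplasmies (the haplogroup path, at 0.995) and
  planted true heteroplasmies appear in both pools; single-strand
  artifacts (deamination-like C>T/G>A by default) appear in one configured
  pool only. Planted heteroplasmy frequencies default to the 1–40% range.
  The per-tissue event counts default to blood 10, RPE+choroid 2, retina 1
  with 2 artifacts each: the blood-dominant tissue imbalance is *imposed*
  through the event lists, not emergent, because the study reports rather
  than models the tissue effect; artifact counts per sample are free
  parameters of the simulation.

What the generator does **not** model: read-level sequencing (FASTQ), PCR
duplicates, mapping bias, NUMT cross-amplification, mtDNA copy number, any
error spectrum other than uniform-with-optional-transition-bias, or
amplicon-specific depth structure. Passing simulation tests therefore
demonstrates that the pipeline implements its own model correctly — not
that the model captures every failure mode of real amplicon data.

## Detection power at the 1% floor

The PASS rule thresholds the *observed* frequency at 1%. For a variant
whose true fraction is exactly 0.01 at 30,000× the observed count is
Binomial with mean ≈ 310 (including the error channel) and standard
deviation ≈ 18 against a threshold of 300, so a single pool passes with
probability ≈ 0.7 and both strands with probability ≈ 0.5 — a coin flip,
as for any thresholded estimator evaluated exactly at its threshold. The
smallest heteroplasmy printed in the study tables is 1.16%, and at that
fraction the both-strand recovery probability already exceeds 99%, which
is why the packaged recovery study plants its lowest event at 1.16% and
why the acceptance script additionally reports (without asserting) the
measured rate at exactly 1%.

## Aggregation and cohort statistics

* **Hot-spots** — a heteroplasmy SNP observed in at least `min_subjects`
  (default 2) distinct subjects, counting a subject once regardless of how
  many tissues carry it. An optional preset excludes the homopolymeric
  C-tract (positions 302–316), where amplicon calls are unstable.
* **Blood-only SNPs** — present in the blood of *every* subject and absent
  from every non-blood sample. The all-subjects rule is the default
  because the looser "only ever seen in blood" reading admits many
  subject-private SNPs.
* **Frequency bands** — half-open $[lo, hi)$ intervals with implicit
  underflow/overflow bands so counts always sum to the table size; a value
  on a lower edge belongs to that band.
* **Odds ratios** — the raw cross-product $(ad)/(bc)$ on carrier/
  non-carrier 2×2 tables. No continuity or Haldane correction: a zero
  cross-cell raises a typed "undefined" signal instead of silently
  shifting the estimate (the printed study values are raw cross-products,
  which is what makes them reproducible to the printed rounding).
* **Fisher's exact test** — two-sided by the point-probability method (the
  sum of hypergeometric probabilities no larger than the observed table's),
  computed in log space; this matches the common reference implementations
  and is pinned against full enumeration in the tests. Mid-p and doubling
  variants would give different numbers and are not used. No
  multiple-testing correction by default, mirroring the study's analysis;
  Benjamini–Hochberg is available behind `adjust = "BH"`.
* **Paired t-test** — `tissue_count_ttest()` is the two-tailed paired test
  on per-subject tissue counts; identical vectors raise a typed
  "undefined" signal rather than returning NaN.

## Verbatim fixtures and their documented quirks

The packaged study tables are transcribed verbatim and checksummed, and
the printed source is internally inconsistent in places. The package
computes from the row-level data and documents rather than repairs the
conflicts (details in the fixture README): the heteroplasmy list holds 167
Subject-3 blood rows where the printed totals say 165; Subject-2 blood
contains the transversion 6266A>C although the printed transversion
summary omits it (so the row-level transversion shares are 5.19% and 8.38%
where the printed summary says 4.4% and 8.48%); and the total-SNP table's
printed totals row differs from its own column sums by two. Aggregate
shares quoted from printed totals use the totals as printed.

## Problem sizes and numerical conventions

The packaged test and acceptance runs use: 200 seeded end-to-end runs for
duplex recovery and artifact rejection at fixed 30,000× per pool, 100 runs
for specificity, 100 simulated subjects for haplogroup recovery, 200
cohort draws for the odds-ratio direction study, and exhaustive
enumeration of every 2×2 table with total $n \le 40$ for the Fisher
oracle. All randomness flows from a single integer seed per simulation
call; identical seeds give byte-identical outputs. Tail probabilities and
hypergeometric sums are computed in log space; Phred scores cap at 100;
coordinates are 1-based inclusive with explicit origin wrap (`end <
start`) for the circular genome.

## Known limitations

Indels are out of scope (SNVs only). The haplogroup scorer is not a full
phylogenetic classifier and the packaged tree covers only the lineages and
decoys it ships with. The annotation set is frozen, so "unique" means
"unknown to this package", not "absent from public databases". The
packaged reference is a synthetic rCRS-length stand-in (correct bases at
all fixture positions, pseudo-random elsewhere); analyses of real data
should load a real rCRS FASTA. The simulator's idealisations listed above
mean real-data performance at the 1% floor will depend on error spectra
and depth structure the model does not capture.
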