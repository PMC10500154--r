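---
title: "methylscape: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{methylscape: models, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`methylscape` is a desk-scale pipeline for whole-genome bisulfite
sequencing (WGBS) differential-methylation analysis in plant
temperature-response designs — several ecotype groups, a control and a
warm growth temperature, triplicate methylomes and transcriptomes —
together with a synthetic-data generator that reproduces the
statistical structure the analysis assumes. This vignette documents the
models, the statistics and the places where the design was genuinely
open.

## The methylation model

Plant cytosine methylation is analysed in three sequence contexts —
CGN, CHG and CHH, with H ∈ {A, C, T} — because distinct maintenance
pathways act on each. A cytosine's context is read 5'→3' on its own
strand with CGN taking precedence over CHG over CHH. All levels are
*weighted* methylation: pooled methylated reads over pooled total reads
for a region and context, never a mean of per-site fractions. The
bisulfite non-conversion rate ε is estimated by pooling all reads on
the chloroplast contig, which is biologically unmethylated, so an
observed site-level probability is
`p_obs = p_true (1 − ε_under) + (1 − p_true) ε`.

## The synthetic world

The generator builds a genome of seven random 300-kb autosomes plus one
30-kb chloroplast contig (~2.1 Mb, giving ≥10⁵ cytosines per context
for stable statistics while staying desk-scale), places
non-overlapping genes, repetitive elements (REs) and pseudogenes by
stick-breaking of the free space, and assigns each cytosine a truth
probability

```
p = base[context] × subcontext_multiplier[trinucleotide] × shape(position)
```

with smooth shapes matching the canonical plant profiles: gene bodies
relatively hypomethylated with Gaussian dips at TSS and TTS, a flat
hypermethylation plateau inside RE bodies, and edge bumps on
pseudogenes. CCG is suppressed within CHG (default factor 0.6). The
default targets are genome-wide weighted levels of ~55% / ~30% / ~6%
(CGN/CHG/CHH).

Because straight multiplication of base levels by shape and subcontext
modulators cannot simultaneously satisfy per-site arithmetic and the
global targets, base levels are *anchored*: when `base_levels` is
unset, the generator rescales each context's base so that the mean
truth probability over autosomal sites equals `target_levels`.
Supplying explicit `base_levels` disables anchoring, so flat-landscape
arithmetic (e.g. CCG multiplier 0.5 on CHG base 0.30 giving exactly
0.15) holds verbatim — this is the configuration the unit tests use for
exact checks.

The warm condition adds a global per-context probability shift
(defaults +0.04 / +0.05 / +0.01, the largest per-context responses seen
in the most temperature-plastic ecotype) plus any planted differential
intervals, clipped to [0, 1]; the chloroplast stays at zero. Sequencing
counts are negative-binomial coverage (mean 30, size 10 — WGBS depth is
over-dispersed) with binomial methylated counts at `p_obs`; ε defaults
to 0.005 and under-conversion of methylated sites to 0, since an
unmethylated control constrains only false methylation. Every random
stream derives from one master seed via a stable byte-hash of
(seed, stream label), so replicates are independent yet exactly
reproducible.

Scenario presets fix the study conditions:

* `scenario_baseline()` — no treatment; used for global-level recovery.
* `scenario_warm_shift()` — global shifts only, no planted intervals,
  so the genome-wide 28C−18C deltas are attributable to the configured
  +4/+5/+1 percentage points.
* `scenario_peaks()` — the shared-peak fixture: eight 50-kb windows,
  two on each of chromosomes 2, 3, 5 and 6, each filled with 12
  clustered hyper-CHG intervals (600 bp, +0.4, spaced >250 bp so each
  merges into its own DMR) in every group. This preset runs on 7×150-kb
  chromosomes — three 50-kb windows each — which keeps a four-group
  genome-wide permutation analysis in the minutes range on one CPU;
  that problem size is the package's choice for routine verification.

What the generator does *not* emulate: read-level artifacts (mapping
bias, duplicates), epiallele haplotypes, linkage between neighbouring
sites beyond the planted intervals, ecotype-specific baselines
(configurable but exchangeable by default), and biological replicate
variance beyond binomial sampling. Passing recovery tests therefore
demonstrates the statistical machinery, not robustness to alignment or
population structure.

## The DMS test

For each candidate cytosine the two-temperature contrast is tested
across all s = 6 samples jointly. Sites first pass a coverage filter:
pooled coverage across samples ≥ 30 and every sample covered at least
once (a per-sample floor of 30 at ~30× data would discard most of the
genome). The heterogeneity statistic is the root mean square of the
Pearson residuals of the s×2 count table,

```
d = sqrt( (1/s) Σ_i n_i (f_i − p̄)² / (p̄ (1 − p̄)) )  =  sqrt(X² / s),
```

with `f_i = m_i/n_i` and `p̄ = Σm_i / Σn_i`. The variance
standardization matters: an unstandardized RMS of frequencies has a
null scale of `1/√n_i`, so when null statistics are pooled genome-wide
for empirical-FDR control the tail is dominated by low-coverage sites
and the procedure loses essentially all power at stringent FDR levels.
Standardization makes the null distribution of `d` comparable across
coverages, which is the property pooled FDR control needs. We verified
this directly: on a 20 000-site mixed panel the frequency form calls
nothing at FDR 0.003, while the standardized form is calibrated
(realized false-discovery proportion ≈ 0.004, within the 1.5× ratio
slack) with ~20% per-site power at a +0.3 shift.

The null is a parametric bootstrap: B = 1000 replicate tables
`m_i* ~ Binomial(n_i, p̄)` per site, with the statistic recomputed
(including the pooled frequency) each time. Per-site permutation
p-values are `(1 + #{d* ≥ d}) / (B + 1)`. Thresholding pools nulls
across sites within a context: for a candidate threshold t,
`eFDR(t) = mean_B #{d* ≥ t} / #{d ≥ t}`, and the call threshold t* is
the smallest observed t with eFDR(t) ≤ 0.003 (ties at t* included).
Realized FDP runs slightly above nominal because the denominator
includes the false calls themselves (ratio-estimator bias — hence the
documented 1.5× slack in the calibration contract). Direction is hyper
when the warm group's pooled level exceeds the control's.

A note on power: with triplicates at 30× and a +0.3 single-site shift,
per-site power at eFDR 0.003 is ~0.2 — the genome-wide null tail over
tens of thousands of sites forces a high threshold, and no single-site
statistic does materially better. Regions rescue this: a planted 600-bp
interval contains dozens of CHG sites, so the probability that at least
one is called — which is what DMS→DMR merging needs — is essentially 1.

DMSs within 250 bp (inclusive) of the same context and direction merge
left-to-right into DMRs; a direction change always splits, so DMRs are
direction-homogeneous and every DMS belongs to exactly one DMR.

## Annotation and integration

DMRs are assigned by midpoint, in precedence order, to promoter
([TSS−2000, TSS), strand-aware), gene body, downstream, else
intergenic; midpoint assignment guarantees each DMR exactly one
category. Promoter length defaults to 2 kb, matching the flank
convention used throughout; it is a parameter. Equidistant promoter
ties go to the lexicographically smaller gene id and are reported. A
gene is a DMG for context c when at least one context-c DMR annotates
to its promoter or body; downstream-only hits do not qualify.

Expression uses TMM library-size factors (trimmed mean of M values:
reference by upper quartile, 30%/5% M/A trims, precision-weighted mean)
and a deliberately compact negative-binomial Wald engine: per-gene
method-of-moments dispersions floored at 1e-8, shrunk 50/50 toward the
trimmed mean dispersion of similar-abundance genes, a per-gene NB GLM
with condition effect and log effective-library offsets, and the Wald
statistic referred to a t distribution with the residual degrees of
freedom. The t reference is the small-sample correction appropriate for
triplicate designs; with a normal reference the type-I error at
n = 3 + 3 is visibly inflated, with the t reference it sits at the
nominal 5% (checked by simulation in the test suite). DEGs default to
raw p ≤ 0.05 and |FC| ≥ 1.5, with adjusted-p and FC > 2 presets
available as options.

DEDMGs are the intersection of any-context DMGs with DEGs. Enrichment
is the hypergeometric upper tail (identical to one-sided Fisher on the
2×2 table) over a universe of *tested* genes — using all annotated
genes would inflate the representation factor, so the expressed/tested
universe is the default and the reported DEDMG share is overlap/DMGs
(the fraction of methylation-responsive genes that also respond
transcriptionally).

## Landscape statistics

DMR density uses 50-kb half-open windows on midpoints. A window is a
density peak when its DMR count reaches `max(floor, quantile)` of that
group/context's nonzero counts; the quantile component can be disabled
(`quantile = NULL`), and fixture verification uses the floor-only rule
(floor 10) because a within-run quantile threshold is not scale-free on
synthetic data — the 99th percentile of window counts lands inside the
planted windows' own counts. Peaks are called per group and then
intersected; a shared peak must be a peak in every group, so adding a
group can only shrink the shared set.

Methylation–feature relationships are summarized by OLS of window
weighted methylation on gene, RE and pseudogene density (bp fraction of
window). RE proximity uses boundary-to-boundary gap distances
(overlap = 0) with right-closed category edges at 2, 5 and 10 kb, and
group differences in normalized abundance and |log2FC| are tested with
Games–Howell (Welch t with Welch–Satterthwaite df against the
studentized range distribution at `q = |t|√2`, evaluated numerically
via R's `ptukey`). Window PCA is a centered SVD of the sample × window
level matrix.

## Numerical conventions

Internal coordinates are 0-based half-open; allc and GFF3 files on disk
are 1-based inclusive and BED output is 0-based half-open, with the
conversions centralized in the I/O layer. Zero pooled coverage yields
an `NA` level (undefined), never 0. Probabilities are clipped to [0, 1]
after every shift. Metaplots pool reads across features (whether the
original figure pooled reads or averaged per-feature levels is
unknowable; pooling matches the weighted-level definition used
everywhere else). Flank bins anchor at annotated boundaries even when
flanks overlap neighbouring features.

## Problem sizes

The default genome is ~2.1 Mb (~1.07 M cytosine sites, ~0.2 M CHG
sites); a baseline triplicate simulation plus genome-wide levels runs
in well under a minute, a 20 000-site calibration panel with B = 1000
permutations in ~20 s, and the four-group shared-peak fixture run
(four genome-wide CHG analyses on the 1.05-Mb peaks preset) in a few
minutes on one CPU. These sizes are deliberate: every published check
in the README and the acceptance script recomputes from scratch at
these scales.

## Known limitations

* The DMS test models binomial sampling only; biological replicate
  overdispersion beyond binomial is not modelled, matching the
  generator but understating uncertainty on real data.
* The DE engine is a compact stand-in calibrated on type-I error and
  recovery, not a reproduction of any commercial pipeline's gene lists.
* The peak rule's floor is count-based and therefore scale-dependent;
  on real genomes the quantile component should be re-enabled.
* Single-site power at stringent empirical FDR is intrinsically low
  (~0.2 at a +0.3 shift, 3v3, 30×); region-level recovery is the
  designed-for operating point.
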