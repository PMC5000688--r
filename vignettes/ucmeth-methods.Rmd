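---
title: "Methods: promoter hypermethylation discovery in ulcerative colitis"
author: "ucmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: promoter hypermethylation discovery in ulcerative colitis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis this package implements

`ucmeth` re-implements, as tested and reusable code, a genome-wide screen
for promoter-hypermethylated genes in ulcerative colitis (UC). The design
under study compares Infinium-450K-style methylation profiles of normal
colon (NC, n = 3) and UC (n = 8) rectal tissue, with a fully methylated
colon-cancer cell line as positive control, and funnels ~20,000-480,000
CpG probes down to a small panel of promoter CpG-island hypermethylation
candidates, which a wet-lab validation layer (MSP, bisulfite sequencing,
qMSP, qRT-PCR) then confirms in a 79-patient cohort.

Because raw array data are an external accession, the package ships a
synthetic-data module that emulates the statistical structure the analysis
assumes. Every pipeline stage is therefore testable end to end against
planted ground truth, without downloads.

# The measurement model

A probe interrogates one CpG with two fluorescence channels, methylated
(M) and unmethylated (U). The generator draws, per probe and sample,

* a true methylation fraction `beta_true` (see below),
* a total intensity `T ~ Lognormal(log 4000, 0.3)` (arbitrary fluorescence
  units),
* an additive optical background `b ~ Normal(200, 30)`, floored at 0,
  entering both channels,

and sets `M = round(d * (beta * T + b))`, `U = round(d * ((1-beta) * T + b))`
where `d` is a per-sample lognormal dye/scanner factor (sd 0.1 on the log
scale). Negative-control probes (600 per sample) draw from the background
distribution alone. Type-II probes (72% of the array, matching the real
platform's design mix) have their betas compressed toward 0.5 by
`beta' = 0.5 + 0.8 * (beta - 0.5)` before the intensity layer — the
known distributional distortion of the second Infinium chemistry, and the
distortion the BMIQ-style normalization must undo.

True methylation fractions come from a three-state mixture. Each probe
gets a baseline state (unmethylated / intermediate / methylated, beta
shapes (2,18), (5,5), (18,2)) with state probabilities that depend on its
annotation compartment: promoter-island probes are predominantly
unmethylated (85/10/5), open-sea probes predominantly methylated
(20/25/55). This mirrors real array biology, where CpG-island promoters
are unmethylated and gene bodies / open sea are methylated. Per-sample
biological variation is a mean/sd-reparameterised beta draw around the
probe baseline with sd 0.05.

Two numerical choices in this layer matter and were made once, by design:

* **Probe baselines are clamped to [0.08, 0.92].** Measured Infinium betas
  rarely reach the extremes (the offset and background compress them), and
  near-boundary baselines make the per-sample beta noise so skewed that a
  pooled t-test at n = 3 vs 8 becomes conservative (empirical size ~0.042
  instead of 0.05 in a design simulation). With the clamp, the t-test is
  correctly calibrated under the null, which is a stated property of the
  analysis.
* **The positive-control sample is floored at beta 0.85 at planted hyper
  probes** so the cell-line analog is unambiguously fully methylated at the
  candidate panel, as its role in the screen requires.

Planted effects: `n_planted_hyper` probes (default 250) with baseline
beta <= 0.5 gain `+delta` (default 0.3) in UC samples; hypomethylation
(default 20 probes) mirrors this downward from high baselines. Restricting
hypermethylation to low baselines is both biologically right (promoter
islands start unmethylated) and what makes the planted shift realizable
without truncation, so the empirical planted delta matches the target.
The default delta of 0.3 was chosen to sit above the screen's
delta-beta > 0.2 gate; the real effect-size distribution in UC is unknown.

# Preprocessing

1. **Detection p-values.** A probe's total signal `M + U` is compared to a
   Gaussian fit of the *doubled* negative controls (background enters both
   channels): `p = 1 - Phi((M+U - mu)/sigma)`. The vendor's exact
   definition is not public; this model is simple, monotone in signal and
   testable.
2. **Dye/brightness scaling.** Each sample is scaled by grand-median /
   sample-median total intensity. This removes exactly the multiplicative
   per-sample factor the generator introduces; full two-channel dye
   chemistry is out of scope.
3. **Background subtraction.** Channel-wise subtraction of the sample's
   mean negative-control intensity, floored at zero.
4. **Call-rate QC.** Samples with call rate (< 0.05 detection p) below
   0.99 are dropped; probes failing detection in *any* retained sample are
   excluded — the strictest reading of a "probe call rate > 99%, high
   quality CpGs only" screen, chosen deliberately and documented here.
5. **Beta values.** `beta = M / (M + U + 100)`; the offset 100 is the
   standard Infinium stabilizer.

## BMIQ-style normalization

Per sample and design type, a three-state beta mixture (states U/H/M) is
fitted by EM:

* E-step with weighted beta densities; M-step maximizes each component's
  weighted beta log-likelihood by BFGS on log-shape parameters (the
  two weighted sufficient statistics `sum r log x`, `sum r log(1-x)` make
  each objective evaluation O(1)), so the observed-data log-likelihood is
  non-decreasing — a property the tests check numerically.
* Initialization is moment matching on tertiles; tolerance 1e-6 relative
  log-likelihood change, cap 500 iterations; non-convergence returns the
  best fit with a warning rather than failing.
* The EM fit subsamples at most 5,000 beta values per fit (seeded,
  deterministic). The fit is a density estimate, for which 5,000 points
  are ample; the transform is applied to all probes.

Type-II probes are then mapped onto the type-I scale: each probe is
assigned a state by the fitted posterior-argmax cutpoints (so assignment
is monotone in beta), U-state and M-state values go through the
parametric quantile map `qbeta(pbeta(x, shapes_II), shapes_I)` of the
matching component, and the intermediate H state is rescaled linearly
onto the gap between the transformed boundaries. Continuity at the
cutpoints makes the whole per-sample map monotone, so within-type-II
rank order is preserved; type-I values are never touched. On generator
output the Kolmogorov-Smirnov distance between type-I and type-II
distributions drops from ~0.24 to ~0.03 per sample.

# The differential-methylation funnel

Per CpG, a two-sided Student's pooled-variance t-test of UC vs NC betas
("independent samples t-test" read classically; Welch is available behind
a flag), with two gates applied jointly: `p < 0.05` **and**
`|delta beta| > 0.2` where `delta beta = mean(UC) - mean(NC)`. Survivors
split into hyper/hypo by sign. Hypermethylated survivors then pass a
fold-change filter `(mean_UC + 0.01) / (mean_NC + 0.01) > 1.7` (the
pseudocount guards near-zero NC means; the source analysis is silent on
zero denominators), and finally a promoter CpG-island selection: probes
annotated `promoter` **and** `island`. No multiple-testing correction is
applied in the funnel — the screen filters on raw p plus an effect-size
gate; BH-adjusted p-values can be added as a report column without
altering the funnel. Positive-control samples are excluded from all
testing and appear only in cluster displays.

The global hyper/hypo comparison uses a two-sided Mann-Whitney U test
(normal approximation with tie correction at scale) on per-probe group
means, separately for the hyper and hypo sets — the display-level
statistic, distinct from the per-probe t-tests.

Under the calibrated study conditions (20,000 probes, 3 vs 8, 250 planted
hyper CpGs at delta 0.3, noise sd 0.05), the funnel recovers >= 99% of
planted hypermethylation with zero false hyper calls among ~19,700 null
probes, and the null configuration rejects at the nominal 5% rate.

# CpG-island calling and annotation

Islands are called from sequence with the classical criteria: windows of
200 bp with GC fraction > 0.50 and observed/expected CpG
`(#CpG * len) / (#C * #G)` > 0.6. (A literal reading of "greater than 50%
CpG dinucleotides" is biologically impossible; the package follows the
standard definition those screens cite, with all thresholds exposed as
arguments.) Qualifying windows are merged; each merged region is snapped
inward to its terminal CpG dinucleotides — islands are CpG-delimited, as
in classical island-search tools — and emitted if the snapped interval
still qualifies, otherwise the longest qualifying sub-interval (leftmost
on ties) is emitted. `N` disqualifies windows. The caller is exact
against a brute-force string-counting oracle on a 1,000-sequence corpus.

That corpus is AT-rich, CpG-free background (bulk vertebrate genome is
CpG-depleted, which is also why islands are detectable at all) with
embedded engineered islands. Uniform iid DNA is deliberately *not* used:
with random composition near GC 0.5 the observed/expected ratio hovers
near 1 everywhere and the island concept degenerates.

Probe annotation: promoter is TSS -1500/+500 strand-aware (in the spirit
of the platform's TSS1500/TSS200 classes), precedence
promoter > exon > intron > intergenic; island relation uses 2 kb shores
and 2 kb shelves. The manifest generator vectorizes these rules; tests
assert agreement with the scalar definitions.

# Clustering and MDS

Hierarchical clustering of samples on the DMC panel (Euclidean, average
linkage — the source names neither, so both are arguments), with purity =
majority-label fraction at a k-cluster cut as the concordance score.
Classical MDS is the double-centered Gram eigendecomposition
(`stats::cmdscale`) on 1 - Pearson distances, with each axis's sign fixed
so its largest-magnitude loading is positive, making coordinates
bit-reproducible.

# Validation-layer statistics

* **MSP frequencies**: percent methylated per gene x group, one decimal.
* **Bisulfite clones**: per-CpG fractions, overall density, text lollipop
  grids.
* **qMSP**: replicate Cts averaged; `dCt = Ct_gene - Ct_Alu` (repeat
  element normalizer); level `2^-(dCt - dCt_IVD)` with in-vitro methylated
  DNA as calibrator; water controls are never quantified.
* **Expression (delta-delta-Ct)**: `dCt = Ct_gene - Ct_housekeeping`,
  referenced to the *mean* dCt of the control group (the calibrator choice
  the source leaves open). The housekeeping assay is a parameter because
  the source is internally inconsistent about it (beta-actin in methods,
  GAPDH in a figure caption).
* **Candidate filter**: three gates — expressed in NC, NC methylation <=
  25%, UC methylation >= 50%. The source states the gates qualitatively
  only; the numeric thresholds are explicit configurable defaults.
* **Group tests**: mean +/- sample SD and pooled t; both-groups-constant
  inputs degenerate to p = 1 (equal means) or a flagged p -> 0 limit.
* **Cohort summary**: n and percent per categorical field to one decimal;
  age as mean, median and range (the published table's age row conflates
  the two labels, so both are emitted).

`qmsp_relative` and `ddct_expression` exactly invert the Ct generator at
zero noise; this closed loop is an acceptance-level test.

# Enrichment

Gene-set over-representation is the upper hypergeometric tail
`P(X >= k)` with significance at raw `p < 1e-3` and overlap >= 2, against
a user-supplied GMT and a universe defaulting to all manifest genes. The
original analysis used a network-based web service with redundancy
reduction; both are external services and out of scope — the transparent
hypergeometric test is the package's deliberate replacement, and specific
term lists are not a comparison surface.

# Problem sizes and determinism

The calibrated study conditions used by the tests and the acceptance
script are 20,000 probes x 12 samples — large enough that call rates,
funnel counts and calibration rates are stable, small enough that a full
simulate-preprocess-funnel cycle takes seconds. Every stochastic step
flows from a single integer seed (generator streams are separated by
fixed offsets), and end-to-end reruns with the same configuration are
bit-identical, which the pipeline tests assert.

# Known limitations

* No IDAT parsing, no two-color channel chemistry, no out-of-band
  background variants (noob), no functional normalization, no batch
  correction, no SNP/cross-reactive probe handling: the generator writes
  matrix-level TSVs and the simplified dye model matches it.
* The published headline probe counts (e.g. 454,215 of 485,577 retained;
  4,397 hyper / 420 hypo; 237 fold-filtered; 48 promoter-island) derive
  from the deposited accession and vendor preprocessing, and are not
  reproducible from synthetic data; the package reproduces the *rules*
  and demonstrates their behavior against planted truth, plus the
  published row-level worked examples (cohort percentages, MSP
  frequencies) exactly.
* Passing tests on generator output shows the pipeline implements its
  stated rules correctly and recovers planted structure under realistic
  noise; it does not certify performance on real arrays, whose artifacts
  (probe cross-reactivity, cellular heterogeneity, batch structure) the
  generator deliberately omits.
* Gene-level deduplication of multi-probe hits is provided but the exact
  published probe-to-gene mapping is not recoverable without the original
  appendix; counts are reported at probe level by default.
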