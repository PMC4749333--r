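---
title: "Evaluating qPCR reference genes: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating qPCR reference genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refstab)
```

## The problem

Relative quantification by qPCR divides a target gene's signal by that of
one or more reference genes. If a reference gene's own expression moves
with the experimental conditions, that movement propagates — inverted —
into every normalized result. `refstab` screens a panel of candidate
reference genes across heterogeneous samples (genotypes, stress
treatments, tissues) and ranks them by expression stability using five
complementary algorithms, then validates the chosen references by showing
what normalization does to a known induction.

The package operates on quantification cycles (Cq): the PCR cycle at which
a reaction's fluorescence crosses threshold. One cycle corresponds to a
(1 + E)-fold difference in starting template, where E is the assay's
amplification efficiency (E = 1 is perfect doubling).

## Data model and replicate handling

A `cq_dataset` is a gene × unit × technical-replicate array, where a unit
is one biological replicate of one sample. Aggregation is two-stage:
technical replicates are averaged within each biological replicate, then
biological replicates within each sample. This matches the usual qPCR
hierarchy, in which technical replicates share one cDNA load (pipetting
noise only) while biological replicates are independent organisms.
Technical-replicate SDs above a threshold (default 0.5 cycles — roughly a
1.4-fold discrepancy at E = 1, the usual plate-QC rule of thumb) are
flagged but never removed or imputed; whether to exclude noisy wells is an
audit decision, not something the data layer should silently take.

Samples are organized into overlapping sets (`genotypes`, `stress`,
`tissues`, `all`), with the `all` set required to be a superset of the
others; one control sample may be shared by every set. Each set is
analyzed self-contained: relative-quantity calibrators, listwise exclusion
of incomplete samples, and all rankings are recomputed within the set.

## Efficiency calibration and relative quantities

Standard curves are ordinary least-squares fits of mean Cq against log10
relative template amount over a serial dilution (at least 3 points;
2-fold, 5-point series are typical). The efficiency is
`E = 10^(−1/slope) − 1`. Efficiencies are accepted up to 1.2; values above
1.1 draw a warning, since over-unity efficiencies indicate inhibitors or
artefacts at high template rather than true super-doubling.

Cq is converted to a linear-scale relative quantity per gene:
`rq = (1 + E)^(minCq − Cq)`, using the gene's minimum Cq within the
analyzed set as calibrator so that `max rq = 1`. The calibrator choice is
immaterial downstream — every stability statistic works on log ratios or
centered logs, where a per-gene constant cancels — and the tests assert
this invariance explicitly. All log-scale work uses log2, matching the
doubling semantics of PCR.

## The five stability methods

**geNorm.** `V_jk = SD(log2(rq_j / rq_k))` over samples (sample SD, n − 1
denominator, as everywhere in the package); `M_j = mean_{k≠j} V_jk`. The
highest-M gene is removed and M recomputed until two remain. The last two
genes have equal M by construction and are reported as a tied pair; in the
consensus they enter with midrank 1.5 each (configurable to 1/2), since
the method genuinely cannot separate them. Exclusion ties are broken by
removing the lexicographically later gene id — an arbitrary but
deterministic rule.

**Pairwise variation / optimal n.** `V(n, n+1)` is the SD of
`log2(NF_n / NF_{n+1})`, where `NF_n` is the per-sample geometric mean of
the n most stable genes' rq. The optimal number of reference genes is the
smallest n with `V < 0.15`, the conventional cutoff below which adding a
gene no longer changes normalization appreciably; the cutoff is a
parameter, and when no V falls below it the result is flagged "not
reached" rather than forced.

**NormFinder.** Works on `y = log2(rq)`. Within each group the matrix is
two-way centered (per-sample mean across genes removes loading, per-gene
group mean removes expression level). Because centering with J genes
leaks a (1/J²)-weighted share of every gene's variance into every
residual, the raw residual variance `s²_gj` is unbiased via
`σ̂²_gj = (J/(J−2)) (s²_gj − Σ_k s²_gk / (J(J−1)))`, clamped at zero (the
standard moment-estimator practice; the correction is exposed as an
option). The intergroup deviation `d_gj` is the gene × group mean table
two-way centered with unweighted means, so it sums to zero over genes
within a group and over groups within a gene. The stability value is
`ρ_j = mean_g(|d_gj| + √(σ̂²_gj / n_g))`; ungrouped mode reports
`ρ_j = √σ̂²_j`. The pipeline uses grouped mode whenever every group in a
set has at least two samples and falls back to ungrouped otherwise (tissue
sets with one sample per tissue cannot support a group term).

**BestKeeper and comparative ΔCt** consume raw mean Cq, not
efficiency-corrected rq, matching the conventions of the original tools:
BestKeeper reports each gene's Cq SD and CV% plus its Pearson correlation
with the per-sample geometric-mean Cq index (ranking is by SD; correlation
ranking is available behind a flag, since the index correlation rewards
co-variation rather than constancy), and the ΔCt method scores each gene
by the mean SD of its pairwise Cq differences. With all efficiencies equal
to 1 the ΔCt score equals geNorm's first-pass M exactly (Cq differences
*are* log2 expression ratios then) — a cross-method identity the test
suite asserts.

**Consensus.** Per-method ranks (midrank ties allowed) are aggregated by
geometric mean and ordered ascending, lexicographic on exact ties. The
geometric mean is the RefFinder convention; it always lies between the
gene's best and worst rank.

## Validation stage

The expression ratio of a target between control and treatment,
normalized by references r = 1…R, is
`R = (1+E_t)^(meanCq_t,ctrl − meanCq_t,trt) / geomean_r (1+E_r)^(meanCq_r,ctrl − meanCq_r,trt)`.
A reference that itself shifts δ log2 units under treatment multiplies R
by exactly 2^−δ — the mechanism by which unstable references obscure or
cancel true inductions, demonstrable here on noiseless fixtures.

Significance comes from a fixed-reallocation randomization test: whole
replicate samples (target and reference wells together, preserving their
pairing) swap condition labels; the two-sided p-value is the proportion of
reallocations whose |log R| reaches the observed one, with +1 smoothing in
numerator and denominator of the Monte-Carlo estimate. When fewer than 10
distinct reallocations exist the test enumerates all of them instead and
returns the exact proportion. One granularity consequence deserves
emphasis: a 3v3 design admits only C(6,3) = 20 distinct reallocations, so
the smallest attainable two-sided p is 0.1 — no effect size can reach
p < 0.05 at 3v3. Designs needing α = 0.05 decisions should use at least
4v4 (70 splits) or pool replicates; the test's conservatism at small n is
a property of the statistic, not an implementation limit.

## The synthetic-data generator

The generator emulates the structure of a diverse-plant-panel study: 25
candidate genes; 20 samples in four overlapping sets (9 genotypes, 8
stress-set samples, 5 tissues, with one shared control present in every
set); 3 biological × 3 technical replicates; per-gene efficiencies drawn
uniformly in [0.90, 1.09] and baseline Cq in [19, 28] cycles — the ranges
validated primer panels typically show. Expression of gene j in
biological replicate i is

`x_ij = β_{group(i), j} + s_i + ε_ij`,  `ε_ij ~ N(0, τ_j²)`,  `s_i ~ N(0, 0.5²)`

on the log2 scale, converted to cycles by `Cq = a_j − x_ij / log2(1+E_j)`,
with N(0, 0.15²) cycles of technical noise per well. Noise is injected on
the log2 scale because that is the scale on which every stability method
measures dispersion, so τ_j *is* the ground-truth instability. The default
τ ascends linearly from 0.02 to 0.8 log2 units across genes, spanning
"essentially perfect reference" to "clearly unusable"; the sample-effect
SD of 0.5 log2 represents realistic loading variation (it cancels in all
ratio statistics but exercises BestKeeper's Cq-scale view); 0.15 cycles of
technical noise is typical instrument repeatability. Group effects default
to zero — stability screening, not differential expression, is the
scenario — and can be switched on per gene × group.

What the generator does **not** emulate: Cq-dependent
(heteroscedastic) noise from low template, amplification inhibitors,
missing wells, plate/batch effects, and correlated co-regulation between
candidate genes. Passing recovery tests therefore show that the
algorithms, given data obeying their own model, identify injected
stability orderings — they do not certify performance on pathological real
plates, which is precisely why the QC layer flags rather than repairs.

## Numerical and design choices

- Sample SD (n − 1) throughout; geometric means computed as
  `exp(mean(log x))` for numerical robustness.
- Missing Cq stays missing at the data layer; listwise sample exclusion
  happens per analyzed set at conversion time, and genes left with no data
  abort with a named error.
- Degenerate inputs: standard curves with non-negative slope return
  `valid = FALSE` rather than erroring (screening workflows want to see
  the failure, not die on it); constant BestKeeper indexes report missing
  correlations; fewer than 3 genes is a hard error for all panel methods.
- Determinism: stability analyses draw no random numbers; the generator
  and randomization test take explicit seeds; report CSVs are written so
  that a rerun with the same inputs is byte-identical.
- Problem sizes in the test and acceptance runs — 200 six-gene oracle
  instances, 50 recovery replicates of the full 25 × 20 design, 500
  dilution fits, 100 null randomization tests — were chosen to estimate
  the checked rates with comfortable margins while keeping a full run in
  well under a minute per block on one core.

## Known limitations

- NormFinder here is the moment-estimator formulation; REML/Bayesian
  variants and the candidate-pair stability values some ports report are
  out of scope.
- BestKeeper's regression-based p-values and outlier-removal heuristics
  are not reproduced; the index is descriptive.
- The randomization test covers two conditions; multi-factor designs and
  bootstrap confidence intervals are out of scope.
- Stability rankings from any of these methods are relative to the panel
  analyzed: a panel of uniformly co-regulated genes would look spuriously
  stable to ratio-based methods (geNorm's known weakness), which is one
  reason four methods plus a consensus are reported rather than one.
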