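# refstab

Reference-gene stability evaluation for qPCR normalization.

Quantitative real-time PCR expresses a target gene's abundance relative to
one or more *reference* (housekeeping) genes, so every conclusion rests on
the assumption that those references are stably expressed across the samples
being compared. That assumption fails often enough — across genotypes,
tissues and stress treatments — that candidate reference genes have to be
screened statistically before use. `refstab` implements the complete
screening workflow used in plant reference-gene surveys, from raw
quantification-cycle (Cq) tables and dilution-series calibration through
five stability algorithms, the optimal-reference-number analysis, and
validation of the chosen references by efficiency-corrected relative
expression with a randomization test. A synthetic-data generator with known
ground truth makes every stage testable.

## The statistics

Let `rq[g, i] = (1 + E_g)^(minCq_g − Cq[g, i])` be the efficiency-corrected
relative quantity of gene *g* in sample *i*, with `E_g` the amplification
efficiency from the gene's standard curve (`E = 10^(−1/slope) − 1`).

- **geNorm M** — for genes *j*, *k*, the pairwise variation `V_jk` is the
  sample SD over samples of `log2(rq_j / rq_k)`; `M_j = mean_{k≠j} V_jk`.
  The gene with the highest M is removed and M recomputed until two genes
  remain (the tied best pair). The pairwise-variation curve
  `V(n, n+1) = SD(log2(NF_n / NF_{n+1}))`, with `NF_n` the geometric mean of
  the *n* most stable genes' rq per sample, determines the optimal number of
  reference genes: the smallest *n* with `V < 0.15`.
- **NormFinder** — decomposes `log2 rq` into sample loading, gene level,
  intragroup variance `σ²_gj` and intergroup deviation `d_gj`; the stability
  value is `ρ_j = mean_g(|d_gj| + √(σ²_gj / n_g))` (ungrouped:
  `ρ_j = √σ²_j`).
- **BestKeeper** — per-gene SD and CV% of raw Cq, plus each gene's Pearson
  correlation with the per-sample geometric-mean Cq index; ranked by SD.
- **Comparative ΔCt** — mean over partner genes of the SD of per-sample Cq
  differences.
- **Comprehensive ranking** — RefFinder-style geometric mean of the four
  methods' ranks, ascending.

Validation uses the REST-style ratio
`R = (1+E_t)^(ΔCq_target) / geomean_r (1+E_r)^(ΔCq_ref)` with a
fixed-reallocation randomization test (whole replicate samples swap
condition labels jointly across genes).

## Worked example

```r
library(refstab)

# a 25-gene x 20-sample study (3 biological x 3 technical replicates),
# per-gene noise SD ascending from 0.02 to 0.8 log2 units
sim <- simulate_cq_dataset(simulation_config(seed = 101))
m   <- aggregate_replicates(sim$dataset)
rq  <- to_relative_quantities(m, sim$efficiency)

gn <- genorm_rank(rq)
#> <genorm_result> 25 genes; most stable pair: gene01/gene02 (M = 0.0748)
pairwise_variation_curve(rq, gn)$optimal_n
#> [1] 2          # V(2/3) = 0.0288 < 0.15: two reference genes suffice

nf <- normfinder_stability(rq)
comprehensive_rank(list(genorm = gn$ranks, normfinder = nf$ranks,
                        bestkeeper = bestkeeper(m)$ranks,
                        deltact = delta_ct_stability(m)$ranks))
#> <stability_table> 25 genes; comprehensive top 4: gene01, gene02, gene03, gene05
```

The generator injected the least noise into the lowest-numbered genes, and
the consensus ranking recovers exactly that order: the top-4 genes are the
four most stable by construction. `geomean_rank` (e.g. 1.565 for `gene01`)
is the geometric mean of the gene's ranks across the four methods.

Validation stage — a true 4-fold induction, recovered with stable
references but cancelled by references that shift 2 log2 units themselves:

```r
val <- simulate_validation_scenario(fold_change = 4, unstable_ref_shift = 2,
                                    reps = 5, noise_sd = 0.2, seed = 8)
randomization_test(val$cq, val$target, val$stable_refs, val$eff, seed = 9)
#> <expression_ratio> target vs treatment/control, refs stable_ref1+stable_ref2: ratio = 3.356
#>   randomization p = 0.006497 (2000 permutations)
expression_ratio(val$cq, val$target, val$unstable_refs, val$eff)
#> <expression_ratio> target vs treatment/control, refs unstable_ref1+unstable_ref2: ratio = 0.9138
```

The whole analysis (all four overlapping sample sets, report CSVs) runs via
`run_full_analysis(sim$dataset, sim$efficiency, out_dir = "reports")`, or
from a shell through the thin wrapper `inst/exec/refstab`
(`refstab simulate|calibrate|rank|validate|all`).

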