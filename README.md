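# thoughtnet

Resting-state functional connectomes, experience-sampling reports of
ongoing thought, and self-reported well-being, linked in one tested
inference chain. The package is aimed at network-neuroscience and
individual-differences researchers who collect (a) ROI time series or
precomputed correlation connectomes, (b) retrospective thought ratings on a
short Likert questionnaire, and (c) well-being domain scores, and want the
full pipeline — decomposition, component discovery, graph metrics,
reliability, mediation — with permutation-exact error control and
reproducible seeds.

## What it computes

1. **Thought-pattern decomposition.** Items are Ward-clustered (squared
   Euclidean distance) into two groups; each group is reduced by PCA on the
   item correlation matrix and varimax-rotated, yielding six per-subject
   component scores (regression method).
2. **Network-based statistic (NBS).** At every connectome edge, OLS of edge
   weight on the six scores plus nuisance regressors (intercept, mean
   connectivity, age, gender, motion fraction). Edges with |t| ≥ T (default
   T = 3.2) form suprathreshold components; each component of size *s*
   (edge count) gets a family-wise-error-corrected p-value from a
   permutation null of the maximal component size *M*:

   p_FWE = ( #{ M_perm ≥ s } + 1 ) / ( n_perm + 1 ),  n_perm = 5,000 by default.

3. **Signed graph metrics** on mask graphs: positive / negative / total node
   strength, *fractional strength* FS = Σw⁺ / Σ|w⁻| (analyzed as ln FS),
   and weighted betweenness centrality on lengths 1/|w|.
4. **Test-retest reliability**: ICC(2,1) with percentile-bootstrap CIs, and
   Pearson correlation of session-to-session changes.
5. **Mediation**: standardized paths a (brain→thought), b
   (thought→well-being), c′ (direct), indirect effect a·b with a
   percentile-bootstrap CI (5,000 resamples), covariate-adjusted,
   Bonferroni-corrected across the two well-being domains.

A synthetic cohort generator (`simulate_cohort()`) plants known factor
structure, known connectome components, a known mediation chain, and a
state/trait retest structure, so the whole chain is testable without any
data download.

## Worked example

```r
library(thoughtnet)

# a desk-scale synthetic study: 200 subjects, 60 nodes, two planted
# components (state-like mediated, trait-like non-mediated), 40 retest
report <- run_synthetic_pipeline(desk_cohort_config(seed = 1))
report
#> <pipeline_report> 200 subjects, 60 nodes
#>   decomposition: variance explained A 87%, B 88%
#>   NBS: 2 significant component(s) across 6 contrast(s)
#>     clusterA_pc1_c1: 11 edges, FWE p = 0.000999
#>     clusterB_pc3_c1: 13 edges, FWE p = 0.000999
```

Both planted components are recovered as FWE-significant NBS components
(p ≈ 0.001 at 1,000 permutations — the smallest value the +1-smoothed
estimator can produce). The mediated, state-like component carries a
significant indirect effect on psychological well-being:

```r
report$mediation$clusterA_pc1_c1$mediation$psychological
#> <mediation_result> a = 0.711, b = 0.507, c' = 0.061; indirect = 0.360,
#>   SE = 0.063, 95% BCI [0.244, 0.500] * (n = 200)
```

a = 0.711 is the standardized brain→thought path (log fractional strength
of the component predicting the thought score), b = 0.507 the adjusted
thought→well-being path, and the indirect effect 0.360 has a bootstrap CI
excluding zero (`*`). The trait-like component shows no significant
indirect effect, but its thought score is far more reliable across
sessions:

```r
report$reliability$score_icc$clusterB_pc3
#> <icc_result> ICC2_1 = 0.717, 95% BCI [0.584, 0.812], p = 8.43e-08 (n = 40)
```

versus ICC ≈ 0.10 for the state-like score — whose *changes*, however,
track changes in its brain component (r = 0.34, p = 0.032). That
dissociation — a transient neurocognitive state that mediates well-being
versus a stable trait that does not — is the qualitative pattern the
pipeline is built to detect.

Tidy accessors and plots are available throughout: `tidy()` / `glance()`
on NBS, ICC, mediation, and model objects; `autoplot()` for the NBS null
distribution, loading heatmaps, and mediation paths.

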