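# hemilat

Statistical analysis of hemispheric lateralisation and interindividual
variability for paired bilateral measurements — typically white matter
tract metrics (HMOA, streamline count, voxel count) measured in both
hemispheres of each participant for language-recruited pathways (the
three arcuate segments AFl/AFa/AFp, IFOF, UF, ILF, FAT).

The package answers three distinct questions about a bilateral cohort:

1. **Is a tract lateralised on average?** Per participant,
   LI = (right − left)/(right + left) ∈ [−1, 1]; the group mean LI is
   tested against zero with a Bayes factor comparing an intercept model
   to a null model, under a Cauchy(0, 0.707) prior truncated to
   [−1, 1] — computed by deterministic quadrature, so results are
   bit-reproducible, with prior-robustness and sample-size-stability
   sweeps built in.
2. **Is one hemisphere more variable across individuals?**
   VI = (MAD_R − MAD_L)/(MAD_R + MAD_L), with MAD the raw median
   absolute deviation; significance comes from a paired hemisphere-swap
   permutation test (each participant's left/right swapped with
   probability 0.5; 100,000 permutations; Bonferroni α = 0.05/24 across
   the 21 tract-level plus 3 hemisphere-averaged tests).
3. **Do lateralisation profiles form discrete phenotypes or a
   continuum?** A 2-D UMAP embedding of the participants × 21 LI matrix
   (n_neighbors = 15, min_dist = 0.1, Euclidean) plus quantitative
   clustering-tendency diagnostics (Hopkins statistic, best k-means
   silhouette) computed on the original feature space.

A calibrated synthetic cohort generator (Gaussian copula on latent
log/logit scales, controllable population LI, MAD ratio, interhemispheric
correlation and reconstruction-failure rates) makes every stage testable
without any external data.

## Worked example

Simulate a 164-participant cohort in the qualitative regime reported for
language pathways (leftward AFl/ILF/FAT, rightward AFa/UF, greater
left-hemisphere variability for ILF/FAT counts, right for AFa/UF):

```r
library(hemilat)
library(dplyr)

cfg <- language_scenario(seed = 42)
cohort <- simulate_cohort(cfg)   # long tibble, 6,888 rows:
                                 # participant x tract x metric x hemisphere

bayes <- bayes_li(cohort)        # 21 Bayesian lateralisation tests
bayes |> filter(metric == "TC")
#> # A tibble: 7 × 9
#>   tract metric     n est_mean est_error  ci_low ci_high     bf10 log10_bf10
#>   <fct> <fct>  <int>    <dbl>     <dbl>   <dbl>   <dbl>    <dbl>      <dbl>
#> 1 AFl   TC       163  -0.212     0.0308 -0.274  -0.154  9.28e+ 7      7.97
#> 2 AFa   TC       162   0.284     0.0287  0.226   0.339  4.17e+15     15.6
#> 3 AFp   TC       164  -0.0888    0.0290 -0.147  -0.0333 5.51e+ 0      0.741
#> 4 IFOF  TC       164  -0.0271    0.0255 -0.0784  0.0218 8.35e- 2     -1.08
#> 5 UF    TC       163   0.348     0.0230  0.301   0.391  9.75e+29     30.0
#> 6 ILF   TC       164  -0.236     0.0241 -0.285  -0.190  1.88e+15     15.3
#> 7 FAT   TC       162  -0.537     0.0168 -0.571  -0.505  3.12e+68     68.5
```

Each row is one tract × metric: the posterior mean and SD of the group
mean LI, its 95% credible interval, and the Bayes factor for
lateralisation over bilaterality. Here the strongly left-lateralised FAT
(est_mean −0.54) reaches extreme evidence, while the IFOF streamline
count (BF10 = 0.08) shows evidence *for* bilaterality — directions and
magnitudes follow the generator's targets.

The variability family, with permutation inference:

```r
vi <- vi_family_analysis(cohort, n_perm = 10000, seed = 1)
vi |> filter(metric == "TC", tract != "ALL") |>
  select(tract, vi, p_value, p_is_floor, significant)
#> # A tibble: 7 × 5
#>   tract      vi p_value p_is_floor significant
#>   <chr>   <dbl>   <dbl> <lgl>      <lgl>
#> 1 AFl    0.164   0.0178 FALSE      FALSE
#> 2 AFa    0.349   0.0001 TRUE       TRUE
#> 3 AFp    0.121   0.102  FALSE      FALSE
#> 4 IFOF  -0.0725  0.300  FALSE      FALSE
#> 5 UF     0.322   0.0001 FALSE      TRUE
#> 6 ILF   -0.328   0.0001 TRUE       TRUE
#> 7 FAT   -0.558   0.0001 TRUE       TRUE
```

Negative VI = greater left-hemisphere dispersion across individuals (ILF,
FAT); positive = right (AFa, UF). `p_is_floor` marks p-values reported at
the 1/n_perm floor because no permuted value was as extreme.

A single fit carries its own numerical certificate (no MCMC, no chains):

```r
fat_tc <- li_table(cohort) |>
  filter(tract == "FAT", metric == "TC") |> pull(li) |> na.omit()
bf_li(fat_tc)
#> Bayesian one-sample lateralisation test (quadrature)
#>   n = 162, prior Cauchy(0, 0.707) on [-1, 1] (mean)
#>   BF10 = 3.116e+68 (log BF = 157.7)
#>   posterior mean -0.5366 (sd 0.0168), 95% CI [-0.571, -0.505]
#>   quadrature error on log BF: 5.4e-05
```

Phenotype structure — embedding plus clustering tendency:

```r
m <- li_matrix(cohort)                  # 158 complete participants x 21
emb <- embed_li(m, seed = 1)            # autoplot(emb) for the map
clusterability(m, seed = 1)
#> Clustering tendency of LI profiles (n = 158)
#>   Hopkins statistic: 0.570 (0.5 = unstructured)
#>   best silhouette: 0.089 at k = 2
```

A best silhouette of 0.09 is far below any clustered regime
(well-separated archetypes exceed 0.5): profiles vary along a continuum
rather than splitting into discrete left/right/bilateral phenotypes.

`run_report(config = cfg, out_dir = "out", seed = 1)` chains all stages
and writes `li.tsv`, `bayes.tsv`, `vi_results.tsv`, `embedding.tsv`,
`clusterability.json` and a manifest sufficient to regenerate every
number bit-identically.

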