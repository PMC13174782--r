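---
title: "Methods: quantifying lateralisation and variability in bilateral tract metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying lateralisation and variability in bilateral tract metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

hemilat analyses paired bilateral measurements — typically white matter
tract metrics (HMOA, streamline count, voxel count) for language-recruited
pathways measured in both hemispheres of each participant. This vignette
is the package's own account of the statistical machinery: the indices,
the inference attached to each, the synthetic cohort generator used to
validate everything, and the numerical and design choices a maintainer
would want written down.

## The two indices

**Lateralisation index (LI).** For a participant's left/right pair,

$$\mathrm{LI} = \frac{\text{right} - \text{left}}{\text{right} + \text{left}}.$$

LI lives in $[-1, 1]$: negative means leftward asymmetry, positive
rightward, zero bilateral. It is antisymmetric under hemisphere swap and
invariant to common positive rescaling, so metrics on very different
scales (anisotropy vs streamline counts) become comparable. A pair with
`left + right == 0` has no defined LI; the pipeline records it as
missing with a warning rather than letting infinities propagate.

**Variability index (VI).** LI asks how different the hemispheres are in
*magnitude*; VI asks which hemisphere is more *variable across
individuals*:

$$\mathrm{VI} = \frac{\mathrm{MAD}_\mathrm{right} - \mathrm{MAD}_\mathrm{left}}
                     {\mathrm{MAD}_\mathrm{right} + \mathrm{MAD}_\mathrm{left}},$$

where MAD is the raw median absolute deviation from the sample median —
no 1.4826 consistency constant, because the constant cancels in the
ratio and the raw form matches the index's definition as a pure
dispersion comparison. Even-length medians are the mean of the two
central order statistics. A negative VI means greater left-hemisphere
dispersion. The two indices are orthogonal: a tract can be strongly
right-lateralised on average while its right hemisphere is also the more
variable one.

## Inference for VI: hemisphere-swap permutation

Because left and right values are paired within participants, the null
of "no systematic variability asymmetry" is operationalised by swapping
each participant's left and right values independently with probability
0.5 and recomputing VI; pairing is never broken across participants. The
p-value is the proportion of permuted VIs at least as extreme in
absolute value (ties inclusive) as the observed VI, over `n_perm`
permutations (100,000 by default). When no permuted value is as extreme,
the p-value is reported at its floor `1/n_perm` with a `p_is_floor`
flag; a smoothed `(count + 1)/(n_perm + 1)` estimator is available by
argument for conservative use. An exact enumeration over all $2^n$ swap
patterns (`exact_permutation_vi()`, guarded at 16 pairs) serves as the
oracle the Monte-Carlo test is validated against.

The family analysis runs 21 tract-level tests plus 3 hemisphere-averaged
global tests (one per metric) and corrects at Bonferroni
$\alpha = 0.05/24 \approx 0.0021$. Hemisphere averaging takes the
arithmetic mean of the seven tract values per hemisphere per
participant, restricted to participants with all tracts reconstructed
bilaterally — the most literal reading of averaging "across all tracts";
pooling all tract values into one vector per hemisphere before the MAD
was the alternative we considered and rejected, since it conflates
between-tract with between-participant dispersion. Each test draws from
an RNG substream derived deterministically from the master seed and the
(tract, metric) label, so results do not depend on test order and any
single test can be reproduced in isolation. The permutation inner loop
is compiled (Rcpp) but consumes R's own RNG stream, so `set.seed()`
semantics are preserved exactly.

## Inference for LI: truncated-Cauchy Bayes factors

Population lateralisation of each tract-metric is tested by comparing an
intercept model (group mean $\mu$ free) to a null model ($\mu \equiv 0$)
for the per-participant LI sample — the Bayesian analogue of a
one-sample t-test. The likelihood is Gaussian with unknown mean and
dispersion. The prior on $\mu$ is Cauchy(0, 0.707) truncated to
$[-1, 1]$: heavy tails for robustness, the conventional "medium effect"
scale, and truncation to the index's logical range. The dispersion
$\sigma$ carries a half-Student-t(3, 2.5) prior in **both** models, a
common weakly-informative default for scale parameters; a built-in
`sigma_prior_sweep()` shows the Bayes factor is insensitive to this
scale over 0.5–10 (the marginal likelihoods move together and the ratio
barely shifts).

**Why quadrature instead of MCMC.** Marginal likelihoods are computed by
deterministic tensor-product Gauss–Legendre quadrature: $\sigma$ on the
log scale over an adaptive range around the sample estimate, and $\mu$
on panels whose breakpoints combine the likelihood region around the
sample mean with quantiles of the Cauchy prior — the latter is what lets
the same code resolve arbitrarily narrow prior scales (down to $10^{-9}$
in the tests) without missing the spike. The grid is refined by doubling
until successive log Bayes factors agree to a relative $10^{-6}$, and
the final disagreement is reported as `numerical_error`. This replaces
the R-hat/trace-plot convergence checks an MCMC fit would need: there
are no chains, results are bit-identical across runs, and the error
estimate is a property of the reported number itself. The test suite
verifies the quadrature against a $10^6$-draw prior-sampling
Monte-Carlo estimator and against an independent noncentral-t
quadrature oracle for the JZS limit.

**Connection to the standard JZS Bayes factor.** With
`parameterisation = "effect_size"` the Cauchy prior moves to the
standardised effect $\delta = \mu/\sigma$ with a Jeffreys prior on
$\sigma$; widening the truncation (e.g. $\pm 10^6$) recovers the
standard JZS one-sample Bayes factor, which the test suite checks
against an independent noncentral-t quadrature oracle across
$n \in \{10, 50, 164\}$ and $|t| \le 6$ (agreement well within 2%).

**Reported summaries.** `est_mean`/`est_error` are the posterior mean
and SD of $\mu$; the 95% interval is the central quantile interval by
default (a highest-density option exists). Bayes factors are stored as
logs internally — real tract data reach $10^{44}$ — and the
per-replicate posterior is approximately Student-like, so a
$\pm 2 \cdot$ SD interval has a per-replicate success probability of
about 0.954 (the normal two-sigma level) rather than exactly 0.95 —
which is why the recovery checks compare the replicate count against an
exact binomial criterion for a 0.95 rate instead of a sharp count.

**Prior robustness.** `prior_sweep()` re-runs the test over Cauchy
widths 0.01–1 and reports whether the direction of evidence and the sign
of the posterior mean are stable. The Jeffreys–Lindley effect is visible
as designed: at very small widths the Bayes factor is drawn toward 1.
One subtlety found while validating: for a sample with very strong
evidence, a width of $10^{-6}$ does *not* yet give BF $\approx 1$. The
Cauchy tail retains density $\propto$ scale$/x^2$ over the truncation
interval, and where that meets an enormous likelihood ratio the product
still contributes; the collapse to 1 completes only as the scale
shrinks further (the excess vanishes linearly in the scale, which the
tests check at $10^{-9}$). A genuine property of the integral, not a
numerical artefact.

**Sample-size stability.** `li_stability()` is a Bayes-factor design
analysis: for each $n$ in a grid it simulates (or subsamples) LI
samples, fits the test, and reports the fraction of replicates with
conclusive evidence (BF$_{10} > 10$, or $< 1/10$ for the null). Tracts
with weak asymmetry need markedly larger cohorts before evidence
stabilises; the tool reports the smallest $n$ at which 90% of replicates
are conclusive.

## Phenotypes: continuum versus clusters

Whether lateralisation profiles form discrete subgroups is addressed in
two complementary ways on the participants × 21 LI feature matrix
(listwise-complete by default, mirroring whole-participant exclusion of
failed reconstructions):

- `embed_li()` produces a 2-D UMAP embedding (n_neighbors = 15,
  min_dist = 0.1, Euclidean — the conventional defaults for this
  analysis) for visual assessment. LI features share the bounded
  $[-1, 1]$ scale, so they are passed unstandardised by default;
  z-scoring is available by flag. The backend is uwot; the seed and all
  parameters are recorded in the result. Embedding determinism is
  guaranteed for a fixed seed and backend version.
- `clusterability()` quantifies clustering tendency on the **original**
  21-D feature space, not the embedding, to avoid projection artefacts:
  the Hopkins statistic against a uniform reference on the feature
  bounding box (power-1 distance variant; ~0.5 for unstructured data)
  plus the best average silhouette over k-means partitions for
  $k = 2..8$. Rows are put into a canonical sort order first so both
  diagnostics are exactly invariant to participant order. A single
  Gaussian cloud sits near silhouette 0.1 (and, being denser than
  uniform, Hopkins ~0.6); well-separated archetypes exceed silhouette
  0.5 and Hopkins 0.7. The validation suite separates the two regimes
  with a silhouette threshold of 0.4, midway between them.

## The synthetic cohort generator

Every stage is validated on generated cohorts, so the generator is
first-class, tested code. Per tract-metric it draws correlated bilateral
pairs through a Gaussian copula on a latent scale (default
interhemispheric correlation 0.5, a typical value for homologous tract
metrics), then maps to the metric's natural domain: log-normal for
streamline and voxel counts (positive, right-skewed), logit-normal for
HMOA (bounded in (0, 1)). Reconstruction failures are tract × hemisphere
events — all three metrics of a failed tract go missing together, as a
failed dissection behaves in real data.

Two population targets are controllable per feature:

- **target_li**: hemisphere locations are offset by
  $\Delta = 2\,\mathrm{atanh}(\lambda)$ (exact for multiplicative
  families in the small-dispersion limit, since LI equals
  $\tanh$ of half the latent log-ratio), then bias-corrected by a
  deterministic calibration pass on $10^4$ probe draws (three
  atanh-space Newton updates). Calibrated accuracy is better than 0.02
  in the population mean LI across targets in $[-0.5, 0.5]$.
- **dispersion_ratio** (right/left MAD): latent scales are
  ratio-adjusted, first-order $s_R/s_L = \text{ratio}/e^{\Delta}$, and
  calibrated the same way to within 10%.

Calibration depends only on the feature parameters, not the cohort
seed, and is memoised; identical configurations therefore produce
bit-identical cohorts.

`language_scenario()` is a ready-made configuration reproducing the
qualitative regime reported for language pathways: leftward AFl/ILF/FAT,
rightward AFa/UF, near-bilateral AFp/IFOF counts; mean-asymmetry targets
are set to published group estimates, latent scales are chosen so the
spread of LI across participants matches the corresponding reported
standard errors at $n = 164$ (posterior SD $\approx$ sample
SD$/\sqrt{n}$, hence scale $\approx 2\,\mathrm{SE}\sqrt{164}$ at
correlation 0.5), and dispersion ratios follow reported variability
indices via MAD ratio $= (1+\mathrm{VI})/(1-\mathrm{VI})$. Failure rates
default to 0.003 per tract per hemisphere, giving whole-cohort exclusion
rates of a few percent, as in real dissection pipelines.

**What the generator does not emulate.** Marginals are exactly
log/logit-normal with a single copula correlation; real tract metrics
have heavier tails, metric-specific skew, between-metric dependence
within a tract, and occasionally bimodal reconstruction artefacts.
Passing tests therefore demonstrate that the *statistical machinery* is
correct and calibrated under realistic-looking conditions — not that any
particular real cohort satisfies the generator's assumptions.

## Numerical choices and degenerate inputs

- Zero denominators (LI with `left + right == 0`; VI with both MADs
  zero) are errors at the single-pair level and missing values with a
  warning at the pipeline level — never NaN or infinity.
- Permutation p-values are never 0: the raw estimator is floored at
  `1/n_perm` and flagged.
- Quadrature: Gauss–Legendre with 48 nodes per panel at the coarsest
  level, up to three doublings, relative tolerance $10^{-6}$ on the log
  Bayes factor; all mass accounting in log space via log-sum-exp.
- Seeds: one master seed per analysis; per-test substreams are derived
  by a deterministic polynomial hash of the (tract, metric) label, kept
  below $2^{31}$.
- Reported problem sizes in the validation suite were chosen to keep the
  full run at a few minutes on one core while leaving comfortable
  statistical margins: 2000 replicates for type-I calibration
  (n_perm = 999), 200 replicates for parameter recovery at $n = 164$,
  20 seeds for the end-to-end scenario, 50 + 50 cohorts for the
  continuum/cluster discrimination.

## Known limitations

- The Bayesian machinery assumes a Gaussian likelihood for LI; with
  $n \gtrsim 30$ per feature the posterior for the mean is insensitive
  to moderate non-normality, but heavy-tailed LI distributions at small
  $n$ would call for a robust likelihood that the package does not
  implement.
- The hemisphere-averaged VI uses per-participant tract means; other
  pooling choices (e.g. concatenating tract values) answer subtly
  different questions and are not offered.
- Hopkins statistics depend on the reference distribution; the uniform
  bounding-box reference makes any concentrated cloud (even a single
  Gaussian) score slightly above 0.5, which is why the discrimination
  rule relies on the silhouette.
- No hierarchical modelling across tracts or metrics: each feature is
  tested marginally, as in the analysis the package operationalises.
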