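---
title: "Comparing diversity indices across organism and trait groups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing diversity indices across organism and trait groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hillpath)
library(dplyr)
```

## The problem

Ecologists quantify the diversity of a community with many competing
indices: richness `S`, Shannon diversity `H`, Simpson diversity `D1`,
Simpson dominance (inverse Simpson) `D2`, Berger–Parker dominance `BP`,
and Simpson evenness `E = D2/S`. These are not interchangeable: they weight
rare and abundant taxa differently, and the choice can change which effects
a study detects — especially in multivariate analyses such as path models
of diversity–diversity couplings. `hillpath` implements a full comparison
pipeline for this question: compute all indices (and the continuous
effective-species-number profile) for several organism/trait groups over a
set of plots, extrapolate richness, quantify a land-use gradient, run
correlation/regression batteries with multiplicity control, rank indices by
their ability to discriminate plots, and fit the same recursive path model
once per index. A ground-truthed synthetic-community generator emulates the
whole multi-group study design so each stage can be validated against known
parameters.

## The index family and the Hill continuum

All computations start from proportional abundances `p_i` (counts, percent
cover, peak heights/intensities, or allele frequencies — the arithmetic is
identical after normalization; the group label is metadata). Zero
abundances are dropped first, so `S` counts taxa actually present. The
indices are tied together by the generalized-entropy family

$$N_a = \left(\sum_i p_i^{\,a}\right)^{1/(1-a)},$$

the *effective species number* at power `a`: `N_0 = S`, `N_1 = exp(H)`
(the analytic limit, used whenever `|a - 1| < 1e-9` to remove the
removable singularity without user-facing branches), `N_2 = D2`, and
`N_Inf = 1/BP`. The profile is non-increasing in `a` and flat exactly for
perfectly even communities; these identities are enforced as tests, and a
separately coded brute-force implementation of every index serves as an
oracle.

Design choices worth knowing:

* `H` uses the natural logarithm, and no log-base option is exposed —
  silent unit mismatches between nats and bits are worse than a missing
  convenience.
* Population ("naive") formulas are used rather than small-sample
  bias-corrected estimators; at the sampling depths this pipeline targets
  the difference is negligible, and the simpler formulas keep every
  downstream identity exact.
* `BP` is reported as the dominance `max(p_i)`; its Hill surrogate `1/BP`
  appears only in the profile functions. Ties for the maximum need no
  tie-break: the shared maximum is the statistic.
* Per-plot values are arithmetic means over focal subsamples, and the
  identity `E = D2/S` is *not* re-imposed on the means: each index is
  computed per sample and then averaged, so plot-level `E` is a mean of
  ratios. Empty samples are flagged, never silently dropped.
* For multilocus allele-frequency data each index is computed per locus
  and averaged across loci; per locus `D1` is the expected heterozygosity
  and `D2` the effective allele number. Frequencies must sum to 1 within
  `1e-6`; renormalization is opt-in so data errors surface.

## Richness extrapolation

Observed richness undercounts the pool whenever sampling misses rare
species. From an incidence (presence/absence) matrix over sampling units,
three classical extrapolators are provided, with `q_k` the number of
species found in exactly `k` of the `N` units:

* Chao: `S_obs + ((N-1)/N) q1^2 / (2 q2)`, falling back to the
  bias-corrected `S_obs + ((N-1)/N) q1(q1-1)/2` when `q2 = 0` (flagged);
* first-order jackknife: `S_obs + q1 (N-1)/N`;
* bootstrap: `S_obs + sum_i (1 - f_i/N)^N`.

The incidence-based (accumulation-curve) forms are used, with the
`(N-1)/N` finite-sample factor, matching the convention of the standard
community-ecology implementations (`vegan::specpool` is used as an
independent cross-check in the tests). Standard errors come from a seeded
bootstrap over sampling units (default `B = 1000`; 100–200 suffices for
table-level reporting) rather than from any of the competing analytic
variance formulas, which differ among published variants. When the
resampling distribution is degenerate — every species in every unit, so
there is nothing to extrapolate — the SE is reported as `NA` with a
`degenerate_se` flag rather than a misleading 0.

## The land-use intensity index

Management intensity per plot is `LUI = sqrt(F' + M' + G')`, where each
component (fertilization in kg N ha⁻¹ yr⁻¹, mowing frequency per year,
grazing in livestock units ha⁻¹ yr⁻¹) is divided by its mean over the
plots of the same region, making the index dimensionless and the three
components equally weighted. Components are averaged over the study years
*before* standardization, and the square root is applied once to the
multi-year index; the text this procedure descends from is ambiguous about
that ordering, so the alternative (standardize within year, average, then
root) is available as `yearly_first = TRUE`. A component that is zero on
every plot of a region is dropped with a warning rather than producing
0/0. Regional means are computed over whatever plots are supplied — the
caller controls the plot universe.

## Simple-statistics batteries

Within each group, all 15 pairwise Pearson correlations among the six
indices are tested, and each index is regressed on LUI by OLS (reporting
`F`, the raw p-value, and the signed correlation `sign(slope)·sqrt(R²)`).
Multiplicity is controlled per group by Bonferroni: raw p-values are
compared against `alpha/m` (0.05/6 ≈ 0.0083 for the regressions), rather
than multiplying p-values — the raw values stay interpretable and the
decision is identical. Plots missing any index are removed listwise within
a group. Transformations to improve residual normality are explicit,
per-index configuration (`none`, `sqrt`, `log1p`) recorded in the output;
nothing is transformed automatically, because no automatic rule can be
audited afterwards. Degenerate cases are marked, not guessed: a
zero-variance index yields `NA` correlations, a noiseless regression is
flagged `perfect_fit`, constant LUI is an error.

## Site discrimination and importance values

A PCA of the index correlation matrix (variables standardized across
plots) summarizes how plots separate in index space. Loadings are reported
as variable–component correlations, and each axis is oriented so its
largest-magnitude loading is positive — a reproducible sign convention, as
eigenvector signs are otherwise arbitrary. Each index then gets one
importance value

$$IV_j = \sum_{k \in \text{retained}} \frac{\lambda_k}{\sum_l \lambda_l}\,|l_{jk}|,$$

the eigenvalue-proportion-weighted sum of absolute loadings over retained
axes. The retention rule is configuration (`kaiser` for eigenvalues at
least 1, `all`, or `first2`), because the source literature for the IV
statistic does not pin either the arithmetic or the retained axes; the
formula above is this package's fixed definition. With all axes retained
`IV <= 1`, and with a single retained axis it reduces to the absolute
first-axis loading. A passive variable (typically LUI) can be projected
onto the axes without influencing them, so its alignment with the index
space can be read off without distorting the ordination.

## Recursive path models

Diversity–diversity couplings are modeled as a recursive (DAG) path model
over observed group-level variables, fitted identically once per index.
Variables are standardized, so estimates are standardized path
coefficients. For this model class, equation-wise OLS of each endogenous
variable on its parents is the maximum-likelihood solution; the tests
verify this against direct numerical minimization of the ML discrepancy.
The implied covariance is assembled from the reduced form
`Sigma = (I-B)^{-1} Psi (I-B)^{-T}` and compared with the sample
covariance through

$$F_{ML} = \ln|\hat\Sigma| - \ln|S| + \mathrm{tr}(S\hat\Sigma^{-1}) - p,
\qquad \chi^2 = (N-1)\,F_{ML},$$

with `df = p(p+1)/2 - t` free-moment counting (`t` = edges + exogenous
variances + exogenous covariances + endogenous residual variances).
Coefficient p-values use Wald z statistics on the least-squares standard
errors — standard large-sample practice for models of this size. Fit is
summarized by the chi-square p-value, `RMSEA =
sqrt(max(0, (chi2 - df)/(df (N-1))))`, and the Tucker–Lewis non-normed
index against the independence null (`chi2_null = (N-1)(-ln|R|)`,
`df_null = p(p-1)/2`); TLNNFI is undefined (NA) when the null fits no
worse than 1 per df. Degenerate situations are explicit: a saturated model
reports `chi2 = 0` with `df = 0` and no RMSEA penalty; collinear parents
are an error; a singular observed covariance (e.g. a noiseless structural
equation) still yields coefficients but no fit statistics.

The default five-variable topology — molecular and plant diversity
exogenous and correlated; plant driving chemical, mycorrhizal and
arthropod diversity; chemical, molecular and mycorrhizal each driving
arthropod diversity — has six edges and twelve free parameters, hence 3
degrees of freedom. The hypothesized diagram it encodes is not uniquely
recoverable from its source description, and more than one six-edge DAG
yields `df = 3`; the topology is therefore fully caller-controlled through
a plain-text edge list (`parent -> child`, `a ~~ b`), and `df` is always
recomputed from the spec, never assumed. Latent variables and
non-recursive loops are out of scope — they belong to general SEM, not to
this model class.

## What the synthetic generator emulates

`scenario()` defaults describe the emulated study: 60 plots in 3 regions,
10 focal subsamples per plot, three years of land use with realistic exact
zeros (unfertilized pastures, unmown meadows), and five data layers. Latent
per-plot diversity scores follow Gaussian structural equations along the
hypothesized path topology with standardized coefficients of magnitude 0.2
or 0.4, a molecular–plant exogenous covariance of 0.2, and a land-use
effect of −0.38 on the plant latent; residual variances are sized so every
latent has unit population variance, which is what makes the generating
coefficients standardized and directly recoverable. Each latent then
drives a species-abundance distribution: the local pool size grows with
the latent through a probit link, and the geometric-series parameter
`k(z)` shrinks with it, so higher latent diversity means both more species
and more evenness (a log-normal rank-abundance family is available to
decouple results from one SAD shape). Counts are drawn multinomially, so
rare species are genuinely missed at realistic sampling depth; local pools
are drawn from a larger regional pool with a heavy-tailed weighting, so
the regional pool is never fully observed and richness extrapolation has
real work to do. The molecular layer is five loci with stable allele
identities whose evenness tracks the molecular latent; the chemical layer
is a dense aligned peak-intensity fingerprint in which every feature has a
positive intensity in every plot.

Two deliberate consequences of that last choice: the chemical layer has no
cross-plot singleton features, so its richness estimators return the
observed value with a degenerate (flagged) SE — the saturated-layer
behavior the pipeline must handle — and its per-plot richness is constant,
so the richness-indexed path model has a zero-variance variable there.
`multi_index_run()` reports such an index as unfit (with the offending
variable named) instead of failing, and the pipeline PCA drops
zero-variance columns with a log note. This is the honest shape of
saturated fingerprinting data: its signal lives in evenness, not richness.

What the generator does *not* emulate: spatial structure and
autocorrelation between neighboring plots, temporal community dynamics,
phylogenetic relatedness, detection biases that differ among taxa, and any
nonlinearity in how real diversity responds to management beyond what the
latent-to-SAD link induces. Passing tests on this generator therefore
demonstrate the *statistical machinery* — calibration, recovery,
direction — not field realism. One known attenuation is intrinsic: indices
computed from finite samples are noisy, slightly nonlinear transforms of
the generating latents, so couplings estimated from computed indices are
biased toward zero relative to the latent-scale coefficients;
parameter-recovery checks are therefore run on the latent scale, and
index-scale checks are directional.

## Numerical conventions and test scale

* Proportions are validated to sum to 1 within `1e-12` after
  normalization; allele frequencies within `1e-6` before it.
* The Hill power `a = 1` uses the `exp(H)` limit under `|a-1| < 1e-9`.
* All randomness is seeded; every generator output is a deterministic
  function of (scenario, seed), and pipeline reruns are byte-identical.
* The chi-square calibration check uses 1000 replicates at `n = 60`
  (Monte-Carlo SE on the mean ≈ 0.08), coefficient recovery 500
  replicates, family-wise-error simulation 400 families, and estimator
  direction 150 replicates of 8-unit subsamples — sizes chosen so each
  property is tested at meaningful precision while the full suite stays
  fast to run routinely.

## Limitations

Bonferroni control is deliberately conservative and no FDR alternative is
offered; mixed models for region effects, coverage-based rarefaction
(Chao–Jost), abundance-based Chao variances, beta/gamma partitioning, and
latent-variable SEM are all out of scope. The IV statistic is one fixed,
documented arithmetic among several in circulation — comparisons against
other software should pin the retention rule first.
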