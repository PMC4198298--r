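---
title: "Methods: signature derivation, risk scoring and resampling nulls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signature derivation, risk scoring and resampling nulls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`progsig` implements a complete prognostic-signature workflow for bulk
transcriptomics: derive a multi-cancer differential-expression signature from
paired normal/tumor cohorts, freeze a Wald-weighted standardized risk score on
a training survival cohort, evaluate recurrence-free-survival separation in
independent cohorts, and ask — by resampling random same-size gene sets —
whether the signature's prognostic power and its co-expression coherence could
have arisen by chance. This vignette documents the statistical model behind
each stage, the tunable parameters, the numerical choices, and what the
synthetic-data generators do and do not emulate.

## Signature derivation from paired cohorts

Within each cancer type, each gene is tested with a paired t-test on the
within-patient differences $d_p = \text{tumor}_p - \text{normal}_p$ of log2
expression: $t = \bar d / (s_d/\sqrt{n})$ on $n-1$ degrees of freedom,
two-sided. P-values are adjusted by the Benjamini–Hochberg step-up procedure
*within* each cancer (each dataset is tested on its own platform and gene
universe, so per-dataset FDR control is the natural scope; `select_common_de()`
accepts externally pooled tables if a global scope is preferred). The paired
fold change is reported as $2^{\bar d}$, the geometric-mean tumor/normal
ratio — consistent with testing on the log2 scale; a linear-mean-ratio variant
is available via `fold_change(linear = TRUE)`.

A gene enters the signature when it is significant (adjusted $p <
\alpha$, default 0.05) **in the same direction** in at least `min_cancers`
(default 4) cancer types. Two readings of "accordant" are possible: the
default requires only that the accordant count be reached, so a gene
significant up in four cancers and down in one still qualifies; `strict =
TRUE` additionally disqualifies any significant discordance. Exact ties
($t = 0$) count for neither direction. Selection is monotone: relaxing
$\alpha$ or lowering `min_cancers` can only add genes.

Gene-level preprocessing mirrors standard microarray practice: probe rows are
collapsed to genes by arithmetic mean, genes are filtered by a detection rule
(present in at least two thirds of samples, where "present" defaults to
exceeding the cohort's 10th-percentile value and is pluggable for
platform-specific detection calls), and X/Y-chromosome genes are removed to
avoid sex confounding. Unannotated genes are retained with a warning rather
than silently dropped, since silent removal shrinks the signature pool.

## The risk score

On a training survival cohort, each signature gene $i$ gets a univariate Cox
proportional-hazards fit of recurrence-free survival on its expression; the
Wald statistic $Z_i = \hat\beta_i/\mathrm{se}(\hat\beta_i)$ becomes the gene's
weight. With $\mu_i$ and $\tau_i$ the mean and standard deviation of gene
$i$'s expression across all training samples, a patient with expression
$e_i$ scores

$$S = \sum_{i=1}^{n} Z_i\,\frac{e_i - \mu_i}{\tau_i}.$$

The triple $(Z_i, \mu_i, \tau_i)$ is frozen at training time (serialized as
YAML by `write_scoring_model()`) and applied unchanged to validation cohorts.
Patients with $S$ strictly above the *scored cohort's own* median are
signature-positive; ties at the median are negative, so the two groups differ
in size by at most the number of tied samples. Two deliberately preserved
alternatives reflect genuine ambiguity in how such scores are transported
across platforms: `restandardize = TRUE` recomputes $\mu, \tau$ on the scored
cohort (useful when training and validation platforms differ in scale), and
the median threshold is always recomputed per cohort rather than carried over
from training. Genes absent from a validation platform are dropped from the
sum without reweighting — the score is a plain sum and no renormalization is
implied — with the used-gene count reported.

Cox fits use the Efron tie approximation (Breslow available via `ties=`).
Two engines exist: `survival::coxph` (default for user-facing fits) and an
internal Newton–Raphson partial-likelihood fit compiled from source, used
inside resampling loops where tens of thousands of univariate fits are
needed. The two agree to at least six decimals on the same data, and the test
suite enforces this equivalence; the clamped-Newton iteration is safe because
the univariate partial likelihood is concave, and coefficients wandering past
|β| > 25 (monotone-likelihood separation) abort the fit as degenerate.

## Survival evaluation

`km_curve()` (product-limit), `logrank_test()` (two-group, df = 1) and
`cox_multivariate()` (joint Efron fit with explicit, mandatory reference
levels for categorical covariates — no silent alphabetical contrasts) cover
the evaluation layer. Stratified analyses reuse the cohort-level
positive/negative labels within each stratum by default — stratification
subsets patients, it does not refit the scoring — with `redichotomize = TRUE`
as the alternative. Strata with fewer than two events are skipped with a
warning. Evaluation p-values are two-sided throughout; the only one-tailed
tests are the resampling nulls below.

## Resampling nulls

Three tests share one logic: compute a statistic for the observed signature,
recompute it for `n_resamples` random same-size gene sets drawn uniformly
without replacement from an explicit pool, and report the right-tail add-one
empirical p-value $(1 + \#\{\text{null} \ge \text{obs}\})/(1 + N)$, which is
never zero and monotone in the observed statistic.

* **Prognostic power**: the statistic is the validation-cohort Wald $z$ of
  the dichotomized signature status, obtained by re-running the *entire*
  pipeline — per-gene Cox refits on training, frozen scoring, validation
  scoring, median split, group Cox fit — for every random signature. Reusing
  cached weights would understate the null spread; identical-size comparison
  requires full refits.
* **Pooled sum of Wald z**: the same statistic summed over several
  (training, validation) cohort pairs, with the null drawn from a comparison
  pool (typically genes prognostically selected genome-wide but outside the
  curated signature universe, via `complement_pool()`).
* **Co-expression coherence**: the statistic is the sum of the weighted
  adjacency matrix inferred by the tree-ensemble method below, compared
  against random same-size sets.

Degenerate resamples (constant scores, inestimable fits) are skipped and
counted rather than imputed; a skip fraction above 5% aborts the run, since a
null assembled from a biased subset of resamples is not trustworthy. The pool
is always an explicit argument: the whole measured gene universe is the
natural choice for the prognostic test, a curated comparison set for the
pooled test.

## Tree-ensemble network inference

For each target gene, an ensemble of randomized regression trees (default
100) predicts the target's standardized expression from all other genes; at
each split, `floor(sqrt(p-1))` candidate regulators are drawn and the best
variance-reducing split is taken; trees grow on bootstrap samples until
fewer than 10 samples remain per node. The weight $w_{ij}$ is the total
variance reduction credited to regulator $i$ in target $j$'s ensemble,
averaged over trees and divided by the sample count, so each target column
sums to (approximately) its explained-variance mass and the statistic is
comparable across same-size gene sets. Targets are standardized to unit
variance beforehand; regressors need no scaling because tree splits are
scale-invariant — the suite asserts exact invariance of the inference under
per-gene affine rescaling at a fixed seed. Self-links are structurally
excluded (zero diagonal) and constant genes yield zero rows/columns with a
warning. The implementation is compiled from source and driven by R's RNG,
so a seed makes the whole inference reproducible.

## Synthetic data: what it emulates, and what it does not

`simulate_paired_cohorts()` draws log2 expression as Gaussian — matching the
scale on which microarray values are analysed after log transformation — with
per-gene baselines spread around `baseline_mean` (default 8, SD 1, a typical
log2 intensity range), an additive per-patient-per-gene random effect
(`pair_effect_sd`, default 0.5) that induces the within-pair correlation the
paired design exploits, residual noise (`noise_sd`, default 0.5), and planted
signed log2 effects (default: 50 genes at 1.0 log2 — a 2-fold change, typical
of a clearly differential gene — perturbed in 5 of 6 cancers). With these
defaults the planted paired t-test non-centrality is about 7.7 at 30 pairs,
so recovery is expected and the interesting quantity is the false-discovery
fraction.

`simulate_survival_cohort()` gives signature genes a single shared latent
factor: gene $= \lambda F + \sqrt{1-\lambda^2}\,\varepsilon$, so every pair
of signature genes correlates at $\lambda^2$ (default loading 0.5 → r =
0.25, a moderate co-expression module; 0.9 → r = 0.81, a tight module).
Event times are exponential under proportional hazards with linear predictor
$\sum_g \beta_g x_g$ (default: 10 of 45 signature genes at log-hazard 0.4 per
expression SD); censoring is the minimum of an independent exponential time
(rate 0.04) and an administrative horizon (60 time units), giving roughly 30%
censoring at the default baseline hazard of 0.1 events per time unit. Ground
truth (planted effects, true β) is always returned — parameter recovery is
the acceptance surface.

Deliberately **not** modelled: probe-level intensities, batch and platform
effects between training and validation, competing risks, non-proportional
hazards, and heavy-tailed expression noise. Passing tests therefore
demonstrate correctness of the statistical machinery under a clean generative
model, not robustness to the messiness of real microarray data; the
`restandardize` option and the pluggable detection predicate are the hooks
for that messiness.

## Numerical choices and problem sizes

* BH adjustment delegates to `stats::p.adjust`; the suite pins it against a
  literal step-up implementation on a thousand random vectors.
* Empirical p-values use the add-one estimator — standard permutation
  practice, avoids p = 0 at finite resamples.
* The determinism contract is strict: every stochastic function requires a
  seed, the pipeline fans one master seed into per-stage seeds by a fixed
  offset rule, and two runs with the same configuration produce bit-identical
  artifacts (the suite compares file checksums).
* Test problem sizes were chosen so each property is tested in the regime
  where its guarantee applies: Cox/log-rank calibration at a few hundred
  samples per replicate (their guarantees are asymptotic — at a few dozen
  samples the log-rank chi-square approximation is visibly anticonservative),
  recovery checks at the study scale (six cohorts of 30 pairs and 1,000
  genes; 300-sample survival cohorts; 45-gene signatures), and resampling
  nulls at 100–200 resamples with the 1,000-resample convention reserved for
  real analyses.
* The end-to-end recovery conditions (10 of 45 genes at log-hazard 0.4,
  loading 0.5) put the linear-predictor variance near 5.2, so the typical
  validation hazard ratio between score halves is large (≈ 6); the
  acceptance checks therefore bound it from below (> 1, and mean > 1.3)
  rather than asserting a narrow band.

## Known limitations

The per-gene Cox weights ignore correlation between signature genes (by
design — the score is a univariate-weighted sum, not a multivariate fit);
the coherence statistic grows with gene-set size and is only meaningful
against same-size nulls; and the detection filter's default presence
predicate is a value-threshold stand-in for platform detection calls, to be
replaced by real calls where available.
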