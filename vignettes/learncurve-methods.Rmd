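---
title: "Evaluating learning methods by repeated random sampling: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating learning methods by repeated random sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(learncurve)
```

## What is being estimated

`learncurve` estimates the expected out-of-sample performance of a learning
*methodology* — a learner family together with its screening and tuning
protocol — as a function of the training-set size, with an explicit
uncertainty statement. The estimand at size $i$ is the mean of the score a
tuned-and-refit model attains on an independent held-out set:

$$M_i = \frac{1}{n}\sum_{j=1}^{n} \text{performance}_{ij},$$

where $n$ repeated random splits are drawn at each size ($n$ constant
across sizes). Uncertainty is quantified by the standard error of the mean,
$SEM_i = s_i/\sqrt{n}$ with $s_i$ the unbiased sample standard deviation,
and the interval $M_i \pm c \cdot SEM_i$.

The modelling assumptions are modest but worth stating: the per-split
scores at a fixed size are treated as exchangeable draws whose mean is
normally distributed enough for a t-interval; splits drawn from the same
finite dataset overlap, so the scores are not strictly independent and the
interval should be read as describing the resampling variability on *this*
dataset, not sampling variability across datasets.

### performance_ij

The per-model score $\text{performance}_{ij}$ is the single held-out-split
score of the model tuned and refit on training split $j$ (macro-averaged
over classes for class-specific metrics in multiclass problems). Averaging
over inner tuning resamples instead was a defensible alternative; we use
the held-out score because it is the quantity whose mean the learning
curve is meant to track, and we state the choice here because the phrase
"average performance of a model" is genuinely ambiguous.

### The critical value

`summarize_size()` uses the Student-t quantile with $n-1$ degrees of
freedom at the configured confidence level (default 0.95). With the small
$n$ typical here (5–20 repeats) the normal quantile would undercover; the
t choice is conservative and converges to the normal value as $n$ grows.
A coverage simulation (10,000 replicates of Gaussian scores at $n = 5$ and
$n = 20$) is part of the acceptance suite and lands within 1% of nominal.

### Best-model selection

Selection is two-staged on the **test** slice only: first the size with
the lowest CI *upper* bound (minimized metrics) or highest CI *lower*
bound (maximized metrics), then the best-scoring single model at that
size. Using the unfavourable CI bound rather than the mean penalises sizes
whose estimate is noisy — the leave-one/two-out extreme, where held-out
sets are tiny and per-split scores nearly binary, is typically rejected on
exactly this ground. With $n = 1$ the CI is undefined; the mean is used as
the bound and flagged. Train and full-data summaries are reported but
never drive selection.

## Sampling

Three schemes split observations: subsampling without replacement
(held-out = complement, so size ≤ n_obs − 1), bootstrap (held-out = the
out-of-bag complement of the distinct training indices — the natural
held-out set for a bootstrap draw, stated here because one could also
reuse the full sample), and k-fold cross-validation. Stratification
preserves strata proportions via the largest-remainder method (ties by
stratum order — "proportions are maintained as closely as integer counts
allow"); the balanced variant starts all strata at
`floor(size/n_strata)` and hands the remainder to strata in decreasing
availability order, erroring (not truncating) when a stratum cannot supply
its share without replacement. All indices are 1-based, in the serialized
outputs as in memory.

## Unsupervised filtering

Three response-blind rules run once, before any sampling: missingness
(keep iff missing fraction ≤ cutoff), threshold (keep iff the value
*strictly* exceeds the threshold — equality fails, the stricter reading of
"below ... filtered out" — in at least `min_samples` samples, default half
the samples; `threshold = "median"` compares against each sample's own
median, the common expression-data convention), and variability (top
`ceiling(keep * p)` features by SD, IQR or MAD; MAD uses the 1.4826
normal-consistency constant, switchable). The response is not a parameter
of any filter, which makes pre-sampling leakage structurally impossible
rather than merely discouraged.

## Supervised screening

Screening is response-aware and therefore runs strictly *inside* each
training split, after sampling and before tuning. Two tests are available:

* **Moderated t**: the per-feature pooled two-sample variance is shrunk
  toward a prior estimated by moment matching on the log sample variances
  (our own implementation of the standard empirical-Bayes construction,
  with a Newton solver for the trigamma inverse); the statistic is
  referred to a t-distribution with $d + d_0$ degrees of freedom. The
  prior df is exposed (`prior_df = 0` gives the classical pooled t,
  large values shrink fully to the prior), and the test suite checks the
  implementation against limma's independent estimate to 1e-6.
* **Permutation test**: labels permuted, features fixed. Monte-Carlo
  p-values use the add-one estimator $(1 + \#\{|t_b| \ge |t_{obs}|\})/(B+1)$
  (never exactly zero, B = 1000 by default); exhaustive enumeration (binary
  response) returns the exact p-value over all distinct assignments, whose
  two-sided minimum is $2/N$ because the complementary assignment always
  ties the observed |statistic|.

Selection is `p < alpha` (default 0.05) capped at `top_k` (default 500) by
|statistic|; an empty selection falls back to the top-k with a logged
message. When both tests run they are combined by intersection (the
conservative reading of "and/or"; union is a switch). Multiclass responses
are screened one-vs-rest with the minimum p per feature — two-sample tests
do not generalise directly, and this is the least surprising lift.

## Learners, tuning and the 1SE rule

The adapter exposes `fit`/`predict` over glmnet, ranger, e1071, xgboost
and class/caret; feature alignment is by name, and a missing column is an
error, never a positional guess. Per-model `presence` is the nonzero
coefficient set for penalized GLMs, the nonzero-importance (used-feature)
set for trees/forests, and all features for kNN; `sign` is the coefficient
sign where the model has coefficients (GLM; linear-SVM primal weights,
oriented empirically because e1071 orders its decision values by label
appearance), and 0 elsewhere.

Grid search scores every configuration on the *same* inner splits (paired
comparison; tenfold CV by default), picks the optimal mean, and also
reports the one-standard-error configuration: the simplest configuration
whose mean lies within one SE **of the optimum** (the conventional form of
the rule; using each configuration's own SE is the other reading). The
complexity order had to be declared somewhere: larger penalty, larger k,
fewer/shallower trees, and smaller SVM cost count as simpler, with ties
broken by grid order so the order is total. The refit on the full training
split uses the best configuration by default (`tuning_rule = "one_se"`
switches); both configurations are retained in the tuning result.

Tuning stability — the frequency of each feature over all $m$ inner fits
(every configuration × every split) — is recorded for every family, using
the used-feature indicator where coefficients do not exist.

## Feature importance

$FIS_i$ is the weighted mean of $\text{presence} \times \text{sign} \times
\text{stability}$ over **all** models of the evaluation, with weights
$\text{performance}_j^2$ (maximized) or $1/(\text{performance}_j +
\varepsilon)^2$ (minimized, $\varepsilon = 10^{-8}$ guarding zero error).
Weights are positive, so FIS is scale-invariant in the weights and bounded
in $[-1, 1]$; a never-selected feature scores exactly 0. Failed fits and
models with undefined scores contribute neither weight nor importance, and
the test-slice score of the evaluation's primary metric feeds the weights
by default (slice and metric switchable).

Undefined scores in general (zero denominators: precision with no positive
predictions, R² of a constant response, and so on) propagate as `NA` —
a distinct missing-score marker — and reduce the effective $n$ of the
affected summary, which records the dropped count. They are never coerced
to 0.

## Determinism and parallelism

A master seed generates one sub-seed per (size, repeat) task up front
(`derive_seeds()`, a frozen golden-seed contract in the test suite); each
task seeds its own RNG, so results are a pure function of (data, config,
seed) and independent of worker count or scheduling. The evaluation is
embarrassingly parallel over tasks (`workers = k` forks on unix). The
acceptance suite asserts byte-identical `evaluation.json`, `summaries.csv`
and `importance.csv` for 1 vs 4 workers. Learners with internal
randomness (forest, boosting, kNN tie-breaking) receive the task seed
explicitly; kNN label predictions wrap the randomized tie-break in a
locally seeded scope for the same reason.

## The synthetic generators: what they do and do not show

`simulate_classification()` plants `n_informative` features with a
between-class mean shift of `effect_size` SD units among standard-Gaussian
noise features (labels drawn iid from `class_fractions`);
`simulate_regression()` draws a sparse linear model with coefficient
magnitudes uniform in `[0.5, 1.5] * coefficient_scale`, random signs, and
Gaussian noise. Both return the ground truth so recovery can be scored.

These generators emulate the *structure* the pipeline must handle — sparse
signal among noise, class imbalance, known effect sizes — but deliberately
not several features of real biomedical data: correlated feature blocks,
heavy-tailed or count-valued measurements, batch effects, missingness
mechanisms, and label noise. Passing tests therefore demonstrate that the
machinery is correct (no leakage, calibrated intervals, faithful
formulas, recoverable planted signal), not that any particular learner
will perform comparably on real expression or methylation matrices.

Problem sizes used by the tests and the acceptance script were chosen so
the checked effects are statistically resolvable: the recovery study uses
200 observations, 50 features (3 informative, noise SD 0.5 against
coefficient magnitudes ~1) over training sizes 20/40/80 with 20 repeats
and 20 master seeds — the steep region of the learning curve, where the
expected drop in mean test MSE between consecutive sizes (roughly
$\sigma^2 k \log p / n$ for the lasso) is several times the Monte-Carlo
standard error of each per-size mean, so the monotonicity check is a real
test of the engine rather than a coin flip. Near the full-data end the
curve is flat and held-out sets shrink to a single observation; a
monotonicity assertion there would measure noise.

## Numerical and degenerate-input choices

* Largest-remainder rounding can momentarily exceed a small stratum's
  availability near size = total; allocations are capped and the excess
  redistributed by spare availability.
* Zero-variance features rank last under every variability measure (their
  measure is 0, not `NA`); variability is computed on non-missing values.
* In the moderated t, features with zero pooled variance are offset away
  from `log(0)` before the moment fit (mirroring the standard practice);
  if *all* variances are zero the prior is inestimable and the call errors.
  A failed moment fit falls back to the ordinary t with a warning.
* `NA` scores in tuning drop out of a configuration's mean; a
  configuration with no defined score is dropped with a message; ties on
  the tuned mean resolve toward the simpler configuration.
* The default size grid spans `ceiling(n/2)` to `n − 1` with equal integer
  steps, the final point pinned at the maximum; both published grids this
  rule was reverse-engineered from are asserted in the acceptance suite,
  and the grid is user-overridable.

## Known limitations

Supervised screening currently covers classification responses only
(two-sample tests one-vs-rest); a correlation-based screen for regression
responses is a natural extension point. The "generalized" kNN named in the
field is unspecified beyond its name, so the adapter wraps standard kNN.
Multinomial GLM sign information is ambiguous across classes and is
reported as 0. Reports are static HTML with embedded figures; the
plot-data JSON emitted alongside is the hook for anyone wanting
interactive widgets. Survival outcomes, multi-output responses and
multi-node execution are out of scope.
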