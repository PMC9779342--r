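---
title: "Weighted risk scores and LMG variance decomposition: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted risk scores and LMG variance decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rscontrib)
```

## The estimator

`rscontrib()` estimates how much of a continuous outcome's variance is
attributable to each of several predefined risk-factor categories whose
member predictors are mutually correlated (air pollutants, smoking
indicators, adiposity measures, SNPs, ...). The procedure has two stages,
repeated over bootstrap resamples.

**Stage 1 — risk-score weights (training split).** All predictors except
SNP variables are standardized to mean zero and unit SD (SNPs keep their
0/1/2 allele-count scale so a coefficient stays per-allele). One ridge
regression is fit with per-coefficient penalty factors: single predictors
are unpenalized (factor 0), category members are penalized (factor 1). The
objective is fixed and public:

$$\frac{1}{2n}\sum_i\Big(y_i-\gamma_0-\mathbf{x}_i^\top\boldsymbol\gamma\Big)^2
+\lambda\sum_j \mathrm{pf}_j\,\gamma_j^2 ,$$

solved in closed form via the centered normal equations
$(X^\top X/n + 2\lambda\,\mathrm{diag}(\mathrm{pf}))\,\boldsymbol\gamma =
X^\top(\mathbf{y}-\bar y)/n$. We deliberately do **not** delegate to an
elastic-net library: such libraries rescale internally and parameterize
$\lambda$ differently, whereas a closed-form objective can be verified
against an independent numerical optimizer to $10^{-8}$ (and is, in the test
suite). Ridge rather than a selector (lasso) is essential: the goal is
meaningful relative weights among correlated members, not variable
selection.

$\lambda$ is chosen on a 100-point log-spaced grid anchored at
$\lambda_{\max}=\max_j |x_j^\top(\mathbf y-\bar y)|/n$ over penalized
columns (the usual grid anchor diverges for pure ridge), descending to
$10^{-4}\lambda_{\max}$, by tenfold cross-validation minimizing pooled
out-of-fold squared error. Because fold assignment is random, the CV + fit
step is repeated (default 20 times, re-randomizing only the folds) and the
coefficient estimates averaged. Each category's averaged coefficients
$\hat\gamma_{kj}$ become weights by signed-sum normalization

$$w_{kj}=\frac{\hat\gamma_{kj}}{\sum_l \hat\gamma_{kl}},\qquad
w_{kj}=\tfrac1{m_k}\ \text{if all}\ \hat\gamma_{kj}=0,$$

which guarantees $\sum_j w_{kj}=1$. Note a subtlety: with mixed-sign
coefficients the weights sum to one but individual weights can leave
$[-1,1]$ (e.g. $\hat\gamma=(3,-1)\mapsto w=(1.5,-0.5)$); sum-to-one is the
property the construction actually provides, and the one the package
asserts. When the signed sum nearly cancels
($|\sum\hat\gamma| < 10^{-8}\sum|\hat\gamma|$) the normalization is
numerically meaningless; the category falls back to uniform weights and the
replicate is flagged. The all-zero branch uses an absolute threshold
$\zeta=10^{-12}$.

**Stage 2 — decomposition (test split).** The risk score
$z_k=\sum_j w_{kj}x_{kj}$ is computed on the test split (standardized with
the *training* statistics, so no information leaks), scaled by its
test-sample interquartile range, and entered with the single predictors in
an OLS model. Its coefficient is then the outcome change per one-IQR
increase of the raw score. The model's $R^2$ is decomposed with the
Lindeman–Merenda–Gold measure over regressor *units* — each risk score, each
plain single predictor, each declared dummy group (e.g. two SES dummies) as
one unit:

$$\mathrm{share}(u)=\sum_{T\subseteq U\setminus\{u\}}
\frac{|T|!\,(p-|T|-1)!}{p!}\big[R^2(T\cup\{u\})-R^2(T)\big].$$

This Shapley subset-sum form costs $2^p$ subset regressions (4096 at the
12 units of a typical application) instead of $p!$ orderings (479 million);
the literal all-orderings average is retained as `lmg_bruteforce()` and the
two are required to agree to $10^{-10}$ in the test suite. Subset $R^2$
values come from one precomputed set of centered cross-products; rank
deficient subsets (possible when bootstrap resampling duplicates rows) use
the minimum-norm pseudoinverse solution, for which $R^2$ is still the
well-defined projection length. Sequential increments are clamped at zero
against $-10^{-16}$-scale floating-point noise, so shares are nonnegative
and still sum to the full-model $R^2$ within $10^{-10}$.

**Bootstrap.** Replicate 0 analyzes the original data; replicates
$1..B-1$ resample participants with replacement. Each replicate is split
60/40, analyzed fully, and summarized across replicates by medians and
percentile intervals. Replicates that degenerate — a zero risk-score IQR or
a rank-deficient test design — are excluded from summaries, counted, and
reported; a run aborts if more than half fail.

## Tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `B` | 200 | bootstrap replicates; 500 is comfortable for small predictor sets, 200 keeps large SNP categories tractable |
| `train_fraction` | 0.6 | train/test split; sizes are `round(0.6 n)` rounded half away from zero |
| `cv_folds` | 10 | folds for $\lambda$ selection |
| `cv_repeats` | 20 | fold re-randomizations averaged per replicate |
| `n_lambda`, `lambda_min_ratio` | 100, $10^{-4}$ | $\lambda$ grid resolution and span |
| `ci_level` | 0.95 | percentile interval level |
| `standardize_on` | `"train"` | see below |
| `seed` | 1 | master seed; replicate/fold streams are derived from it |

## Decisions where the design was genuinely open

* **$\lambda$ rule.** Minimum mean CV error, not the one-standard-error
  rule; ties resolve to the larger (more shrinking) $\lambda$ because the
  grid is descending.
* **Standardization timing.** The default computes standardization
  statistics on each replicate's training split and freezes them for its
  test split — the leakage-safe choice. `standardize_on = "full"`
  standardizes the original table once before bootstrapping, which is the
  other defensible reading; the two are one flag apart and the package
  asserts neither as canonical.
* **Quantile convention.** All quantiles — the IQR that scales risk scores
  and the percentile CI bounds — use linear interpolation between order
  statistics (type 7, R's default). IQR values genuinely differ across
  conventions, so one is fixed repo-wide. The IQR is computed on the test
  split of the current replicate, the sample in which the scaled score
  enters the regression.
* **SD convention.** $n-1$ denominator throughout.
* **Bootstrap p-values.** Reported coefficients carry
  $p = 2\min(f^+, f^-)$ where $f^\pm$ are the fractions of replicate
  coefficients $\ge 0$ / $\le 0$, floored at the minimum attainable
  $2/B_\mathrm{eff}$. This sign-crossing definition is an interpretation
  (percentile-bootstrap practice), and is labeled as such in the output
  manifest. Share CIs cannot cross zero by construction and are not used
  for significance.
* **Degenerate training columns.** A member that is constant in a training
  split (a rare binary under resampling) is centered to zeros, its
  coefficient forced to 0 before normalization, and the event flagged —
  keeping the replicate usable rather than discarding it.

## The synthetic generator

`synthetic_model()` specifies marginals (continuous mean/SD, binary
prevalence, SNP minor-allele frequency), a compound-symmetric latent
correlation $\rho_k$ within each category block, an optional correlation
matrix among singles, per-predictor effects on the raw scale, and a noise
SD; `generate_cohort()` draws latent Gaussians, maps them through the
marginals (thresholding for binary, binomial quantile for SNP), and builds
the outcome as a standardized linear combination. All dependence lives on
the latent scale — the simplest scheme that is positive definite by
construction — which means realized correlations of *discretized* variables
are attenuated relative to $\rho_k$ (a thresholded pair at latent 0.6
realizes roughly 0.4–0.55 depending on prevalences). `true_contributions()`
computes the implied predictor covariance analytically (orthant
probabilities for threshold pairs via one-dimensional quadrature) and takes
the population LMG over units, treating each category's full member block
as one unit; it is the ground-truth oracle for the recovery tests.

`salia_template()` packages a realistic template: 510 participants, age,
height and two nearly-exclusive SES dummies as singles, and genetic (20
SNPs by default, 278 optional), obesity, smoking and air-pollution
categories whose marginals follow published descriptive statistics of an
elderly German women's cohort. Its effects are calibrated so the analytic
population decomposition gives genetic 11%, smoking 5%, obesity 4%, air
pollution 0.5%, SES 0.8%, height 0.4%, age 0.3% of variance (total
$R^2=22\%$) — mirroring the qualitative ranking reported for lung-function
outcomes. The SES dummies are generated as two negatively correlated
binaries (latent $-0.9$), not strictly mutually exclusive, because the
copula supports only monotone thresholding of one latent per variable.

What passing tests on such cohorts do *not* show: the generator has no
linkage-disequilibrium structure among SNPs, no spatial exposure model, no
nonlinearity or interactions, and Gaussian tails everywhere; real-data
behavior under model misspecification is outside what the test suite can
certify.

`synthetic_model_shares()` builds the cleanest possible recovery fixture:
independent continuous blocks with equal within-block effects chosen so the
population LMG shares equal a prescribed vector exactly (independence makes
each unit's share its marginal $R^2$ contribution). The package's recovery
study uses shares 0.12/0.06/0.01 at $n=2000$, $B=100$ over 20 seeds, and
the null-calibration study uses all-zero shares at $n=1000$ — sizes chosen
to make medians stable while a full run stays desk-scale.

## Numerical notes

* The ridge path is solved by Schur complement of the unpenalized block and
  a single eigendecomposition of the penalized block per fold, so the whole
  100-$\lambda$ grid costs one small eigen plus $O(p^2)$ per grid point;
  cross-validation folds reuse total cross-products minus the held-out
  fold's contribution.
* $\lambda = 0$ with a singular system is an error (OLS is not defined);
  penalized constant columns are harmless for $\lambda>0$ (their
  coefficients are exactly zero).
* `bootstrap_resample`, `split_train_test` and the CV folds each draw from
  independent streams derived from `(seed, replicate, repeat)`, so any
  replicate can be reproduced in isolation and replicates are
  order-independent.
* Simulated cohorts written by the CLI use 17-significant-digit formatting
  so `simulate → write → read` round-trips doubles exactly.

## Limitations

The approach is confined to linear regression — the LMG decomposition has no
accepted analogue for generalized linear models, so binary outcomes are out
of scope. Contributions are relative to the fitted linear model: omitted
categories, nonlinearity, or measurement error shift all shares. The
train/test split halves the effective sample twice (weights and
decomposition are estimated on disjoint data), which is the price of
internally estimated weights; the bootstrap absorbs the split randomness
but cannot recover the lost power. Weight normalization by signed sum is
unstable near cancellation; the uniform fallback is logged rather than
hidden, and frequent fallbacks in a real analysis signal that a category's
members do not share a coherent direction of effect.
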