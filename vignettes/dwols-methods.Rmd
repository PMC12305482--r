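---
title: "Estimating optimal adaptive treatment strategies with dWOLS and
  machine-learned propensities"
author: "dwolsml"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating optimal adaptive treatment strategies with dWOLS and machine-learned propensities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

An adaptive treatment strategy (dynamic treatment regime) is a sequence of
decision rules, one per stage $t = 1, \dots, T$, mapping a patient's
accumulated history $H_t = (\bar A_{t-1}, \bar X_t)$ to a binary treatment
decision $A_t \in \{0, 1\}$.  The target of estimation is the *blip*
$\gamma_t(a_t, h_t)$: the effect of receiving $a_t$ versus the reference
treatment 0 at stage $t$, for a patient with history $h_t$, assuming
optimal decisions at all later stages.  With linear blips
$\gamma_t = \psi_t^\top h_t^{\psi} a_t$, the optimal rule is the sign rule:
treat when $\hat\psi_t^\top h_t^{\psi} > 0$, withhold when it is negative,
and leave the action undefined when it is exactly zero (`dwols()` reports
this as a distinct `NA`, never silently coerced to an action).

Estimation proceeds by backward recursion on the stagewise working model
$$Q_t(h_t, a_t) = \beta_t^\top h_t + \psi_t^\top h_t^{\psi} a_t,$$
fitted at stage $T$ to the outcome $Y$ (larger is better), and at earlier
stages to the *pseudo-outcome*
$$\tilde Y_t = \hat\beta_{t+1}^\top h_{t+1} +
  \max(0, \hat\psi_{t+1}^\top h_{t+1}^{\psi}),$$
the model's prediction of the outcome had the patient been treated
optimally from stage $t+1$ on.  Ordinary least squares at each stage is
Q-learning (`method = "qlearn"`).  Dynamic weighted OLS (dWOLS) instead
weights each subject by
$$w_t = |a_t - E[A_t \mid H_t]|,$$
which satisfies the balancing condition $w(1, h)P(A_t{=}1 \mid h) =
w(0, h)P(A_t{=}0 \mid h)$ and renders the blip estimate doubly robust: at
each stage, consistency requires only that either the treatment
probability model or the outcome model be correct.

Identification assumes no interference, consistency, positivity, and
sequential conditional exchangeability.  The package does not (and cannot)
test the exchangeability assumption; positivity is surfaced as a
diagnostic — the share of balancing weights below 0.01 per stage, and the
propensity-overlap histograms of `plot.dwols()`.

## Machine-learned propensities and cross-fitting

The treatment model $E[A_t \mid H_t]$ may be estimated by logistic
regression or by flexible learners (random forest, naive Bayes, SVM with
Platt-type probability calibration, a single-hidden-layer neural network
with 3 hidden nodes and weight decay 0.1, or a SuperLearner stacking
ensemble).  Flexible learners can overfit, which manifests as predicted
probabilities piled near 0/1 and artificial positivity violations.  The
package therefore cross-fits: the sample is split into $K$ near-equal
folds (default $K = 2$; sizes differ by at most one) and each subject's
probability is predicted by a model trained on the other folds only.  The
split is redrawn at each stage.  $K = 1$ disables cross-fitting.  Two
folds are the default because the point-estimate gains from more folds are
small relative to the added computation; $K$ is configurable from 1 to 10.

The SuperLearner here is a compact stacking ensemble written for this
package: candidate learners are cross-validated (default 10-fold), the
meta-weights minimise the cross-validated squared error on the probability
scale subject to non-negativity (solved by non-negative least squares)
and are normalised to sum to one, and the retained candidates are refitted
on the full training set.  A candidate that fails to fit is dropped with a
warning — mirroring the practical fragility of some learners (the SVM
especially) — and an all-candidate failure is an error.  The default
candidate library is logistic regression, logistic regression with all
pairwise interactions, random forest, the neural net, and the SVM.

No propensity truncation is applied anywhere: the weights $|a - p|$
*shrink* as $p \to 0$ or $1$, and clipping would break the balancing
identity that double robustness rests on.

## Inference: the adaptive m-out-of-n bootstrap

When the propensities are machine-learned, the ordinary n-out-of-n
bootstrap can be inconsistent: duplicated subjects may land in different
cross-fitting folds, creating dependence between splits, and the blip
estimator is non-regular near $\psi^\top h = 0$.  The package implements
the adaptive m-out-of-n bootstrap:

1. Estimate $\hat\psi$ on the full sample.
2. For $m_j = \lfloor q^j n \rfloor$, $j = 0, \dots, K$ (defaults
   $q = 0.95$, $K = 14$, so $m_K \approx n/2$), draw $B$ resamples of
   $m_j$ whole subject trajectories with replacement, rerun the *entire*
   pipeline (cross-fitting and learner refits included) on each, and form
   the ECDF of $\sqrt{m_j}(\hat\psi_{jb} - \hat\psi)$ per parameter.
3. Select the $j$ at which the bootstrap distribution is most stable:
   the minimiser of the Kolmogorov distance between successive ECDFs,
   ties broken toward the larger subsample.
4. Estimate the convergence-rate exponent $\beta$ in the working
   $n^\beta$ rate as the OLS slope of
   $\log \widehat{\mathrm{Var}}(\hat\psi_j)$ on $-2\log m_j$ (so a
   $\sqrt n$-consistent estimator gives $\beta = 0.5$ exactly).
5. Report $\hat\psi \pm z_{0.975} (m_{j^*}/n)^{\hat\beta}
   \sqrt{\widehat{\mathrm{Var}}(\hat\psi_{j^*})}$ — at $m = n$ this is the
   usual normal interval, and the $(m/n)^\beta$ factor transports the
   bootstrap variance from the subsample to the full-sample scale.

Two conventions in this procedure are genuinely ambiguous in the
surrounding literature, and both resolutions are configurable for
sensitivity analysis: the ECDF statistic's scaling (`scale = "sqrt_m"`,
the conventional normalisation consistent with asymptotic normality, vs
the raw `"m"`), and the selection direction (`select = "argmin"` of the
successive sup-distance, which matches the stability rationale, vs the
literal `"argmax"`).  The defaults are the stability-consistent choices.
Per-grid-point seeds are derived from one master seed by a counter scheme,
so every grid point is independently reproducible; failed replicates are
dropped and counted, with more than 10% failures at any grid point an
error.  The standard percentile bootstrap (`percentile_boot()`, type-7
quantiles) is provided as the regular-case baseline.

## The synthetic scenario generator

No public registry data accompany the methodology, so the package ships a
two-stage generator (`generate_scenario()`) emulating five study designs:

* $X_1 \sim N(0,1)$, $A_1 \sim \mathrm{Bern}(\mathrm{expit}(f_1(X_1)))$,
  $X_2 = 0.5X_1 + N(0,1)$,
  $A_2 \sim \mathrm{Bern}(\mathrm{expit}(f_2(X_1, X_2, A_1)))$,
  $Y = g(X_1, X_2) + A_1(\psi_{10} + \psi_{11}X_1) +
  A_2(\psi_{20} + \psi_{21}X_2) + N(0,1)$, with default
  $\psi^* = (1, -1, 1, -1)$.
* The complexity ladder is strictly nested: *simple* means linear terms
  with coefficient 0.5; *medium* adds $-0.5 v^2$; *complex* adds
  $0.5|v| + 0.5\sin(2v)$.  Study 1 keeps $g$ simple and varies $f$;
  Study 2 the reverse; Studies 3–5 vary both.  Study 4 multiplies the
  treatment predictors by 4, pushing probabilities to the boundary
  (practical positivity violations); Study 5 adds eight pure-noise
  covariates for a 10-covariate analysis problem.
* Every coefficient is overridable through a nested coefficient map, so
  alternative generating equations can be dropped in verbatim without
  touching code; `true_blip_values()` returns whatever $\psi^*$ the
  config carries, and the harness measures bias against exactly those.

Two deliberate design choices deserve explanation.  First, the stage-2
covariate equation carries **no stage-1 treatment effect by default**
(the `A1` coefficient in the `x2` block ships as 0).  If $A_1$ shifted
$X_2$, the generating $\psi_{10}, \psi_{11}$ would no longer be the
stage-1 estimand — $A_1$ would act on $Y$ additionally through $X_2$'s
treatment-free and blip terms — and bias measured against the nominal
$\psi^*$ would conflate estimator error with estimand mismatch.  The
coefficient is exposed for users who want the harder, indirect-effect
setting.  Second, the analysis models follow the canonical two-stage
specification: $A_1 \sim X_1$; $A_2 \sim X_1 + X_2 + A_1$; stage-2
outcome model with main terms $X_1, X_2, A_1, A_2$ plus $A_1{:}X_1$,
$A_1{:}X_2$, $A_2{:}X_2$; stage-1 model with $A_1$, $X_1$ and their
interaction.

What the generator does *not* emulate: censored or survival outcomes,
more than two stages, non-binary treatments, measurement error, and
unmeasured confounding.  Tests passing on these scenarios demonstrate
internal correctness of the estimator and its inference under the stated
identification assumptions — not robustness to their violation in real
registries.

## Numerical choices

* Weighted least squares is solved by QR on the $\sqrt w$-scaled design;
  rank is checked against the singular values with relative tolerance
  $10^{-10}$, and a deficient design is an error naming the collinear
  columns.  All-zero weights and single-arm stages (an unidentified blip)
  are errors, not warnings.
* Ties $\hat\psi^\top h = 0$ leave the pseudo-outcome untouched
  ($\max(0, \cdot)$ is unaffected) and surface only in rule reporting as
  the undefined action.
* The selection tie-break in the m-out-of-n grid prefers the larger
  subsample; the two-sample Kolmogorov distance is computed exactly
  (tie-safe pooled scan).
* Replicate seeds in the harness are `seed + r`; per-(grid, replicate)
  bootstrap seeds are counter-derived and stay below $2^{31}$.

## Double robustness and the fitted-Q pseudo-outcome: a caveat

The package uses the fitted-Q pseudo-outcome
$\hat\beta^\top h + \max(0, \hat\psi^\top h^\psi)$ (the Q-learning
construction), not the regret-adjusted alternative.  This has a
consequence worth stating precisely, because it shapes what "double
robustness" can promise across stages:

* Within a stage, the blip estimate tolerates an arbitrary treatment-free
  misspecification *provided the blip covariates' main effects remain in
  the treatment-free design* — the balancing weights make the
  treatment-by-blip regressors orthogonal to any function of history only
  after those main effects are projected out.
* Across stages, a misspecified stage-2 treatment-free fit contaminates
  the pseudo-outcome, and the contamination enters the *stage-1 blip*
  whenever it projects onto treatment-history terms (i.e. when earlier
  treatments are correlated with the misspecified part).  A correct
  stage-1 treatment model cannot repair this, because the error sits in
  the response itself.  This is visible in published two-stage
  evaluations of this estimator family as stage-1 bias appearing
  precisely in the "correct treatment model, complex outcome model"
  study.

The double-robustness simulations in the test suite therefore use a
design where the property holds exactly — randomised stage-1 treatment
and a stage-2 assignment model free of $A_1$ — so that the 3-Monte-Carlo-SE
bias bound is a sharp test of the implementation rather than of the
estimand gap.  Relatedly, the tight recovery tests set
$\psi^* = (1, -1, 2.5, -0.5)$: the stage-2 blip $2.5 - 0.5X_2$ is then
positive with probability $\approx 1 - 3\times10^{-5}$, the
$\max(0,\cdot)$ is effectively linear, and the stage-1 target coincides
exactly with the generating coefficients.  With a sign-changing stage-2
blip (the generator's default $\psi^*$), $E[\max(0, \psi_2^\top
h)\mid X_1]$ is a smooth nonlinear function of $X_1$, so a linear stage-1
treatment-free model is *mildly misspecified by construction* — correct
stage-1 propensities absorb this, which is itself a small demonstration
of double robustness.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script runs are sized for a single CPU:
bias tables use 200 (tests) or 1000 (acceptance script) replicates at
$n = 300$ with logistic propensities; the double-robustness bounds use
200 replicates at $n = 5000$; sample-mean bootstrap coverage uses 500
replicates at $n = 400$ with $B = 200$ (m-out-of-n) and $B = 1000$
(percentile).  The m-out-of-n coverage study around the full
SuperLearner pipeline is run scaled down: 20 replicates at $n = 300$
with $B = 50$ per grid point and a two-candidate ensemble (logistic
regression with and without pairwise interactions) under twofold
cross-fitting — the full design with the five-learner ensemble and
hundreds of replicates is a many-hour computation and the scaled run
preserves its structure (full grid $q = 0.95$, $K = 14$, whole-pipeline
refits in every resample).  Coverage conclusions from 20 replicates
carry a binomial error of roughly $\pm 7$ percentage points and are
assessed accordingly.

## Known limitations

* Binary treatments and a single continuous final outcome only; no
  censoring or survival outcomes.
* The pseudo-outcome is the fitted-Q form; the regret-style construction
  is not implemented.
* Learner hyperparameters default to the underlying packages' defaults
  (plus the stated neural-net settings); no tuning is performed.
* The m-out-of-n interval assumes asymptotic normality of the estimator;
  the rate regression assumes a polynomial $n^\beta$ rate.
* Asymptotic (sandwich-type) standard errors, double-bootstrap
  calibration, and subsampling without replacement are out of scope.
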