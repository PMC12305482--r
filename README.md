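# dwolsml

Doubly robust estimation of optimal adaptive treatment strategies
(dynamic treatment regimes) by **dynamic weighted ordinary least squares
(dWOLS)**, with treatment probabilities modelled either parametrically or
by machine-learning algorithms under cross-fitting, and inference by an
**adaptive m-out-of-n bootstrap**.

## Who this is for

Biostatisticians and epidemiologists estimating stage-wise treatment
rules from observational longitudinal data — one row per subject,
per-stage covariates and binary treatments, one continuous final outcome
— who want the robustness of a doubly robust estimator without betting
everything on a parametric propensity model, and who need confidence
intervals that remain honest when the nuisance models are machine-learned.

## The estimator

At each stage $t$ the working model is
$Q_t(h_t, a_t) = \beta_t^\top h_t + \psi_t^\top h_t^{\psi} a_t$,
where $\psi_t^\top h_t^{\psi}$ is the *blip*: the treatment effect at
stage $t$ for history $h_t$ under optimal future decisions.  Fitting is
by backward recursion — the outcome $Y$ at the last stage, the
pseudo-outcome $\hat\beta_{t+1}^\top h_{t+1} + \max(0,
\hat\psi_{t+1}^\top h_{t+1}^{\psi})$ earlier — using weighted least
squares with the balancing weights

$$w_t = \lvert a_t - E[A_t \mid H_t] \rvert,$$

which make the estimate of $\psi_t$ consistent if *either* the treatment
model or the outcome model is correctly specified (double robustness).
The implied decision rule is the sign of the fitted blip: treat if
positive, withhold if negative, undefined if exactly zero.

$E[A_t \mid H_t]$ can be fitted by logistic regression, random forest,
naive Bayes, SVM (Platt-calibrated probabilities), a neural net, or a
SuperLearner stacking ensemble — all under K-fold cross-fitting (default
twofold) so that no subject is predicted by a model trained on its own
fold.  Confidence intervals come from the adaptive m-out-of-n bootstrap:
resample $m_j = \lfloor 0.95^j n \rfloor$ subjects, reruns of the whole
pipeline, stability-based choice of $m$, a convergence-rate exponent
estimated from how the bootstrap variance scales with $m$, and the
rescaled normal interval
$\hat\psi \pm 1.96\,(m/n)^{\hat\beta}\sqrt{\widehat{\mathrm{Var}}}$.
See the methods vignette (`vignettes/dwols-methods.Rmd`) for the full
account.

## Worked example

```r
library(dwolsml)

## two-stage synthetic trajectories: X1 -> A1 -> X2 -> A2 -> Y,
## true blips 1 - X1 (stage 1) and 1 - X2 (stage 2)
sc <- generate_scenario(scenario_config(study = 1, complexity = "simple",
                                        n = 1000, seed = 7))
sp <- scenario_specs(1)

fit <- dwols(sp$outcome, sp$blip.mod, sp$treat.mod, sp$tf.mod,
             data = sc$data, learner = "logit", folds = 2, seed = 1)
fit
```

```
Dynamic weighted OLS fit, 2 stages, 1000 subjects
Propensity learner: logit with 2 cross-fitting fold(s)

Stage 1 blip (psi):
(Intercept)          X1 
     1.0011     -0.9535 

Stage 2 blip (psi):
(Intercept)          X2 
     1.0184     -1.0699 
```

The fitted blips recover the generating rules: treat at stage 1 when
$1.00 - 0.95\,X_1 > 0$ (truth: $1 - X_1$), and at stage 2 when
$1.02 - 1.07\,X_2 > 0$ (truth: $1 - X_2$).  `predict(fit, newdata,
stage = 2)` returns the recommended action (1 = treat, 0 = withhold,
`NA` = undefined) for new subjects, and

```r
confint(fit, method = "mn", config = mn_boot_config(B = 200, seed = 1))
```

reruns the entire pipeline on m-out-of-n resamples and returns, per blip
parameter, the interval built from the stability-selected subsample size
and the estimated convergence rate.

For a simulation study over replicated datasets:

```r
rr <- run_replicates(scenario_config(3, "medium", n = 300),
                     methods = list(logit = "logit",
                                    sl = learner_spec("superlearner")),
                     R = 200, seed = 1)
summarize_replicates(rr)   # bias, SD, RMSE, RMSE ratio, MC errors
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/dwols-sim.R` (subcommands `run-study`, `coverage`, `fit`;
YAML configs via `read_run_config()`).

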