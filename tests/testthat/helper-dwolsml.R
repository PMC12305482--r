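## shared test fixtures, all built in code

## SuperLearner with inexpensive candidates, used wherever the ensemble sits
## inside a resampling loop
sl_cheap <- function() {
  learner_spec("superlearner",
               candidates = list(learner_spec("logit"),
                                 learner_spec("logit_int")),
               cv_folds = 5)
}

## single-stage logistic data for propensity-module tests
make_logistic_data <- function(n, seed = 1, beta = c(0, 1)) {
  set.seed(seed)
  X1 <- rnorm(n)
  p <- plogis(beta[1] + beta[2] * X1)
  data.frame(X1 = X1, A1 = rbinom(n, 1, p), p_true = p)
}

## a learner that always predicts a constant probability
constant_learner <- function(p = 0.5) {
  learner_spec(list(name = "constant",
                    fit = function(x, y) p,
                    predict = function(m, nx) rep(m, nrow(nx))))
}

## blip truth used for the tight recovery/double-robustness checks: the
## stage-2 blip 2.5 - 0.5 * X2 is positive with probability ~1, so the
## stage-1 estimand is exactly linear and equals the generating values
psi_exact <- c(1, -1, 2.5, -0.5)

## per-session cache for expensive shared computations
.test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .test_cache)) {
    assign(key, force(expr), envir = .test_cache)
  }
  get(key, envir = .test_cache)
}
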