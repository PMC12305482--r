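test_that("constant propensities reduce dWOLS to OLS Q-learning
           coefficient-for-coefficient", {
  sc <- generate_scenario(scenario_config(1, "simple", n = 400, seed = 2))
  sp <- scenario_specs(1)
  fw <- dwols(sp$outcome, sp$blip.mod, sp$treat.mod, sp$tf.mod, sc$data,
              propensity = list(0.5, 0.5))
  fq <- dwols(sp$outcome, sp$blip.mod, sp$treat.mod, sp$tf.mod, sc$data,
              method = "qlearn")
  expect_equal(coef(fw), coef(fq), tolerance = 1e-8)
  for (t in 1:2) {
    expect_equal(fw$beta[[t]], fq$beta[[t]], tolerance = 1e-8)
  }
})

test_that("the stage-T response is the outcome and earlier responses are the
           fitted-Q pseudo-outcomes", {
  sc <- generate_scenario(scenario_config(1, "simple", n = 300, seed = 5))
  sp <- scenario_specs(1)
  fit <- dwols(sp$outcome, sp$blip.mod, sp$treat.mod, sp$tf.mod, sc$data,
               learner = "logit", seed = 9)
  expect_equal(fit$stages[[2]]$response, sc$data$Y)
  Hf <- model.matrix(sp$tf.mod[[2]], sc$data)
  Hb <- model.matrix(sp$blip.mod[[2]], sc$data)
  expect_equal(fit$stages[[1]]$response,
               pseudo_outcome(fit$beta[[2]], fit$psi[[2]], Hf, Hb))
})

test_that("degenerate treatment arms and bad inputs are rejected with the
           stage identified", {
  sc <- generate_scenario(scenario_config(1, "simple", n = 200, seed = 3))
  sp <- scenario_specs(1)
  d <- sc$data
  d$A2 <- 0
  expect_error(dwols(sp$outcome, sp$blip.mod, sp$treat.mod, sp$tf.mod, d),
               "stage 2.*unidentified")
  d2 <- sc$data
  d2$A1[5] <- 2
  expect_error(dwols(sp$outcome, sp$blip.mod, sp$treat.mod, sp$tf.mod, d2),
               "coded 0/1")
  d3 <- sc$data
  d3$X2[c(4, 9)] <- NA
  expect_error(dwols(sp$outcome, sp$blip.mod, sp$treat.mod, sp$tf.mod, d3),
               "missing values in rows: 4, 9")
  ## a collinear treatment-free term fails naming the stage
  d4 <- sc$data
  d4$X1dup <- d4$X1
  expect_error(
    dwols(sp$outcome, sp$blip.mod, sp$treat.mod,
          list(~ X1 + X1dup, sp$tf.mod[[2]]), d4),
    "stage 1.*collinear")
})

test_that("blip parameters are recovered and double robustness holds under
           single-model misspecification", {
  ## moderate-size version; the full-size run lives in the acceptance suite
  sp <- scenario_specs(1)
  R <- 60
  n <- 2000
  est_ok <- est_wrong_tf <- est_wrong_p <- matrix(NA_real_, R, 4)
  ## for the wrong-outcome-model arm the misspecification must not project
  ## onto treatment-history terms (randomised A1, history-free A2 model),
  ## or the fitted-Q pseudo-outcome carries the error into stage 1
  ovr <- list(treat1 = list(linear = c(X1 = 0)),
              treat2 = list(linear = c(X1 = 0.5, X2 = 0.5, A1 = 0)))
  for (r in seq_len(R)) {
    sc <- generate_scenario(
      scenario_config(1, "simple", n = n, seed = 7000 + r,
                      psi = psi_exact))
    set.seed(r)
    est_ok[r, ] <- coef(dwols(sp$outcome, sp$blip.mod, sp$treat.mod,
                              sp$tf.mod, sc$data, learner = "logit"))
    ## (a) correct outcome model, arbitrary (wrong) propensities
    pw <- list(plogis(1 - 2 * sc$data$X1), plogis(0.3 - sc$data$X2))
    est_wrong_p[r, ] <- coef(dwols(sp$outcome, sp$blip.mod, sp$treat.mod,
                                   sp$tf.mod, sc$data, propensity = pw))
    ## (b) correct propensities, badly wrong treatment-free model (the
    ## generating outcome mean has quadratic, absolute-value and sine
    ## terms; the fitted treatment-free model is linear)
    sc2 <- generate_scenario(
      scenario_config(2, "complex", n = n, seed = 7000 + r,
                      psi = psi_exact, overrides = ovr))
    est_wrong_tf[r, ] <- coef(dwols(sp$outcome, sp$blip.mod, sp$treat.mod,
                                    sp$tf.mod, sc2$data,
                                    propensity = list(sc2$truth$p1,
                                                      sc2$truth$p2)))
  }
  for (E in list(est_ok, est_wrong_tf, est_wrong_p)) {
    bias <- colMeans(E) - psi_exact
    mcse <- apply(E, 2, sd) / sqrt(R)
    expect_true(all(abs(bias) <= 3 * mcse))
  }
})

test_that("an irrelevant history covariate leaves the blip estimates
           unbiased", {
  sp <- scenario_specs(1)
  R <- 150
  est <- matrix(NA_real_, R, 4)
  for (r in seq_len(R)) {
    sc <- generate_scenario(
      scenario_config(1, "simple", n = 2000, seed = 4000 + r,
                      psi = psi_exact))
    d <- sc$data
    set.seed(r)
    d$Z <- rnorm(nrow(d))
    est[r, ] <- coef(dwols(sp$outcome, sp$blip.mod, sp$treat.mod,
                           list(~ X1 + Z, ~ X1 + X2 + A1 + A1:X1 +
                                  A1:X2 + Z),
                           d, learner = "logit"))
  }
  bias <- colMeans(est) - psi_exact
  mcse <- apply(est, 2, sd) / sqrt(R)
  expect_true(all(abs(bias) <= 3 * mcse))
})

test_that("fit methods expose coefficients, rules, predictions and
           diagnostics", {
  sc <- generate_scenario(scenario_config(1, "simple", n = 300, seed = 11))
  sp <- scenario_specs(1)
  fit <- dwols(sp$outcome, sp$blip.mod, sp$treat.mod, sp$tf.mod, sc$data,
               learner = "logit", seed = 1)
  co <- coef(fit)
  expect_named(co, c("psi10", "psi11", "psi20", "psi21"))
  expect_equal(unname(co[1:2]), unname(fit$psi[[1]]))
  ## predictions agree with the sign rule applied to new data
  nd <- data.frame(X1 = c(-10, 10), X2 = 0, A1 = 0, A2 = 0, Y = 0)
  act <- predict(fit, nd, stage = 1)
  blip <- predict(fit, nd, stage = 1, type = "blip")
  expect_identical(as.integer(act),
                   as.integer(optimal_rule(fit$psi[[1]],
                                           cbind(1, nd$X1))))
  expect_equal(unname(blip),
               unname(fit$psi[[1]][1] + fit$psi[[1]][2] * nd$X1))
  expect_length(residuals(fit, stage = 2), 300)
  expect_length(fit$diagnostics$low_weight_share, 2)
  expect_output(print(summary(fit)), "Stage 2 blip")
})
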