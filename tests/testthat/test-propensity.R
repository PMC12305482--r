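test_that("cross-fitting folds are near-equal, seeded, and deterministic", {
  d300 <- make_logistic_data(300, seed = 1)
  d301 <- make_logistic_data(301, seed = 2)
  pe <- crossfit_propensity(d300, A1 ~ X1, folds = 2, seed = 10)
  expect_equal(as.integer(sort(table(pe$fold))), c(150L, 150L))
  pe2 <- crossfit_propensity(d301, A1 ~ X1, folds = 2, seed = 10)
  expect_equal(as.integer(sort(table(pe2$fold))), c(150L, 151L))
  ## same call, same seed: bitwise identical
  pe_b <- crossfit_propensity(d300, A1 ~ X1, folds = 2, seed = 10)
  expect_identical(pe$p, pe_b$p)
  expect_identical(pe$fold, pe_b$fold)
  ## probabilities are probabilities
  expect_true(all(is.finite(pe$p) & pe$p >= 0 & pe$p <= 1))
})

test_that("predictions never depend on the subject's own fold's labels", {
  d <- make_logistic_data(200, seed = 4)
  pe <- crossfit_propensity(d, A1 ~ X1, folds = 2, seed = 21)
  d_mut <- d
  in2 <- pe$fold == 2
  d_mut$A1[in2] <- 1 - d_mut$A1[in2]   # flip fold 2's labels
  pe_mut <- crossfit_propensity(d_mut, A1 ~ X1, folds = 2, seed = 21)
  expect_identical(pe_mut$fold, pe$fold)
  ## fold-2 subjects are predicted by the fold-1-trained model: unchanged
  expect_identical(pe_mut$p[in2], pe$p[in2])
  ## fold-1 subjects are predicted by the fold-2-trained model: changed
  expect_false(isTRUE(all.equal(pe_mut$p[!in2], pe$p[!in2])))
})

test_that("without cross-fitting a logistic learner recovers the generating
           probabilities", {
  d <- make_logistic_data(5000, seed = 6)
  pe <- crossfit_propensity(d, A1 ~ X1, learner = "logit", folds = 1,
                            seed = 1)
  expect_lt(mean(abs(pe$p - d$p_true)), 0.02)
  expect_identical(unique(pe$fold), 1L)
})

test_that("a one-class fold triggers re-partition and eventually a
           positivity error", {
  ## 3 treated among 60: folds of 20 often miss a treated subject, but a
  ## re-partition that works exists
  set.seed(8)
  d <- data.frame(X1 = rnorm(60), A1 = rep(c(1, 0), c(3, 57)))
  pe <- crossfit_propensity(d, A1 ~ X1, folds = 3, seed = 1)
  cnt <- table(pe$fold, d$A1)
  expect_true(all(cnt > 0))
  ## 1 treated subject can never appear in both folds
  d1 <- data.frame(X1 = rnorm(40), A1 = rep(c(1, 0), c(1, 39)))
  expect_error(crossfit_propensity(d1, A1 ~ X1, folds = 2, seed = 1),
               "positivity")
})

test_that("every built-in learner yields valid cross-fitted probabilities", {
  d <- make_logistic_data(150, seed = 9)
  for (lrn in c("logit", "logit_int", "naive_bayes", "neural_net",
                "svm")) {
    pe <- crossfit_propensity(d, A1 ~ X1, learner = lrn, folds = 2,
                              seed = 3)
    expect_true(all(is.finite(pe$p) & pe$p >= 0 & pe$p <= 1),
                label = lrn)
  }
  pe_rf <- crossfit_propensity(d, A1 ~ X1,
                               learner = learner_spec("random_forest",
                                                      ntree = 50),
                               folds = 2, seed = 3)
  expect_true(all(pe_rf$p >= 0 & pe_rf$p <= 1))
})

test_that("SuperLearner weights form a simplex and a single candidate gets
           weight one", {
  d <- make_logistic_data(200, seed = 12)
  sl1 <- superlearner_fit(d["X1"], d$A1,
                          candidates = list(learner_spec("logit")),
                          cv_folds = 5, seed = 1)
  expect_equal(unname(sl1$weights), 1)
  sl2 <- superlearner_fit(d["X1"], d$A1,
                          candidates = list(learner_spec("logit"),
                                            constant_learner(),
                                            learner_spec("logit_int")),
                          cv_folds = 5, seed = 1)
  expect_true(all(sl2$weights >= 0))
  expect_equal(sum(sl2$weights), 1, tolerance = 1e-12)
})

test_that("SuperLearner upweights the correct model and its risk is near the
           best candidate's", {
  d <- make_logistic_data(2000, seed = 15)
  sl <- superlearner_fit(d["X1"], d$A1,
                         candidates = list(constant_learner(0.5),
                                           learner_spec("logit")),
                         cv_folds = 10, seed = 2)
  expect_gte(unname(sl$weights["logit"]), 0.9)
  ## held-out squared-error dominance
  d_new <- make_logistic_data(2000, seed = 16)
  p_ens <- predict(sl, d_new["X1"])
  risk_ens <- mean((p_ens - d_new$A1)^2)
  risk_const <- mean((0.5 - d_new$A1)^2)
  g <- glm(A1 ~ X1, binomial, d)
  risk_logit <- mean((predict(g, d_new, type = "response") - d_new$A1)^2)
  expect_lte(risk_ens, min(risk_const, risk_logit) + 0.01)
})

test_that("a failing candidate is dropped with a warning; all failing is an
           error", {
  d <- make_logistic_data(200, seed = 18)
  broken <- learner_spec(list(name = "broken",
                              fit = function(x, y) stop("no fit"),
                              predict = function(m, nx) NULL))
  expect_warning(
    sl <- superlearner_fit(d["X1"], d$A1,
                           candidates = list(broken,
                                             learner_spec("logit")),
                           cv_folds = 5, seed = 1),
    "dropping candidate")
  expect_equal(sl$candidates, "logit")
  expect_error(
    suppressWarnings(
      superlearner_fit(d["X1"], d$A1, candidates = list(broken),
                       cv_folds = 5, seed = 1)),
    "all SuperLearner candidates failed")
})
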