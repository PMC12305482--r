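test_that("the subsample grid is floor(q^j n), starts at n, and guards its
           lower end", {
  g <- m_grid(300, q = 0.95, K_grid = 14)
  expect_equal(g[1], 300)
  expect_equal(g[length(g)], 146)          # ~ n/2
  expect_true(all(diff(g) < 0))            # strictly decreasing after dedup
  expect_equal(as.integer(g), as.integer(floor(0.95^attr(g, "j") * 300)))
  ## duplicates removed preserving order
  g2 <- m_grid(60, q = 0.99, K_grid = 10)
  expect_false(any(duplicated(g2)))
  expect_equal(g2[1], 60)
  ## any grid value below 2 is an error advising a smaller K_grid
  expect_error(m_grid(10, q = 0.5, K_grid = 4), "K_grid")
  expect_error(m_grid(1), "at least 2")
})

test_that("bootstrap deviations are reproducible, and degenerate estimators
           give unit-step ECDFs", {
  set.seed(30)
  d <- data.frame(x = rnorm(80))
  cfg <- mn_boot_config(B = 20, K_grid = 4, seed = 77)
  est <- function(dd) c(mu = mean(dd$x))
  e1 <- bootstrap_ecdfs(d, est, cfg)
  e2 <- bootstrap_ecdfs(d, est, cfg)
  expect_identical(e1$deviations, e2$deviations)
  ## constant estimator: every deviation is exactly zero
  ec <- bootstrap_ecdfs(d, function(dd) c(k = 3.14), cfg)
  expect_true(all(vapply(ec$deviations,
                         function(M) all(M == 0), logical(1))))
})

test_that("sqrt-m-scaled deviations of a sample mean follow the CLT at the
           full-sample grid point", {
  set.seed(31)
  d <- data.frame(x = rnorm(400))
  cfg <- mn_boot_config(B = 1000, K_grid = 2, seed = 5)
  ec <- bootstrap_ecdfs(d, function(dd) c(mu = mean(dd$x)), cfg)
  dev <- ec$deviations[[1]][, "mu"]        # sqrt(n) (mean_b - mean)
  ks <- suppressWarnings(
    ks.test(dev, pnorm, sd = sd(d$x))$statistic)
  expect_lt(unname(ks), 0.06)
})

test_that("stability selection minimises the successive Kolmogorov distance
           with ties toward larger m", {
  set.seed(32)
  base <- rnorm(200)
  fake <- function(devs) {
    structure(list(psi_hat = c(p = 0), m = seq(100, by = -10,
                                               length.out = length(devs)),
                   deviations = lapply(devs, function(v)
                     matrix(v, ncol = 1, dimnames = list(NULL, "p"))),
                   config = mn_boot_config(B = 2)),
              class = "mn_ecdfs")
  }
  ## all ECDFs identical -> D = 0 everywhere -> first index (largest m)
  expect_equal(as.integer(select_m(fake(rep(list(base), 6)))), 1L)
  ## distinct until the 5th, identical afterwards -> stabilisation at 5
  devs <- c(lapply(4:1, function(k) base + k), rep(list(base), 4))
  expect_equal(as.integer(select_m(fake(devs))), 5L)
  ## the literal argmax alternative picks the least stable neighbour
  expect_equal(as.integer(select_m(fake(devs), select = "argmax")), 1L)
})

test_that("the rate regression recovers closed-form exponents and rejects
           degenerate input", {
  m <- m_grid(400)
  expect_equal(estimate_rate(2.7 / m, m), 0.5, tolerance = 1e-12)
  expect_equal(estimate_rate(rep(0.3, length(m)), m), 0, tolerance = 1e-12)
  ## zero-variance points are excluded; fewer than two left is an error
  v <- c(1 / m[1:2], rep(0, length(m) - 2))
  expect_equal(estimate_rate(v, m), 0.5, tolerance = 1e-12)
  expect_error(estimate_rate(c(1, rep(0, length(m) - 1)), m),
               "at least 2")
  ## CLT oracle: bootstrap variance of a sample mean scales as 1/m
  set.seed(33)
  d <- data.frame(x = rnorm(400))
  ec <- bootstrap_ecdfs(d, function(dd) c(mu = mean(dd$x)),
                        mn_boot_config(B = 400, seed = 8))
  v_hat <- vapply(ec$estimates, function(E) var(E[, "mu"]), numeric(1))
  expect_lt(abs(estimate_rate(v_hat, ec$m) - 0.5), 0.1)
})

test_that("the rescaled interval reduces to the normal CI at m = n and
           scales as (m/n)^rate", {
  ci <- mn_ci(2, m_star = 400, n = 400, rate_exponent = 0.5,
              variance = 0.04, level = 0.95)
  expect_equal(unname(ci), 2 + c(-1, 1) * qnorm(0.975) * 0.2,
               tolerance = 1e-12)
  ci4 <- mn_ci(2, m_star = 100, n = 400, rate_exponent = 0.5,
               variance = 0.04, level = 0.95)
  expect_equal(diff(unname(ci4)), diff(unname(ci)) / 2, tolerance = 1e-12)
})

test_that("failures beyond the tolerated share stop the bootstrap with a
           count", {
  set.seed(34)
  d <- data.frame(x = rnorm(50))
  flaky <- function(dd) {
    if (runif(1) < 0.4) stop("refit failed")
    c(mu = mean(dd$x))
  }
  expect_error(
    bootstrap_ecdfs(d, flaky, mn_boot_config(B = 40, K_grid = 2,
                                             seed = 9)),
    "replicates failed")
})

test_that("the percentile bootstrap uses type-7 quantiles and collapses for
           constant estimators", {
  set.seed(35)
  d <- data.frame(x = rnorm(120))
  pb <- percentile_boot(d, function(dd) c(mu = mean(dd$x)), B = 1000,
                        level = 0.95, seed = 44)
  x <- sort(pb$estimates[, "mu"])
  ## hand-computed type-7 interpolation at probs 0.025 / 0.975
  h_lo <- (length(x) - 1) * 0.025 + 1
  h_hi <- (length(x) - 1) * 0.975 + 1
  lo <- x[floor(h_lo)] + (h_lo - floor(h_lo)) *
    (x[ceiling(h_lo)] - x[floor(h_lo)])
  hi <- x[floor(h_hi)] + (h_hi - floor(h_hi)) *
    (x[ceiling(h_hi)] - x[floor(h_hi)])
  expect_equal(pb$summary$lower, lo, tolerance = 1e-12)
  expect_equal(pb$summary$upper, hi, tolerance = 1e-12)
  pc <- percentile_boot(d, function(dd) c(k = 1.5), B = 50, seed = 1)
  expect_equal(pc$summary$lower, 1.5)
  expect_equal(pc$summary$upper, 1.5)
})

test_that("mn_boot assembles selection, rate and interval per parameter", {
  set.seed(36)
  d <- data.frame(x = rnorm(200, mean = 1), y = rnorm(200))
  est <- function(dd) c(mx = mean(dd$x), my = mean(dd$y))
  res <- mn_boot(d, est, mn_boot_config(B = 60, K_grid = 6, seed = 13))
  s <- res$summary
  expect_equal(s$parameter, c("mx", "my"))
  expect_true(all(s$m %in% m_grid(200, K_grid = 6)))
  expect_true(all(s$lower <= s$estimate & s$estimate <= s$upper))
  expect_true(all(is.finite(s$rate_exponent)))
})
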