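#' Run replicate simulations of the dWOLS pipeline
#'
#' For each replicate, generates a dataset from the scenario (replicate
#' seeds are `seed + r`), then fits dWOLS once per method on that shared
#' dataset (a paired design, which cancels Monte-Carlo noise out of the
#' RMSE ratios), recording the four blip estimates.  A method failure in a
#' replicate is logged and excluded with a count; a method failing in more
#' than 20% of replicates is reported as unavailable for the scenario.
#'
#' @param config A [scenario_config()]; its `seed` is ignored in favour of
#'   the per-replicate seeds.
#' @param methods Named list of propensity learners (names or
#'   [learner_spec()]s).  An unnamed character vector is named after
#'   itself.  The special name `"qlearn"` runs unweighted Q-learning.
#' @param R Number of replicates (>= 2).
#' @param seed Master seed.
#' @param folds Cross-fitting folds passed to [dwols()].
#' @param specs Analysis models; default [scenario_specs()] for the study.
#' @return Object of class `"dwols_replicates"`: `estimates` (array
#'   replicate x parameter x method), `truth`, `failures` (count per
#'   method), `unavailable` (logical per method), `config`, `seed`.
#' @export
run_replicates <- function(config, methods = "logit", R = 200L, seed = 1L,
                           folds = 2L, specs = scenario_specs(config$study)) {
  if (R < 2) stop("'R' must be at least 2", call. = FALSE)
  if (is.character(methods)) {
    methods <- stats::setNames(as.list(methods), methods)
  }
  if (is.null(names(methods)) || any(names(methods) == "")) {
    stop("'methods' must be named", call. = FALSE)
  }
  mnames <- names(methods)
  pars <- c("psi10", "psi11", "psi20", "psi21")
  est <- array(NA_real_, c(R, length(pars), length(methods)),
               dimnames = list(NULL, pars, mnames))
  fails <- stats::setNames(integer(length(methods)), mnames)
  for (r in seq_len(R)) {
    cfg <- config
    cfg$seed <- seed + r
    sc <- generate_scenario(cfg)
    for (mi in seq_along(methods)) {
      set.seed(jb_seed(seed + r, mi, 0L))
      fit <- tryCatch({
        if (identical(methods[[mi]], "qlearn")) {
          dwols(specs$outcome, specs$blip.mod, specs$treat.mod,
                specs$tf.mod, data = sc$data, method = "qlearn")
        } else {
          dwols(specs$outcome, specs$blip.mod, specs$treat.mod,
                specs$tf.mod, data = sc$data, learner = methods[[mi]],
                folds = folds)
        }
      }, error = function(e) NULL)
      if (is.null(fit)) {
        fails[mi] <- fails[mi] + 1L
      } else {
        est[r, , mi] <- coef(fit)[pars]
      }
    }
  }
  structure(list(estimates = est, truth = true_blip_values(config),
                 failures = fails, unavailable = fails > 0.2 * R,
                 config = config, seed = seed, R = R),
            class = "dwols_replicates")
}

#' Performance metrics over simulation replicates
#'
#' Computes, per method and blip parameter: bias (mean estimate minus true
#' value), the standard deviation of the estimates (divisor R - 1), RMSE
#' \eqn{\sqrt{\mathrm{bias}^2 + \mathrm{variance}}}, the ratio of that RMSE
#' to the baseline method's, and the Monte Carlo errors of the bias
#' (\eqn{\mathrm{SD}/\sqrt{R}}) and of the SD
#' (\eqn{\mathrm{SD}/\sqrt{2(R-1)}}).  A pure function of the replicate
#' array: permuting replicates changes nothing.
#'
#' @param raw A [run_replicates()] result, or an array replicate x
#'   parameter x method.
#' @param truth True parameter values (taken from `raw` when available).
#' @param baseline Method name for the RMSE ratio denominator (default
#'   `"logit"` when present, else the first method); the baseline's own
#'   ratio is exactly 1.
#' @return Data frame of class `"dwols_metrics"`, one row per method x
#'   parameter, with a `replicates` column counting the non-failed
#'   replicates used.
#' @export
summarize_replicates <- function(raw, truth = NULL, baseline = NULL) {
  est <- if (inherits(raw, "dwols_replicates")) raw$estimates else raw
  if (is.null(truth) && inherits(raw, "dwols_replicates")) {
    truth <- raw$truth
  }
  pars <- dimnames(est)[[2]]
  methods <- dimnames(est)[[3]]
  truth <- rep_len(truth, length(pars))
  baseline <- baseline %||%
    (if ("logit" %in% methods) "logit" else methods[1L])
  rows <- list()
  for (m in methods) {
    for (pi in seq_along(pars)) {
      e <- est[, pi, m]
      e <- e[!is.na(e)]
      Rm <- length(e)
      if (Rm < 2L) {
        rows[[length(rows) + 1L]] <- data.frame(
          method = m, parameter = pars[pi], bias = NA_real_, sd = NA_real_,
          rmse = NA_real_, rmse_ratio = NA_real_, mc_bias = NA_real_,
          mc_sd = NA_real_, replicates = Rm)
        next
      }
      bias <- mean(e) - truth[pi]
      s <- stats::sd(e)
      rows[[length(rows) + 1L]] <- data.frame(
        method = m, parameter = pars[pi], bias = bias, sd = s,
        rmse = sqrt(bias^2 + s^2), rmse_ratio = NA_real_,
        mc_bias = s / sqrt(Rm), mc_sd = s / sqrt(2 * (Rm - 1)),
        replicates = Rm)
    }
  }
  out <- do.call(rbind, rows)
  base_rmse <- out$rmse[out$method == baseline]
  names(base_rmse) <- out$parameter[out$method == baseline]
  out$rmse_ratio <- out$rmse / base_rmse[out$parameter]
  class(out) <- c("dwols_metrics", "data.frame")
  out
}

#' Coverage study for m-out-of-n confidence intervals
#'
#' Per replicate: generate a scenario dataset, run the adaptive m-out-of-n
#' bootstrap around the full dWOLS pipeline, and record whether each
#' parameter's interval covers its true value.  Reports the coverage
#' proportion with its binomial Monte Carlo error
#' \eqn{\sqrt{c(1-c)/R}}, together with the point-estimate bias, the mean
#' selected subsample size, and the mean estimated convergence-rate
#' exponent.  Replicates whose bootstrap fails are excluded with a count.
#'
#' @param config A [scenario_config()].
#' @param method Propensity learner for [dwols()].
#' @param R Number of replicates (>= 50 recommended).
#' @param boot_config An [mn_boot_config()].
#' @param seed Master seed; replicate r uses `seed + r` for data generation
#'   and a derived seed for the bootstrap.
#' @param folds Cross-fitting folds.
#' @param specs Analysis models; default [scenario_specs()].
#' @return Object of class `"dwols_coverage"`: `summary` (per parameter:
#'   coverage, its MC error, bias of the point estimates, mean selected
#'   `m`, mean rate exponent), `covered` (replicate x parameter logical),
#'   `failures`, `R_effective`.
#' @export
coverage_study <- function(config, method = "logit", R = 100L,
                           boot_config = mn_boot_config(), seed = 1L,
                           folds = 2L,
                           specs = scenario_specs(config$study)) {
  pars <- c("psi10", "psi11", "psi20", "psi21")
  truth <- true_blip_values(config)
  covered <- matrix(NA, R, length(pars), dimnames = list(NULL, pars))
  msel <- rate <- matrix(NA_real_, R, length(pars),
                         dimnames = list(NULL, pars))
  point <- matrix(NA_real_, R, length(pars), dimnames = list(NULL, pars))
  failures <- 0L
  for (r in seq_len(R)) {
    cfg <- config
    cfg$seed <- seed + r
    sc <- generate_scenario(cfg)
    est <- function(d) {
      fit <- dwols(specs$outcome, specs$blip.mod, specs$treat.mod,
                   specs$tf.mod, data = d, learner = method, folds = folds)
      coef(fit)
    }
    bc <- boot_config
    bc$seed <- jb_seed(seed + r, 99L, 0L)
    res <- tryCatch(mn_boot(sc$data, est, bc), error = function(e) NULL)
    if (is.null(res)) {
      failures <- failures + 1L
      next
    }
    s <- res$summary
    idx <- match(pars, s$parameter)
    covered[r, ] <- s$lower[idx] <= truth & truth <= s$upper[idx]
    msel[r, ] <- s$m[idx]
    rate[r, ] <- s$rate_exponent[idx]
    point[r, ] <- s$estimate[idx]
  }
  Re <- colSums(!is.na(covered))
  cov <- colMeans(covered, na.rm = TRUE)
  structure(list(
    summary = data.frame(
      parameter = pars,
      coverage = unname(cov),
      mc_coverage = unname(sqrt(cov * (1 - cov) / pmax(Re, 1))),
      bias = unname(colMeans(point, na.rm = TRUE) - truth),
      mean_m = unname(colMeans(msel, na.rm = TRUE)),
      mean_rate = unname(colMeans(rate, na.rm = TRUE))),
    covered = covered, failures = failures, R_effective = Re,
    config = config, boot_config = boot_config),
    class = "dwols_coverage")
}

#' @export
print.dwols_coverage <- function(x, digits = 3, ...) {
  cat("m-out-of-n coverage study,", max(x$R_effective), "replicates",
      if (x$failures > 0) paste0("(", x$failures, " failed)"), "\n")
  s <- x$summary
  s[, -1] <- round(s[, -1], digits)
  print(s, row.names = FALSE)
  invisible(x)
}
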