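#' Extract blip coefficients from a dwols fit
#'
#' Returns all blip coefficients as a flat named vector.  Names follow the
#' convention `psi<t><j>`: stage index followed by the position of the term
#' within the stage's blip model (0 = intercept), so the canonical two-stage
#' fit with one tailoring variable per stage yields `psi10`, `psi11`,
#' `psi20`, `psi21`.  Term labels are kept in the `"terms"` attribute.
#'
#' @param object A fitted [dwols()] object.
#' @param ... Unused.
#' @return Named numeric vector of blip coefficients.
#' @export
coef.dwols <- function(object, ...) {
  out <- numeric(0)
  terms <- character(0)
  for (t in seq_len(object$n_stages)) {
    psi <- object$psi[[t]]
    nm <- paste0("psi", t, seq_along(psi) - 1L)
    terms <- c(terms, paste0("stage ", t, ": ", names(psi)))
    names(psi) <- nm
    out <- c(out, psi)
  }
  attr(out, "terms") <- terms
  out
}

#' @export
print.dwols <- function(x, digits = 4, ...) {
  cat("Dynamic", if (x$method == "qlearn") "(unweighted / Q-learning)"
      else "weighted", "OLS fit,", x$n_stages, "stages,", x$n, "subjects\n")
  if (x$method == "dwols") {
    lrn <- if (is.character(x$learner)) x$learner else
      if (!is.null(x$learner$name)) x$learner$name else "custom"
    cat("Propensity learner:", lrn, "with", x$folds, "cross-fitting fold(s)\n")
  }
  for (t in seq_len(x$n_stages)) {
    cat("\nStage", t, "blip (psi):\n")
    print(round(x$psi[[t]], digits))
  }
  invisible(x)
}

#' @export
summary.dwols <- function(object, ...) {
  tabs <- lapply(seq_len(object$n_stages), function(t) {
    s <- object$stages[[t]]
    data.frame(term = names(s$psi), estimate = unname(s$psi))
  })
  rec <- vapply(seq_len(object$n_stages), function(t) {
    opt <- object$stages[[t]]$opt
    c(treat = mean(opt == 1, na.rm = TRUE),
      withhold = mean(opt == 0, na.rm = TRUE),
      undefined = mean(is.na(opt)))
  }, numeric(3))
  structure(list(fit = object, psi_tables = tabs, rule_shares = rec,
                 low_weight_share = object$diagnostics$low_weight_share),
            class = "summary.dwols")
}

#' @export
print.summary.dwols <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("\nRecommended-action shares (rows: treat / withhold / undefined):\n")
  colnames(x$rule_shares) <- paste("stage", seq_len(ncol(x$rule_shares)))
  print(round(x$rule_shares, 3))
  lw <- x$low_weight_share
  if (x$fit$method == "dwols" && any(lw > 0.05)) {
    cat("\nNote: share of balancing weights < 0.01 is",
        paste(sprintf("%.1f%%", 100 * lw), collapse = ", "),
        "per stage —\npossible practical positivity violation.\n")
  }
  invisible(x)
}

#' Recommended actions or blip values for new subjects
#'
#' @param object A fitted [dwols()] object.
#' @param newdata Data frame of covariates; defaults to the training data.
#' @param stage Stage index.
#' @param type `"action"` for the optimal-rule recommendation (1/0/`NA`
#'   undefined), `"blip"` for the fitted blip values.
#' @param ... Unused.
#' @return Integer action vector or numeric blip vector.
#' @export
predict.dwols <- function(object, newdata = NULL, stage = 1L,
                          type = c("action", "blip"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$data
  Hb <- stats::model.matrix(object$blip.mod[[stage]], newdata)
  r <- optimal_rule(object$psi[[stage]], Hb)
  if (type == "action") r else attr(r, "blip")
}

#' @export
residuals.dwols <- function(object, stage = NULL, ...) {
  if (is.null(stage)) {
    lapply(object$stages, `[[`, "residuals")
  } else {
    object$stages[[stage]]$residuals
  }
}

#' Propensity-overlap diagnostic plot
#'
#' Histograms of the cross-fitted treatment probabilities by observed
#' treatment group, one panel per stage.  Piled-up mass near 0 or 1 signals
#' practical positivity violations (and many near-zero balancing weights).
#'
#' @param x A fitted [dwols()] object (method `"dwols"`).
#' @param ... Passed to [graphics::hist()].
#' @export
plot.dwols <- function(x, ...) {
  if (x$method != "dwols") {
    stop("no propensities to plot for a Q-learning fit", call. = FALSE)
  }
  op <- graphics::par(mfrow = c(1, x$n_stages))
  on.exit(graphics::par(op))
  for (t in seq_len(x$n_stages)) {
    p <- x$propensity[[t]]$p
    a <- x$data[[x$treatments[t]]]
    brk <- seq(0, 1, by = 0.05)
    h1 <- graphics::hist(p[a == 1], breaks = brk, plot = FALSE)
    h0 <- graphics::hist(p[a == 0], breaks = brk, plot = FALSE)
    ylim <- c(0, max(h1$counts, h0$counts))
    graphics::plot(h1, col = grDevices::adjustcolor("steelblue", 0.6),
                   ylim = ylim, xlab = "P(A = 1 | H)",
                   main = paste("Stage", t), ...)
    graphics::plot(h0, col = grDevices::adjustcolor("orange", 0.6),
                   add = TRUE)
    graphics::legend("topright", fill = c("steelblue", "orange"),
                     legend = c("treated", "untreated"), bty = "n")
  }
  invisible(x)
}

#' Bootstrap confidence intervals for blip parameters
#'
#' Refits the entire dWOLS pipeline (including cross-fitting and learner
#' refits) on resamples of whole subject trajectories.  `method = "mn"` uses
#' the adaptive m-out-of-n bootstrap ([mn_boot()]), appropriate when the
#' propensities are machine-learned and the ordinary bootstrap may be
#' inconsistent; `method = "percentile"` is the standard n-out-of-n
#' percentile bootstrap.
#'
#' @param object A fitted [dwols()] object.
#' @param parm Parameters to report (names as in [coef.dwols()]); default all.
#' @param level Confidence level.
#' @param method `"mn"` or `"percentile"`.
#' @param config An [mn_boot_config()] for `method = "mn"`.
#' @param B Replicates for the percentile bootstrap.
#' @param seed Seed for the resampling.
#' @param ... Unused.
#' @return Matrix with columns `lower` and `upper`, one row per parameter.
#' @export
confint.dwols <- function(object, parm = NULL, level = 0.95,
                          method = c("mn", "percentile"),
                          config = mn_boot_config(level = level),
                          B = 1000L, seed = NULL, ...) {
  method <- match.arg(method)
  est <- dwols_estimator(object)
  if (method == "mn") {
    config$level <- level
    if (!is.null(seed)) config$seed <- seed
    res <- mn_boot(object$data, est, config)
    ci <- as.matrix(res$summary[, c("lower", "upper")])
    rownames(ci) <- res$summary$parameter
  } else {
    res <- percentile_boot(object$data, est, B = B, level = level,
                           seed = seed)
    ci <- as.matrix(res$summary[, c("lower", "upper")])
    rownames(ci) <- res$summary$parameter
  }
  if (!is.null(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Estimator closure for bootstrap refitting
#'
#' Wraps a fitted [dwols()] object into a function of a data frame that
#' refits the complete pipeline (propensity cross-fitting included) and
#' returns the flat blip coefficient vector — the estimator the bootstrap
#' machinery resamples.
#'
#' @param object A fitted [dwols()] object.
#' @return `function(data)` returning a named numeric vector.
#' @export
dwols_estimator <- function(object) {
  force(object)
  function(d) {
    fit <- dwols(object$outcome, object$blip.mod, object$treat.mod,
                 object$tf.mod, data = d, method = object$method,
                 learner = object$learner, folds = object$folds)
    coef(fit)
  }
}
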