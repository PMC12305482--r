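#' Configuration of a synthetic two-stage scenario
#'
#' Describes one cell of the five-study simulation design.  The studies
#' vary which generating model is simple and which is complex:
#'
#' * Study 1 — outcome model simple, treatment model at `complexity`;
#' * Study 2 — treatment model simple, outcome model at `complexity`;
#' * Study 3 — both at `complexity`;
#' * Study 4 — as Study 3, with the treatment linear predictor scaled up
#'   (default factor 4) to induce practical positivity violations;
#' * Study 5 — as Study 4, with 10 covariates (the extra ones are pure
#'   noise entering the analysis models only).
#'
#' The complexity ladder is strictly nested: `"simple"` uses linear terms
#' only, `"medium"` adds quadratic terms, `"complex"` adds absolute-value
#' and sine terms on top.  Zeroing the added coefficients (via `overrides`)
#' reduces each tier exactly to the one below.
#'
#' @param study Integer 1-5.
#' @param complexity `"simple"`, `"medium"`, or `"complex"`.
#' @param n Sample size (>= 50).
#' @param seed Integer seed; generation is deterministic given the config.
#' @param psi True blip parameters `c(psi10, psi11, psi20, psi21)`: stage-1
#'   intercept and X1 coefficient, stage-2 intercept and X2 coefficient.
#' @param overrides Optional nested list of coefficient overrides, merged
#'   into the documented defaults (see [scenario_coefs()]).  This is the
#'   hook for dropping in alternative generating equations verbatim.
#' @return List of class `"scenario_config"`.
#' @export
scenario_config <- function(study = 1L,
                            complexity = c("simple", "medium", "complex"),
                            n = 300L, seed = NULL,
                            psi = c(1, -1, 1, -1), overrides = NULL) {
  complexity <- match.arg(complexity)
  study <- as.integer(study)
  if (!study %in% 1:5) stop("'study' must be 1-5", call. = FALSE)
  if (n < 50) stop("'n' must be at least 50", call. = FALSE)
  if (length(psi) != 4L || anyNA(psi) || any(!is.finite(psi))) {
    stop("'psi' must be 4 finite values", call. = FALSE)
  }
  structure(list(study = study, complexity = complexity, n = as.integer(n),
                 seed = seed, psi = psi, overrides = overrides),
            class = "scenario_config")
}

#' Default generating coefficients for a scenario
#'
#' Returns the full coefficient map used by [generate_scenario()], with any
#' `overrides` from the config merged in (nested [utils::modifyList()]
#' semantics).  Components:
#'
#' * `treat1`, `treat2` — treatment linear predictors: `intercept`,
#'   `linear`, `quad`, `abs`, `sin` coefficient vectors named by variable;
#'   the sine frequency is `sin_freq`.  `treat_scale` multiplies the whole
#'   predictor (4 in Studies 4-5, else 1).
#' * `outcome` — same structure for the treatment-free outcome mean.
#' * `x2` — the stage-2 covariate equation `X2 = intercept + X1 * <X1> +
#'   A1 * <A1> + N(0, sd)`.  The `A1` coefficient ships as 0 so that the
#'   configured `psi` are exactly the estimands at both stages; setting it
#'   non-zero is supported for sensitivity but shifts the stage-1 target.
#' * `noise_sd` — outcome noise standard deviation.
#'
#' @param config A [scenario_config()].
#' @return Nested list of coefficients.
#' @export
scenario_coefs <- function(config) {
  co <- list(
    treat1 = list(intercept = 0,
                  linear = c(X1 = 0.5),
                  quad = c(X1 = -0.5),
                  abs = c(X1 = 0.5),
                  sin = c(X1 = 0.5)),
    treat2 = list(intercept = 0,
                  linear = c(X1 = 0.5, X2 = 0.5, A1 = 0.5),
                  quad = c(X1 = -0.5, X2 = -0.5),
                  abs = c(X1 = 0.5, X2 = 0.5),
                  sin = c(X1 = 0.5, X2 = 0.5)),
    outcome = list(intercept = 0,
                   linear = c(X1 = 0.5, X2 = 0.5),
                   quad = c(X1 = -0.5, X2 = -0.5),
                   abs = c(X1 = 0.5, X2 = 0.5),
                   sin = c(X1 = 0.5, X2 = 0.5)),
    x2 = list(intercept = 0, X1 = 0.5, A1 = 0, sd = 1),
    sin_freq = 2,
    treat_scale = if (config$study >= 4L) 4 else 1,
    noise_sd = 1)
  if (!is.null(config$overrides)) {
    co <- utils::modifyList(co, config$overrides)
  }
  co
}

## complexity ladder: linear, + quadratic, + absolute value and sine
ladder <- function(vals, block, complexity, freq) {
  out <- rep(block$intercept, nrow(vals))
  for (v in names(block$linear)) {
    out <- out + block$linear[[v]] * vals[[v]]
  }
  if (complexity %in% c("medium", "complex")) {
    for (v in names(block$quad)) out <- out + block$quad[[v]] * vals[[v]]^2
  }
  if (complexity == "complex") {
    for (v in names(block$abs)) out <- out + block$abs[[v]] * abs(vals[[v]])
    for (v in names(block$sin)) {
      out <- out + block$sin[[v]] * sin(freq * vals[[v]])
    }
  }
  out
}

#' Generate a synthetic two-stage trajectory dataset
#'
#' Draws, per subject: \eqn{X_1 \sim N(0,1)}; \eqn{A_1 \sim
#' \mathrm{Bern}(\mathrm{expit}(f_1(X_1)))}; \eqn{X_2 = 0.5 X_1 + N(0,1)};
#' \eqn{A_2 \sim \mathrm{Bern}(\mathrm{expit}(f_2(X_1, X_2, A_1)))}; and
#' \eqn{Y = g(X_1, X_2) + A_1(\psi_{10} + \psi_{11} X_1) + A_2(\psi_{20} +
#' \psi_{21} X_2) + N(0, 1)}, where the complexity of \eqn{f} and \eqn{g}
#' follows the study design (see [scenario_config()]).  In Studies 4-5 the
#' treatment predictors are scaled up so the generated probabilities pile
#' near 0/1; Study 5 adds eight pure-noise covariates `W11..W14`,
#' `W21..W24`.
#'
#' By construction the stage-2 treatment effect given history is exactly
#' \eqn{\psi_{20} + \psi_{21} X_2}, and (with the default `x2` equation,
#' which carries no treatment effect) the stage-1 effect is exactly
#' \eqn{\psi_{10} + \psi_{11} X_1}.
#'
#' @param config A [scenario_config()].
#' @param force Optional named list, e.g. `list(A1 = 1)` or
#'   `list(A2 = 0)`, replacing the treatment draws by fixed values while
#'   leaving every random draw in place — so two calls with the same seed
#'   differing only in `force` are counterfactuals of one another.
#' @return List of class `"dwols_scenario"`: `data` (data frame with
#'   columns `X1`, `X2`, `A1`, `A2`, `Y`, plus `W*` in Study 5), `truth`
#'   (true `psi`, the per-subject generating probabilities `p1`, `p2`, the
#'   treatment-free mean `mu`, the model complexities, and the coefficient
#'   map), and `config`.
#' @examples
#' sc <- generate_scenario(scenario_config(study = 1, n = 300, seed = 7))
#' head(sc$data)
#' @export
generate_scenario <- function(config, force = list()) {
  stopifnot(inherits(config, "scenario_config"))
  co <- scenario_coefs(config)
  tc <- if (config$study == 2L) "simple" else config$complexity
  oc <- if (config$study == 1L) "simple" else config$complexity
  n <- config$n
  if (!is.null(config$seed)) set.seed(config$seed)

  X1 <- stats::rnorm(n)
  W1 <- if (config$study == 5L) {
    matrix(stats::rnorm(n * 4L), n, 4L,
           dimnames = list(NULL, paste0("W1", 1:4)))
  }
  f1 <- co$treat_scale *
    ladder(data.frame(X1 = X1), co$treat1, tc, co$sin_freq)
  p1 <- stats::plogis(f1)
  A1 <- stats::rbinom(n, 1L, p1)
  if (!is.null(force$A1)) A1 <- rep_len(force$A1, n)

  X2 <- co$x2$intercept + co$x2$X1 * X1 + co$x2$A1 * A1 +
    stats::rnorm(n, sd = co$x2$sd)
  W2 <- if (config$study == 5L) {
    matrix(stats::rnorm(n * 4L), n, 4L,
           dimnames = list(NULL, paste0("W2", 1:4)))
  }
  f2 <- co$treat_scale *
    ladder(data.frame(X1 = X1, X2 = X2, A1 = A1), co$treat2, tc,
           co$sin_freq)
  p2 <- stats::plogis(f2)
  A2 <- stats::rbinom(n, 1L, p2)
  if (!is.null(force$A2)) A2 <- rep_len(force$A2, n)

  mu <- ladder(data.frame(X1 = X1, X2 = X2), co$outcome, oc, co$sin_freq)
  psi <- config$psi
  Y <- mu + A1 * (psi[1] + psi[2] * X1) + A2 * (psi[3] + psi[4] * X2) +
    stats::rnorm(n, sd = co$noise_sd)

  data <- data.frame(X1 = X1, X2 = X2, A1 = A1, A2 = A2, Y = Y)
  if (config$study == 5L) data <- cbind(data, W1, W2)
  structure(list(
    data = data,
    truth = list(psi = psi, p1 = p1, p2 = p2, mu = mu,
                 treat_complexity = tc, outcome_complexity = oc,
                 positivity_stress = config$study >= 4L, coefs = co),
    config = config),
    class = "dwols_scenario")
}

#' True blip parameters of a scenario
#'
#' The generating blip coefficients used by [generate_scenario()]; the
#' harness measures bias against exactly these.  A `psi` supplied in the
#' config (or via overrides) is returned verbatim.
#'
#' @param config A [scenario_config()].
#' @return Named numeric vector `c(psi10, psi11, psi20, psi21)`.
#' @export
true_blip_values <- function(config) {
  stats::setNames(config$psi, c("psi10", "psi11", "psi20", "psi21"))
}

#' Analysis-model specifications for the simulation studies
#'
#' The models fitted to the simulated data: stage-1 treatment modelled on
#' `X1`; stage-2 treatment on `X1`, `X2`, `A1`; stage-2 outcome model with
#' main terms `X1`, `X2`, `A1`, `A2` and the two-way interactions
#' `A1:X1`, `A1:X2`, `A2:X2`; stage-1 outcome model with `A1`, `X1` and
#' their interaction.  (The `A2` terms are the stage-2 blip, the `A1`
#' terms at stage 1 the stage-1 blip.)  In Study 5 the noise covariates
#' enter the treatment models and the treatment-free parts as main terms.
#'
#' @param study Integer 1-5.
#' @return List with `outcome`, `blip.mod`, `treat.mod`, `tf.mod`, ready to
#'   pass to [dwols()].
#' @export
scenario_specs <- function(study = 1L) {
  if (study == 5L) {
    w1 <- paste0("W1", 1:4)
    w2 <- paste0("W2", 1:4)
    t1 <- stats::reformulate(c("X1", w1), response = "A1")
    t2 <- stats::reformulate(c("X1", "X2", "A1", w1, w2), response = "A2")
    f1 <- stats::reformulate(c("X1", w1))
    f2 <- stats::reformulate(c("X1", "X2", "A1", "A1:X1", "A1:X2", w1, w2))
  } else {
    t1 <- A1 ~ X1
    t2 <- A2 ~ X1 + X2 + A1
    f1 <- ~ X1
    f2 <- ~ X1 + X2 + A1 + A1:X1 + A1:X2
  }
  list(outcome = "Y",
       blip.mod = list(~ X1, ~ X2),
       treat.mod = list(t1, t2),
       tf.mod = list(f1, f2))
}
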