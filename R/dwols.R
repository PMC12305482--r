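#' Dynamic weighted ordinary least squares for optimal adaptive treatment
#' strategies
#'
#' Fits the parameters of stagewise linear blip functions by backward
#' recursion.  At the final stage \eqn{T} the outcome is regressed on the
#' treatment-free terms plus treatment-by-blip interactions,
#' \eqn{Q_t(h_t, a_t) = \beta_t^\top h_t + \psi_t^\top h_t^{\psi} a_t},
#' using weighted least squares with balancing weights
#' \eqn{w_t = |a_t - E[A_t \mid H_t]|}; at earlier stages the response is the
#' pseudo-outcome \eqn{\hat\beta_{t+1}^\top h_{t+1} + \max(0,
#' \hat\psi_{t+1}^\top h_{t+1}^{\psi})}, the fitted value under optimal
#' future treatment.  The estimator is doubly robust: the blip estimates are
#' consistent if, at each stage, either the treatment-probability model or
#' the outcome model is correctly specified.
#'
#' Treatment probabilities are estimated by the requested learner under
#' K-fold cross-fitting (see [crossfit_propensity()]), redrawn at each stage.
#' With `method = "qlearn"` unit weights are used throughout, which is
#' ordinary least-squares Q-learning; the same reduction occurs for any
#' constant propensity, since constant weights cancel in weighted least
#' squares.
#'
#' @param outcome The outcome variable: a character name or a one-sided
#'   formula such as `~ Y`.  Larger values must represent better outcomes.
#' @param blip.mod List of one-sided formulas, one per stage, giving the blip
#'   (treatment-effect-modifier) terms.  An intercept is always included.
#' @param treat.mod List of two-sided formulas, one per stage, whose left-hand
#'   side is the binary stage treatment and whose right-hand side lists the
#'   history variables used to model it, e.g. `A2 ~ X1 + X2 + A1`.
#' @param tf.mod List of one-sided formulas giving the treatment-free model at
#'   each stage.
#' @param data A data frame, one row per subject, with no missing values in
#'   any variable referenced by the models.
#' @param method `"dwols"` (balancing weights) or `"qlearn"` (unit weights,
#'   ordinary least squares).
#' @param learner Propensity learner: a name accepted by [learner_spec()]
#'   (`"logit"`, `"logit_int"`, `"random_forest"`, `"naive_bayes"`, `"svm"`,
#'   `"neural_net"`, `"superlearner"`), a [learner_spec()] object, or a custom
#'   list with `fit` and `predict` functions.
#' @param folds Number of cross-fitting folds `K` (1 = fit and predict on the
#'   full sample, no cross-fitting).
#' @param propensity Optional pre-computed treatment probabilities: a list
#'   with one numeric vector (or one [crossfit_propensity()] result) per
#'   stage.  When supplied, `learner` and `folds` are ignored.
#' @param seed Optional integer seed making the cross-fitting splits (and any
#'   stochastic learner) reproducible.  `NULL` uses the ambient RNG stream.
#' @param tol Rank tolerance passed to the stagewise weighted least squares.
#'
#' @return An object of class `"dwols"` with components `psi` (list of blip
#'   coefficient vectors per stage), `beta` (treatment-free coefficients),
#'   `stages` (per-stage detail: weights, pseudo-outcome used as response,
#'   fitted optimal actions, residuals), `propensity`, and `diagnostics`
#'   (share of balancing weights below 0.01 per stage, a practical-positivity
#'   indicator).  Methods: [coef.dwols()], [predict.dwols()],
#'   [confint.dwols()], `print`, `summary`, `plot`, `residuals`.
#'
#' @examples
#' sc <- generate_scenario(scenario_config(study = 1, n = 300, seed = 1))
#' sp <- scenario_specs(1)
#' fit <- dwols(sp$outcome, sp$blip.mod, sp$treat.mod, sp$tf.mod,
#'              data = sc$data, learner = "logit", folds = 2, seed = 1)
#' coef(fit)
#' @export
dwols <- function(outcome, blip.mod, treat.mod, tf.mod, data,
                  method = c("dwols", "qlearn"),
                  learner = "logit", folds = 2L,
                  propensity = NULL, seed = NULL, tol = 1e-10) {
  method <- match.arg(method)
  yvar <- if (inherits(outcome, "formula")) all.vars(outcome)[1L] else
    as.character(outcome)
  if (!is.list(blip.mod)) blip.mod <- list(blip.mod)
  if (!is.list(treat.mod)) treat.mod <- list(treat.mod)
  if (!is.list(tf.mod)) tf.mod <- list(tf.mod)
  n_stages <- length(blip.mod)
  if (length(treat.mod) != n_stages || length(tf.mod) != n_stages) {
    stop("'blip.mod', 'treat.mod' and 'tf.mod' must have one entry per stage",
         call. = FALSE)
  }
  data <- as.data.frame(data)
  n <- nrow(data)
  avars <- vapply(treat.mod, function(f) all.vars(f)[1L], character(1))

  used <- unique(c(yvar, avars,
                   unlist(lapply(c(blip.mod, treat.mod, tf.mod), all.vars))))
  missing_vars <- setdiff(used, names(data))
  if (length(missing_vars)) {
    stop("variables not found in 'data': ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  }
  na_rows <- which(rowSums(is.na(data[used])) > 0)
  if (length(na_rows)) {
    stop("missing values in rows: ",
         paste(utils::head(na_rows, 10L), collapse = ", "),
         if (length(na_rows) > 10L) " ..." else "", call. = FALSE)
  }
  for (t in seq_len(n_stages)) {
    a <- data[[avars[t]]]
    if (!all(a %in% c(0, 1))) {
      stop("treatment '", avars[t], "' must be coded 0/1", call. = FALSE)
    }
    if (length(unique(a)) < 2L) {
      stop("stage ", t, ": all subjects received the same treatment; ",
           "the blip is unidentified", call. = FALSE)
    }
  }

  if (!is.null(seed)) set.seed(seed)

  ## propensities (stage loop runs backward, mirroring the recursion)
  prop <- vector("list", n_stages)
  if (method == "dwols") {
    if (!is.null(propensity)) {
      if (!is.list(propensity)) propensity <- list(propensity)
      if (length(propensity) != n_stages) {
        stop("'propensity' must supply one element per stage", call. = FALSE)
      }
      for (t in seq_len(n_stages)) {
        pe <- propensity[[t]]
        if (inherits(pe, "propensity_estimate")) {
          prop[[t]] <- pe
        } else {
          p <- as.numeric(pe)
          if (length(p) == 1L) p <- rep(p, n)
          if (length(p) != n) {
            stop("propensity vector at stage ", t,
                 " has wrong length", call. = FALSE)
          }
          prop[[t]] <- structure(
            list(p = p, fold = rep(1L, n), folds = 1L, learner = "supplied",
                 formula = NULL),
            class = "propensity_estimate")
        }
      }
    } else {
      for (t in rev(seq_len(n_stages))) {
        prop[[t]] <- crossfit_propensity(data, treat.mod[[t]],
                                         learner = learner, folds = folds)
      }
    }
  }

  ## backward recursion
  resp <- data[[yvar]]
  stages <- vector("list", n_stages)
  for (t in rev(seq_len(n_stages))) {
    a <- data[[avars[t]]]
    Hb <- stats::model.matrix(blip.mod[[t]], data)
    Hf <- stats::model.matrix(tf.mod[[t]], data)
    blip_names <- ifelse(colnames(Hb) == "(Intercept)", avars[t],
                         paste(avars[t], colnames(Hb), sep = ":"))
    Xd <- cbind(Hf, Hb * a)
    colnames(Xd) <- c(colnames(Hf), blip_names)
    w <- if (method == "qlearn") rep(1, n) else
      compute_weights(prop[[t]]$p, a)
    fs <- tryCatch(
      fit_stage(Xd, resp, w, tol = tol),
      error = function(e) stop("stage ", t, ": ", conditionMessage(e),
                               call. = FALSE))
    kb <- ncol(Hb)
    beta <- fs$coefficients[seq_len(ncol(Hf))]
    psi <- fs$coefficients[ncol(Hf) + seq_len(kb)]
    names(psi) <- colnames(Hb)
    blip_value <- drop(Hb %*% psi)
    stages[[t]] <- list(
      psi = psi, beta = beta, weights = w,
      response = resp,                       # pseudo-outcome used at stage t
      blip = blip_value,
      opt = optimal_rule(psi, Hb),
      residuals = fs$residuals,
      blip_terms = colnames(Hb), tf_terms = colnames(Hf))
    ## pseudo-outcome feeding stage t-1
    resp <- pseudo_outcome(beta, psi, Hf, Hb)
  }

  diag_low <- vapply(stages, function(s) mean(s$weights < 0.01), numeric(1))
  structure(list(
    call = match.call(), n = n, n_stages = n_stages,
    outcome = yvar, treatments = avars,
    blip.mod = blip.mod, treat.mod = treat.mod, tf.mod = tf.mod,
    method = method, learner = learner, folds = folds,
    psi = lapply(stages, `[[`, "psi"),
    beta = lapply(stages, `[[`, "beta"),
    stages = stages, propensity = prop,
    diagnostics = list(low_weight_share = diag_low),
    data = data),
    class = "dwols")
}

#' Pseudo-outcome under optimal continuation
#'
#' Given fitted stage-(t+1) coefficients, returns the stage-t regression
#' response \eqn{\hat\beta^\top h + \max(0, \hat\psi^\top h^{\psi})}: the
#' predicted outcome had the subject received the better of the two
#' treatments at stage t+1.  A negative fitted blip contributes zero (the
#' optimal action is then to withhold).
#'
#' @param beta Treatment-free coefficient vector.
#' @param psi Blip coefficient vector.
#' @param H Treatment-free design matrix (rows = subjects).
#' @param H_blip Blip design matrix.
#' @return Numeric vector, one pseudo-outcome per subject.
#' @export
pseudo_outcome <- function(beta, psi, H, H_blip) {
  drop(as.matrix(H) %*% beta) + pmax(0, drop(as.matrix(H_blip) %*% psi))
}

#' Optimal decision rule implied by blip coefficients
#'
#' Applies the sign rule: treat (1) when \eqn{\hat\psi^\top h > 0}, withhold
#' (0) when \eqn{\hat\psi^\top h < 0}, and `NA` ("undefined") when the fitted
#' blip is exactly zero.  The undefined value is deliberately distinct and is
#' never coerced to either action.
#'
#' @param psi Blip coefficient vector.
#' @param h A blip covariate vector (including the leading 1 for the
#'   intercept) or a matrix with one row per subject.
#' @return Integer vector of recommended actions (1, 0, or `NA` when the rule
#'   is undefined), with the fitted blip values as attribute `"blip"`.
#' @examples
#' optimal_rule(c(1, -2), c(1, 0))    # treat
#' optimal_rule(c(1, -2), c(1, 0.5))  # undefined (NA)
#' @export
optimal_rule <- function(psi, h) {
  h <- if (is.matrix(h)) h else matrix(h, nrow = 1L)
  if (ncol(h) != length(psi)) {
    stop("'psi' and 'h' are not conformable", call. = FALSE)
  }
  b <- drop(h %*% psi)
  out <- ifelse(b > 0, 1L, ifelse(b < 0, 0L, NA_integer_))
  attr(out, "blip") <- b
  out
}
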