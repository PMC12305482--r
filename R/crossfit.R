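#' Cross-fitted treatment-probability estimation
#'
#' Estimates \eqn{E[A_t \mid H_t]} with the requested learner under K-fold
#' cross-fitting: the sample is randomly partitioned into `folds` near-equal
#' parts (sizes differing by at most one) and each subject's probability is
#' predicted by a model trained on the other folds only.  This structural
#' separation of training and prediction prevents the overfitting that can
#' otherwise accentuate practical positivity violations when flexible
#' learners are used.  With `folds = 1` the model is fitted and evaluated on
#' the full sample (no cross-fitting).
#'
#' If a fold ends up containing a single treatment class, the partition is
#' redrawn (at most 10 attempts) before failing with a positivity message.
#'
#' @param data Data frame, one row per subject.
#' @param formula Two-sided formula `A ~ <history terms>` naming the binary
#'   stage treatment and its predictors.
#' @param learner A learner name, [learner_spec()], or custom-learner list.
#' @param folds Number of folds `K` (default 2).
#' @param seed Optional integer seed; `NULL` uses the ambient RNG stream
#'   (deterministic inside a seeded caller).
#' @return An object of class `"propensity_estimate"`: list with `p`
#'   (predicted probabilities), `fold` (fold assignment per subject),
#'   `folds`, `learner` (name), and `formula`.
#' @examples
#' sc <- generate_scenario(scenario_config(study = 1, n = 300, seed = 1))
#' pe <- crossfit_propensity(sc$data, A1 ~ X1, learner = "logit", seed = 1)
#' range(pe$p)
#' @export
crossfit_propensity <- function(data, formula, learner = "logit",
                                folds = 2L, seed = NULL) {
  spec <- as_learner(learner)
  folds <- as.integer(folds)
  if (folds < 1L) stop("'folds' must be >= 1", call. = FALSE)
  avar <- all.vars(formula)[1L]
  a <- data[[avar]]
  if (is.null(a) || anyNA(a) || !all(a %in% c(0, 1))) {
    stop("treatment '", avar, "' must be coded 0/1 with no missing values",
         call. = FALSE)
  }
  rhs <- all.vars(formula)[-1L]
  x <- data[rhs]
  n <- nrow(data)
  if (!is.null(seed)) set.seed(seed)

  if (folds == 1L) {
    p <- fit_learner(spec, x, a)(x)
    return(structure(list(p = p, fold = rep(1L, n), folds = 1L,
                          learner = spec$name, formula = formula),
                     class = "propensity_estimate"))
  }

  fold <- NULL
  for (attempt in seq_len(10L)) {
    cand <- sample(rep_len(seq_len(folds), n))
    counts <- table(factor(cand, levels = seq_len(folds)),
                    factor(a, levels = c(0, 1)))
    if (all(counts > 0L)) { fold <- cand; break }
  }
  if (is.null(fold)) {
    stop("could not build cross-fitting folds with both treatment classes ",
         "in every fold after 10 attempts; the data show a severe ",
         "positivity problem", call. = FALSE)
  }
  p <- numeric(n)
  for (v in seq_len(folds)) {
    tr <- fold != v
    pred <- fit_learner(spec, x[tr, , drop = FALSE], a[tr])
    p[!tr] <- pred(x[!tr, , drop = FALSE])
  }
  structure(list(p = p, fold = fold, folds = folds,
                 learner = spec$name, formula = formula),
            class = "propensity_estimate")
}

#' @export
print.propensity_estimate <- function(x, ...) {
  cat("Cross-fitted propensities:", x$learner, "learner,",
      x$folds, "fold(s),", length(x$p), "subjects\n")
  cat("range:", sprintf("%.4f", min(x$p)), "-", sprintf("%.4f", max(x$p)),
      "  share < 0.05 or > 0.95:",
      sprintf("%.1f%%", 100 * mean(x$p < 0.05 | x$p > 0.95)), "\n")
  invisible(x)
}
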