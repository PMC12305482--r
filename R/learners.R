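#' Specify a treatment-probability learner
#'
#' Constructs a learner specification for [crossfit_propensity()] /
#' [dwols()].  Built-in learners:
#'
#' * `"logit"` — main-terms logistic regression (`stats::glm.fit`).
#' * `"logit_int"` — logistic regression with all pairwise interactions.
#' * `"random_forest"` — [randomForest::randomForest()]; probability =
#'   fraction of trees voting treatment, `ntree` default 500.
#' * `"naive_bayes"` — [e1071::naiveBayes()].
#' * `"svm"` — [e1071::svm()] with Platt-type sigmoid probability
#'   calibration (`probability = TRUE`); calibration failures raise a
#'   descriptive error rather than returning class labels.
#' * `"neural_net"` — [nnet::nnet()], single hidden layer with
#'   `hidden_nodes` (default 3) units and `weight_decay` (default 0.1).
#' * `"superlearner"` — stacking ensemble over `candidates` (default:
#'   logit, logit with interactions, random forest, neural net, svm); see
#'   [superlearner_fit()].
#'
#' Hyperparameters are passed through `...` and default to the underlying
#' packages' defaults.  A custom learner may be given as a list with
#' elements `fit(x, y)` and `predict(model, newx)` (and optionally `name`).
#'
#' @param name Learner name (see above), or a custom-learner list.
#' @param ... Hyperparameter overrides (e.g. `ntree`, `hidden_nodes`,
#'   `weight_decay`, `candidates`, `cv_folds`).
#' @return An object of class `"learner_spec"`.
#' @export
learner_spec <- function(name, ...) {
  if (is.list(name)) {
    if (is.null(name$fit) || is.null(name$predict)) {
      stop("a custom learner needs 'fit' and 'predict' functions",
           call. = FALSE)
    }
    return(structure(list(name = name$name %||% "custom",
                          custom = name, args = list(...)),
                     class = "learner_spec"))
  }
  name <- match.arg(name, c("logit", "logit_int", "random_forest",
                            "naive_bayes", "svm", "neural_net",
                            "superlearner"))
  structure(list(name = name, custom = NULL, args = list(...)),
            class = "learner_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_learner <- function(learner) {
  if (inherits(learner, "learner_spec")) learner
  else learner_spec(learner)
}

#' Fit a learner and return a probability predictor
#'
#' @param spec A [learner_spec()].
#' @param x Data frame of predictors.
#' @param y Binary response vector (0/1).
#' @return `function(newx)` returning probabilities in \[0, 1\].
#' @keywords internal
fit_learner <- function(spec, x, y) {
  spec <- as_learner(spec)
  a <- spec$args
  if (!is.null(spec$custom)) {
    m <- spec$custom$fit(x, y)
    pr <- spec$custom$predict
    return(function(nx) clamp01(pr(m, nx)))
  }
  switch(spec$name,
    logit = glm_predictor(~ ., x, y),
    logit_int = glm_predictor(~ .^2, x, y),
    random_forest = {
      m <- randomForest::randomForest(
        x = x, y = factor(y, levels = c(0, 1)),
        ntree = a$ntree %||% 500)
      function(nx) clamp01(unname(stats::predict(m, nx,
                                                 type = "prob")[, "1"]))
    },
    naive_bayes = {
      m <- e1071::naiveBayes(x = x, y = factor(y, levels = c(0, 1)))
      function(nx) clamp01(unname(stats::predict(m, nx,
                                                 type = "raw")[, "1"]))
    },
    svm = {
      m <- tryCatch(
        e1071::svm(x = as.matrix(x), y = factor(y, levels = c(0, 1)),
                   probability = TRUE, kernel = a$kernel %||% "radial",
                   cost = a$cost %||% 1),
        error = function(e) stop("svm probability calibration failed: ",
                                 conditionMessage(e), call. = FALSE))
      function(nx) {
        pr <- stats::predict(m, as.matrix(nx), probability = TRUE)
        pp <- attr(pr, "probabilities")
        if (is.null(pp)) {
          stop("svm probability calibration failed: no probability model",
               call. = FALSE)
        }
        clamp01(unname(pp[, "1"]))
      }
    },
    neural_net = {
      m <- nnet::nnet(x = as.matrix(x), y = y,
                      size = a$hidden_nodes %||% 3,
                      decay = a$weight_decay %||% 0.1,
                      entropy = TRUE, trace = FALSE,
                      maxit = a$maxit %||% 100)
      function(nx) clamp01(drop(stats::predict(m, as.matrix(nx))))
    },
    superlearner = {
      m <- superlearner_fit(x, y,
                            candidates = a$candidates %||%
                              default_sl_candidates(),
                            cv_folds = a$cv_folds %||% 10L)
      function(nx) clamp01(stats::predict(m, nx))
    })
}

clamp01 <- function(p) {
  if (anyNA(p) || any(!is.finite(p))) {
    stop("learner produced non-finite probabilities", call. = FALSE)
  }
  pmin(pmax(as.numeric(p), 0), 1)
}

## lean design builders for the logistic learners: numeric predictors skip
## the model.frame machinery (a relevant saving inside the bootstrap)
design_main <- function(d) {
  if (all(vapply(d, is.numeric, logical(1)))) {
    cbind(`(Intercept)` = 1, as.matrix(d))
  } else {
    stats::model.matrix(~ ., d)
  }
}

design_pairwise <- function(d) {
  if (!all(vapply(d, is.numeric, logical(1)))) {
    return(stats::model.matrix(~ .^2, d))
  }
  M <- as.matrix(d)
  k <- ncol(M)
  if (k < 2L) return(cbind(`(Intercept)` = 1, M))
  prods <- do.call(cbind, lapply(seq_len(k - 1L), function(i) {
    P <- M[, i] * M[, (i + 1L):k, drop = FALSE]
    colnames(P) <- paste(colnames(M)[i], colnames(M)[(i + 1L):k],
                         sep = ":")
    P
  }))
  cbind(`(Intercept)` = 1, M, prods)
}

glm_predictor <- function(form, x, y) {
  des <- if (identical(form, ~ .^2)) design_pairwise else design_main
  X <- des(x)
  fit <- suppressWarnings(stats::glm.fit(X, y,
                                         family = stats::binomial()))
  co <- fit$coefficients
  co[is.na(co)] <- 0
  function(nx) clamp01(stats::plogis(drop(des(nx) %*% co)))
}

#' Default SuperLearner candidate library
#'
#' Logistic regression, logistic regression with pairwise interactions,
#' random forest, neural net, and SVM.
#'
#' @return List of [learner_spec()] objects.
#' @export
default_sl_candidates <- function() {
  list(learner_spec("logit"), learner_spec("logit_int"),
       learner_spec("random_forest"), learner_spec("neural_net"),
       learner_spec("svm"))
}

#' SuperLearner stacking ensemble for a binary response
#'
#' Computes V-fold cross-validated predictions for every candidate learner,
#' finds the meta-weights minimising the cross-validated squared error on
#' the probability scale subject to non-negativity
#' ([pracma::lsqnonneg()]), normalises them to sum to one, and refits each
#' retained candidate on the full training set.  The ensemble prediction is
#' the weight-averaged candidate probability.  A candidate that fails to
#' fit is dropped with a warning; if all fail, an error is raised.
#'
#' @param x Data frame of predictors.
#' @param y Binary response (0/1), at least two observations per class.
#' @param candidates List of [learner_spec()]s (default
#'   [default_sl_candidates()]).
#' @param cv_folds Number of cross-validation folds for the meta-learning
#'   step (default 10).
#' @param seed Optional seed for the fold split.
#' @return Object of class `"superlearner"` with elements `weights`
#'   (named, non-negative, summing to 1), `candidates`, `predictors`, and
#'   `cv_risk` (cross-validated squared-error risk per candidate).
#'   `predict(object, newx)` returns ensemble probabilities.
#' @export
superlearner_fit <- function(x, y, candidates = default_sl_candidates(),
                             cv_folds = 10L, seed = NULL) {
  if (!length(candidates)) stop("empty candidate list", call. = FALSE)
  if (min(table(factor(y, levels = c(0, 1)))) < 2L) {
    stop("need at least two observations per class", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- length(y)
  cv_folds <- max(2L, min(cv_folds, n))
  fold <- sample(rep_len(seq_len(cv_folds), n))
  k <- length(candidates)
  cand_names <- vapply(seq_len(k), function(i) {
    nm <- as_learner(candidates[[i]])$name
    if (nm %in% c("custom", "")) paste0("custom", i) else nm
  }, character(1))
  Z <- matrix(NA_real_, n, k, dimnames = list(NULL, cand_names))
  ok <- rep(TRUE, k)
  for (i in seq_len(k)) {
    Z[, i] <- tryCatch({
      z <- numeric(n)
      for (v in seq_len(cv_folds)) {
        tr <- fold != v
        pred <- fit_learner(candidates[[i]], x[tr, , drop = FALSE], y[tr])
        z[!tr] <- pred(x[!tr, , drop = FALSE])
      }
      z
    }, error = function(e) {
      warning("dropping candidate '", cand_names[i], "': ",
              conditionMessage(e), call. = FALSE)
      ok[i] <<- FALSE
      NA_real_
    })
  }
  if (!any(ok)) stop("all SuperLearner candidates failed", call. = FALSE)
  Zk <- Z[, ok, drop = FALSE]
  w <- if (ncol(Zk) == 1L) 1 else pracma::lsqnonneg(Zk, y)$x
  if (sum(w) <= 0) w <- rep(1, ncol(Zk))    # degenerate: fall back to average
  w <- w / sum(w)
  names(w) <- cand_names[ok]
  predictors <- lapply(which(ok), function(i) fit_learner(candidates[[i]], x, y))
  cv_risk <- colMeans((Zk - y)^2)
  structure(list(weights = w, candidates = cand_names[ok],
                 predictors = predictors, cv_risk = cv_risk),
            class = "superlearner")
}

#' @export
predict.superlearner <- function(object, newdata, ...) {
  P <- vapply(object$predictors, function(f) f(newdata),
              numeric(nrow(newdata)))
  if (is.null(dim(P))) P <- matrix(P, nrow = 1L)
  drop(P %*% object$weights)
}

#' @export
print.superlearner <- function(x, ...) {
  cat("SuperLearner stacking ensemble\n")
  print(data.frame(candidate = x$candidates,
                   weight = round(unname(x$weights), 4),
                   cv_risk = round(unname(x$cv_risk), 5)))
  invisible(x)
}
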