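#' Configuration for the adaptive m-out-of-n bootstrap
#'
#' Defaults follow the simulation protocol: grid ratio `q = 0.95` and
#' `K_grid = 14`, so the smallest subsample is about half the sample size;
#' `B = 200` bootstrap replicates per grid point.
#'
#' @param q Grid ratio in (0, 1); subsample sizes are
#'   \eqn{m_j = \lfloor q^j n \rfloor}, \eqn{j = 0, \dots, K_{grid}}.
#' @param K_grid Largest grid exponent (>= 1).
#' @param B Bootstrap replicates per grid point (>= 2).
#' @param level Confidence level.
#' @param scale Normalisation of the bootstrap deviations used for the
#'   stability ECDFs: `"sqrt_m"` (the conventional \eqn{\sqrt{m_j}} scaling,
#'   consistent with asymptotic normality; default) or `"m"` (raw
#'   \eqn{m_j}), selectable for sensitivity analysis.
#' @param select `"argmin"` (default): choose the grid point minimising the
#'   Kolmogorov distance between successive ECDFs, i.e. where the bootstrap
#'   distribution is most stable; `"argmax"` is available for sensitivity.
#' @param seed Master seed; per-(j, b) seeds are derived by a counter-based
#'   scheme so each grid point is independently reproducible.
#' @param max_drop Maximum tolerated fraction of failed replicates at any
#'   grid point before erroring (default 0.1).
#' @return List of class `"mn_boot_config"`.
#' @export
mn_boot_config <- function(q = 0.95, K_grid = 14L, B = 200L, level = 0.95,
                           scale = c("sqrt_m", "m"),
                           select = c("argmin", "argmax"),
                           seed = NULL, max_drop = 0.1) {
  stopifnot(q > 0, q < 1, K_grid >= 1, B >= 2, level > 0, level < 1)
  structure(list(q = q, K_grid = as.integer(K_grid), B = as.integer(B),
                 level = level, scale = match.arg(scale),
                 select = match.arg(select), seed = seed,
                 max_drop = max_drop),
            class = "mn_boot_config")
}

#' Subsample-size grid for the m-out-of-n bootstrap
#'
#' Returns \eqn{m_j = \lfloor q^j \cdot n \rfloor} for
#' \eqn{j = 0, \dots, K_{grid}}, so the grid always starts at \eqn{m_0 = n}.
#' Duplicate values are removed preserving order.  Any grid value below 2
#' is an error (choose a smaller `K_grid`).
#'
#' @param n Sample size (>= 2).
#' @param q Grid ratio in (0, 1).
#' @param K_grid Largest exponent.
#' @return Integer vector of subsample sizes, with the exponents kept as
#'   attribute `"j"`.
#' @examples
#' m_grid(300)          # 300 ... 146 (about n/2)
#' @export
m_grid <- function(n, q = 0.95, K_grid = 14L) {
  if (n < 2) stop("'n' must be at least 2", call. = FALSE)
  stopifnot(q > 0, q < 1, K_grid >= 1)
  j <- 0:K_grid
  m <- floor(q^j * n)
  if (any(m < 2)) {
    stop("grid value m_", min(j[m < 2]), " = ", m[which(m < 2)[1L]],
         " is below 2; use a smaller 'K_grid' (or larger 'q')",
         call. = FALSE)
  }
  keep <- !duplicated(m)
  structure(as.integer(m[keep]), j = j[keep])
}

## counter-based per-(j, b) seed; keeps everything below 2^31
jb_seed <- function(seed, j, b) {
  as.integer(((as.numeric(seed) %% 100000) * 20011 +
                j * 1000003 + b) %% 2147483647L) + 1L
}

#' Bootstrap deviation ECDFs over the subsample-size grid
#'
#' For each grid point \eqn{m_j} and each replicate \eqn{b}, resamples
#' \eqn{m_j} whole subject rows with replacement, reruns the entire
#' estimator on the resample, and records the normalised deviation
#' \eqn{\sqrt{m_j}\,(\hat\psi_{jb} - \hat\psi)} (or raw-\eqn{m_j} scaling,
#' per `config$scale`).  Failed replicates are dropped and counted; more
#' than `config$max_drop` failures at any grid point is an error.
#'
#' @param data Data frame of subject trajectories.
#' @param estimator Function of a data frame returning a named numeric
#'   vector of parameter estimates (e.g. [dwols_estimator()]).
#' @param config An [mn_boot_config()].
#' @return List of class `"mn_ecdfs"`: `psi_hat` (full-sample estimate),
#'   `m` (grid), `deviations` (per grid point, a replicates-by-parameters
#'   matrix of normalised deviations), `estimates` (raw bootstrap
#'   estimates), `dropped` (failure count per grid point), `config`.
#' @export
bootstrap_ecdfs <- function(data, estimator, config = mn_boot_config()) {
  n <- nrow(data)
  psi_hat <- estimator(data)
  if (is.null(names(psi_hat))) {
    names(psi_hat) <- paste0("par", seq_along(psi_hat))
  }
  m <- m_grid(n, config$q, config$K_grid)
  seed <- config$seed %||% sample.int(2147483646L, 1L)
  ests <- vector("list", length(m))
  dropped <- integer(length(m))
  for (ji in seq_along(m)) {
    E <- matrix(NA_real_, config$B, length(psi_hat),
                dimnames = list(NULL, names(psi_hat)))
    for (b in seq_len(config$B)) {
      set.seed(jb_seed(seed, attr(m, "j")[ji], b))
      idx <- sample.int(n, m[ji], replace = TRUE)
      e <- tryCatch(estimator(data[idx, , drop = FALSE]),
                    error = function(err) NULL)
      if (!is.null(e)) E[b, ] <- e
    }
    bad <- rowSums(is.na(E)) > 0
    dropped[ji] <- sum(bad)
    if (dropped[ji] > config$max_drop * config$B) {
      stop("more than ", round(100 * config$max_drop),
           "% of bootstrap replicates failed at m = ", m[ji], call. = FALSE)
    }
    ests[[ji]] <- E[!bad, , drop = FALSE]
  }
  fac <- if (config$scale == "sqrt_m") sqrt(m) else as.numeric(m)
  deviations <- lapply(seq_along(m), function(ji) {
    sweep(ests[[ji]], 2, psi_hat) * fac[ji]
  })
  structure(list(psi_hat = psi_hat, m = m, deviations = deviations,
                 estimates = ests, dropped = dropped, config = config,
                 seed = seed),
            class = "mn_ecdfs")
}

## exact two-sample Kolmogorov sup-distance (tie-safe)
ks_dist <- function(x, y) {
  nx <- length(x); ny <- length(y)
  w <- c(x, y)
  o <- order(w)
  z <- cumsum(ifelse(o <= nx, 1 / nx, -1 / ny))
  ws <- w[o]
  keep <- c(diff(ws) != 0, TRUE)
  max(abs(z[keep]))
}

#' Stability-based selection of the subsample size
#'
#' Computes, per parameter, the Kolmogorov (sup-norm) distance
#' \eqn{D_j = \sup_x |R_j(x) - R_{j+1}(x)|} between the bootstrap-deviation
#' ECDFs at successive grid points, and selects the grid index where the
#' distribution is most stable (`argmin` of \eqn{D_j} by default; ties are
#' broken toward the larger subsample, i.e. the smaller index).
#'
#' @param ecdfs A [bootstrap_ecdfs()] result.
#' @param select `"argmin"` (default) or `"argmax"`; defaults to the choice
#'   recorded in the config.
#' @return Named integer vector of selected grid indices (1-based positions
#'   into `ecdfs$m`), with the matrix of successive distances as attribute
#'   `"D"`.
#' @export
select_m <- function(ecdfs, select = NULL) {
  select <- select %||% ecdfs$config$select
  J <- length(ecdfs$m)
  if (J < 2L) stop("need at least 2 grid points", call. = FALSE)
  pars <- colnames(ecdfs$deviations[[1L]])
  D <- matrix(NA_real_, J - 1L, length(pars),
              dimnames = list(NULL, pars))
  for (j in seq_len(J - 1L)) {
    for (p in seq_along(pars)) {
      D[j, p] <- ks_dist(ecdfs$deviations[[j]][, p],
                         ecdfs$deviations[[j + 1L]][, p])
    }
  }
  pick <- apply(D, 2, if (identical(select, "argmax")) which.max else
    which.min)
  structure(as.integer(pick), names = pars, D = D)
}

#' Convergence-rate exponent from bootstrap variances
#'
#' Under the working assumption that the estimator converges at rate
#' \eqn{n^{\beta}}, the bootstrap variance scales as
#' \eqn{\mathrm{Var}(\hat\psi_{m}) \propto m^{-2\beta}}, so \eqn{\beta} is
#' the ordinary least-squares slope of \eqn{\log \widehat{\mathrm{Var}}}
#' on \eqn{-2 \log m}.  A \eqn{\sqrt{n}}-consistent estimator gives 0.5; a
#' non-converging one gives 0.  Grid points with zero variance are
#' excluded; fewer than two remaining points is an error.
#'
#' @param variances Bootstrap variance per grid point.
#' @param m Subsample sizes.
#' @return The estimated rate exponent (scalar).
#' @examples
#' m <- m_grid(400)
#' estimate_rate(1 / m, m)   # exactly 0.5
#' @export
estimate_rate <- function(variances, m) {
  if (length(variances) != length(m)) {
    stop("'variances' and 'm' must have equal length", call. = FALSE)
  }
  keep <- variances > 0
  if (any(!keep)) {
    variances <- variances[keep]
    m <- m[keep]
  }
  if (length(unique(m)) < 2L) {
    stop("need at least 2 grid points with positive variance", call. = FALSE)
  }
  x <- -2 * log(m)
  unname(stats::coef(stats::lm.fit(cbind(1, x), log(variances)))[2L])
}

#' m-out-of-n confidence interval
#'
#' \eqn{\hat\psi \pm z_{(1+level)/2} \, (m/n)^{\beta}
#' \sqrt{\widehat{\mathrm{Var}}(\hat\psi_m)}}: the bootstrap variance at the
#' selected subsample size, rescaled to the full sample through the
#' estimated convergence-rate exponent.  At \eqn{m = n} this reduces to the
#' usual normal-approximation interval.
#'
#' @param psi_hat Full-sample point estimate.
#' @param m_star Selected subsample size.
#' @param n Full sample size.
#' @param rate_exponent Estimated convergence-rate exponent.
#' @param variance Bootstrap variance at `m_star`.
#' @param level Confidence level.
#' @return Numeric vector `c(lower, upper)`.
#' @export
mn_ci <- function(psi_hat, m_star, n, rate_exponent, variance,
                  level = 0.95) {
  stopifnot(variance >= 0, level > 0, level < 1)
  half <- stats::qnorm((1 + level) / 2) *
    (m_star / n)^rate_exponent * sqrt(variance)
  c(lower = psi_hat - half, upper = psi_hat + half)
}

#' Adaptive m-out-of-n bootstrap inference
#'
#' Runs the complete procedure: full-sample estimate, bootstrap of the
#' entire estimator over the subsample grid ([bootstrap_ecdfs()]),
#' stability-based selection of \eqn{m} per parameter ([select_m()]),
#' convergence-rate estimation from the bootstrap variances
#' ([estimate_rate()]), and the rescaled normal confidence interval
#' ([mn_ci()]).  Resampling is always of whole subject rows.
#'
#' @param data Data frame of subject trajectories.
#' @param estimator Function of a data frame returning a named numeric
#'   vector (e.g. [dwols_estimator()]).
#' @param config An [mn_boot_config()].
#' @return Object of class `"mn_boot"`: `summary` (data frame with one row
#'   per parameter: estimate, selected `m`, `rate_exponent`, bootstrap
#'   `variance` at the selected `m`, `lower`, `upper`), `ecdfs`, `dropped`,
#'   and `config`.
#' @export
mn_boot <- function(data, estimator, config = mn_boot_config()) {
  ec <- bootstrap_ecdfs(data, estimator, config)
  pick <- select_m(ec)
  pars <- names(ec$psi_hat)
  V <- vapply(ec$estimates,
              function(E) apply(E, 2, stats::var), numeric(length(pars)))
  V <- matrix(V, nrow = length(pars))   # parameters x grid
  rows <- lapply(seq_along(pars), function(p) {
    rate <- estimate_rate(V[p, ], ec$m)
    ji <- pick[p]
    ci <- mn_ci(unname(ec$psi_hat[p]), ec$m[ji], nrow(data), rate,
                V[p, ji], config$level)
    data.frame(parameter = pars[p], estimate = unname(ec$psi_hat[p]),
               m = ec$m[ji], rate_exponent = rate,
               variance = V[p, ji],
               lower = unname(ci["lower"]), upper = unname(ci["upper"]))
  })
  structure(list(summary = do.call(rbind, rows), ecdfs = ec,
                 dropped = ec$dropped, config = config),
            class = "mn_boot")
}

#' @export
print.mn_boot <- function(x, digits = 4, ...) {
  cat("Adaptive m-out-of-n bootstrap (q =", x$config$q,
      ", K =", x$config$K_grid, ", B =", x$config$B, ")\n")
  s <- x$summary
  s[, -1] <- round(s[, -1], digits)
  print(s, row.names = FALSE)
  if (any(x$dropped > 0)) {
    cat("dropped replicates per grid point:",
        paste(x$dropped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Standard percentile bootstrap
#'
#' n-out-of-n resampling of whole subject rows with replacement; the
#' confidence bounds are the type-7 (linear-interpolation) quantiles of the
#' bootstrap estimates.  Provided as the regular-case baseline against
#' which the m-out-of-n procedure is compared.
#'
#' @param data Data frame of subject trajectories.
#' @param estimator Function of a data frame returning a named numeric
#'   vector.
#' @param B Number of bootstrap replicates.
#' @param level Confidence level.
#' @param seed Optional seed.
#' @param max_drop Maximum tolerated fraction of failed replicates.
#' @return Object of class `"percentile_boot"`: `summary` data frame
#'   (estimate, lower, upper per parameter), `estimates` matrix, `dropped`.
#' @export
percentile_boot <- function(data, estimator, B = 1000L, level = 0.95,
                            seed = NULL, max_drop = 0.1) {
  n <- nrow(data)
  psi_hat <- estimator(data)
  if (is.null(names(psi_hat))) {
    names(psi_hat) <- paste0("par", seq_along(psi_hat))
  }
  if (!is.null(seed)) set.seed(seed)
  E <- matrix(NA_real_, B, length(psi_hat),
              dimnames = list(NULL, names(psi_hat)))
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    e <- tryCatch(estimator(data[idx, , drop = FALSE]),
                  error = function(err) NULL)
    if (!is.null(e)) E[b, ] <- e
  }
  bad <- rowSums(is.na(E)) > 0
  if (sum(bad) > max_drop * B) {
    stop("more than ", round(100 * max_drop),
         "% of bootstrap replicates failed", call. = FALSE)
  }
  E <- E[!bad, , drop = FALSE]
  probs <- c((1 - level) / 2, (1 + level) / 2)
  ci <- apply(E, 2, stats::quantile, probs = probs, type = 7)
  structure(list(
    summary = data.frame(parameter = names(psi_hat),
                         estimate = unname(psi_hat),
                         lower = unname(ci[1L, ]),
                         upper = unname(ci[2L, ])),
    estimates = E, dropped = sum(bad), level = level),
    class = "percentile_boot")
}

#' @export
print.percentile_boot <- function(x, digits = 4, ...) {
  cat("Percentile bootstrap,", nrow(x$estimates), "replicates\n")
  s <- x$summary
  s[, -1] <- round(s[, -1], digits)
  print(s, row.names = FALSE)
  invisible(x)
}
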