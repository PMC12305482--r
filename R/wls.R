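#' Balancing weights for dWOLS
#'
#' Computes the absolute-difference balancing weights \eqn{w_i = |a_i - p_i|}
#' from predicted treatment probabilities.  These weights satisfy the balancing
#' condition \eqn{w(1, h)\,P(A=1 \mid h) = w(0, h)\,P(A=0 \mid h)} pointwise,
#' which is what confers double robustness on the stagewise weighted
#' regression: a subject whose treatment was nearly certain gets weight near
#' zero, so the weighted treated and untreated groups are comparable.
#'
#' No truncation or clipping is applied: as \eqn{p \to 0} or \eqn{1} the
#' weights shrink rather than explode, and clipping would break the balancing
#' identity.  Positivity problems show up as a large share of near-zero
#' weights; see the `diagnostics` element of a fitted [dwols()] object.
#'
#' @param p Numeric vector of predicted treatment probabilities in \[0, 1\].
#' @param a Binary treatment vector (coded exactly 0/1).
#' @return Numeric vector of weights, each in \[0, 1\].
#' @examples
#' compute_weights(c(0.5, 0.2, 1.0), c(1, 0, 1))
#' @export
compute_weights <- function(p, a) {
  if (length(p) != length(a)) {
    stop("'p' and 'a' must have the same length", call. = FALSE)
  }
  if (anyNA(a) || !all(a %in% c(0, 1))) {
    stop("treatment must be coded 0/1 with no missing values", call. = FALSE)
  }
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    stop("treatment probabilities must lie in [0, 1]", call. = FALSE)
  }
  abs(a - p)
}

#' Weighted least squares for one decision stage
#'
#' Solves the weighted least-squares problem for a single stage of the
#' backward recursion, returning the full coefficient vector.  The solve is
#' QR-based on the row-scaled design \eqn{\sqrt{w}X}; rank is checked by
#' singular values with a relative tolerance of `tol` (default `1e-10`) and a
#' rank-deficient design is an error that names the collinear columns rather
#' than silently dropping them.
#'
#' @param X Numeric design matrix (treatment-free columns followed by
#'   blip-by-treatment interaction columns, as assembled by [dwols()]).
#' @param y Response (outcome or pseudo-outcome) vector.
#' @param w Non-negative weight vector, not all zero.
#' @param tol Relative singular-value tolerance for rank determination.
#' @return A list with `coefficients`, `fitted`, and `residuals`.
#' @keywords internal
fit_stage <- function(X, y, w, tol = 1e-10) {
  X <- as.matrix(X)
  if (nrow(X) != length(y) || length(y) != length(w)) {
    stop("design, response and weights must conform", call. = FALSE)
  }
  if (anyNA(w) || any(w < 0)) {
    stop("weights must be non-negative", call. = FALSE)
  }
  if (all(w == 0)) {
    stop("all weights are zero; the weighted regression is undefined",
         call. = FALSE)
  }
  sw <- sqrt(w)
  Xw <- X * sw
  yw <- y * sw
  d <- svd(Xw, nu = 0, nv = 0)$d
  if (d[1] <= 0 || sum(d > tol * d[1]) < ncol(Xw)) {
    qx <- qr(Xw, tol = 1e-8)
    bad <- colnames(Xw)[qx$pivot[seq(qx$rank + 1L, ncol(Xw))]]
    stop("singular design after weighting; collinear terms: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  qx <- qr(Xw)
  coefs <- qr.coef(qx, yw)
  fitted <- drop(X %*% coefs)
  list(coefficients = coefs, fitted = fitted, residuals = y - fitted)
}
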