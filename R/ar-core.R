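# Autoregressive decomposition primitives.
#
# All model fitting in this file is plain ordinary least squares on the lag
# design matrix, solved through a QR factorization (stats::lm.fit).  There is
# no intercept: channels are demeaned over the fitted segment beforehand.
# Variances are population variances (mean of squares over the valid
# samples), which makes the in-sample monotonicity var(eps_ij) <= var(eps_i)
# an exact algebraic fact rather than an approximation.

# Lag design matrix: rows are valid time points t, column n holds x[t - n].
lag_design <- function(x, order, t_valid) {
  idx <- outer(t_valid, seq_len(order), "-")
  matrix(x[idx], nrow = length(t_valid), ncol = order)
}

# First valid output index for a series whose leading `context` samples are
# history: predictions need `order` lags, context supplies up to that many.
first_valid <- function(order, context) max(order, context) + 1L

#' Fit a univariate autoregressive model to one channel
#'
#' Estimates coefficients `a(n)` of
#' `x(t) = sum_n a(n) x(t - n) + eps(t)` by ordinary least squares and
#' returns the innovation series `eps` -- the unpredictable component of the
#' channel.  The channel is demeaned over the fitted segment first; the
#' model has no intercept.
#'
#' If `context > 0`, the first `context` samples are treated as pre-event
#' history: they supply lags but produce no output, so with
#' `context >= order` the innovation series covers every post-context
#' sample.  Without context the first `order` samples produce no output
#' (they are dropped, never zero-padded).
#'
#' @param x numeric vector, one channel (context samples first, if any).
#' @param order model order N (number of lags).
#' @param context number of leading history samples.
#' @param name channel name used in error messages.
#' @return list with `coef` (length `order`), `innovations`, `sigma2`
#'   (population variance of the innovations), `mean` (removed mean),
#'   `t_valid` (indices of `x` the innovations correspond to).
#' @export
fit_ar <- function(x, order, context = 0L, name = "channel") {
  order <- as.integer(order); context <- as.integer(context)
  if (order < 1L) stop("`order` must be >= 1")
  T_ <- length(x)
  t0 <- first_valid(order, context)
  if (t0 > T_) stop(sprintf("channel %s too short: %d samples, need > %d",
                            name, T_, t0 - 1L))
  t_valid <- t0:T_
  if (length(t_valid) < 10L * order)
    warning(sprintf("channel %s: %d samples fitted with order %d; fewer than 10x the model order",
                    name, length(t_valid), order))
  mu <- mean(x[t_valid])
  xc <- x - mu
  D <- lag_design(xc, order, t_valid)
  y <- xc[t_valid]
  if (qr(D)$rank < order)
    stop(sprintf("rank-deficient lag design for channel %s (constant or degenerate signal)",
                 name))
  fit <- stats::lm.fit(D, y)
  eps <- as.numeric(fit$residuals)
  list(coef = as.numeric(fit$coefficients), innovations = eps,
       sigma2 = mean(eps^2), mean = mu, t_valid = t_valid)
}

#' Fit a directed influence regression
#'
#' Regresses an innovation series `eps_i` on the lagged history of an
#' influencing channel `x_j`:
#' `eps_i(t) = sum_n b(n) x_j(t - n) + eps_ij(t)`.
#' The residual `eps_ij` is the part of channel i's innovation that the past
#' of channel j cannot explain; its population variance can only be smaller
#' than or equal to `var(eps_i)` in sample, which is what makes the derived
#' Granger causality nonnegative.
#'
#' @param eps_i numeric vector of innovations at times `t_valid`.
#' @param x_j numeric vector, the influencing channel on the full time axis
#'   (same axis `t_valid` indexes into); it is demeaned over `t_valid`.
#' @param order model order N (same as the univariate fit).
#' @param t_valid time indices of `x_j` that `eps_i` corresponds to.
#' @param name pair name used in error messages.
#' @return list with `coef` (b, length `order`), `residuals` (eps_ij),
#'   `sigma2`.
#' @export
fit_influence <- function(eps_i, x_j, order, t_valid, name = "pair") {
  if (min(t_valid) <= order)
    stop("influencing channel history of `order` samples required at each valid t")
  if (length(eps_i) != length(t_valid))
    stop("length mismatch between innovations and valid time indices")
  if (max(t_valid) > length(x_j))
    stop("influencing channel shorter than the valid time range")
  xj <- x_j - mean(x_j[t_valid])
  D <- lag_design(xj, order, t_valid)
  if (qr(D)$rank < order)
    stop(sprintf("degenerate influencing signal for %s", name))
  fit <- stats::lm.fit(D, eps_i)
  res <- as.numeric(fit$residuals)
  list(coef = as.numeric(fit$coefficients), residuals = res,
       sigma2 = mean(res^2))
}

#' Directed influence signal
#'
#' The contribution of the influencing channel to the influenced channel's
#' innovation: `c_ij(t) = eps_i(t) - eps_ij(t)`.  This identity is
#' definitional, so `c_ij + eps_ij` reconstructs `eps_i` exactly.
#'
#' @param eps_i univariate innovation series.
#' @param eps_ij influence-regression residual series.
#' @return numeric vector `c_ij`.
#' @export
influence_signal <- function(eps_i, eps_ij) {
  if (length(eps_i) != length(eps_ij)) stop("length mismatch")
  eps_i - eps_ij
}

#' Granger causality from innovation variances
#'
#' `GC(i <- j) = log(var(eps_i) / var(eps_ij))`.  With both variances taken
#' in sample from [fit_ar()] and [fit_influence()] on the same segment the
#' value is always nonnegative.
#'
#' @param var_eps_i variance of the univariate innovations.
#' @param var_eps_ij variance of the influence-regression residuals.
#' @return scalar GC value (natural log).
#' @export
granger_causality <- function(var_eps_i, var_eps_ij) {
  if (!is.finite(var_eps_i) || !is.finite(var_eps_ij) ||
      var_eps_i <= 0 || var_eps_ij <= 0)
    stop("innovation variances must be positive")
  log(var_eps_i / var_eps_ij)
}

# Free bivariate AR fit: x_i regressed on its own lags AND x_j's lags, with
# the autoregressive coefficients unconstrained.  This is the classical
# two-model GC formulation; the package's two-stage decomposition constrains
# the autoregressive part to the univariate fit instead.  Exposed because
# windowed GC uses it, and because it is the natural cross-check for the
# two-stage estimator.
#' Classical (free-fit) bivariate Granger causality
#'
#' Fits the unrestricted bivariate model (own lags plus the influencing
#' channel's lags, all coefficients free) and the restricted univariate
#' model on the same segment, and returns `log(var_restricted /
#' var_unrestricted)`.
#'
#' @param x_i influenced channel (numeric vector).
#' @param x_j influencing channel, same length.
#' @param order model order N.
#' @return scalar GC value.
#' @export
bivariate_gc <- function(x_i, x_j, order) {
  if (length(x_i) != length(x_j)) stop("length mismatch")
  T_ <- length(x_i)
  if (T_ <= 2L * order) stop("signal too short for the bivariate fit")
  t_valid <- (order + 1L):T_
  xi <- x_i - mean(x_i[t_valid]); xj <- x_j - mean(x_j[t_valid])
  D1 <- lag_design(xi, order, t_valid)
  D2 <- lag_design(xj, order, t_valid)
  y <- xi[t_valid]
  r1 <- stats::lm.fit(D1, y)$residuals
  r2 <- stats::lm.fit(cbind(D1, D2), y)$residuals
  granger_causality(mean(r1^2), mean(r2^2))
}

#' Sliding-window Granger causality
#'
#' Recomputes classical two-model GC (free bivariate fit) independently in
#' each sliding window, the conventional way of tracking connectivity over
#' time.  Each value is timestamped at the window center.  Provided for
#' comparison with the sample-resolution influence signals: narrow windows
#' give volatile estimates, wide windows smear temporal detail.
#'
#' @param x_i influenced channel.
#' @param x_j influencing channel, same length.
#' @param order model order N.
#' @param window_samples window length in samples (>= 10 * order advised;
#'   a warning is issued below that).
#' @param step_samples hop between window starts.
#' @return data.frame with `center` (sample index of the window center) and
#'   `gc`; `floor((T - window) / step) + 1` rows.
#' @export
windowed_gc <- function(x_i, x_j, order, window_samples, step_samples) {
  T_ <- length(x_i)
  if (length(x_j) != T_) stop("length mismatch")
  if (window_samples > T_) stop("window longer than the signal")
  if (window_samples < 10L * order)
    warning("window shorter than 10x the model order; estimates will be unstable")
  starts <- seq(1L, T_ - window_samples + 1L, by = step_samples)
  gc <- vapply(starts, function(s) {
    idx <- s:(s + window_samples - 1L)
    bivariate_gc(x_i[idx], x_j[idx], order)
  }, numeric(1))
  data.frame(center = starts + (window_samples - 1) / 2, gc = gc)
}
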