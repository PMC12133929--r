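#' Fit the dynamic influence decomposition of a multichannel recording
#'
#' The core estimator of the package.  For each channel i a univariate
#' autoregressive model of order N is fit by least squares, giving the
#' innovation process `eps_i` (the unpredictable component of the channel).
#' Then, for every ordered channel pair (i <- j), the innovation is
#' regressed on the influencing channel's N-sample history, splitting it
#' into a directed influence signal `c_ij` (the part of `eps_i` explainable
#' from channel j's past) and a residual `eps_ij`.  Crucially the univariate
#' autoregressive coefficients are kept fixed in the second stage, so the
#' pair regression models the innovation directly rather than refitting the
#' channel's own dynamics.
#'
#' The decomposition satisfies two exact identities on the fitted segment:
#' `x_i(t) = sum_n a_i(n) x_i(t-n) + eps_i(t)` (after demeaning) and
#' `eps_i(t) = c_ij(t) + eps_ij(t)` for every pair.  In-sample,
#' `var(eps_ij) <= var(eps_i)`, so the derived Granger causality
#' `log(var(eps_i)/var(eps_ij))` is nonnegative.
#'
#' The innovations and influence signals are assembled into the inflated
#' array (see [inflated()]): an M x M x T' array with `eps_i` on the
#' diagonal and `c_ij` at off-diagonal cell (i, j), the representation used
#' as classifier input downstream.
#'
#' @param x an [eeg_recording], or a channels x time numeric matrix.  If the
#'   first `context` columns are pre-event history, pass `context` so the
#'   output covers the full analysis window; otherwise the first N output
#'   samples are dropped (never zero-padded).
#' @param order model order N.  Choose N / srate in the 100--200 ms range;
#'   at 160 Hz the conventional default is N = 20.
#' @param context number of leading history samples in `x`.
#' @param scope label recorded in the output metadata: `"recording"` when
#'   fitting a continuous run (models can then be applied to epochs via
#'   [predict.didi()]), `"epoch"` when fitting a single epoch.
#' @return An object of class `"didi"`: a list with elements
#'   `order`, `channel_names`, `srate`, `ar` (coefficient matrix M x N,
#'   innovation variances, removed means), `influence` (coefficient array
#'   M x M x N and residual variance matrix), `gc` (M x M Granger causality
#'   matrix, `NA` on the diagonal), and `inflated` (the M x M x T' array).
#' @seealso [inflate_epoch()], [predict.didi()], [granger_causality()]
#' @examples
#' spec <- var_spec(n_channels = 2, order = 1,
#'                  coeffs = array(c(0.5, 0.4, 0, 0.5), c(1, 2, 2)),
#'                  n_samples = 2000, seed = 1)
#' fit <- didi(simulate_var(spec), order = 4)
#' summary(fit)
#' @export
didi <- function(x, order = 20L, context = 0L,
                 scope = c("recording", "epoch")) {
  scope <- match.arg(scope)
  srate <- NA_real_
  if (inherits(x, "eeg_recording")) {
    srate <- x$srate
    sig <- x$signal
  } else {
    sig <- as.matrix(x)
  }
  M <- nrow(sig); T_ <- ncol(sig)
  ch <- rownames(sig)
  if (is.null(ch)) ch <- paste0("ch", seq_len(M))
  order <- as.integer(order); context <- as.integer(context)
  if (context > 0L && context < order)
    warning("context shorter than the model order; extra startup samples are dropped")

  t0 <- first_valid(order, context)
  if (t0 > T_) stop("signal too short for the requested order")
  t_valid <- t0:T_
  Tp <- length(t_valid)

  a <- matrix(NA_real_, M, order)
  mu <- numeric(M)
  sig2 <- numeric(M)
  eps <- matrix(NA_real_, M, Tp)
  for (i in seq_len(M)) {
    f <- fit_ar(sig[i, ], order, context = context, name = ch[i])
    a[i, ] <- f$coef; mu[i] <- f$mean; sig2[i] <- f$sigma2
    eps[i, ] <- f$innovations
  }

  b <- array(NA_real_, c(M, M, order))
  pair_sig2 <- matrix(NA_real_, M, M)
  infl <- array(0, c(M, M, Tp),
                dimnames = list(influenced = ch, influencing = ch, NULL))
  for (i in seq_len(M)) {
    infl[i, i, ] <- eps[i, ]
    for (j in seq_len(M)) {
      if (i == j) next
      g <- fit_influence(eps[i, ], sig[j, ], order, t_valid,
                         name = paste0(ch[i], "<-", ch[j]))
      b[i, j, ] <- g$coef
      pair_sig2[i, j] <- g$sigma2
      infl[i, j, ] <- influence_signal(eps[i, ], g$residuals)
    }
  }

  gc <- matrix(NA_real_, M, M, dimnames = list(ch, ch))
  for (i in seq_len(M)) for (j in seq_len(M)) if (i != j)
    gc[i, j] <- granger_causality(sig2[i], pair_sig2[i, j])

  rownames(a) <- ch
  structure(list(order = order, channel_names = ch, srate = srate,
                 context = context, scope = scope, n_fitted = Tp,
                 ar = list(coef = a, sigma2 = sig2, mean = mu),
                 influence = list(coef = b, sigma2 = pair_sig2),
                 gc = gc,
                 inflated = new_inflated(infl, srate, ch, order, scope),
                 innovations = eps,
                 call = match.call()),
            class = "didi")
}

new_inflated <- function(data, srate, channel_names, order, scope) {
  structure(list(data = data, srate = srate, channel_names = channel_names,
                 order = order, fit_scope = scope),
            class = "inflated_epoch")
}

#' @export
print.inflated_epoch <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<inflated_epoch> %d x %d x %d (order %d, fit scope: %s)\n",
              d[1], d[2], d[3], x$order, x$fit_scope))
  invisible(x)
}

#' Extract the inflated array from a fitted decomposition
#' @param object a `"didi"` fit.
#' @return the `"inflated_epoch"` object (M x M x T' array plus metadata).
#' @export
inflated <- function(object) {
  stopifnot(inherits(object, "didi"))
  object$inflated
}

#' Granger causality matrix of a fitted decomposition
#' @param object a `"didi"` fit.
#' @return M x M matrix; cell (i, j) is GC(i <- j), `NA` on the diagonal.
#' @export
gc_matrix <- function(object) {
  stopifnot(inherits(object, "didi"))
  object$gc
}

#' @export
print.didi <- function(x, ...) {
  cat(sprintf("<didi> influence decomposition: %d channels, order %d, %d fitted samples (scope: %s)\n",
              length(x$channel_names), x$order, x$n_fitted, x$scope))
  invisible(x)
}

#' @export
summary.didi <- function(object, ...) {
  structure(list(order = object$order, scope = object$scope,
                 n_fitted = object$n_fitted,
                 channel_names = object$channel_names,
                 innovation_var = stats::setNames(object$ar$sigma2,
                                                  object$channel_names),
                 gc = object$gc),
            class = "summary.didi")
}

#' @export
print.summary.didi <- function(x, ...) {
  cat(sprintf("Dynamic influence decomposition (order %d, %d samples, scope: %s)\n\n",
              x$order, x$n_fitted, x$scope))
  cat("Innovation variances:\n")
  print(round(x$innovation_var, 4))
  cat("\nGranger causality, GC(i <- j) [rows influenced, columns influencing]:\n")
  print(round(x$gc, 4))
  invisible(x)
}

#' @export
coef.didi <- function(object, ...) {
  list(ar = object$ar$coef, influence = object$influence$coef)
}

#' @export
residuals.didi <- function(object, ...) object$innovations

#' Apply a fitted decomposition to new epochs
#'
#' Applies the stored univariate and influence coefficients to new data:
#' the model is fit once per continuous recording (maximizing the samples
#' behind each coefficient) and then used to decompose individual epochs.
#' Each epoch should carry at least `order` pre-event context samples so
#' the output covers its full analysis window.
#'
#' @param object a `"didi"` fit (typically `scope = "recording"`).
#' @param newdata a channels x time matrix (single epoch) or an
#'   [epoch_set].
#' @param context leading history samples in `newdata` (ignored for an
#'   `epoch_set`, which knows its own context).
#' @param ... unused.
#' @return an `"inflated_epoch"` for a matrix, or a list of them for an
#'   `epoch_set`.
#' @export
predict.didi <- function(object, newdata, context = 0L, ...) {
  if (inherits(newdata, "epoch_set")) {
    return(lapply(seq_len(n_epochs(newdata)), function(k)
      apply_didi(object, get_epoch(newdata, k), newdata$context)))
  }
  apply_didi(object, as.matrix(newdata), context)
}

apply_didi <- function(fit, epoch, context) {
  M <- length(fit$channel_names); N <- fit$order
  if (nrow(epoch) != M) stop("channel count mismatch with the fitted model")
  T_ <- ncol(epoch)
  t0 <- first_valid(N, as.integer(context))
  if (t0 > T_) stop("epoch too short for the model order")
  t_valid <- t0:T_
  Tp <- length(t_valid)
  # demean over the valid segment of this epoch (the models carry no
  # intercept; epoch-level offsets are nuisance)
  mu <- rowMeans(epoch[, t_valid, drop = FALSE])
  xc <- epoch - mu
  eps <- matrix(NA_real_, M, Tp)
  for (i in seq_len(M)) {
    D <- lag_design(xc[i, ], N, t_valid)
    eps[i, ] <- xc[i, t_valid] - as.numeric(D %*% fit$ar$coef[i, ])
  }
  infl <- array(0, c(M, M, Tp),
                dimnames = list(influenced = fit$channel_names,
                                influencing = fit$channel_names, NULL))
  for (i in seq_len(M)) {
    infl[i, i, ] <- eps[i, ]
    for (j in seq_len(M)) {
      if (i == j) next
      D <- lag_design(xc[j, ], N, t_valid)
      pred <- as.numeric(D %*% fit$influence$coef[i, j, ])
      infl[i, j, ] <- pred            # c_ij = explained part of eps_i
    }
  }
  new_inflated(infl, fit$srate, fit$channel_names, N, "recording")
}

#' Inflate a single epoch
#'
#' Convenience wrapper producing the M x M x T' inflated array for one
#' epoch: univariate innovations `eps_i` on the diagonal, directed
#' influence signals `c_ij` off-diagonal.  With `models = NULL` the
#' decomposition is fit on the epoch itself (per-epoch scope); with a
#' `"didi"` fit supplied, the precomputed per-recording coefficients are
#' applied instead.
#'
#' @param epoch channels x time numeric matrix, including any leading
#'   context samples.
#' @param order model order N (ignored when `models` is supplied).
#' @param models optional `"didi"` fit whose coefficients are applied.
#' @param context number of leading history samples in `epoch`.
#' @return an `"inflated_epoch"`.
#' @export
inflate_epoch <- function(epoch, order = 20L, models = NULL, context = 0L) {
  if (!is.null(models)) {
    stopifnot(inherits(models, "didi"))
    return(apply_didi(models, as.matrix(epoch), context))
  }
  fit <- didi(epoch, order = order, context = context, scope = "epoch")
  fit$inflated
}

#' Inflate every epoch of an epoch set
#'
#' Runs [inflate_epoch()] over an [epoch_set] and stacks the flattened
#' results into the classifier input layout (see [flatten()]): an
#' `n_epochs x M^2 x T'` array, row (i-1)*M + j of each slice carrying
#' component (i <- j).
#'
#' @param epochs an [epoch_set].
#' @param order model order N.
#' @param models optional `"didi"` fit (per-recording scope).
#' @return list with `data` (n x M^2 x T'), `labels`, `M`,
#'   `channel_names`, `order`, `fit_scope`, `srate`.
#' @export
inflate_set <- function(epochs, order = 20L, models = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  n <- n_epochs(epochs)
  first <- inflate_epoch(get_epoch(epochs, 1), order = order,
                         models = models, context = epochs$context)
  M <- dim(first$data)[1]; Tp <- dim(first$data)[3]
  out <- array(NA_real_, c(n, M * M, Tp))
  out[1, , ] <- flatten(first)
  if (n > 1) for (k in 2:n) {
    ie <- inflate_epoch(get_epoch(epochs, k), order = order,
                        models = models, context = epochs$context)
    out[k, , ] <- flatten(ie)
  }
  list(data = out, labels = epochs$labels, M = M,
       channel_names = epochs$channel_names,
       order = if (is.null(models)) as.integer(order) else models$order,
       fit_scope = if (is.null(models)) "epoch" else "recording",
       srate = epochs$srate)
}
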