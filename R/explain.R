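# Turning classifier gradients into connectivity-support representations.
# A saliency map is the per-component, per-sample magnitude of the gradient
# of a class score with respect to the flattened inflated input; reshaping
# one of its columns back into an M x M matrix gives a connectivity support
# matrix for that instant, and averaging over a time interval (or the whole
# epoch) gives condensed / static support maps.

#' Saliency map of a classification decision
#'
#' Computes the input gradient of the target class score (see
#' [input_gradient()]) and takes its elementwise magnitude: the estimated
#' significance of every inflated data component at every time sample for
#' the decision.  Off-diagonal rows speak for directed connections, the
#' diagonal rows for processes confined to single electrodes.
#'
#' The gradient is taken with respect to the network's input tensor (the
#' standardized data), the conventional scale for saliency: differentiating
#' through to the raw scale would multiply each channel by the reciprocal
#' of its standard deviation and spuriously inflate the apparent importance
#' of low-variance components.
#'
#' @param model a trained `"eegnet"`.
#' @param x classifier input, `M^2 x T'` matrix (a flattened inflated
#'   epoch); an `"inflated_epoch"` is flattened automatically.
#' @param target_class class label/index; `NULL` for the predicted class.
#' @param signed keep the gradient sign instead of the magnitude.
#' @param t0 time (s) of the first sample relative to the event, for the
#'   map's time axis.
#' @return object of class `"saliency_map"`: `values` (M^2 x T',
#'   nonnegative unless `signed`), `M`, `channel_names`, `target_class`,
#'   `srate`, `t0`.
#' @export
saliency_map <- function(model, x, target_class = NULL, signed = FALSE,
                         t0 = 0) {
  srate <- NA_real_; ch <- NULL
  if (inherits(x, "inflated_epoch")) {
    srate <- x$srate; ch <- x$channel_names
    x <- flatten(x)
  }
  x <- as.matrix(x)
  M <- as.integer(round(sqrt(nrow(x))))
  if (M * M != nrow(x)) stop("input row count is not a perfect square")
  if (is.null(ch)) ch <- paste0("ch", seq_len(M))
  g <- input_gradient(model, x, target_class, scale = "input")
  vals <- if (signed) g$gradient else abs(g$gradient)
  structure(list(values = vals, M = M, channel_names = ch,
                 target_class = g$target_class, srate = srate, t0 = t0,
                 signed = signed),
            class = "saliency_map")
}

#' @export
print.saliency_map <- function(x, ...) {
  cat(sprintf("<saliency_map> %d components x %d samples (M = %d), class '%s'%s\n",
              nrow(x$values), ncol(x$values), x$M, x$target_class,
              if (x$signed) ", signed" else ""))
  invisible(x)
}

new_support_matrix <- function(m, channel_names, time_label) {
  dimnames(m) <- list(influenced = channel_names,
                      influencing = channel_names)
  structure(m, class = c("support_matrix", "matrix"),
            time_label = time_label)
}

#' Connectivity support matrix at one time sample
#'
#' Reorders column `t` of the saliency map back into an M x M square:
#' off-diagonal cell (i, j) is the support for the directed connection
#' i <- j, the diagonal holds per-electrode process support.
#'
#' @param saliency a `"saliency_map"`.
#' @param t sample index (1-based) into the map's time axis.
#' @return a `"support_matrix"` (M x M, channel-named).
#' @export
support_at <- function(saliency, t) {
  stopifnot(inherits(saliency, "saliency_map"))
  Tn <- ncol(saliency$values)
  if (t < 1 || t > Tn) stop("time index out of range")
  new_support_matrix(unflatten_column(saliency$values[, t], saliency$M),
                     saliency$channel_names, sprintf("t=%d", t))
}

#' Time-averaged connectivity support matrix
#'
#' Averages the saliency map over the half-open sample interval
#' `[t0, t1)` and reshapes to M x M.  Averaging over the full range gives
#' the static connectivity support matrix of the epoch.  The operation is
#' linear in the saliency values.
#'
#' @param saliency a `"saliency_map"`.
#' @param t0,t1 half-open sample interval; defaults cover the full range.
#' @return a `"support_matrix"`.
#' @export
support_avg <- function(saliency, t0 = 1L, t1 = ncol(saliency$values) + 1L) {
  stopifnot(inherits(saliency, "saliency_map"))
  Tn <- ncol(saliency$values)
  t0 <- as.integer(t0); t1 <- as.integer(t1)
  if (t0 < 1L || t1 > Tn + 1L || t0 >= t1)
    stop("empty or out-of-range interval")
  cols <- t0:(t1 - 1L)
  avg <- rowMeans(saliency$values[, cols, drop = FALSE])
  new_support_matrix(unflatten_column(avg, saliency$M),
                     saliency$channel_names,
                     sprintf("t in [%d, %d)", t0, t1))
}

#' Average support matrices across epochs
#'
#' Simple elementwise mean of support matrices from several epochs -- the
#' basic cross-trial aggregation; inferential statistics across subjects or
#' groups are out of scope.
#'
#' @param matrices list of `"support_matrix"` objects of equal dimension.
#' @return a `"support_matrix"`.
#' @export
support_mean <- function(matrices) {
  stopifnot(length(matrices) >= 1L)
  acc <- Reduce(`+`, lapply(matrices, unclass)) / length(matrices)
  new_support_matrix(acc, rownames(matrices[[1]]),
                     sprintf("mean of %d epochs", length(matrices)))
}

#' Write a support matrix to CSV
#' @param m a `"support_matrix"`.
#' @param path output path; channel names become the header / first column.
#' @export
write_support_csv <- function(m, path) {
  utils::write.csv(as.data.frame(unclass(m)), path, row.names = TRUE)
  invisible(path)
}
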