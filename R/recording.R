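#' Multichannel recording container
#'
#' Light-weight container for a continuous multichannel signal: an M x T
#' numeric matrix (one row per channel), a sampling rate in Hz, unique
#' channel names and an optional event table used for epoching.
#'
#' @param signal numeric matrix, channels x time.
#' @param srate sampling rate in Hz.
#' @param channel_names character vector of length `nrow(signal)`; defaults
#'   to `"ch1" ... "chM"`.
#' @param events optional `data.frame` with columns `sample` (1-based index
#'   into the time axis) and `label`.
#' @return An object of class `"eeg_recording"`.
#' @export
eeg_recording <- function(signal, srate, channel_names = NULL, events = NULL) {
  signal <- as.matrix(signal)
  if (!is.numeric(signal)) stop("`signal` must be a numeric matrix")
  M <- nrow(signal); T_ <- ncol(signal)
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(M))
  channel_names <- as.character(channel_names)
  if (length(channel_names) != M) stop("need one channel name per row")
  if (anyDuplicated(channel_names)) stop("channel names must be unique")
  if (!is.numeric(srate) || length(srate) != 1L || srate <= 0)
    stop("`srate` must be a positive scalar (Hz)")
  if (!is.null(events)) {
    events <- as.data.frame(events)
    if (!all(c("sample", "label") %in% names(events)))
      stop("`events` needs columns `sample` and `label`")
    if (nrow(events) && (any(events$sample < 1) || any(events$sample > T_)))
      stop("event sample indices outside [1, T]")
  } else {
    events <- data.frame(sample = integer(0), label = character(0))
  }
  rownames(signal) <- channel_names
  structure(list(signal = signal, srate = srate,
                 channel_names = channel_names, events = events),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
              nrow(x$signal), ncol(x$signal), x$srate,
              ncol(x$signal) / x$srate, nrow(x$events)))
  cat("channels:", paste(utils::head(x$channel_names, 8), collapse = ", "),
      if (length(x$channel_names) > 8) "..." else "", "\n")
  invisible(x)
}

#' Labeled fixed-length epochs
#'
#' Holds event-locked epochs as an `n_epochs x M x (context + n_samples)`
#' array.  The first `context` samples of each epoch are pre-event history:
#' they provide the autoregressive lags so that innovation and influence
#' signals are defined from the first analysis sample onwards, and are
#' consumed (not returned) by [inflate_epoch()].
#'
#' @param data numeric array, `n_epochs x M x L`.
#' @param labels factor or vector of per-epoch class labels.
#' @param srate sampling rate in Hz.
#' @param channel_names character vector of length M.
#' @param context number of leading pre-event context samples per epoch.
#' @param t0 time (s) of the first post-context sample relative to the event.
#' @return An object of class `"epoch_set"`.
#' @export
epoch_set <- function(data, labels, srate, channel_names = NULL,
                      context = 0L, t0 = 0) {
  if (length(dim(data)) != 3L) stop("`data` must be n_epochs x M x L")
  n <- dim(data)[1]; M <- dim(data)[2]; L <- dim(data)[3]
  if (length(labels) != n) stop("one label per epoch required")
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(M))
  if (length(channel_names) != M) stop("need one channel name per channel")
  context <- as.integer(context)
  if (context < 0L || context >= L) stop("invalid context length")
  structure(list(data = data, labels = factor(labels), srate = srate,
                 channel_names = as.character(channel_names),
                 context = context, t0 = t0),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d epochs x %d channels x %d samples (+%d context) @ %g Hz\n",
              d[1], d[2], d[3] - x$context, x$context, x$srate))
  print(table(x$labels))
  invisible(x)
}

#' Number of epochs / channels helpers
#' @param x an `epoch_set`.
#' @export
n_epochs <- function(x) dim(x$data)[1]

#' Extract one epoch as a channels x time matrix
#' @param x an `epoch_set`.
#' @param i epoch index.
#' @param drop_context drop the leading context samples?
#' @return numeric matrix M x L.
#' @export
get_epoch <- function(x, i, drop_context = FALSE) {
  m <- x$data[i, , , drop = TRUE]
  if (is.null(dim(m))) m <- matrix(m, nrow = dim(x$data)[2])
  rownames(m) <- x$channel_names
  if (drop_context && x$context > 0L) m <- m[, -seq_len(x$context), drop = FALSE]
  m
}
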