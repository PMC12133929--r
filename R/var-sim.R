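# Coupled vector-autoregressive simulator.  The generator is the package's
# validation surface: it produces recordings with known directed couplings
# (optionally switching on only inside a sub-window of each epoch), so the
# decomposition, the classifier and the saliency maps can all be checked
# against a planted ground truth.

#' Specification of a stationary VAR process
#'
#' @param n_channels number of channels M.
#' @param order VAR order K.
#' @param coeffs numeric array K x M x M; `coeffs[k, i, j]` is the weight of
#'   `x_j(t - k)` in `x_i(t)`.
#' @param noise_sd innovation standard deviation(s); scalar or length M,
#'   all > 0.
#' @param n_samples number of samples T to return.
#' @param srate nominal sampling rate in Hz attached to simulated
#'   recordings.
#' @param seed integer seed; identical seeds give bit-identical recordings.
#' @return object of class `"var_spec"`.  Construction fails if the
#'   companion-matrix spectral radius is >= 1 (non-stationary process).
#' @export
var_spec <- function(n_channels, order, coeffs, noise_sd = 1,
                     n_samples, srate = 64, seed = NULL) {
  M <- as.integer(n_channels); K <- as.integer(order)
  coeffs <- array(coeffs, c(K, M, M))
  noise_sd <- rep_len(noise_sd, M)
  if (any(noise_sd <= 0)) stop("noise_sd must be positive for every channel")
  n_samples <- as.integer(n_samples)
  if (K >= n_samples) stop("VAR order must be smaller than the sample count")
  rho <- companion_radius(coeffs)
  if (rho >= 1)
    stop(sprintf("non-stationary VAR: companion spectral radius %.4f >= 1", rho))
  structure(list(n_channels = M, order = K, coeffs = coeffs,
                 noise_sd = noise_sd, n_samples = n_samples,
                 srate = srate, seed = seed, spectral_radius = rho),
            class = "var_spec")
}

companion_radius <- function(coeffs) {
  K <- dim(coeffs)[1]; M <- dim(coeffs)[2]
  C <- matrix(0, M * K, M * K)
  for (k in seq_len(K))
    C[seq_len(M), (k - 1) * M + seq_len(M)] <- coeffs[k, , ]
  if (K > 1)
    C[(M + 1):(M * K), seq_len(M * (K - 1))] <- diag(M * (K - 1))
  max(Mod(eigen(C, only.values = TRUE)$values))
}

#' Simulate a VAR recording
#'
#' Iterates the process with i.i.d. Gaussian innovations.  A burn-in of
#' `10 * order` samples (initialized from noise) is discarded so initial
#' transients never reach the returned segment.
#'
#' @param spec a [var_spec].
#' @param extra_coeff optional function `(t) -> K x M x M` additive
#'   coefficient perturbation at sample t of the returned segment (used by
#'   [make_switching_dataset()] for time-switching couplings).
#' @return an [eeg_recording] of `spec$n_samples` samples.
#' @export
simulate_var <- function(spec, extra_coeff = NULL) {
  stopifnot(inherits(spec, "var_spec"))
  M <- spec$n_channels; K <- spec$order; T_ <- spec$n_samples
  burn <- 10L * K
  total <- T_ + burn
  if (!is.null(spec$seed)) set.seed(spec$seed)
  x <- matrix(0, M, total)
  x[, seq_len(K)] <- stats::rnorm(M * K) * spec$noise_sd
  A <- lapply(seq_len(K), function(k) spec$coeffs[k, , , drop = TRUE])
  A <- lapply(A, function(a) matrix(a, M, M))
  for (t in (K + 1):total) {
    v <- stats::rnorm(M) * spec$noise_sd
    for (k in seq_len(K)) v <- v + A[[k]] %*% x[, t - k]
    if (!is.null(extra_coeff)) {
      trel <- t - burn
      if (trel >= 1L) {
        E <- extra_coeff(trel)
        if (!is.null(E)) for (k in seq_len(K))
          v <- v + matrix(E[k, , ], M, M) %*% x[, t - k]
      }
    }
    x[, t] <- v
  }
  eeg_recording(x[, (burn + 1):total, drop = FALSE], srate = spec$srate)
}

#' Specification of a planted-coupling classification dataset
#'
#' Defines two epoch populations that differ only by one directed coupling:
#' in "coupled" epochs the lag-1 coefficient of channel pair
#' (i <- j) is raised by `coupling_gain` inside the half-open active window
#' `[t_on, t_off)` (1-based, epoch-relative); "uncoupled" epochs come from
#' the unmodified base process.  This emulates task-related switching of a
#' directed interaction, with a known ground-truth mask for validating
#' localization.
#'
#' @param base a [var_spec]; its `n_samples` is ignored (epochs are
#'   simulated at `context_samples + epoch_length`).
#' @param planted_pair integer pair `c(i, j)`: influenced, influencing;
#'   `i != j`.
#' @param coupling_gain added lag-1 coefficient; the augmented process must
#'   remain stationary.
#' @param active_window integer pair `c(t_on, t_off)`, half-open, within
#'   `[1, epoch_length + 1]`.
#' @param epoch_length epoch length in samples (excluding context).
#' @param n_epochs_per_class epochs per class label.
#' @param context_samples pre-event history attached to each epoch; must be
#'   >= the analysis model order so influence signals cover the full epoch.
#' @param seed integer seed.
#' @return object of class `"switching_spec"`.
#' @export
switching_spec <- function(base, planted_pair = c(1L, 2L),
                           coupling_gain = 0.8,
                           active_window = c(33L, 97L),
                           epoch_length = 128L,
                           n_epochs_per_class = 50L,
                           context_samples = 8L,
                           seed = 1L) {
  stopifnot(inherits(base, "var_spec"))
  i <- as.integer(planted_pair[1]); j <- as.integer(planted_pair[2])
  if (i == j) stop("planted pair must be two distinct channels")
  M <- base$n_channels
  if (i > M || j > M) stop("planted pair outside the channel range")
  t_on <- as.integer(active_window[1]); t_off <- as.integer(active_window[2])
  epoch_length <- as.integer(epoch_length)
  if (!(1L <= t_on && t_on < t_off && t_off <= epoch_length + 1L))
    stop("active_window must satisfy 1 <= t_on < t_off <= epoch_length + 1")
  aug <- base$coeffs
  aug[1, i, j] <- aug[1, i, j] + coupling_gain
  rho <- companion_radius(aug)
  if (rho >= 1)
    stop(sprintf("coupling_gain makes the process non-stationary (radius %.4f)", rho))
  structure(list(base = base, planted_pair = c(i, j),
                 coupling_gain = coupling_gain,
                 active_window = c(t_on, t_off),
                 epoch_length = epoch_length,
                 n_epochs_per_class = as.integer(n_epochs_per_class),
                 context_samples = as.integer(context_samples),
                 seed = as.integer(seed)),
            class = "switching_spec")
}

#' Generate a labeled switching-coupling dataset
#'
#' Simulates `2 * n_epochs_per_class` independent epochs (each its own VAR
#' run with burn-in), half with the planted coupling active inside the
#' active window, half without.  Classes are exactly balanced by
#' construction.
#'
#' @param spec a [switching_spec].
#' @return list with `epochs` (an [epoch_set], labels `coupled` /
#'   `uncoupled`) and `ground_truth` (binary M x M x epoch_length mask, 1
#'   exactly at `[i, j, t_on:(t_off-1)]`).
#' @export
make_switching_dataset <- function(spec) {
  stopifnot(inherits(spec, "switching_spec"))
  base <- spec$base
  M <- base$n_channels; K <- base$order
  ctx <- spec$context_samples
  L <- ctx + spec$epoch_length
  n_per <- spec$n_epochs_per_class
  n <- 2L * n_per
  labels <- rep(c("coupled", "uncoupled"), each = n_per)

  i <- spec$planted_pair[1]; j <- spec$planted_pair[2]
  on <- spec$active_window[1]; off <- spec$active_window[2]
  E <- array(0, c(K, M, M)); E[1, i, j] <- spec$coupling_gain
  # active window is epoch-relative (after context)
  bump <- function(trel) {
    t_ep <- trel - ctx
    if (t_ep >= on && t_ep < off) E else NULL
  }

  set.seed(spec$seed)
  seeds <- sample.int(.Machine$integer.max, n)
  data <- array(NA_real_, c(n, M, L))
  for (k in seq_len(n)) {
    s <- var_spec(M, K, base$coeffs, base$noise_sd, n_samples = L,
                  srate = base$srate, seed = seeds[k])
    rec <- simulate_var(s, extra_coeff = if (labels[k] == "coupled") bump else NULL)
    data[k, , ] <- rec$signal
  }
  gt <- array(0L, c(M, M, spec$epoch_length))
  gt[i, j, on:(off - 1L)] <- 1L
  list(epochs = epoch_set(data, labels, srate = base$srate,
                          context = ctx, t0 = 0),
       ground_truth = gt)
}
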