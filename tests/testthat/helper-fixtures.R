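# Shared fixtures, generated in code at test time.

# a stationary 3-channel VAR spec with mild diagonal dynamics
base_var3 <- function(n_samples = 136, seed = 1) {
  var_spec(3, 1, coeffs = array(diag(0.5, 3), c(1, 3, 3)),
           n_samples = n_samples, srate = 64, seed = seed)
}

# unidirectional coupling j -> i: x_i(t) = ar_i x_i(t-1) + gain x_j(t-lag) + e
coupled_pair <- function(T_, ar_i = 0.1, ar_j = 0.3, gain = 0.5, lag = 2,
                         seed = 1) {
  set.seed(seed)
  xj <- if (ar_j > 0) as.numeric(stats::arima.sim(list(ar = ar_j), T_))
        else stats::rnorm(T_)
  e <- stats::rnorm(T_)
  xi <- numeric(T_)
  for (t in (lag + 1):T_) xi[t] <- ar_i * xi[t - 1] + gain * xj[t - lag] + e[t]
  list(xi = xi, xj = xj)
}

# small classifier configuration used by several tests
small_net_config <- function(n_channels = 9, n_samples = 96, n_classes = 2,
                             dropout = 0, n_epochs = 2, seed = 3, ...) {
  eegnet_config(n_channels, n_samples, n_classes, srate = 64,
                n_temporal_filters = 4, depth_multiplier = 2,
                n_separable_filters = 8, dropout = dropout,
                n_epochs = n_epochs, seed = seed, ...)
}

# minimal EDF writer (16-bit little-endian), for round-trip tests only
write_tiny_edf <- function(path, signal, srate, labels,
                           pmin = -200, pmax = 200) {
  M <- nrow(signal); T_ <- ncol(signal)
  record_dur <- 1
  spr <- srate * record_dur
  n_rec <- T_ %/% spr
  stopifnot(n_rec * spr == T_)
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(s, w) {
    s <- substr(as.character(s), 1, w)
    writeChar(formatC(s, width = -w), con, eos = NULL)
  }
  pad("0", 8); pad("patient", 80); pad("recording", 80)
  pad("01.01.20", 8); pad("00.00.00", 8)
  pad(256 * (1 + M), 8); pad("", 44); pad(n_rec, 8); pad(record_dur, 8)
  pad(M, 4)
  for (l in labels) pad(l, 16)
  for (i in 1:M) pad("transducer", 80)
  for (i in 1:M) pad("uV", 8)
  for (i in 1:M) pad(pmin, 8)
  for (i in 1:M) pad(pmax, 8)
  for (i in 1:M) pad(dmin, 8)
  for (i in 1:M) pad(dmax, 8)
  for (i in 1:M) pad("", 80)
  for (i in 1:M) pad(spr, 8)
  for (i in 1:M) pad("", 32)
  scale_ <- (dmax - dmin) / (pmax - pmin)
  for (r in seq_len(n_rec)) for (i in seq_len(M)) {
    seg <- signal[i, ((r - 1) * spr + 1):(r * spr)]
    dig <- as.integer(round(dmin + (seg - pmin) * scale_))
    writeBin(dig, con, size = 2, endian = "little")
  }
  invisible(path)
}
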