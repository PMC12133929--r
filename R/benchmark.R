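#' End-to-end switching-coupling benchmark
#'
#' The package's reference validation experiment, run end to end from one
#' seed: generate a planted switching-coupling dataset
#' ([make_switching_dataset()]), inflate every epoch
#' ([inflate_set()]), train the compact convolutional classifier on a
#' 70/30 split, measure held-out accuracy, and test whether the saliency
#' maps localize the planted directed coupling -- i.e. whether the planted
#' pair's flattened row carries more mean saliency inside the active window
#' than every other off-diagonal row.
#'
#' Study conditions (defaults): 3 channels of a diagonal VAR(1) (a = 0.5)
#' at 64 Hz, 2 s epochs, lag-1 coupling 1 <- 2 with gain 0.8 active during
#' 0.5--1.5 s, 50 epochs per class, model order 8 (125 ms), classifier with
#' 4 temporal filters x depth 2, 8 separable filters, Adam (2e-3) for 150
#' passes.  The vignette discusses these choices.
#'
#' @param seed integer; drives dataset generation, the split and the
#'   classifier.
#' @param coupling_gain planted lag-1 gain (0 gives a null dataset whose
#'   classes are statistically identical).
#' @param order autoregressive model order used for inflation (and epoch
#'   context length).
#' @param n_epochs_per_class epochs per class.
#' @param n_passes classifier training passes.
#' @param lr Adam learning rate.
#' @return list with `accuracy` (held-out), `n_test`, `n_correct`,
#'   `planted_row`, `planted_rank` (rank of the planted pair's row among
#'   all off-diagonal rows by mean in-window saliency; 1 = strongest),
#'   `n_offdiag`, `row_saliency` (mean in-window saliency per flattened
#'   row), `model`, `labels_test`, `predictions`.
#' @export
switching_benchmark <- function(seed = 1L, coupling_gain = 0.8,
                                order = 8L, n_epochs_per_class = 50L,
                                n_passes = 150L, lr = 2e-3) {
  M <- 3L; epoch_len <- 128L; srate <- 64
  active <- c(33L, 97L); pair <- c(1L, 2L)
  base <- var_spec(M, 1, coeffs = array(diag(0.5, M), c(1, M, M)),
                   n_samples = order + epoch_len, srate = srate, seed = 1)
  sp <- switching_spec(base, planted_pair = pair,
                       coupling_gain = coupling_gain,
                       active_window = active, epoch_length = epoch_len,
                       n_epochs_per_class = n_epochs_per_class,
                       context_samples = order, seed = seed)
  ds <- make_switching_dataset(sp)
  infl <- inflate_set(ds$epochs, order = order)

  n <- n_epochs(ds$epochs)
  set.seed(seed + 1000L)
  idx <- sample(n)
  n_tr <- round(0.7 * n)
  tr_i <- idx[seq_len(n_tr)]; te_i <- idx[(n_tr + 1L):n]

  cfg <- eegnet_config(M * M, epoch_len, 2, srate = srate,
                       n_temporal_filters = 4L, depth_multiplier = 2L,
                       n_separable_filters = 8L, dropout = 0.25,
                       n_epochs = n_passes, batch_size = 16L, lr = lr,
                       seed = seed)
  model <- eegnet_train(cfg, infl$data[tr_i, , ], infl$labels[tr_i])
  pred <- predict(model, infl$data[te_i, , ])
  acc <- mean(pred == infl$labels[te_i])

  # mean saliency per flattened row inside the active window, averaged over
  # the coupled test epochs, explanation targeted at the coupled class
  co <- te_i[infl$labels[te_i] == "coupled"]
  win <- active[1]:(active[2] - 1L)
  row_sal <- rowMeans(vapply(co, function(k)
    rowMeans(saliency_map(model, infl$data[k, , ],
                          target_class = "coupled")$values[, win]),
    numeric(M * M)))
  planted_row <- row_of(pair[1], pair[2], M)
  offdiag <- setdiff(seq_len(M * M), row_of(seq_len(M), seq_len(M), M))
  rk <- rank(-row_sal[offdiag])[match(planted_row, offdiag)]

  list(accuracy = acc, n_test = length(te_i),
       n_correct = sum(pred == infl$labels[te_i]),
       planted_row = planted_row, planted_rank = unname(rk),
       n_offdiag = length(offdiag), row_saliency = row_sal,
       model = model, labels_test = infl$labels[te_i], predictions = pred)
}
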