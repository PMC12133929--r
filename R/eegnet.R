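# Compact convolutional classifier in the EEGNet family, implemented in
# base R with exact, hand-derived backpropagation.  The architecture is the
# standard compact EEG pipeline: a temporal convolution whose kernel spans
# about half a second of signal, a depthwise "spatial" convolution across
# all input channels, a separable (depthwise temporal + pointwise)
# convolution, average pooling, and a dense softmax head.  Implementing the
# backward pass explicitly gives the gradient of any class score with
# respect to the input, which is the quantity the explanation stage
# consumes; the same machinery trains the network by Adam.
#
# Kernels are forced to odd lengths so that same-padding is symmetric and
# the adjoint of a convolution is convolution with the reversed kernel.

#' Classifier configuration
#'
#' @param n_channels input rows: M^2 for inflated data, M for raw EEG.
#' @param n_samples input columns T'.
#' @param n_classes number of classes.
#' @param srate sampling rate in Hz; sets the default temporal kernel.
#' @param temporal_kernel temporal kernel length in samples (default: the
#'   odd number nearest srate/2, i.e. about half a second of history).
#' @param n_temporal_filters,depth_multiplier,n_separable_filters filter
#'   counts of the three convolutional stages.
#' @param sep_kernel separable-stage depthwise kernel length (odd).
#' @param pool1,pool2 average-pooling factors after stages 2 and 3.
#' @param dropout dropout fraction applied after each pooling stage.
#' @param n_epochs,batch_size,lr training passes, minibatch size, Adam
#'   learning rate.
#' @param activation `"elu"` (default) or `"linear"` (no nonlinearity;
#'   mainly for diagnostics -- a linear network has an input-independent
#'   gradient).
#' @param seed RNG seed governing initialization, shuffling and dropout;
#'   fixed seed gives a bit-reproducible training history on one machine.
#' @return object of class `"eegnet_config"`.
#' @export
eegnet_config <- function(n_channels, n_samples, n_classes, srate,
                          temporal_kernel = NULL,
                          n_temporal_filters = 8L, depth_multiplier = 2L,
                          n_separable_filters = 16L, sep_kernel = 17L,
                          pool1 = 4L, pool2 = 8L, dropout = 0.25,
                          n_epochs = 40L, batch_size = 16L, lr = 1e-3,
                          activation = c("elu", "linear"), seed = 1L) {
  activation <- match.arg(activation)
  odd <- function(k) { k <- as.integer(k); if (k %% 2L == 0L) k + 1L else k }
  if (is.null(temporal_kernel)) temporal_kernel <- odd(round(srate / 2))
  temporal_kernel <- odd(temporal_kernel)
  sep_kernel <- odd(sep_kernel)
  if (temporal_kernel > n_samples)
    stop("temporal kernel longer than the input")
  counts <- c(n_channels, n_samples, n_classes, n_temporal_filters,
              depth_multiplier, n_separable_filters, pool1, pool2,
              batch_size, n_epochs)
  if (any(counts < 1)) stop("all counts must be >= 1")
  T1 <- n_samples %/% pool1
  T2 <- T1 %/% pool2
  if (T2 < 1) stop("pooling factors leave no time samples")
  if (sep_kernel > T1) sep_kernel <- odd(max(3L, T1 - 1L))
  structure(list(n_channels = as.integer(n_channels),
                 n_samples = as.integer(n_samples),
                 n_classes = as.integer(n_classes), srate = srate,
                 temporal_kernel = temporal_kernel,
                 n_temporal_filters = as.integer(n_temporal_filters),
                 depth_multiplier = as.integer(depth_multiplier),
                 n_separable_filters = as.integer(n_separable_filters),
                 sep_kernel = sep_kernel,
                 pool1 = as.integer(pool1), pool2 = as.integer(pool2),
                 T1 = as.integer(T1), T2 = as.integer(T2),
                 dropout = dropout, n_epochs = as.integer(n_epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 activation = activation, seed = as.integer(seed)),
            class = "eegnet_config")
}

# same-padding embedding: E[l, t] = xpad[t + l - 1], pad = (L-1)/2 zeros
# on each side; conv is then k %*% E.
embed_same <- function(x, L) {
  T_ <- length(x); pad <- (L - 1L) %/% 2L
  xp <- c(numeric(pad), x, numeric(pad))
  matrix(xp[outer(seq_len(L), 0:(T_ - 1L), "+")], L, T_)
}

avgpool_matrix <- function(T_, p) {
  Tp <- T_ %/% p
  PM <- matrix(0, T_, Tp)
  for (k in seq_len(Tp)) PM[((k - 1L) * p + 1L):(k * p), k] <- 1 / p
  PM
}

act_fun <- function(x, kind) {
  if (kind == "linear") return(x)
  ifelse(x > 0, x, exp(pmin(x, 0)) - 1)          # ELU, alpha = 1
}
act_grad <- function(x, kind) {
  if (kind == "linear") return(array(1, dim(x)))
  ifelse(x > 0, 1, exp(pmin(x, 0)))
}

init_params <- function(cfg) {
  F1 <- cfg$n_temporal_filters; D <- cfg$depth_multiplier
  F2 <- cfg$n_separable_filters; C <- cfg$n_channels
  L1 <- cfg$temporal_kernel; L2 <- cfg$sep_kernel
  g <- function(n, s) stats::rnorm(n) * s
  list(K1 = matrix(g(F1 * L1, sqrt(2 / L1)), F1, L1),
       Wsp = matrix(g(C * F1 * D, sqrt(2 / C)), C, F1 * D),
       K2 = matrix(g(F1 * D * L2, sqrt(2 / L2)), F1 * D, L2),
       P = matrix(g(F2 * F1 * D, sqrt(2 / (F1 * D))), F2, F1 * D),
       b2 = numeric(F2),
       W = matrix(g(cfg$n_classes * F2 * cfg$T2, 0.01),
                  cfg$n_classes, F2 * cfg$T2),
       b = numeric(cfg$n_classes))
}

zero_like <- function(p) lapply(p, function(a) { a[] <- 0; a })

# forward pass for one standardized sample x (C x T).  masks = NULL means
# evaluation mode (no dropout).  Returns logits plus every intermediate the
# backward pass needs.
net_forward <- function(par, x, cfg, pm, masks = NULL) {
  F1 <- cfg$n_temporal_filters; D <- cfg$depth_multiplier
  C <- cfg$n_channels; T_ <- cfg$n_samples
  H <- array(0, c(F1, C, T_))
  for (c_ in seq_len(C))
    H[, c_, ] <- par$K1 %*% embed_same(x[c_, ], cfg$temporal_kernel)
  Z <- matrix(0, F1 * D, T_)
  for (f in seq_len(F1)) {
    cols <- ((f - 1L) * D + 1L):(f * D)
    Z[cols, ] <- t(par$Wsp[, cols, drop = FALSE]) %*% H[f, , ]
  }
  A1 <- act_fun(Z, cfg$activation)
  P1 <- A1 %*% pm$PM1
  P1d <- if (is.null(masks)) P1 else P1 * masks$m1 / (1 - cfg$dropout)
  S <- matrix(0, F1 * D, cfg$T1)
  for (ch in seq_len(F1 * D))
    S[ch, ] <- par$K2[ch, ] %*% embed_same(P1d[ch, ], cfg$sep_kernel)
  U <- par$P %*% S + par$b2
  A2 <- act_fun(U, cfg$activation)
  P2 <- A2 %*% pm$PM2
  P2d <- if (is.null(masks)) P2 else P2 * masks$m2 / (1 - cfg$dropout)
  v <- as.vector(P2d)
  logits <- as.vector(par$W %*% v + par$b)
  list(logits = logits, x = x, H = H, Z = Z, P1 = P1, P1d = P1d, S = S,
       U = U, P2 = P2, P2d = P2d, v = v, masks = masks)
}

# backward pass: given d(loss)/d(logits), returns parameter gradients and
# the gradient with respect to the (standardized) input.
net_backward <- function(par, fwd, dlogits, cfg, pm, want_input = FALSE) {
  F1 <- cfg$n_temporal_filters; D <- cfg$depth_multiplier
  C <- cfg$n_channels; L1 <- cfg$temporal_kernel; L2 <- cfg$sep_kernel
  g <- zero_like(par)
  g$W <- dlogits %o% fwd$v
  g$b <- dlogits
  dv <- as.vector(t(par$W) %*% dlogits)
  dP2d <- matrix(dv, cfg$n_separable_filters, cfg$T2)
  dP2 <- if (is.null(fwd$masks)) dP2d else
    dP2d * fwd$masks$m2 / (1 - cfg$dropout)
  dA2 <- dP2 %*% t(pm$PM2)
  dU <- dA2 * act_grad(fwd$U, cfg$activation)
  g$P <- dU %*% t(fwd$S)
  g$b2 <- rowSums(dU)
  dS <- t(par$P) %*% dU
  dP1d <- matrix(0, F1 * D, cfg$T1)
  for (ch in seq_len(F1 * D)) {
    g$K2[ch, ] <- as.vector(embed_same(fwd$P1d[ch, ], L2) %*% dS[ch, ])
    dP1d[ch, ] <- rev(par$K2[ch, ]) %*% embed_same(dS[ch, ], L2)
  }
  dP1 <- if (is.null(fwd$masks)) dP1d else
    dP1d * fwd$masks$m1 / (1 - cfg$dropout)
  dA1 <- dP1 %*% t(pm$PM1)
  dZ <- dA1 * act_grad(fwd$Z, cfg$activation)
  dH <- array(0, dim(fwd$H))
  for (f in seq_len(F1)) {
    cols <- ((f - 1L) * D + 1L):(f * D)
    dH[f, , ] <- par$Wsp[, cols, drop = FALSE] %*% dZ[cols, , drop = FALSE]
    g$Wsp[, cols] <- fwd$H[f, , ] %*% t(dZ[cols, , drop = FALSE])
  }
  dX <- NULL
  if (want_input) dX <- matrix(0, C, cfg$n_samples)
  K1rev <- par$K1[, L1:1, drop = FALSE]
  for (c_ in seq_len(C)) {
    dHc <- matrix(dH[, c_, ], F1, cfg$n_samples)
    g$K1 <- g$K1 + dHc %*% t(embed_same(fwd$x[c_, ], L1))
    if (want_input) {
      acc <- numeric(cfg$n_samples)
      for (f in seq_len(F1))
        acc <- acc + as.vector(K1rev[f, ] %*% embed_same(dHc[f, ], L1))
      dX[c_, ] <- acc
    }
  }
  list(grads = g, dX = dX)
}

softmax <- function(z) { z <- z - max(z); e <- exp(z); e / sum(e) }

#' Build an (untrained) classifier
#'
#' Initializes the network parameters from the configuration's seed.  The
#' untrained model already supports [predict.eegnet()] and
#' [input_gradient()]; on balanced data its accuracy sits at chance.
#'
#' @param config an [eegnet_config].
#' @param labels optional label vocabulary (character); defaults to
#'   `"class1" ... "classK"` until training replaces it.
#' @return object of class `"eegnet"`.
#' @export
eegnet_build <- function(config, labels = NULL) {
  stopifnot(inherits(config, "eegnet_config"))
  set.seed(config$seed)
  if (is.null(labels)) labels <- paste0("class", seq_len(config$n_classes))
  structure(list(config = config, params = init_params(config),
                 labels = labels,
                 standardize = list(mu = numeric(config$n_channels),
                                    sd = rep(1, config$n_channels)),
                 history = data.frame(epoch = integer(0), loss = numeric(0),
                                      accuracy = numeric(0)),
                 trained = FALSE),
            class = "eegnet")
}

#' @export
print.eegnet <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<eegnet> %d x %d input, %d classes, kernels %d/%d, %s\n",
              cfg$n_channels, cfg$n_samples, cfg$n_classes,
              cfg$temporal_kernel, cfg$sep_kernel,
              if (x$trained) sprintf("trained (%d passes, final loss %.4f)",
                                     nrow(x$history),
                                     utils::tail(x$history$loss, 1))
              else "untrained"))
  invisible(x)
}

as_input_array <- function(x) {
  if (is.matrix(x)) x <- array(x, c(1, dim(x)))
  if (length(dim(x)) != 3L) stop("input must be n x channels x samples")
  x
}

#' Train the classifier
#'
#' Minimizes softmax cross-entropy by Adam on minibatches.  Per-channel
#' standardization statistics (mean, sd over all training samples and time
#' points) are computed from the training data only and stored in the
#' model; influence signals span orders of magnitude across pairs, so
#' unstandardized inputs would swamp the early layers.
#'
#' @param model an `"eegnet"` from [eegnet_build()], or an
#'   [eegnet_config] (a model is built from it).
#' @param x training inputs, `n x n_channels x n_samples` array (a single
#'   `channels x samples` matrix is promoted).
#' @param y per-sample labels (factor or character); at least two distinct
#'   classes required.
#' @return the trained `"eegnet"`, with `history` (per-pass loss and
#'   training accuracy).
#' @export
eegnet_train <- function(model, x, y) {
  if (inherits(model, "eegnet_config")) model <- eegnet_build(model)
  stopifnot(inherits(model, "eegnet"))
  cfg <- model$config
  x <- as_input_array(x)
  n <- dim(x)[1]
  if (dim(x)[2] != cfg$n_channels || dim(x)[3] != cfg$n_samples)
    stop("input shape does not match the configuration")
  y <- factor(y)
  if (nlevels(y) < 2L) stop("training data contain a single class")
  if (nlevels(y) != cfg$n_classes)
    stop(sprintf("found %d classes but the model was configured for %d",
                 nlevels(y), cfg$n_classes))
  yi <- as.integer(y)

  # training-set standardization only; evaluation data never touch these
  mu <- apply(x, 2, mean)
  sd_ <- apply(x, 2, stats::sd)
  sd_[sd_ == 0] <- 1
  model$standardize <- list(mu = mu, sd = sd_)
  xs <- sweep(sweep(x, 2, mu, "-"), 2, sd_, "/")

  set.seed(cfg$seed)
  par <- init_params(cfg)
  mstate <- zero_like(par); vstate <- zero_like(par)
  beta1 <- 0.9; beta2 <- 0.999; epsb <- 1e-8; step <- 0L
  pm <- list(PM1 = avgpool_matrix(cfg$n_samples, cfg$pool1),
             PM2 = avgpool_matrix(cfg$T1, cfg$pool2))
  FD <- cfg$n_temporal_filters * cfg$depth_multiplier
  hist_ep <- integer(0); hist_loss <- numeric(0); hist_acc <- numeric(0)

  for (ep in seq_len(cfg$n_epochs)) {
    idx <- sample.int(n)
    losses <- numeric(0); correct <- 0L
    for (b0 in seq(1L, n, by = cfg$batch_size)) {
      batch <- idx[b0:min(b0 + cfg$batch_size - 1L, n)]
      g <- zero_like(par)
      for (k in batch) {
        masks <- if (cfg$dropout > 0)
          list(m1 = matrix(stats::runif(FD * cfg$T1) > cfg$dropout,
                           FD, cfg$T1),
               m2 = matrix(stats::runif(cfg$n_separable_filters * cfg$T2) >
                             cfg$dropout,
                           cfg$n_separable_filters, cfg$T2))
        else NULL
        fwd <- net_forward(par, matrix(xs[k, , ], cfg$n_channels), cfg, pm,
                           masks)
        p <- softmax(fwd$logits)
        losses <- c(losses, -log(max(p[yi[k]], 1e-12)))
        correct <- correct + (which.max(p) == yi[k])
        dlog <- p; dlog[yi[k]] <- dlog[yi[k]] - 1
        bw <- net_backward(par, fwd, dlog / length(batch), cfg, pm)
        for (nm in names(g)) g[[nm]] <- g[[nm]] + bw$grads[[nm]]
      }
      step <- step + 1L
      for (nm in names(par)) {
        mstate[[nm]] <- beta1 * mstate[[nm]] + (1 - beta1) * g[[nm]]
        vstate[[nm]] <- beta2 * vstate[[nm]] + (1 - beta2) * g[[nm]]^2
        mh <- mstate[[nm]] / (1 - beta1^step)
        vh <- vstate[[nm]] / (1 - beta2^step)
        par[[nm]] <- par[[nm]] - cfg$lr * mh / (sqrt(vh) + epsb)
      }
    }
    hist_ep <- c(hist_ep, ep)
    hist_loss <- c(hist_loss, mean(losses))
    hist_acc <- c(hist_acc, correct / n)
  }
  model$params <- par
  model$labels <- levels(y)
  model$history <- data.frame(epoch = hist_ep, loss = hist_loss,
                              accuracy = hist_acc)
  model$trained <- TRUE
  model
}

#' Predict classes or class probabilities
#'
#' @param object an `"eegnet"`.
#' @param x `n x channels x samples` array (or one `channels x samples`
#'   matrix).
#' @param type `"class"` for labels, `"prob"` for the softmax matrix.
#' @param ... unused.
#' @return factor of predicted labels, or an `n x n_classes` probability
#'   matrix (rows sum to 1).
#' @export
predict.eegnet <- function(object, x, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  cfg <- object$config
  x <- as_input_array(x)
  xs <- sweep(sweep(x, 2, object$standardize$mu, "-"),
              2, object$standardize$sd, "/")
  pm <- list(PM1 = avgpool_matrix(cfg$n_samples, cfg$pool1),
             PM2 = avgpool_matrix(cfg$T1, cfg$pool2))
  probs <- t(vapply(seq_len(dim(x)[1]), function(k)
    softmax(net_forward(object$params,
                        matrix(xs[k, , ], cfg$n_channels),
                        cfg, pm)$logits),
    numeric(cfg$n_classes)))
  colnames(probs) <- object$labels
  if (type == "prob") return(probs)
  factor(object$labels[max.col(probs)], levels = object$labels)
}

#' Gradient of a class score with respect to the input
#'
#' Backpropagates the pre-softmax score (logit) of the target class down to
#' the raw input.  The logit, not the softmax probability, is
#' differentiated: the softmax saturates once the model is confident and
#' its gradient vanishes, while the logit keeps a usable signal.  Dropout
#' is disabled (evaluation mode), so the gradient is deterministic.
#'
#' @param model a (typically trained) `"eegnet"`.
#' @param x one input, `channels x samples` matrix (raw scale; the model's
#'   stored standardization is applied internally).
#' @param target_class label (as in the model vocabulary) or class index;
#'   `NULL` uses the predicted class.
#' @param scale `"raw"` (default) chains through the stored per-channel
#'   standardization, giving the derivative with respect to the data as
#'   passed in; `"input"` returns the derivative with respect to the
#'   network's input tensor (the standardized data), the conventional scale
#'   for saliency maps -- on the raw scale low-variance channels are
#'   amplified by 1/sd, which distorts importance comparisons across
#'   channels.
#' @return list with `gradient` (same shape as `x`), `target_class`,
#'   `logits`.
#' @export
input_gradient <- function(model, x, target_class = NULL,
                           scale = c("raw", "input")) {
  scale <- match.arg(scale)
  stopifnot(inherits(model, "eegnet"))
  cfg <- model$config
  x <- as.matrix(x)
  if (!all(dim(x) == c(cfg$n_channels, cfg$n_samples)))
    stop("input shape does not match the configuration")
  xs <- (x - model$standardize$mu) / model$standardize$sd
  pm <- list(PM1 = avgpool_matrix(cfg$n_samples, cfg$pool1),
             PM2 = avgpool_matrix(cfg$T1, cfg$pool2))
  fwd <- net_forward(model$params, xs, cfg, pm)
  if (is.null(target_class)) {
    ci <- which.max(fwd$logits)
  } else if (is.numeric(target_class)) {
    ci <- as.integer(target_class)
    if (ci < 1L || ci > cfg$n_classes) stop("unknown class index")
  } else {
    ci <- match(as.character(target_class), model$labels)
    if (is.na(ci)) stop(sprintf("unknown class label '%s'", target_class))
  }
  dlog <- numeric(cfg$n_classes); dlog[ci] <- 1
  bw <- net_backward(model$params, fwd, dlog, cfg, pm, want_input = TRUE)
  grad <- if (scale == "raw") bw$dX / model$standardize$sd else bw$dX
  dimnames(grad) <- dimnames(x)
  list(gradient = grad, target_class = model$labels[ci],
       logits = fwd$logits)
}
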