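# Readers, writers and preprocessing.  EDF files are read with a minimal
# purpose-built parser (header + 16-bit little-endian sample records, scaled
# to physical units); no EDF reading package is depended on.  The package's
# own array container is R-native serialization of the recording / epoch
# structures with a documented layout (signal, labels, meta), written next
# to a JSON index-map sidecar where a flattened layout is involved.

#' Read a multichannel recording from disk
#'
#' Supports EDF (European Data Format, read-only; annotation channels are
#' skipped) and the package's R-native container written by
#' [write_recording()].
#'
#' @param path file path; format inferred from the extension (`.edf` or
#'   `.rds`) unless given.
#' @param format `"auto"`, `"edf"` or `"container"`.
#' @param channels optional channel-name subset (e.g. the 19 names of
#'   [montage_1020()]); unknown names raise an error listing what is
#'   available.
#' @return an [eeg_recording].
#' @export
read_recording <- function(path, format = c("auto", "edf", "container"),
                           channels = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf"
              else "container"
  rec <- if (format == "edf") read_edf(path) else {
    obj <- readRDS(path)
    if (!inherits(obj, "eeg_recording"))
      stop(sprintf("parse error: %s does not contain a recording", path))
    obj
  }
  if (!is.null(channels)) {
    miss <- setdiff(channels, rec$channel_names)
    if (length(miss))
      stop(sprintf("unknown channel(s) %s; available: %s",
                   paste(miss, collapse = ", "),
                   paste(rec$channel_names, collapse = ", ")))
    keep <- match(channels, rec$channel_names)
    rec <- eeg_recording(rec$signal[keep, , drop = FALSE], rec$srate,
                         channels, rec$events)
  }
  rec
}

#' Write a recording to the package's array container
#' @param rec an [eeg_recording].
#' @param path output path (`.rds`).
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  saveRDS(rec, path)
  invisible(path)
}

#' Write / read an epoch set (with labels and metadata)
#' @param x an [epoch_set]; for `read_epochs`, a path.
#' @param path output path (`.rds`).
#' @rdname epoch_io
#' @export
write_epochs <- function(x, path) {
  stopifnot(inherits(x, "epoch_set"))
  saveRDS(x, path)
  invisible(path)
}

#' @param path container path.
#' @rdname epoch_io
#' @export
read_epochs <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "epoch_set"))
    stop(sprintf("parse error: %s does not contain an epoch set", path))
  obj
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) {
    out <- rawToChar(readBin(con, "raw", n))
    trimws(out)
  }
  version <- rd(8)
  if (!nzchar(version)) stop(sprintf("parse error in %s: empty EDF header", path))
  rd(80); rd(80); rd(8); rd(8)                 # patient, recording, date, time
  header_bytes <- suppressWarnings(as.integer(rd(8)))
  rd(44)                                       # reserved
  n_records <- suppressWarnings(as.integer(rd(8)))
  record_dur <- suppressWarnings(as.numeric(rd(8)))
  ns <- suppressWarnings(as.integer(rd(4)))
  if (anyNA(c(header_bytes, n_records, record_dur, ns)) || ns < 1)
    stop(sprintf("parse error in %s: malformed EDF header", path))
  fld <- function(w) vapply(seq_len(ns), function(i) rd(w), character(1))
  labels <- fld(16)
  fld(80); fld(8)                              # transducer, physical dim
  pmin_ <- as.numeric(fld(8)); pmax_ <- as.numeric(fld(8))
  dmin_ <- as.numeric(fld(8)); dmax_ <- as.numeric(fld(8))
  fld(80)                                      # prefiltering
  nspr <- as.integer(fld(8))                   # samples per record
  fld(32)                                      # reserved
  keep <- !grepl("annotation", labels, ignore.case = TRUE)
  if (!any(keep)) stop(sprintf("no signal channels in %s", path))
  if (length(unique(nspr[keep])) != 1L)
    stop("EDF channels with differing sampling rates are not supported")
  spr <- nspr[keep][1]
  srate <- spr / record_dur
  scale_ <- (pmax_ - pmin_) / (dmax_ - dmin_)
  sig <- matrix(NA_real_, sum(keep), n_records * spr)
  ki <- which(keep)
  for (r in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      raw_s <- readBin(con, "integer", n = nspr[s], size = 2,
                       endian = "little", signed = TRUE)
      if (length(raw_s) < nspr[s])
        stop(sprintf("parse error in %s: truncated data record %d", path, r))
      k <- match(s, ki)
      if (!is.na(k))
        sig[k, ((r - 1) * spr + 1):(r * spr)] <-
          pmin_[s] + (raw_s - dmin_[s]) * scale_[s]
    }
  }
  eeg_recording(sig, srate, make.unique(labels[keep]))
}

#' Average rereference
#'
#' Subtracts, at every time sample, the instantaneous mean across channels;
#' after the operation each column of the signal sums to zero.  The
#' standard EEG reference-free transformation applied before model fitting.
#'
#' @param rec an [eeg_recording] (M >= 2 channels).
#' @return the rereferenced recording.
#' @export
average_rereference <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(rec$signal) < 2L) stop("average reference needs at least 2 channels")
  rec$signal <- sweep(rec$signal, 2, colMeans(rec$signal))
  rec
}

#' Extract event-locked epochs
#'
#' Cuts fixed-length epochs around events: the analysis window is the
#' half-open interval `[tmin, tmax)` seconds relative to each event
#' (`round((tmax - tmin) * srate)` samples), preceded by `context_samples`
#' of additional history for the autoregressive lags.  Epochs whose full
#' window (including context) falls outside the recording are dropped and
#' counted in a message.
#'
#' @param rec an [eeg_recording] with events.
#' @param event_labels labels to keep; `NULL` keeps all.
#' @param tmin,tmax window in seconds relative to the event (tmin < tmax;
#'   event at t = 0).
#' @param context_samples pre-window history samples per epoch.
#' @return an [epoch_set]; its labels are the event labels.
#' @export
extract_epochs <- function(rec, event_labels = NULL, tmin = -0.2, tmax = 3.0,
                           context_samples = 0L) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (tmin >= tmax) stop("tmin must be smaller than tmax")
  ev <- rec$events
  if (!is.null(event_labels)) ev <- ev[ev$label %in% event_labels, , drop = FALSE]
  if (nrow(ev) == 0L) stop("no matching events")
  fs <- rec$srate
  len <- as.integer(round((tmax - tmin) * fs))
  off <- as.integer(round(tmin * fs))
  ctx <- as.integer(context_samples)
  T_ <- ncol(rec$signal)
  starts <- ev$sample + off - ctx
  ok <- starts >= 1L & (starts + ctx + len - 1L) <= T_
  if (any(!ok))
    message(sprintf("dropped %d epoch(s) exceeding the recording bounds",
                    sum(!ok)))
  ev <- ev[ok, , drop = FALSE]; starts <- starts[ok]
  if (nrow(ev) == 0L) stop("all epochs exceed the recording bounds")
  data <- array(NA_real_, c(nrow(ev), nrow(rec$signal), ctx + len))
  for (k in seq_len(nrow(ev)))
    data[k, , ] <- rec$signal[, starts[k]:(starts[k] + ctx + len - 1L)]
  epoch_set(data, ev$label, fs, rec$channel_names, context = ctx, t0 = tmin)
}

#' Grouped train/test split
#'
#' Random split at the group level (subjects or sessions): all epochs of a
#' group land on the same side, preventing leakage of subject-specific
#' signal into the evaluation set.
#'
#' @param groups per-epoch group identifiers.
#' @param train_frac fraction of groups assigned to training (default 0.7).
#' @param seed RNG seed.
#' @return list with integer index vectors `train` and `test` and the seed
#'   (recorded for the audit trail).
#' @export
split_by_group <- function(groups, train_frac = 0.7, seed = 1L) {
  g <- unique(groups)
  set.seed(seed)
  n_train <- max(1L, round(train_frac * length(g)))
  tr_g <- sample(g, n_train)
  list(train = which(groups %in% tr_g),
       test = which(!groups %in% tr_g),
       train_groups = tr_g, seed = seed)
}

#' Content fingerprint and pipeline audit record
#'
#' Collects the information needed to reproduce an analysis byte-for-byte:
#' a content fingerprint of the data (dimensions and moment sums), the
#' split assignment and its seed, the model order and fitting scope, and
#' the classifier seed.
#'
#' @param data numeric array whose fingerprint is recorded.
#' @param split result of [split_by_group()], optional.
#' @param fit a `"didi"` fit or [inflate_set()] result, optional.
#' @param model an `"eegnet"`, optional.
#' @return a list of class `"didi_audit"`; print method shows it compactly.
#' @export
audit_record <- function(data = NULL, split = NULL, fit = NULL,
                         model = NULL) {
  fp <- NULL
  if (!is.null(data))
    fp <- paste(c(dim(data), format(sum(data), digits = 17),
                  format(sum(data^2), digits = 17)), collapse = ":")
  out <- list(data_fingerprint = fp,
              split_seed = split$seed, n_train = length(split$train),
              n_test = length(split$test),
              order = if (!is.null(fit)) fit$order,
              fit_scope = if (!is.null(fit)) fit$fit_scope %||% fit$scope,
              classifier_seed = if (!is.null(model)) model$config$seed,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  structure(out, class = "didi_audit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.didi_audit <- function(x, ...) {
  cat("<didi_audit>\n")
  for (nm in names(x)) if (!is.null(x[[nm]]))
    cat(sprintf("  %-18s %s\n", nm, paste(x[[nm]], collapse = ",")))
  invisible(x)
}
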