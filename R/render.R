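# Electrode-map rendering of connectivity support.  Pure base graphics:
# a schematic head (circle, nose, ears), electrodes at their 2D montage
# positions, directed arrows j -> i for the strongest off-diagonal cells
# (width proportional to support) and electrode circles whose radius tracks
# the diagonal support.  Rendering is deterministic: the same matrix,
# montage and parameters always produce the same drawing commands.

#' Bundled 19-channel 10-20 montage
#'
#' Schematic 2D positions (head of unit radius, nose up) for the 19
#' electrodes of the international 10-20 placement system.
#'
#' @return data.frame with columns `name`, `x`, `y`.
#' @export
montage_1020 <- function() {
  path <- system.file("extdata", "montage_1020.csv", package = "didi")
  if (!nzchar(path)) stop("bundled montage not found")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Evenly spaced circular montage for arbitrary channel names
#'
#' Fallback layout for data whose channels are not scalp electrodes (e.g.
#' simulated recordings): positions evenly spaced on a circle of radius
#' 0.8, first channel at the top, clockwise.
#'
#' @param channel_names character vector.
#' @return data.frame with columns `name`, `x`, `y`.
#' @export
circular_montage <- function(channel_names) {
  n <- length(channel_names)
  th <- pi / 2 - 2 * pi * (seq_len(n) - 1) / n
  data.frame(name = channel_names, x = 0.8 * cos(th), y = 0.8 * sin(th))
}

montage_lookup <- function(montage, names_needed) {
  idx <- match(names_needed, montage$name)
  if (anyNA(idx))
    stop(sprintf("montage has no position for channel(s): %s",
                 paste(names_needed[is.na(idx)], collapse = ", ")))
  montage[idx, , drop = FALSE]
}

draw_head <- function() {
  th <- seq(0, 2 * pi, length.out = 181)
  graphics::plot(cos(th), sin(th), type = "l", asp = 1, axes = FALSE,
                 xlab = "", ylab = "", xlim = c(-1.35, 1.35),
                 ylim = c(-1.25, 1.45))
  graphics::lines(c(-0.1, 0, 0.1), c(0.995, 1.12, 0.995))          # nose
  phi <- seq(-0.4 * pi, 0.4 * pi, length.out = 41)
  graphics::lines(-1 - 0.08 * cos(phi), 0.35 * sin(phi))           # ears
  graphics::lines(1 + 0.08 * cos(phi), 0.35 * sin(phi))
}

#' Render a connectivity support map on the electrode montage
#'
#' Draws the head outline with electrodes at their montage positions; the
#' `top_k` largest off-diagonal cells become directed arrows from the
#' influencing to the influenced electrode with line width proportional to
#' their value, and each electrode's circle radius is proportional to its
#' diagonal (process) support.  Widths and radii are normalized to the
#' maximum displayed value, so maps are comparable only under a shared
#' `scale_max`.
#'
#' @param m a `"support_matrix"` (or plain M x M matrix with channel-name
#'   dimnames).
#' @param montage data.frame with `name`, `x`, `y` covering all channels;
#'   default the bundled 10-20 montage.
#' @param top_k number of arrows to draw (default 20 keeps maps legible).
#' @param scale_max value mapped to the maximal width/radius; `NULL` uses
#'   the matrix's own maximum (per-figure normalization).
#' @param file optional PNG path; when given the figure is written there
#'   (480 x 480 px) instead of the active device.
#' @param main plot title.
#' @return invisibly, a data.frame of the arrows drawn (`from`, `to`,
#'   `value`).
#' @export
render_support_map <- function(m, montage = montage_1020(), top_k = 20L,
                               scale_max = NULL, file = NULL, main = NULL) {
  m <- unclass(m)
  ch <- rownames(m)
  if (is.null(ch)) stop("support matrix needs channel-name dimnames")
  pos <- montage_lookup(montage, ch)
  M <- nrow(m)
  off <- m; diag(off) <- NA
  vals <- off[!is.na(off)]
  if (is.null(scale_max)) scale_max <- max(m, 0)
  if (scale_max <= 0) scale_max <- 1
  ord <- order(off, decreasing = TRUE, na.last = NA)
  keep <- utils::head(ord[off[ord] > 0], top_k)

  if (!is.null(file)) {
    grDevices::png(file, width = 480, height = 480)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  op <- graphics::par(mar = c(0.5, 0.5, if (is.null(main)) 0.5 else 2, 0.5))
  on.exit(graphics::par(op), add = TRUE)
  draw_head()
  if (!is.null(main)) graphics::title(main)
  arrows_df <- data.frame(from = character(0), to = character(0),
                          value = numeric(0))
  for (cell in keep) {
    i <- ((cell - 1L) %% M) + 1L   # row index (influenced)
    j <- ((cell - 1L) %/% M) + 1L  # column index (influencing)
    w <- 0.5 + 4 * off[cell] / scale_max
    graphics::arrows(pos$x[j], pos$y[j], pos$x[i], pos$y[i],
                     lwd = w, length = 0.09, col = "#B2182B")
    arrows_df <- rbind(arrows_df,
                       data.frame(from = ch[j], to = ch[i],
                                  value = off[cell]))
  }
  r <- 0.035 + 0.07 * diag(m) / scale_max
  graphics::symbols(pos$x, pos$y, circles = r, inches = FALSE, add = TRUE,
                    bg = "#F0F0F0", fg = "black")
  graphics::text(pos$x, pos$y, ch, cex = 0.55)
  invisible(arrows_df)
}

#' Export a saliency map as a video frame sequence
#'
#' Writes one rendered support map per time sample (optionally strided) as
#' numbered PNG frames with a global normalization, so frames are directly
#' comparable and can be assembled into a video with any external encoder
#' (e.g. `ffmpeg -i frame_%04d.png out.mp4`).
#'
#' @param saliency a `"saliency_map"`.
#' @param montage electrode montage (see [render_support_map()]).
#' @param dir output directory (created if missing).
#' @param stride render every `stride`-th sample.
#' @param top_k arrows per frame.
#' @return character vector of the frame files written, in order.
#' @export
export_frames <- function(saliency, montage = montage_1020(), dir,
                          stride = 1L, top_k = 20L) {
  stopifnot(inherits(saliency, "saliency_map"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ts <- seq(1L, ncol(saliency$values), by = stride)
  global_max <- max(saliency$values)
  files <- character(length(ts))
  for (k in seq_along(ts)) {
    files[k] <- file.path(dir, sprintf("frame_%04d.png", k))
    lab <- if (is.finite(saliency$srate))
      sprintf("t = %.3f s", saliency$t0 + (ts[k] - 1) / saliency$srate)
    else sprintf("t = %d", ts[k])
    render_support_map(support_at(saliency, ts[k]), montage,
                       top_k = top_k, scale_max = global_max,
                       file = files[k], main = lab)
  }
  files
}

#' @export
plot.support_matrix <- function(x, ...) {
  render_support_map(x, ...)
}
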