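# Deterministic, invertible mapping between the 3D inflated array and the
# 2D classifier input.  Row order is influenced-major: component (i <- j)
# lives at row (i-1)*M + j.  The choice of which index varies fastest is
# immaterial to learning, but it is frozen here and written into serialized
# metadata so saliency rows are always decodable back to channel pairs.

#' Row index of an ordered channel pair
#' @param i influenced channel index (1-based).
#' @param j influencing channel index (1-based).
#' @param M number of channels.
#' @return row index in 1..M^2 (vectorized).
#' @export
row_of <- function(i, j, M) {
  if (any(i < 1 | i > M | j < 1 | j > M)) stop("channel index out of range")
  (i - 1L) * M + j
}

#' Ordered channel pair of a row index
#' @param row row index in 1..M^2 (vectorized).
#' @param M number of channels.
#' @return list with `i` (influenced) and `j` (influencing).
#' @export
pair_of <- function(row, M) {
  if (any(row < 1 | row > M * M)) stop("row index out of range")
  list(i = ((row - 1L) %/% M) + 1L, j = ((row - 1L) %% M) + 1L)
}

#' Channel-pair index map
#'
#' Tabulates the row layout of the flattened inflated data, one row per
#' component: row, influenced index/name, influencing index/name.  Written
#' as a JSON sidecar next to serialized datasets so saliency rows can be
#' decoded without the originating R session.
#'
#' @param M number of channels.
#' @param channel_names optional channel names (length M).
#' @return data.frame with columns `row`, `i`, `j`, `influenced`,
#'   `influencing`.
#' @export
pair_index_map <- function(M, channel_names = NULL) {
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(M))
  rows <- seq_len(M * M)
  p <- pair_of(rows, M)
  data.frame(row = rows, i = p$i, j = p$j,
             influenced = channel_names[p$i],
             influencing = channel_names[p$j])
}

#' Flatten an inflated epoch to the 2D classifier input
#'
#' Merges the two channel dimensions of the M x M x T' inflated array into
#' M^2 rows (influenced-major, see [row_of()]); the time dimension is
#' untouched.  Exactly inverted by [unflatten_column()] applied per column.
#'
#' @param x an `"inflated_epoch"` or a plain M x M x T' array.
#' @return M^2 x T' matrix; rownames are `"<influenced><-<influencing>"`.
#' @export
flatten <- function(x) {
  arr <- if (inherits(x, "inflated_epoch")) x$data else x
  d <- dim(arr)
  if (length(d) != 3L || d[1] != d[2])
    stop("expected an M x M x T array")
  M <- d[1]
  ch <- if (inherits(x, "inflated_epoch")) x$channel_names
        else dimnames(arr)[[1]]
  # aperm so j varies fastest within each influenced block
  out <- matrix(aperm(arr, c(2, 1, 3)), nrow = M * M, ncol = d[3])
  map <- pair_index_map(M, ch)
  rownames(out) <- paste0(map$influenced, "<-", map$influencing)
  out
}

#' Reshape a flattened column back into a square support matrix
#'
#' @param column numeric vector of length M^2 (one time sample of a
#'   flattened inflated epoch or saliency map).
#' @param M number of channels.
#' @param channel_names optional names for the dimnames.
#' @return M x M matrix; cell (i, j) = `column[(i-1)*M + j]`.
#' @export
unflatten_column <- function(column, M, channel_names = NULL) {
  if (length(column) != M * M)
    stop(sprintf("column length %d is not M^2 = %d", length(column), M * M))
  out <- matrix(column, nrow = M, ncol = M, byrow = TRUE)
  if (!is.null(channel_names)) dimnames(out) <- list(channel_names, channel_names)
  out
}

#' Write the pair index map as a JSON sidecar
#' @param M number of channels.
#' @param channel_names optional channel names.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_index_map <- function(M, channel_names = NULL, path) {
  map <- pair_index_map(M, channel_names)
  jsonlite::write_json(list(layout = "influenced_major",
                            row_formula = "(i-1)*M + j", M = M,
                            rows = map),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
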