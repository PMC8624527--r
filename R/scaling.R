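#' Min-max scaling of batch collections to [-1, 1]
#'
#' Fits a per-channel affine map sending the training minimum to -1 and the
#' training maximum to +1 across all batches (inputs and outputs alike), and
#' applies it. Constant channels (max == min) are mapped to 0 and flagged; the
#' min-max formula is undefined there. Values outside the training range (e.g.
#' on later test batches transformed with a stored map) are transformed by the
#' same affine map and may leave [-1, 1]; they are never clipped.
#'
#' @param batches List of [batch_ts()] objects.
#' @param transform Optional previously fitted `scaling_transform`; when given
#'   it is applied as-is instead of refitting.
#' @return List with elements `batches` (scaled) and `transform`.
#' @export
minmax_normalize <- function(batches, transform = NULL) {
  if (!length(batches)) stop("empty batch collection")
  if (is.null(transform)) transform <- fit_scaling(batches)
  scaled <- lapply(batches, apply_scaling, transform = transform)
  list(batches = scaled, transform = transform)
}

#' Fit a min-max scaling transform
#'
#' @inheritParams minmax_normalize
#' @return An object of class `scaling_transform`: per-channel `lo`/`hi`
#'   bounds and a constant-channel flag.
#' @export
fit_scaling <- function(batches) {
  if (!length(batches)) stop("empty batch collection")
  chans <- c(colnames(batches[[1]]$u), colnames(batches[[1]]$y))
  vals <- lapply(chans, function(ch) {
    unlist(lapply(batches, function(b) channel_values(b, ch)), use.names = FALSE)
  })
  for (i in seq_along(chans)) {
    v <- vals[[i]]
    bad <- which(!is.finite(v))
    if (length(bad)) {
      stop("non-finite value in channel '", chans[i], "' at pooled index ",
           bad[1])
    }
    if (!length(v)) stop("channel '", chans[i], "' has no finite values")
  }
  lo <- vapply(vals, min, numeric(1))
  hi <- vapply(vals, max, numeric(1))
  structure(
    list(channel = chans, lo = lo, hi = hi, constant = hi == lo),
    class = "scaling_transform")
}

channel_values <- function(b, ch) {
  if (ch %in% colnames(b$u)) return(b$u[, ch])
  # for outputs only observed rows define the training range
  b$y[b$y_observed, ch]
}

scale_one <- function(x, lo, hi, constant) {
  if (constant) return(ifelse(is.na(x), x, 0))
  -1 + 2 * (x - lo) / (hi - lo)
}

unscale_one <- function(x, lo, hi, constant) {
  if (constant) return(ifelse(is.na(x), x, lo))
  lo + (x + 1) * (hi - lo) / 2
}

transform_channel <- function(transform, ch, x, inverse = FALSE) {
  i <- match(ch, transform$channel)
  if (is.na(i)) stop("unknown channel '", ch, "' in scaling transform")
  f <- if (inverse) unscale_one else scale_one
  f(x, transform$lo[i], transform$hi[i], transform$constant[i])
}

#' Apply or invert a scaling transform on one batch
#'
#' @param batch A [batch_ts()] object.
#' @param transform A `scaling_transform`.
#' @param inverse If `TRUE`, map from normalized back to physical units.
#' @return The transformed batch.
#' @export
apply_scaling <- function(batch, transform, inverse = FALSE) {
  b <- batch
  for (ch in colnames(b$u)) {
    b$u[, ch] <- transform_channel(transform, ch, b$u[, ch], inverse)
  }
  for (ch in colnames(b$y)) {
    b$y[, ch] <- transform_channel(transform, ch, b$y[, ch], inverse)
  }
  b
}

#' @export
print.scaling_transform <- function(x, ...) {
  cat("<scaling_transform> channels to [-1, 1]:\n")
  print(data.frame(channel = x$channel, lo = x$lo, hi = x$hi,
                   constant = x$constant), row.names = FALSE)
  invisible(x)
}

scaling_to_list <- function(tr) {
  list(channel = tr$channel, lo = tr$lo, hi = tr$hi, constant = tr$constant)
}

scaling_from_list <- function(l) {
  structure(list(channel = as.character(l$channel), lo = as.numeric(l$lo),
                 hi = as.numeric(l$hi), constant = as.logical(l$constant)),
            class = "scaling_transform")
}
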