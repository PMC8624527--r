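#' Build ARX regression vectors from batch time series
#'
#' For a chosen target output, forms at each usable time k the regression
#' vector
#' \deqn{X(k) = [y(k-1), ..., y(k-n_y),
#'               u_1(k-p-1), ..., u_r(k-p-1), ...,
#'               u_1(k-p-n_u), ..., u_r(k-p-n_u)]^T}
#' together with the target `y(k)` and the modeling vector
#' `z(k) = [X(k)^T, y(k)]^T` used for clustering. Lag windows never cross a
#' batch boundary: the first `max(n_y, p + n_u)` samples of each batch are
#' trimmed. Batches too short to yield a single pair are skipped with a
#' warning.
#'
#' @param batches List of [batch_ts()] objects (normally normalized and with
#'   outputs interpolated to the fast grid).
#' @param target Which output to model, `"X"` or `"P"` (or any `y` column).
#' @param n_y Number of output lags (>= 0).
#' @param n_u Number of input lags (>= 1).
#' @param p Pure delay in samples (default 0).
#' @return An object of class `regression_dataset` with fields `X` (N x n
#'   matrix, n = n_y + n_u * r), `y` (length-N target), `z` (N x (n+1)
#'   modeling vectors), `batch_id`, `time_index`, `split`, and the orders.
#' @export
build_regression_vectors <- function(batches, target, n_y, n_u, p = 0L) {
  stopifnot(n_y >= 0, n_u >= 1, p >= 0)
  if (!length(batches)) stop("empty batch collection")
  r <- ncol(batches[[1]]$u)
  w <- max(n_y, p + n_u)
  per_batch <- lapply(batches, function(b) {
    n_t <- nrow(b$u)
    if (n_t <= w) {
      warning("batch '", b$batch_id, "' shorter than the lag window; skipped")
      return(NULL)
    }
    ks <- (w + 1L):n_t
    yv <- b$y[, target]
    cols <- vector("list", n_y + n_u)
    j <- 0L
    for (l in seq_len(n_y)) {
      j <- j + 1L
      cols[[j]] <- yv[ks - l]
    }
    ublocks <- vector("list", n_u)
    for (l in seq_len(n_u)) {
      ublocks[[l]] <- b$u[ks - p - l, , drop = FALSE]
    }
    X <- do.call(cbind, c(cols[seq_len(n_y)], ublocks))
    list(X = X, y = yv[ks], batch_id = rep(b$batch_id, length(ks)),
         time_index = ks,
         split = if (!is.null(b$split)) b$split[ks] else rep(NA_character_, length(ks)))
  })
  per_batch <- Filter(Negate(is.null), per_batch)
  if (!length(per_batch)) stop("all batches shorter than the lag window")
  X <- do.call(rbind, lapply(per_batch, `[[`, "X"))
  y <- unlist(lapply(per_batch, `[[`, "y"), use.names = FALSE)
  colnames(X) <- regressor_names(target, n_y, n_u,
                                 colnames(batches[[1]]$u))
  structure(
    list(X = X, y = y, z = unname(cbind(X, y)),
         batch_id = unlist(lapply(per_batch, `[[`, "batch_id"), use.names = FALSE),
         time_index = unlist(lapply(per_batch, `[[`, "time_index"), use.names = FALSE),
         split = unlist(lapply(per_batch, `[[`, "split"), use.names = FALSE),
         target = target, n_y = n_y, n_u = n_u, p = p, r = r),
    class = "regression_dataset")
}

regressor_names <- function(target, n_y, n_u, u_names) {
  c(if (n_y > 0) paste0(target, ".l", seq_len(n_y)),
    unlist(lapply(seq_len(n_u), function(l) paste0(u_names, ".l", l))))
}

#' @export
print.regression_dataset <- function(x, ...) {
  cat(sprintf(
    "<regression_dataset> target %s, N = %d pairs, n = %d (n_y = %d, n_u = %d, p = %d, r = %d)\n",
    x$target, length(x$y), ncol(x$X), x$n_y, x$n_u, x$p, x$r))
  invisible(x)
}

# Subset a regression_dataset by row index, keeping metadata consistent.
subset_dataset <- function(ds, idx) {
  structure(
    list(X = ds$X[idx, , drop = FALSE], y = ds$y[idx],
         z = ds$z[idx, , drop = FALSE],
         batch_id = ds$batch_id[idx], time_index = ds$time_index[idx],
         split = ds$split[idx],
         target = ds$target, n_y = ds$n_y, n_u = ds$n_u, p = ds$p, r = ds$r),
    class = "regression_dataset")
}
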