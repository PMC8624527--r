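#' Batch time-series container
#'
#' One fermentation batch on a uniform fast time grid: six auxiliary input
#' channels (broth temperature `T`, dissolved oxygen `DO`, `pH`, air flow `q`,
#' stirring speed `v`, tank pressure `p`) and two target outputs (cell
#' concentration `X`, product concentration `P`). Outputs are typically
#' observed on a slower grid (assay interval); `y_observed` marks which output
#' rows are true observations as opposed to interpolated values.
#'
#' @param batch_id Identifier (coerced to character).
#' @param u Numeric matrix, one row per time step, 6 columns named
#'   `T, DO, pH, q, v, p` (arbitrary physical units before normalization).
#' @param y Numeric matrix, one row per time step, columns named `X` and `P`.
#'   May contain `NA` on rows where `y_observed` is `FALSE`.
#' @param y_observed Logical vector marking true (slow-grid) observations.
#'   Default: all rows observed.
#' @param step_minutes Positive sampling interval of the fast grid (default 5).
#' @param split Optional character vector of per-sample split labels
#'   (`"train"`, `"validation"`, `"test"`).
#' @return An object of class `batch_ts`.
#' @export
batch_ts <- function(batch_id, u, y, y_observed = NULL, step_minutes = 5,
                     split = NULL) {
  u <- as.matrix(u)
  y <- as.matrix(y)
  rownames(u) <- NULL
  rownames(y) <- NULL
  if (is.null(colnames(u))) colnames(u) <- input_channels()[seq_len(ncol(u))]
  if (is.null(colnames(y))) colnames(y) <- output_channels()[seq_len(ncol(y))]
  if (is.null(y_observed)) y_observed <- rep(TRUE, nrow(y))
  obj <- structure(
    list(batch_id = as.character(batch_id),
         step_minutes = step_minutes,
         u = u, y = y,
         y_observed = as.logical(y_observed),
         split = split),
    class = "batch_ts")
  validate_batch_ts(obj)
  obj
}

validate_batch_ts <- function(b) {
  stopifnot(inherits(b, "batch_ts"))
  n <- nrow(b$u)
  if (n < 1L) stop("batch '", b$batch_id, "': empty time grid")
  if (nrow(b$y) != n || length(b$y_observed) != n) {
    stop("batch '", b$batch_id, "': u, y and y_observed must have equal length")
  }
  if (!is.numeric(b$step_minutes) || b$step_minutes <= 0) {
    stop("batch '", b$batch_id, "': step_minutes must be positive")
  }
  if (!is.null(b$split) && length(b$split) != n) {
    stop("batch '", b$batch_id, "': split labels must match the grid length")
  }
  obs <- which(b$y_observed)
  if (length(obs) && any(!is.finite(b$y[obs, , drop = FALSE]))) {
    stop("batch '", b$batch_id, "': observed output rows must be finite")
  }
  invisible(b)
}

#' @export
print.batch_ts <- function(x, ...) {
  cat(sprintf("<batch_ts '%s'>  %d samples @ %g min, %d inputs, %d outputs (%d observed)\n",
              x$batch_id, nrow(x$u), x$step_minutes, ncol(x$u), ncol(x$y),
              sum(x$y_observed)))
  invisible(x)
}

#' Read batches from a delimited text table
#'
#' Expects columns `time_min`, the six input channels, the outputs `X`, `P`,
#' `batch_id` and an `observed` flag (0/1); an optional `split` column carries
#' data-split labels. One file may hold several batches.
#'
#' @param path CSV file path.
#' @return List of [batch_ts()] objects, in order of first appearance.
#' @export
read_batches <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("time_min", input_channels(), "X", "P", "batch_id", "observed")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  ids <- unique(df$batch_id)
  lapply(ids, function(id) {
    d <- df[df$batch_id == id, , drop = FALSE]
    d <- d[order(d$time_min), , drop = FALSE]
    step <- if (nrow(d) > 1) diff(d$time_min[1:2]) else 5
    batch_ts(id,
             u = as.matrix(d[, input_channels()]),
             y = as.matrix(d[, c("X", "P")]),
             y_observed = d$observed != 0,
             step_minutes = step,
             split = if ("split" %in% names(d)) d$split else NULL)
  })
}

#' Write batches to a delimited text table
#'
#' @param batches List of [batch_ts()] objects.
#' @param path Output CSV file path.
#' @export
write_batches <- function(batches, path) {
  rows <- lapply(batches, function(b) {
    n <- nrow(b$u)
    d <- data.frame(time_min = (seq_len(n) - 1L) * b$step_minutes)
    d <- cbind(d, as.data.frame(b$u), as.data.frame(b$y))
    d$batch_id <- b$batch_id
    d$observed <- as.integer(b$y_observed)
    if (!is.null(b$split)) d$split <- b$split
    d
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
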