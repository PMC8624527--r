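#' Prediction error metrics
#'
#' Computes the relative error series `e(k) = (y(k) - yhat(k)) / y(k)`, the
#' mean absolute percentage error MAPE = mean |e(k)| (reported as a fraction,
#' e.g. 0.0435 for 4.35%), and RMSE = sqrt(mean (y - yhat)^2). Samples with
#' |y| below `floor` are excluded from the relative-error statistics (their
#' count is reported); RMSE uses all samples.
#'
#' @param y_true,y_pred Equal-length numeric vectors.
#' @param floor Smallest |y| admitted to the relative error (default 1e-8 on
#'   the normalized scale).
#' @param label Optional data-split label carried in the report.
#' @return An object of class `evaluation_report`: `mape`, `rmse`,
#'   `rel_error` (NA where excluded), `n`, `n_excluded`, `label`.
#' @export
error_metrics <- function(y_true, y_pred, floor = 1e-8, label = NA_character_) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) > 0)
  ok <- abs(y_true) >= floor
  if (!any(ok)) stop("all samples fall below the |y| floor; MAPE undefined")
  if (any(!ok)) {
    pwa_log(sum(!ok), " samples below the |y| floor excluded from MAPE")
  }
  rel <- rep(NA_real_, length(y_true))
  rel[ok] <- (y_true[ok] - y_pred[ok]) / y_true[ok]
  structure(
    list(mape = mean(abs(rel[ok])),
         rmse = sqrt(mean((y_true - y_pred)^2)),
         rel_error = rel,
         n = length(y_true),
         n_excluded = sum(!ok),
         label = label),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report%s> n = %d: MAPE = %.6f, RMSE = %.6g (%d excluded from MAPE)\n",
              if (is.na(x$label)) "" else paste0(" ", x$label),
              x$n, x$mape, x$rmse, x$n_excluded))
  invisible(x)
}

#' Fit a single global affine ARX model by least squares
#'
#' The natural baseline against which the multi-model is judged: one affine
#' law `[X^T, 1] theta` over the whole regressor space.
#'
#' @param dataset A `regression_dataset`.
#' @return A [pwarx_model()] with S = 1.
#' @export
fit_global_arx <- function(dataset) {
  A <- cbind(dataset$X, 1)
  theta <- qr.coef(qr(A), dataset$y)
  theta[is.na(theta)] <- 0
  pwarx_model(orders = list(n_y = dataset$n_y, n_u = dataset$n_u,
                            p = dataset$p, r = dataset$r),
              target = dataset$target,
              theta = list(as.numeric(theta)),
              centers = matrix(colMeans(dataset$z), 1))
}

#' Evaluate a model on a data split
#'
#' Builds regression vectors on the requested split, predicts one step ahead
#' in normalized space, and reports metrics on the normalized scale and (when
#' the model carries a scaling transform) on the physical scale, together
#' with an RMSE-versus-cumulative-sample-size table in 20-sample increments.
#'
#' @param model A [pwarx_model()].
#' @param batches List of [batch_ts()] objects on the model's (normalized)
#'   scale, outputs interpolated to the fast grid, with per-sample split
#'   labels.
#' @param split Split label to evaluate (`"test"`, `"validation"`,
#'   `"train"`), or `NULL` for all samples.
#' @param increment Step of the cumulative-RMSE table (default 20).
#' @return List with `normalized` and `physical` evaluation reports (the
#'   latter `NULL` without a scaling transform), the `rmse_by_size` table,
#'   `y`, `y_hat`, and `region`.
#' @export
evaluate_model <- function(model, batches, split = "test", increment = 20L) {
  ds <- build_regression_vectors(batches, model$target, model$orders$n_y,
                                 model$orders$n_u, model$orders$p)
  idx <- if (is.null(split)) seq_along(ds$y) else which(ds$split == split)
  if (!length(idx)) stop("no samples with split label '", split, "'")
  ds <- subset_dataset(ds, idx)
  pred <- predict_one_step(model, ds$X)
  rep_norm <- error_metrics(ds$y, pred$y_hat, label = split %||% "all")
  rep_phys <- NULL
  if (!is.null(model$scaling)) {
    y_p <- transform_channel(model$scaling, model$target, ds$y, inverse = TRUE)
    yh_p <- transform_channel(model$scaling, model$target, pred$y_hat,
                              inverse = TRUE)
    rep_phys <- error_metrics(y_p, yh_p, floor = 1e-8, label = split %||% "all")
  }
  sizes <- seq(increment, length(ds$y), by = increment)
  if (!length(sizes) || sizes[length(sizes)] != length(ds$y)) {
    sizes <- unique(c(sizes, length(ds$y)))
  }
  rmse_by_size <- data.frame(
    n = sizes,
    rmse = vapply(sizes, function(m) {
      sqrt(mean((ds$y[seq_len(m)] - pred$y_hat[seq_len(m)])^2))
    }, numeric(1)))
  list(normalized = rep_norm, physical = rep_phys,
       rmse_by_size = rmse_by_size,
       y = ds$y, y_hat = pred$y_hat, region = pred$region)
}

#' Free-run simulation of a PWARX model
#'
#' Iterates the model on its own output predictions (parallel model), using
#' the recorded inputs. One-step-ahead prediction is the default evaluation
#' mode; this is provided for inspecting long-horizon behavior.
#'
#' @param model A [pwarx_model()].
#' @param batch A [batch_ts()] on the model's scale.
#' @return Numeric vector of simulated outputs on the batch grid (NA over the
#'   initial lag window).
#' @export
simulate_free_run <- function(model, batch) {
  o <- model$orders
  w <- max(o$n_y, o$p + o$n_u)
  n_t <- nrow(batch$u)
  y_sim <- rep(NA_real_, n_t)
  y_sim[seq_len(w)] <- batch$y[seq_len(w), model$target]
  for (k in (w + 1L):n_t) {
    ylags <- if (o$n_y > 0) y_sim[k - seq_len(o$n_y)] else numeric(0)
    ulags <- as.numeric(t(batch$u[k - o$p - seq_len(o$n_u), , drop = FALSE]))
    X <- c(ylags, ulags)
    y_sim[k] <- predict_one_step(model, X)$y_hat
  }
  y_sim
}
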