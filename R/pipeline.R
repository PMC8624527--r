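#' Fit a complete piecewise-affine soft-sensor model
#'
#' End-to-end identification on normalized batch data: (1) select orders by
#' FNN/Cao analysis (unless given), (2) build regression vectors on the
#' training split, (3) jointly optimize the number of local models and their
#' parameters with the compression-factor swarm, (4) learn dividing surfaces
#' between adjacent regions with linear-kernel LS-SVMs, and (5) assemble the
#' prediction-ready model.
#'
#' @param batches Normalized [batch_ts()] list with outputs on the full grid
#'   and (optionally) per-sample split labels.
#' @param target Output channel to model.
#' @param orders Optional list `(n_y, n_u, p)`; when `NULL` they are selected
#'   by [select_orders()] on the training split.
#' @param config A [swarm_config()].
#' @param S_max,y_ts,theta_bound,polish Passed to [identify_pwarx()].
#' @param lssvm_gamma Passed to [build_surfaces()].
#' @param scaling Optional `scaling_transform` stored in the model.
#' @param seed Integer seed controlling the whole fit.
#' @return List with `model` (a [pwarx_model()]), `fit` (the `pwarx_fit`),
#'   `dataset` (training `regression_dataset`), and `order_selection`
#'   diagnostics (when orders were selected here).
#' @export
fit_soft_sensor <- function(batches, target = "X", orders = NULL,
                            config = swarm_config(), S_max = 6, y_ts = NULL,
                            theta_bound = 10, polish = FALSE,
                            lssvm_gamma = 10, scaling = NULL, seed = 1L) {
  has_split <- !is.null(batches[[1]]$split)
  train_batches <- batches
  order_sel <- NULL
  if (is.null(orders)) {
    order_sel <- select_orders(batches, target)
    orders <- list(n_y = order_sel$n_y, n_u = order_sel$n_u, p = 0L)
  }
  ds <- build_regression_vectors(batches, target, orders$n_y, orders$n_u,
                                 orders$p %||% 0L)
  if (has_split && any(ds$split == "train", na.rm = TRUE)) {
    ds <- subset_dataset(ds, which(ds$split == "train"))
  }
  fit <- identify_pwarx(ds, config = config, S_max = S_max, y_ts = y_ts,
                        theta_bound = theta_bound, polish = polish,
                        seed = seed)
  surfaces <- if (fit$S >= 2L) {
    build_surfaces(ds$X, fit$labels, fit$centers, lssvm_gamma = lssvm_gamma)
  } else {
    list()
  }
  model <- pwarx_model(
    orders = list(n_y = orders$n_y, n_u = orders$n_u, p = orders$p %||% 0L,
                  r = ds$r),
    target = target, theta = fit$theta, surfaces = surfaces,
    centers = fit$centers, scaling = scaling,
    metadata = list(seed = seed, S_max = S_max, y_ts = fit$y_ts,
                    factor_mode = config$factor_mode,
                    threshold_met = fit$threshold_met))
  list(model = model, fit = fit, dataset = ds, order_selection = order_sel)
}
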