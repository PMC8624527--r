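#' Assembled piecewise-affine ARX soft-sensor model
#'
#' Bundles everything needed to predict: orders, the S local parameter
#' vectors, dividing surfaces, cluster centers and the scaling transform.
#'
#' @param orders List with `n_y`, `n_u`, `p`, `r`.
#' @param target Output channel name the model predicts.
#' @param theta List of S parameter vectors, each of length
#'   `n_y + n_u * r + 1`.
#' @param surfaces List of `dividing_surface` objects (may be empty for
#'   S = 1).
#' @param centers S x (n + 1) matrix of cluster centers in modeling space.
#' @param scaling Optional `scaling_transform` mapping physical units to the
#'   normalized scale the model operates on.
#' @param metadata Optional list (seeds, configuration echo, ...).
#' @return An object of class `pwarx_model`.
#' @export
pwarx_model <- function(orders, target, theta, surfaces = list(),
                        centers = NULL, scaling = NULL, metadata = list()) {
  n <- orders$n_y + orders$n_u * orders$r
  d_theta <- n + 1L
  stopifnot(all(vapply(theta, length, integer(1)) == d_theta))
  for (s in surfaces) {
    stopifnot(inherits(s, "dividing_surface"), length(s$w) == n)
  }
  if (is.null(centers)) centers <- matrix(0, length(theta), n + 1L)
  structure(
    list(orders = orders, target = target, theta = theta,
         surfaces = surfaces, centers = as.matrix(centers),
         scaling = scaling, metadata = metadata,
         S = length(theta)),
    class = "pwarx_model")
}

#' @export
print.pwarx_model <- function(x, ...) {
  cat(sprintf("<pwarx_model> target %s: S = %d local models, n_y = %d, n_u = %d, p = %d, r = %d (%d surfaces)\n",
              x$target, x$S, x$orders$n_y, x$orders$n_u, x$orders$p,
              x$orders$r, length(x$surfaces)))
  invisible(x)
}

#' One-step-ahead prediction
#'
#' Assigns each regression vector to its region via the dividing surfaces
#' (nearest-center fallback for inconsistent sign patterns) and applies the
#' corresponding local affine law `[X^T, 1] theta_region`.
#'
#' @param model A [pwarx_model()].
#' @param X Regression vector (length n) or matrix of such rows.
#' @return List with `y_hat` and `region` per row.
#' @export
predict_one_step <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  n <- model$orders$n_y + model$orders$n_u * model$orders$r
  if (ncol(X) != n) {
    stop("regression vector has dimension ", ncol(X), ", expected ", n)
  }
  region <- assign_region(X, model$surfaces, model$centers, model$S)
  Theta <- do.call(cbind, model$theta)
  pred_all <- cbind(X, 1) %*% Theta
  list(y_hat = pred_all[cbind(seq_len(nrow(X)), region)], region = region)
}

#' @export
predict.pwarx_model <- function(object, newdata, ...) {
  predict_one_step(object, newdata)$y_hat
}

#' Serialize a PWARX model to JSON
#'
#' The file is plain text and round-trips losslessly (full double precision).
#'
#' @param model A [pwarx_model()].
#' @param path Output path.
#' @export
write_pwarx_model <- function(model, path) {
  obj <- list(
    format = "pwasoft-model",
    version = 1L,
    target = model$target,
    orders = model$orders,
    theta = model$theta,
    surfaces = lapply(model$surfaces, function(s) {
      list(pair = s$pair, w = s$w, v = s$v)
    }),
    centers = model$centers,
    scaling = if (!is.null(model$scaling)) scaling_to_list(model$scaling),
    metadata = model$metadata)
  obj <- obj[!vapply(obj, is.null, logical(1))]
  # digits = I(17): exact IEEE double round-trip
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Read a PWARX model from JSON
#'
#' @param path Path written by [write_pwarx_model()].
#' @return A [pwarx_model()].
#' @export
read_pwarx_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "pwasoft-model")) {
    stop("not a pwasoft model file: ", path)
  }
  theta <- if (is.matrix(obj$theta)) {
    lapply(seq_len(nrow(obj$theta)), function(i) as.numeric(obj$theta[i, ]))
  } else {
    lapply(obj$theta, as.numeric)
  }
  surfaces <- list()
  if (length(obj$surfaces)) {
    mk <- function(pair, w, v) structure(
      list(pair = as.integer(pair), w = as.numeric(w), v = as.numeric(v)),
      class = "dividing_surface")
    surfaces <- if (is.data.frame(obj$surfaces)) {
      lapply(seq_len(nrow(obj$surfaces)), function(i) {
        mk(obj$surfaces$pair[[i]], obj$surfaces$w[[i]], obj$surfaces$v[[i]])
      })
    } else {
      lapply(obj$surfaces, function(s) mk(s$pair, s$w, s$v))
    }
  }
  pwarx_model(orders = lapply(obj$orders, as.integer),
              target = obj$target,
              theta = theta,
              surfaces = surfaces,
              centers = as.matrix(obj$centers),
              scaling = if (length(obj$scaling)) scaling_from_list(obj$scaling),
              metadata = obj$metadata %||% list())
}
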