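#' Least squares support vector machine classifier
#'
#' Trains the two-class LS-SVM by solving the (N+1) x (N+1) symmetric linear
#' system
#' \deqn{\begin{bmatrix} 0 & y^T \\ y & \Omega + I/\gamma \end{bmatrix}
#'       \begin{bmatrix} b \\ \alpha \end{bmatrix} =
#'       \begin{bmatrix} 0 \\ 1 \end{bmatrix}}
#' with kernel-label matrix Omega_kl = y_k y_l K(x_k, x_l). The first block
#' row enforces sum_k alpha_k y_k = 0. The decision function is
#' `sign(sum_k alpha_k y_k K(x, x_k) + b)`.
#'
#' @param x Numeric matrix of training points (rows).
#' @param labels Vector in {-1, +1}; both classes must be present.
#' @param kernel `"linear"` (default; required for hyperplane extraction) or
#'   `"rbf"`.
#' @param lssvm_gamma Penalty weight on the squared slacks (> 0, default 10).
#' @param rbf_width RBF width parameter sigma in
#'   `K(xi, xj) = exp(-|xi - xj|^2 / sigma^2)` (default 0.2).
#' @return An object of class `lssvm_model` with `alpha`, `b`, the kernel
#'   spec, the training data, and the KKT residual of the solved system.
#' @export
lssvm_solve <- function(x, labels, kernel = c("linear", "rbf"),
                        lssvm_gamma = 10, rbf_width = 0.2) {
  kernel <- match.arg(kernel)
  x <- as.matrix(x)
  labels <- as.numeric(labels)
  if (!all(labels %in% c(-1, 1))) stop("labels must be in {-1, +1}")
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  if (lssvm_gamma <= 0) stop("lssvm_gamma must be positive")
  N <- nrow(x)
  K <- kernel_matrix(x, x, kernel, rbf_width)
  Omega <- (labels %o% labels) * K
  A <- rbind(c(0, labels), cbind(labels, Omega + diag(N) / lssvm_gamma))
  rhs <- c(0, rep(1, N))
  sol <- tryCatch(solve(A, rhs), error = function(e) {
    stop("LS-SVM system is singular (reciprocal condition estimate ",
         signif(rcond(A), 3), "): ", conditionMessage(e))
  })
  kkt <- max(abs(A %*% sol - rhs)) / max(1, max(abs(rhs)))
  structure(
    list(alpha = unname(sol[-1]), b = unname(sol[1]), kernel = kernel,
         lssvm_gamma = lssvm_gamma, rbf_width = rbf_width,
         x = x, labels = labels, kkt_residual = kkt),
    class = "lssvm_model")
}

kernel_matrix <- function(a, b, kernel, rbf_width) {
  if (kernel == "linear") {
    a %*% t(b)
  } else {
    d2 <- outer(rowSums(a^2), rep(1, nrow(b))) - 2 * a %*% t(b) +
      outer(rep(1, nrow(a)), rowSums(b^2))
    exp(-pmax(d2, 0) / rbf_width^2)
  }
}

#' Decision values of a trained LS-SVM
#'
#' @param model An `lssvm_model`.
#' @param x Matrix of query points (rows).
#' @return Numeric decision values; classify by their sign.
#' @export
lssvm_decision <- function(model, x) {
  x <- as.matrix(x)
  K <- kernel_matrix(x, model$x, model$kernel, model$rbf_width)
  as.numeric(K %*% (model$alpha * model$labels) + model$b)
}

#' @export
print.lssvm_model <- function(x, ...) {
  cat(sprintf("<lssvm_model> %s kernel, N = %d, gamma = %g, KKT residual = %.3g\n",
              x$kernel, nrow(x$x), x$lssvm_gamma, x$kkt_residual))
  invisible(x)
}

#' Extract the dividing hyperplane from a linear-kernel LS-SVM
#'
#' With the linear kernel the primal weight vector is recovered as
#' `w = sum_k alpha_k y_k x_k`; the offset is the mean of `y_k - w^T x_k`
#' over all training points (the numerically stable version of reading it
#' off one support vector). The surface is `w^T X + v = 0` and is oriented so
#' that the +1 class lies on the non-negative side.
#'
#' @param model A linear-kernel `lssvm_model`.
#' @param pair Optional region index pair `c(i, j)` recorded on the surface
#'   (region i being the +1 class).
#' @return An object of class `dividing_surface` with `w`, `v`, `pair`.
#' @export
extract_hyperplane <- function(model, pair = c(1L, 2L)) {
  if (model$kernel != "linear") {
    stop("hyperplane parameters require a linear kernel; RBF models can only ",
         "classify through lssvm_decision()")
  }
  w <- as.numeric(t(model$x) %*% (model$alpha * model$labels))
  v <- mean(model$labels - model$x %*% w)
  structure(list(pair = as.integer(pair), w = w, v = v),
            class = "dividing_surface")
}

#' @export
print.dividing_surface <- function(x, ...) {
  cat(sprintf("<dividing_surface> regions (%d, %d): [w, v] = [%s]\n",
              x$pair[1], x$pair[2],
              paste(signif(c(x$w, x$v), 4), collapse = ", ")))
  invisible(x)
}
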