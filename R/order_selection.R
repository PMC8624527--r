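#' False-nearest-neighbor model order selection
#'
#' The model order (number of output lags `n_y` and input lags `n_u`) is
#' treated as an embedding-dimension problem: regression vectors of growing
#' dimension are built from the input/output series, and the minimum dimension
#' at which close neighbors stop separating is found with the false nearest
#' neighbor criterion and Cao's E/E0 ratio statistics. Distances use the
#' L-infinity norm, so appending coordinates can only grow a distance and the
#' growth factor alpha(p, n) is always >= 1.
#'
#' @name order_selection
NULL

# Nested (n_y, n_u) schedule, output lag first: (1,1), (2,1), (2,2), (3,2), ...
# Each entry's regressor coordinate set contains the previous entry's, which
# is what makes the L-infinity statistics monotone. Entries are kept while the
# total dimension n_y + n_u * r stays within n_max.
lag_schedule <- function(n_max, r) {
  sched <- list(c(1L, 1L))
  repeat {
    last <- sched[[length(sched)]]
    nxt <- if (last[1] == last[2]) c(last[1] + 1L, last[2]) else c(last[1], last[2] + 1L)
    if (nxt[1] + nxt[2] * r > n_max) break
    sched[[length(sched) + 1L]] <- nxt
  }
  data.frame(n_y = vapply(sched, `[`, integer(1), 1),
             n_u = vapply(sched, `[`, integer(1), 2),
             dim = vapply(sched, function(s) s[1] + s[2] * r, integer(1)))
}

#' L-infinity nearest neighbor of one point
#'
#' @param vectors Numeric matrix, one point per row (>= 2 rows).
#' @param p_index Query row index.
#' @return List with `index` (nearest row != `p_index`, ties broken by the
#'   smallest index) and `distance` (max-coordinate distance).
#' @export
linf_nearest_neighbor <- function(vectors, p_index) {
  vectors <- as.matrix(vectors)
  if (nrow(vectors) < 2L) stop("need at least 2 vectors")
  d <- linf_dist_to_point(vectors, p_index)
  d[p_index] <- Inf
  i <- which.min(d)   # which.min returns the first minimum: smallest index
  list(index = i, distance = d[i])
}

linf_dist_to_point <- function(V, p) {
  d <- abs(V[, 1] - V[p, 1])
  if (ncol(V) > 1L) {
    for (j in 2:ncol(V)) d <- pmax(d, abs(V[, j] - V[p, j]))
  }
  d
}

# Nearest neighbor (index and distance) for every row.
linf_nn_all <- function(V) {
  N <- nrow(V)
  idx <- integer(N)
  dst <- numeric(N)
  for (p in seq_len(N)) {
    d <- linf_dist_to_point(V, p)
    d[p] <- Inf
    i <- which.min(d)
    idx[p] <- i
    dst[p] <- d[i]
  }
  list(index = idx, dist = dst)
}

linf_pair_dist <- function(V, i, j) {
  D <- abs(V[i, , drop = FALSE] - V[j, , drop = FALSE])
  do.call(pmax, lapply(seq_len(ncol(D)), function(k) D[, k]))
}

#' Fraction of false nearest neighbors between two embedding dimensions
#'
#' For each point, its nearest neighbor is found at dimension n; the distance
#' of the same pair is re-evaluated at dimension n+1 (whose coordinates must
#' extend the dimension-n coordinates). The default (standard Kennel-style)
#' criterion flags a false neighbor when the relative distance growth
#' `(d_{n+1} - d_n) / d_n` reaches the threshold `R_T`. The variant dividing
#' by the dimension-(n+1) distance is available as `criterion = "printed"`;
#' under L-infinity nesting that ratio is below 1, so it cannot flag anything
#' for thresholds in the conventional [10, 50] range.
#'
#' @param vectors_n Matrix of dimension-n vectors.
#' @param vectors_n1 Matrix of dimension-(n+1) vectors, row-aligned with
#'   `vectors_n`.
#' @param R_T Threshold (conventionally in [10, 50]).
#' @param criterion `"kennel"` (default) or `"printed"`.
#' @return List with `ratio` (flagged fraction among evaluated points),
#'   `n_false`, `n_evaluated`, and `n_skipped` (zero-distance points excluded
#'   by the zero-distance rule).
#' @export
false_neighbor_ratio <- function(vectors_n, vectors_n1, R_T = 10,
                                 criterion = c("kennel", "printed")) {
  criterion <- match.arg(criterion)
  vectors_n <- as.matrix(vectors_n)
  vectors_n1 <- as.matrix(vectors_n1)
  if (nrow(vectors_n) != nrow(vectors_n1)) {
    stop("vectors_n and vectors_n1 must have the same number of rows")
  }
  nn <- linf_nn_all(vectors_n)
  d_n <- nn$dist
  d_n1 <- linf_pair_dist(vectors_n1, seq_len(nrow(vectors_n1)), nn$index)
  ok <- d_n > 0
  flag <- if (criterion == "kennel") {
    (d_n1[ok] - d_n[ok]) / d_n[ok] >= R_T
  } else {
    abs(d_n1[ok] - d_n[ok]) / d_n1[ok] >= R_T
  }
  if (any(!ok)) pwa_log(sum(!ok), " zero-distance points skipped in FNN ratio")
  list(ratio = if (any(ok)) mean(flag) else 0,
       n_false = sum(flag), n_evaluated = sum(ok), n_skipped = sum(!ok))
}

# Regression vectors for one (n_y, n_u) entry with an explicit trim window so
# that different dimensions stay row-aligned across the schedule.
embed_vectors <- function(batches, target, n_y, n_u, trim) {
  per_batch <- lapply(batches, function(b) {
    n_t <- nrow(b$u)
    if (n_t <= trim) return(NULL)
    ks <- (trim + 1L):n_t
    yv <- b$y[, target]
    cols <- lapply(seq_len(n_y), function(l) yv[ks - l])
    ublocks <- lapply(seq_len(n_u), function(l) b$u[ks - l, , drop = FALSE])
    V <- do.call(cbind, c(cols, ublocks))
    colnames(V) <- c(if (n_y > 0) paste0("y.l", seq_len(n_y)),
                     unlist(lapply(seq_len(n_u), function(l) {
                       paste0("u", seq_len(ncol(b$u)), ".l", l)
                     })))
    V
  })
  per_batch <- Filter(Negate(is.null), per_batch)
  if (!length(per_batch)) stop("series too short for the requested embedding")
  do.call(rbind, per_batch)
}

#' Cao's E/E0 statistics over the lag schedule
#'
#' Tabulates, for each schedule entry of dimension n (with successor of
#' dimension n'), the mean neighbor-distance growth factor
#' `E(n) = mean_p alpha(p, n)` with `alpha(p, n) = d^{(n')}(p) / d^{(n)}(p)`,
#' the ratio `E0(n) = E(next) / E(n)`, and the false-neighbor fraction.
#' Points whose dimension-n nearest-neighbor distance is exactly zero are
#' excluded from the mean (zero-distance rule) and counted.
#'
#' @param batches List of [batch_ts()] objects (or a single batch).
#' @param target Output channel to model.
#' @param n_max Largest total regressor dimension to consider.
#' In addition to E/E0, the appended-coordinate statistic `E2` (the ratio of
#' mean appended-coordinate neighbor differences between consecutive
#' dimensions) is tabulated: for a structureless (noise) series every
#' appended coordinate is unpredictable from the current embedding, so E2
#' stays near 1 at every dimension, which is what the `degenerate` flag
#' detects; a deterministic series drives E2 away from 1 at some dimension.
#'
#' @param R_T False-neighbor threshold.
#' @param tol Stability tolerance on |E0 - 1|.
#' @param tol2 Noise-detection tolerance on |E2 - 1| (default 0.1).
#' @param criterion FNN criterion, see [false_neighbor_ratio()].
#' @return An object of class `embedding_diagnostics`: the schedule table with
#'   columns `n_y, n_u, dim, E, E0, E2, fnn_ratio, n_skipped`, the
#'   parameters, and a `degenerate` flag (E2 within `1 +/- tol2` at every
#'   dimension: no appended coordinate ever becomes predictable, as for white
#'   noise, which has no finite embedding dimension).
#' @export
cao_statistics <- function(batches, target = "X", n_max = 8, R_T = 10,
                           tol = 0.05, tol2 = 0.1, criterion = "kennel") {
  if (inherits(batches, "batch_ts")) batches <- list(batches)
  r <- ncol(batches[[1]]$u)
  sched <- lag_schedule(n_max, r)
  K <- nrow(sched)
  if (K < 2L) {
    stop("n_max = ", n_max, " leaves fewer than two schedule entries; ",
         "increase n_max")
  }
  # one extra entry beyond the schedule is needed to evaluate E at the last one
  last <- c(sched$n_y[K], sched$n_u[K])
  ext <- if (last[1] == last[2]) c(last[1] + 1L, last[2]) else c(last[1], last[2] + 1L)
  all_ny <- c(sched$n_y, ext[1])
  all_nu <- c(sched$n_u, ext[2])
  trim <- max(all_ny, all_nu)
  V <- lapply(seq_along(all_ny), function(i) {
    embed_vectors(batches, target, all_ny[i], all_nu[i], trim)
  })
  if (nrow(V[[1]]) < 2L) stop("series too short for Cao statistics")
  E <- numeric(K)
  Estar <- numeric(K)
  fnn <- numeric(K)
  skipped <- integer(K)
  for (m in seq_len(K)) {
    nn <- linf_nn_all(V[[m]])
    d_n <- nn$dist
    d_n1 <- linf_pair_dist(V[[m + 1L]], seq_along(d_n), nn$index)
    ok <- d_n > 0
    if (!any(ok)) {
      stop("all dimension-", sched$dim[m], " nearest-neighbor distances are ",
           "zero; series is degenerate")
    }
    alpha <- d_n1[ok] / d_n[ok]
    E[m] <- mean(alpha)
    skipped[m] <- sum(!ok)
    fnn[m] <- mean((d_n1[ok] - d_n[ok]) / d_n[ok] >= R_T)
    # L-infinity difference over the coordinates appended at this step (each
    # scaled by its own dispersion so channels are comparable), between each
    # point and its dimension-n nearest neighbor
    app <- setdiff(colnames(V[[m + 1L]]), colnames(V[[m]]))
    A <- V[[m + 1L]][, app, drop = FALSE]
    A <- sweep(A, 2, pmax(apply(A, 2, stats::sd), .Machine$double.eps), "/")
    Estar[m] <- mean(linf_pair_dist(A, seq_along(d_n), nn$index))
  }
  E0 <- c(E[-1] / E[-K], NA_real_)
  E2 <- c(Estar[-1] / Estar[-K], NA_real_)
  degenerate <- all(abs(E2[seq_len(K - 1L)] - 1) < tol2)
  structure(
    list(table = cbind(sched, E = E, E0 = E0, E2 = E2, fnn_ratio = fnn,
                       n_skipped = skipped),
         R_T = R_T, tol = tol, tol2 = tol2, criterion = criterion,
         degenerate = degenerate),
    class = "embedding_diagnostics")
}

#' @export
print.embedding_diagnostics <- function(x, ...) {
  cat("<embedding_diagnostics> R_T =", x$R_T, " tol =", x$tol, "\n")
  print(x$table, row.names = FALSE)
  if (isTRUE(x$degenerate)) {
    cat("degenerate: no finite embedding dimension (noise-like series)\n")
  }
  invisible(x)
}

#' Select model orders (n_y, n_u) by FNN/Cao analysis
#'
#' Finds the minimum embedding dimension `n_min` as the smallest schedule
#' dimension at which the false-neighbor fraction has dropped to (near) zero
#' -- the method's primary termination rule -- or at which the E0 statistic
#' has stabilized at 1 (|E0 - 1| < tol), whichever happens at a smaller
#' dimension. It then ranks every split `n_y + n_u * r = n_min` (with
#' `n_u >= 1`) by one-step least-squares ARX residual on a held-out tail of
#' the data, and returns the best split with the full diagnostics.
#'
#' @inheritParams cao_statistics
#' @param delta0 False-neighbor fraction at or below which a dimension counts
#'   as fully unfolded (default 0.01).
#' @param holdout Fraction of pairs (chronological tail) held out for ranking
#'   candidate splits.
#' @return List with `n_y`, `n_u`, `n_min`, `diagnostics`, and the
#'   per-candidate held-out residual table `candidates`.
#' @export
select_orders <- function(batches, target = "X", n_max = 8, R_T = 10,
                          tol = 0.05, tol2 = 0.1, delta0 = 0.01,
                          criterion = "kennel", holdout = 0.25) {
  if (inherits(batches, "batch_ts")) batches <- list(batches)
  diag <- cao_statistics(batches, target, n_max, R_T, tol, tol2, criterion)
  tab <- diag$table
  K <- nrow(tab)
  hit_fnn <- which(tab$fnn_ratio <= delta0)
  hit_e0 <- which(abs(tab$E0[seq_len(K - 1L)] - 1) < tol)
  hits <- c(hit_fnn, hit_e0)
  if (!length(hits)) {
    stop("no embedding dimension satisfied the stability rule within n_max = ",
         n_max, "; increase n_max")
  }
  n_min <- tab$dim[min(hits)]
  if (diag$degenerate) {
    warning("appended coordinates never become predictable (E2 flat at 1); ",
            "the series looks like noise with no finite embedding dimension")
  }
  r <- ncol(batches[[1]]$u)
  cand <- expand.grid(n_y = 0:n_min, n_u = 1:n_min)
  cand <- cand[cand$n_y + cand$n_u * r == n_min, , drop = FALSE]
  if (!nrow(cand)) stop("no (n_y, n_u) split matches n_min = ", n_min)
  cand$holdout_rss <- vapply(seq_len(nrow(cand)), function(i) {
    ds <- build_regression_vectors(batches, target, cand$n_y[i], cand$n_u[i])
    N <- length(ds$y)
    n_hold <- max(1L, floor(holdout * N))
    tr <- seq_len(N - n_hold)
    te <- (N - n_hold + 1L):N
    A <- cbind(ds$X[tr, , drop = FALSE], 1)
    theta <- qr.coef(qr(A), ds$y[tr])
    theta[is.na(theta)] <- 0
    pred <- cbind(ds$X[te, , drop = FALSE], 1) %*% theta
    mean((ds$y[te] - pred)^2)
  }, numeric(1))
  best <- which.min(cand$holdout_rss)
  pwa_log("select_orders: n_min = ", n_min, ", chose (n_y, n_u) = (",
          cand$n_y[best], ", ", cand$n_u[best], ")")
  list(n_y = cand$n_y[best], n_u = cand$n_u[best], n_min = n_min,
       diagnostics = diag, candidates = cand)
}
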