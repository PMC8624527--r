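#' Joint optimization of the number and parameters of local models
#'
#' A particle encodes all S local models: the affine parameter vectors
#' theta_i (length d_theta = n_y + n_u*r + 1, affine term included) and the
#' cluster centers Z_i in modeling (z-) space (length n + 1), flattened as
#' [theta_1, Z_1, ..., theta_S, Z_S]. Fitness is the sum of squared one-step
#' residuals J1 after assigning every modeling vector to its nearest center.
#' An outer loop grows S from 1 until the best J1 meets the search threshold
#' Y_ts.
#'
#' @name identification
NULL

encode_particle <- function(theta_list, centers) {
  S <- length(theta_list)
  as.numeric(unlist(lapply(seq_len(S), function(i) {
    c(theta_list[[i]], centers[i, ])
  })))
}

decode_particle <- function(position, S, d_theta, d_z) {
  blk <- d_theta + d_z
  stopifnot(length(position) == S * blk)
  theta <- vector("list", S)
  centers <- matrix(0, S, d_z)
  for (i in seq_len(S)) {
    off <- (i - 1L) * blk
    theta[[i]] <- position[off + seq_len(d_theta)]
    centers[i, ] <- position[off + d_theta + seq_len(d_z)]
  }
  list(theta = theta, centers = centers)
}

#' Assign modeling vectors to their nearest cluster center
#'
#' Euclidean norm distance; ties go to the lowest center index.
#'
#' @param z Matrix of modeling vectors (rows).
#' @param centers Matrix of cluster centers (rows), same column count as `z`.
#' @return List with `labels` (per-row center index) and `sizes` (per-center
#'   counts; clusters may be empty).
#' @export
assign_clusters <- function(z, centers) {
  z <- as.matrix(z)
  centers <- as.matrix(centers)
  if (ncol(z) != ncol(centers)) {
    stop("dimension mismatch: z has ", ncol(z), " columns, centers have ",
         ncol(centers))
  }
  # squared distances via the expansion |z - c|^2 = |z|^2 - 2 z.c + |c|^2
  d2 <- outer(rowSums(z^2), rep(1, nrow(centers))) -
    2 * z %*% t(centers) +
    outer(rep(1, nrow(z)), rowSums(centers^2))
  labels <- max.col(-d2, ties.method = "first")
  list(labels = labels,
       sizes = tabulate(labels, nbins = nrow(centers)))
}

#' J1 fitness of one particle encoding
#'
#' Assigns each modeling vector z(k) to the particle's nearest cluster
#' center, then sums the squared residuals of the corresponding local affine
#' law: J1 = sum_k (y(k) - [X(k)^T, 1] theta_label(k))^2. Each empty cluster
#' adds a penalty of 10 times the J1 of the non-empty part, which keeps the
#' optimizer from inflating S with unused centers.
#'
#' @param position Flattened particle position (or a list with `theta` and
#'   `centers` as returned by the decoder).
#' @param dataset A `regression_dataset`.
#' @param S Number of local models encoded.
#' @return The (penalized) J1 value.
#' @export
fitness_J1 <- function(position, dataset, S) {
  d_theta <- ncol(dataset$X) + 1L
  d_z <- ncol(dataset$z)
  enc <- if (is.list(position)) position else {
    decode_particle(position, S, d_theta, d_z)
  }
  asg <- assign_clusters(dataset$z, enc$centers)
  Theta <- do.call(cbind, enc$theta)             # d_theta x S
  pred_all <- cbind(dataset$X, 1) %*% Theta      # N x S
  pred <- pred_all[cbind(seq_along(dataset$y), asg$labels)]
  J1 <- sum((dataset$y - pred)^2)
  n_empty <- sum(asg$sizes == 0L)
  if (n_empty > 0L) J1 <- J1 * (1 + 10 * n_empty)
  J1
}

#' Per-cluster ordinary least squares refit
#'
#' Fits each local affine law by least squares on its cluster, given labels.
#' Used as the attainable-parameter oracle in recovery tests and as an opt-in
#' polish step after the swarm search. Rank-deficient clusters get the
#' minimum-norm solution with a warning.
#'
#' @param labels Per-pair cluster labels in 1..S.
#' @param dataset A `regression_dataset`.
#' @param S Number of clusters (default `max(labels)`).
#' @return List of theta vectors (length n + 1 each).
#' @export
refine_local_parameters <- function(labels, dataset, S = max(labels)) {
  A_full <- cbind(dataset$X, 1)
  lapply(seq_len(S), function(i) {
    idx <- which(labels == i)
    if (!length(idx)) stop("cluster ", i, " is empty")
    A <- A_full[idx, , drop = FALSE]
    b <- dataset$y[idx]
    qr_A <- qr(A)
    if (qr_A$rank < ncol(A)) {
      warning("cluster ", i, " is rank-deficient (", length(idx),
              " points); using the minimum-norm solution")
      sv <- svd(A)
      pos <- sv$d > max(dim(A)) * .Machine$double.eps * sv$d[1]
      theta <- sv$v[, pos, drop = FALSE] %*%
        ((t(sv$u[, pos, drop = FALSE]) %*% b) / sv$d[pos])
      as.numeric(theta)
    } else {
      as.numeric(qr.coef(qr_A, b))
    }
  })
}

# Per-cluster least squares without warnings; clusters too small to
# determine theta keep their previous value.
ols_theta_quiet <- function(labels, dataset, S, d_theta, fallback,
                            theta_bound) {
  A_full <- cbind(dataset$X, 1)
  lapply(seq_len(S), function(i) {
    idx <- which(labels == i)
    if (length(idx) < d_theta) return(fallback[[i]])
    th <- qr.coef(qr(A_full[idx, , drop = FALSE]), dataset$y[idx])
    th[is.na(th)] <- 0
    pmin(pmax(as.numeric(th), -theta_bound), theta_bound)
  })
}

# Greedy farthest-point sample of S rows of z, started from a random row.
farthest_point_centers <- function(z, S) {
  N <- nrow(z)
  idx <- sample.int(N, 1L)
  if (S > 1L) {
    d <- rowSums((z - matrix(z[idx, ], N, ncol(z), byrow = TRUE))^2)
    for (i in 2:S) {
      nxt <- which.max(d)
      idx <- c(idx, nxt)
      d2 <- rowSums((z - matrix(z[nxt, ], N, ncol(z), byrow = TRUE))^2)
      d <- pmin(d, d2)
    }
  }
  z[idx, , drop = FALSE]
}

# A few Lloyd iterations pull farthest-point seeds (cloud extremes) to the
# cluster interiors; empty clusters keep their previous center.
lloyd_refine <- function(z, centers, iters = 3L) {
  for (it in seq_len(iters)) {
    asg <- assign_clusters(z, centers)
    for (s in seq_len(nrow(centers))) {
      idx <- which(asg$labels == s)
      if (length(idx)) centers[s, ] <- colMeans(z[idx, , drop = FALSE])
    }
  }
  centers
}

# Initial swarm for a given S: centers by farthest-point sampling refined by
# a few Lloyd steps; theta of half the particles from per-cluster least
# squares on the induced labels (a strong, data-driven start), the rest
# uniform in the theta box.
init_encoding_swarm <- function(dataset, S, config, d_theta, d_z,
                                theta_bound) {
  n <- config$n_particles
  P <- matrix(0, n, S * (d_theta + d_z))
  for (i in seq_len(n)) {
    centers <- farthest_point_centers(dataset$z, S)
    centers <- lloyd_refine(dataset$z, centers)
    if (i <= ceiling(n / 2)) {
      labels <- assign_clusters(dataset$z, centers)$labels
      theta <- lapply(seq_len(S), function(s) {
        idx <- which(labels == s)
        if (length(idx) < d_theta) {
          stats::runif(d_theta, -theta_bound, theta_bound)
        } else {
          A <- cbind(dataset$X[idx, , drop = FALSE], 1)
          th <- qr.coef(qr(A), dataset$y[idx])
          th[is.na(th)] <- 0
          pmin(pmax(as.numeric(th), -theta_bound), theta_bound)
        }
      })
    } else {
      theta <- lapply(seq_len(S), function(s) {
        stats::runif(d_theta, -theta_bound, theta_bound)
      })
    }
    P[i, ] <- encode_particle(theta, centers)
  }
  P
}

#' Identify a piecewise-affine ARX model by cluster-coupled swarm search
#'
#' Outer loop over the number of local models S = 1, 2, ...: for each S the
#' swarm minimizes [fitness_J1()] over the joint (theta, centers) encoding;
#' the loop stops at the smallest S whose best J1 meets the search threshold
#' `y_ts` (lexicographic treatment of the {J1, S} bi-objective). If `S_max`
#' is reached without meeting the threshold, the S with the smallest best J1
#' is returned and flagged.
#'
#' @param dataset A `regression_dataset`.
#' @param config A [swarm_config()]; its `lower`/`upper` are ignored (bounds
#'   are set per block: theta in [-theta_bound, theta_bound], centers in the
#'   data bounding box) and its `y_ts` is ignored in favor of `y_ts` below.
#' @param S_max Largest number of local models to try.
#' @param y_ts Search threshold on J1. Default: 1% of the total output sum of
#'   squares around the mean.
#' @param theta_bound Half-width of the theta search box (default 10,
#'   appropriate for data normalized to [-1, 1]).
#' @param polish If `TRUE`, refit each local model by per-cluster least
#'   squares after the search (off by default; the swarm's theta are kept).
#' @param seed RNG seed for the whole identification.
#' @return An object of class `pwarx_fit`: `S`, `theta` (list), `centers`
#'   (z-space), `labels`, `sizes`, per-S best-J1 table, `J1`, traces,
#'   `threshold_met`, `y_ts`, `seed`.
#' @export
identify_pwarx <- function(dataset, config = swarm_config(), S_max = 6,
                           y_ts = NULL, theta_bound = 10, polish = FALSE,
                           seed = 1L) {
  N <- length(dataset$y)
  if (!N) stop("empty dataset")
  if (is.null(y_ts)) y_ts <- 0.01 * sum((dataset$y - mean(dataset$y))^2)
  d_theta <- ncol(dataset$X) + 1L
  d_z <- ncol(dataset$z)
  z_lo <- apply(dataset$z, 2, min)
  z_hi <- apply(dataset$z, 2, max)
  per_S <- list()
  best <- NULL
  for (S in seq_len(S_max)) {
    set.seed(derive_seed(seed, S))
    lower <- rep(c(rep(-theta_bound, d_theta), z_lo), S)
    upper <- rep(c(rep(theta_bound, d_theta), z_hi), S)
    cfg <- config
    cfg$lower <- lower
    cfg$upper <- upper
    cfg$y_ts <- y_ts
    cfg$seed <- NULL          # RNG already seeded deterministically above
    init <- init_encoding_swarm(dataset, S, cfg, d_theta, d_z, theta_bound)
    fit_fn <- function(pos) fitness_J1(pos, dataset, S)
    repair <- function(pos) {
      enc <- decode_particle(pos, S, d_theta, d_z)
      asg <- assign_clusters(dataset$z, enc$centers)
      empty <- which(asg$sizes == 0L)
      if (length(empty)) {
        # teleport empty-cluster centers to the worst-fit points
        Theta <- do.call(cbind, enc$theta)
        pred_all <- cbind(dataset$X, 1) %*% Theta
        pred <- pred_all[cbind(seq_len(nrow(dataset$X)), asg$labels)]
        resid <- abs(dataset$y - pred)
        ord <- order(resid, decreasing = TRUE)
        for (j in seq_along(empty)) {
          enc$centers[empty[j], ] <- dataset$z[ord[j], ]
        }
        pos <- encode_particle(enc$theta, enc$centers)
      }
      pos
    }
    # elitist refinement of the incumbent: per-cluster least squares on the
    # labels induced by its centers (collapses the theta subproblem), with a
    # Lloyd-stepped-center variant; the swarm keeps exploring center space
    local_search <- function(position, value) {
      enc <- decode_particle(position, S, d_theta, d_z)
      best <- NULL
      for (centers in list(enc$centers, lloyd_refine(dataset$z, enc$centers, 1L))) {
        labels <- assign_clusters(dataset$z, centers)$labels
        theta <- ols_theta_quiet(labels, dataset, S, d_theta, enc$theta,
                                 theta_bound)
        pos <- encode_particle(theta, centers)
        f <- fitness_J1(pos, dataset, S)
        if (is.null(best) || f < best$value) best <- list(position = pos, value = f)
      }
      best
    }
    res <- pso_optimize(fit_fn, S * (d_theta + d_z), cfg, init = init,
                        repair_fn = repair, local_search_fn = local_search)
    per_S[[S]] <- list(S = S, J1 = res$value, trace = res$trace,
                       par = res$par, threshold_met = res$threshold_met)
    pwa_log("identify_pwarx: S = ", S, ", best J1 = ", signif(res$value, 6))
    if (is.null(best) || res$value < best$J1) best <- per_S[[S]]
    if (res$value <= y_ts) break
  }
  threshold_met <- best$J1 <= y_ts
  if (!threshold_met) {
    warning("S_max = ", S_max, " reached without meeting Y_ts = ",
            signif(y_ts, 6), "; returning the best S found (S = ", best$S, ")")
  }
  enc <- decode_particle(best$par, best$S, d_theta, d_z)
  asg <- assign_clusters(dataset$z, enc$centers)
  theta <- enc$theta
  if (polish) theta <- refine_local_parameters(asg$labels, dataset, best$S)
  structure(
    list(S = best$S, theta = theta, centers = enc$centers,
         labels = asg$labels, sizes = asg$sizes,
         J1 = fitness_J1(list(theta = theta, centers = enc$centers),
                         dataset, best$S),
         per_S = data.frame(S = vapply(per_S, `[[`, integer(1), "S"),
                            J1 = vapply(per_S, `[[`, numeric(1), "J1")),
         traces = lapply(per_S, `[[`, "trace"),
         threshold_met = threshold_met, y_ts = y_ts, seed = seed,
         polish = polish),
    class = "pwarx_fit")
}

#' @export
print.pwarx_fit <- function(x, ...) {
  cat(sprintf("<pwarx_fit> S = %d local models, J1 = %.6g (Y_ts = %.6g, %s)\n",
              x$S, x$J1, x$y_ts,
              if (x$threshold_met) "threshold met" else "S cap reached"))
  cat("cluster sizes:", paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}
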