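# Independent brute-force oracles, written with plain loops and none of the
# package's internal helpers, so they can vouch for the vectorized paths.

oracle_linf_nn <- function(V, p) {
  best_i <- NA_integer_
  best_d <- Inf
  for (i in seq_len(nrow(V))) {
    if (i == p) next
    d <- 0
    for (j in seq_len(ncol(V))) d <- max(d, abs(V[i, j] - V[p, j]))
    if (d < best_d) {
      best_d <- d
      best_i <- i
    }
  }
  list(index = best_i, distance = best_d)
}

# Piecewise-linear interpolation between observed knots, evaluated pointwise.
oracle_linear_interp <- function(t_obs, y_obs, t_query) {
  sapply(t_query, function(t) {
    if (t <= t_obs[1]) return(y_obs[1])
    if (t >= t_obs[length(t_obs)]) return(y_obs[length(y_obs)])
    i <- max(which(t_obs <= t))
    if (t_obs[i] == t) return(y_obs[i])
    w <- (t - t_obs[i]) / (t_obs[i + 1] - t_obs[i])
    (1 - w) * y_obs[i] + w * y_obs[i + 1]
  })
}

# Regression-vector construction by explicit index bookkeeping.
oracle_regression_vectors <- function(y, u, n_y, n_u, p = 0) {
  w <- max(n_y, p + n_u)
  n_t <- length(y)
  X <- NULL
  yy <- NULL
  for (k in (w + 1):n_t) {
    row <- c()
    for (l in seq_len(n_y)) row <- c(row, y[k - l])
    for (l in seq_len(n_u)) row <- c(row, u[k - p - l, ])
    X <- rbind(X, row)
    yy <- c(yy, y[k])
  }
  list(X = unname(X), y = yy)
}

# Cao statistics by double loops, mirroring the nested-schedule construction.
oracle_cao_table <- function(y, u, n_max) {
  r <- ncol(u)
  sched <- list(c(1L, 1L))
  repeat {
    last <- sched[[length(sched)]]
    nxt <- if (last[1] == last[2]) c(last[1] + 1L, last[2]) else c(last[1], last[2] + 1L)
    if (nxt[1] + nxt[2] * r > n_max) break
    sched[[length(sched) + 1L]] <- nxt
  }
  last <- sched[[length(sched)]]
  ext <- if (last[1] == last[2]) c(last[1] + 1L, last[2]) else c(last[1], last[2] + 1L)
  all_s <- c(sched, list(ext))
  trim <- max(unlist(all_s))
  vecs <- lapply(all_s, function(s) {
    n_y <- s[1]; n_u <- s[2]
    ks <- (trim + 1):length(y)
    V <- NULL
    for (k in ks) {
      row <- c()
      for (l in seq_len(n_y)) row <- c(row, y[k - l])
      for (l in seq_len(n_u)) row <- c(row, u[k - l, ])
      V <- rbind(V, row)
    }
    unname(V)
  })
  K <- length(sched)
  E <- numeric(K)
  for (m in seq_len(K)) {
    Vn <- vecs[[m]]
    Vn1 <- vecs[[m + 1]]
    alphas <- c()
    for (pp in seq_len(nrow(Vn))) {
      nn <- oracle_linf_nn(Vn, pp)
      if (nn$distance == 0) next
      d1 <- 0
      for (j in seq_len(ncol(Vn1))) {
        d1 <- max(d1, abs(Vn1[pp, j] - Vn1[nn$index, j]))
      }
      alphas <- c(alphas, d1 / nn$distance)
    }
    E[m] <- mean(alphas)
  }
  list(E = E, E0 = E[-1] / E[-K])
}

oracle_assign_clusters <- function(z, centers) {
  labels <- integer(nrow(z))
  for (i in seq_len(nrow(z))) {
    best <- Inf
    for (s in seq_len(nrow(centers))) {
      d <- sqrt(sum((z[i, ] - centers[s, ])^2))
      if (d < best) {
        best <- d
        labels[i] <- s
      }
    }
  }
  labels
}

oracle_J1 <- function(theta_list, centers, X, y, z) {
  labels <- oracle_assign_clusters(z, centers)
  J <- 0
  for (i in seq_along(y)) {
    th <- theta_list[[labels[i]]]
    J <- J + (y[i] - sum(c(X[i, ], 1) * th))^2
  }
  n_empty <- sum(!(seq_len(nrow(centers)) %in% labels))
  J * (1 + 10 * n_empty)
}

# LS-SVM system assembled entry by entry and solved with a generic solver.
oracle_lssvm <- function(x, labels, gamma, kernel = "linear", width = 0.2) {
  N <- nrow(x)
  A <- matrix(0, N + 1, N + 1)
  A[1, 2:(N + 1)] <- labels
  A[2:(N + 1), 1] <- labels
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      Kij <- if (kernel == "linear") {
        sum(x[i, ] * x[j, ])
      } else {
        exp(-sum((x[i, ] - x[j, ])^2) / width^2)
      }
      A[i + 1, j + 1] <- labels[i] * labels[j] * Kij
    }
    A[i + 1, i + 1] <- A[i + 1, i + 1] + 1 / gamma
  }
  sol <- qr.solve(A, c(0, rep(1, N)))
  list(b = sol[1], alpha = sol[-1])
}

oracle_assign_region <- function(X, surfaces, centers, S) {
  out <- integer(nrow(X))
  for (i in seq_len(nrow(X))) {
    feas <- rep(TRUE, S)
    for (s in surfaces) {
      v <- sum(s$w * X[i, ]) + s$v
      if (v < 0) feas[s$pair[1]] <- FALSE
      if (v > 0) feas[s$pair[2]] <- FALSE
    }
    if (any(feas)) {
      out[i] <- which(feas)[1]
    } else {
      best <- Inf
      for (s in seq_len(S)) {
        d <- sqrt(sum((X[i, ] - centers[s, seq_len(ncol(X))])^2))
        if (d < best) {
          best <- d
          out[i] <- s
        }
      }
    }
  }
  out
}

# Small deterministic ARX(2,1) batch used by several tests.
make_arx21_batch <- function(n = 400, seed = 42, noise_sd = 0,
                             normalize = TRUE) {
  set.seed(seed)
  u <- matrix(pwasoft:::ar1_series(n, 0.7, 0.4), ncol = 1)
  y <- numeric(n)
  e <- stats::rnorm(n, 0, noise_sd)
  for (k in 3:n) y[k] <- 0.6 * y[k - 1] - 0.2 * y[k - 2] + 0.5 * u[k - 1] + e[k]
  b <- batch_ts("arx21", u = u, y = cbind(X = y, P = 0))
  if (normalize) minmax_normalize(list(b))$batches else list(b)
}

make_noise_batch <- function(n = 1500, seed = 7) {
  set.seed(seed)
  b <- batch_ts("noise", u = matrix(stats::rnorm(n), ncol = 1),
                y = cbind(X = stats::rnorm(n), P = 0))
  minmax_normalize(list(b))$batches
}

# Best label agreement over all permutations of 1..S.
label_agreement <- function(found, truth, S) {
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  max(vapply(perms(seq_len(S)), function(p) mean(p[found] == truth),
             numeric(1)))
}
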