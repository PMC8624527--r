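#' Synthetic data generators
#'
#' Two families of ground-truth data keep every pipeline stage testable
#' without external measurements: exact piecewise-affine ARX systems with a
#' known partition (for recovery scoring), and a mechanistic batch
#' fermentation surrogate (logistic biomass growth with environmental
#' modulation and Luedeking-Piret product formation) emulating the sampling
#' design of a soft-sensing campaign: fast-grid inputs, slow-grid assayed
#' outputs, interpolation, [-1, 1] normalization, and train/validation/test
#' splits. All generators are pure functions of their spec and seed.
#'
#' @name synthetic_data
NULL

#' Specification of a synthetic PWARX system
#'
#' @param theta List of S true parameter vectors (length n_y + n_u*r + 1).
#' @param partition Region rule on regressor space: either
#'   `list(type = "centers", centers = <S x n matrix>)` (nearest center) or
#'   `list(type = "threshold", coord = j, breaks = <increasing breakpoints>)`
#'   (region by interval of regressor coordinate j; S = length(breaks) + 1).
#' @param orders List with `n_y`, `n_u`, `p`, `r`.
#' @param noise_sd Output noise standard deviation (>= 0).
#' @param n_samples Samples per batch.
#' @param n_batches Number of batches.
#' @param u_gen Function `(n_samples, r)` returning the input matrix for one
#'   batch; default stationary AR(1) per channel (coefficient 0.9,
#'   stationary sd 0.25).
#' @param y0 Initial output values over the lag window (default 0).
#' @return An object of class `pwarx_spec`.
#' @export
pwarx_spec <- function(theta, partition, orders, noise_sd = 0,
                       n_samples = 200, n_batches = 1, u_gen = NULL,
                       y0 = NULL) {
  stopifnot(noise_sd >= 0, n_samples > 0, n_batches >= 1)
  d_theta <- orders$n_y + orders$n_u * orders$r + 1L
  stopifnot(all(vapply(theta, length, integer(1)) == d_theta))
  S <- if (partition$type == "centers") nrow(partition$centers)
       else length(partition$breaks) + 1L
  stopifnot(S == length(theta))
  if (is.null(u_gen)) {
    u_gen <- function(n, r) {
      sapply(seq_len(r), function(j) ar1_series(n, coef = 0.9, sd = 0.25))
    }
  }
  structure(list(theta = theta, partition = partition, orders = orders,
                 noise_sd = noise_sd, n_samples = n_samples,
                 n_batches = n_batches, u_gen = u_gen,
                 y0 = y0, S = S),
            class = "pwarx_spec")
}

# Stationary AR(1) with the given stationary standard deviation.
ar1_series <- function(n, coef = 0.9, sd = 0.25, mean = 0) {
  innov_sd <- sd * sqrt(1 - coef^2)
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sd)
  for (k in seq_len(n - 1L)) x[k + 1L] <- coef * x[k] + stats::rnorm(1, 0, innov_sd)
  x + mean
}

region_of <- function(partition, X_row) {
  if (partition$type == "centers") {
    d2 <- rowSums((partition$centers -
                     matrix(X_row, nrow(partition$centers),
                            length(X_row), byrow = TRUE))^2)
    which.min(d2)
  } else {
    findInterval(X_row[partition$coord], partition$breaks) + 1L
  }
}

#' Generate data from a synthetic PWARX system
#'
#' Simulates `y(k) = [X(k)^T, 1] theta_{region(X(k))} + e(k)` with Gaussian
#' noise, batch by batch, and returns both the batches and the ground truth
#' needed to score recovery (per-pair regime labels aligned with
#' [build_regression_vectors()] output, the true theta, and the partition).
#'
#' @param spec A [pwarx_spec()].
#' @param seed Integer seed.
#' @return List with `batches`, `truth` (list: `labels`, `theta`,
#'   `partition`, `S`), and `spec`.
#' @export
gen_pwarx_dataset <- function(spec, seed = 1L) {
  o <- spec$orders
  w <- max(o$n_y, o$p + o$n_u)
  batches <- vector("list", spec$n_batches)
  labels <- integer(0)
  for (b in seq_len(spec$n_batches)) {
    set.seed(derive_seed(seed, b))
    n_t <- spec$n_samples
    u <- spec$u_gen(n_t, o$r)
    if (is.null(dim(u))) u <- matrix(u, ncol = o$r)
    y <- numeric(n_t)
    y[seq_len(w)] <- spec$y0 %||% rep(0, w)
    noise <- stats::rnorm(n_t, 0, spec$noise_sd)
    lab_b <- integer(n_t - w)
    for (k in (w + 1L):n_t) {
      ylags <- if (o$n_y > 0) y[k - seq_len(o$n_y)] else numeric(0)
      ulags <- as.numeric(t(u[k - o$p - seq_len(o$n_u), , drop = FALSE]))
      X <- c(ylags, ulags)
      i <- region_of(spec$partition, X)
      lab_b[k - w] <- i
      y[k] <- sum(c(X, 1) * spec$theta[[i]]) + noise[k]
      if (!is.finite(y[k]) || abs(y[k]) > 1e6) {
        stop("unstable recursion: |y| diverged under theta_", i,
             " = [", paste(signif(spec$theta[[i]], 4), collapse = ", "), "]")
      }
    }
    labels <- c(labels, lab_b)
    ymat <- cbind(X = y, P = 0)
    batches[[b]] <- batch_ts(paste0("pwarx_", b), u = u, y = ymat)
  }
  list(batches = batches,
       truth = list(labels = labels, theta = spec$theta,
                    partition = spec$partition, S = spec$S),
       spec = spec)
}

#' Specification of the fermentation surrogate
#'
#' Defaults emulate a protease-producing yeast batch: ~80 h duration, inputs
#' logged every 5 min around their control setpoints (temperature 28 C, pH
#' 7.3, dissolved oxygen ~40%, air flow 1100 L/h, stirring 250 rpm, tank
#' pressure 0.04 MPa) with AR(1) perturbations of 2% of the setpoint,
#' outputs assayed hourly, 10 batches thinned to 96 retained samples each,
#' and per-sample train/validation/test split sizes 576/204/180.
#'
#' @param mu_max Maximum specific growth rate (1/h).
#' @param K Biomass carrying capacity (g/L).
#' @param X0 Inoculum biomass (g/L).
#' @param lp_a,lp_b Luedeking-Piret growth-associated (g product / g biomass)
#'   and non-growth-associated (g product / (g biomass * h)) coefficients.
#' @param widths Bell-curve widths of the T / pH / DO growth modulation, in
#'   the units of each input.
#' @param setpoints Named input setpoints.
#' @param ar_coef,ar_frac AR(1) coefficient and perturbation size as a
#'   fraction of each setpoint.
#' @param duration_h Batch duration (hours).
#' @param step_minutes Input sampling interval.
#' @param obs_minutes Output assay interval.
#' @param n_batches Number of batches.
#' @param keep_per_batch Retained samples per batch after uniform thinning.
#' @param split Named train/validation/test sizes; must sum to
#'   `n_batches * keep_per_batch`.
#' @return An object of class `fermentation_spec`.
#' @export
fermentation_spec <- function(mu_max = 0.12, K = 40, X0 = 0.5,
                              lp_a = 0.08, lp_b = 0.002,
                              widths = c(T = 2, pH = 0.6, DO = 15),
                              setpoints = c(T = 28, DO = 40, pH = 7.3,
                                            q = 1100, v = 250, p = 0.04),
                              ar_coef = 0.9, ar_frac = 0.02,
                              duration_h = 80, step_minutes = 5,
                              obs_minutes = 60, n_batches = 10,
                              keep_per_batch = 96,
                              split = c(train = 576, validation = 204,
                                        test = 180)) {
  stopifnot(mu_max >= 0, K > 0, X0 > 0, lp_a >= 0, lp_b >= 0)
  if (sum(split) != n_batches * keep_per_batch) {
    stop("split sizes must sum to n_batches * keep_per_batch = ",
         n_batches * keep_per_batch)
  }
  structure(as.list(environment()), class = "fermentation_spec")
}

#' Generate fermentation surrogate batches
#'
#' Integrates logistic biomass growth, multiplicatively modulated by
#' bell-shaped deviations of temperature, pH and dissolved oxygen from their
#' setpoints, and Luedeking-Piret product formation
#' `dP/dt = a dX/dt + b X`, on the fast input grid. Hourly output
#' observations are marked in the mask; outputs are then interpolated to the
#' fast grid, all channels normalized to [-1, 1], each batch uniformly
#' thinned to the retained sample count, and per-sample split labels
#' assigned sequentially (train, then validation, then test).
#'
#' @param spec A [fermentation_spec()].
#' @param seed Integer seed.
#' @return List with `batches` (normalized, interpolated, thinned),
#'   `batches_raw` (physical units, full fast grid), `transform` (the
#'   scaling), and `spec`.
#' @export
gen_fermentation_batches <- function(spec, seed = 1L) {
  n_t <- as.integer(spec$duration_h * 60 / spec$step_minutes)
  dt <- spec$step_minutes / 60
  obs_every <- as.integer(spec$obs_minutes / spec$step_minutes)
  raw <- vector("list", spec$n_batches)
  for (b in seq_len(spec$n_batches)) {
    set.seed(derive_seed(seed, 100L + b))
    u <- sapply(names(spec$setpoints), function(ch) {
      sp <- spec$setpoints[[ch]]
      ar1_series(n_t, coef = spec$ar_coef, sd = spec$ar_frac * sp, mean = sp)
    })
    colnames(u) <- names(spec$setpoints)
    X <- numeric(n_t)
    P <- numeric(n_t)
    X[1] <- spec$X0 * stats::runif(1, 0.9, 1.1)
    for (k in seq_len(n_t - 1L)) {
      mod <- exp(-((u[k, "T"] - spec$setpoints[["T"]]) / spec$widths[["T"]])^2) *
        exp(-((u[k, "pH"] - spec$setpoints[["pH"]]) / spec$widths[["pH"]])^2) *
        exp(-((u[k, "DO"] - spec$setpoints[["DO"]]) / spec$widths[["DO"]])^2)
      dX <- spec$mu_max * mod * X[k] * (1 - X[k] / spec$K)
      X[k + 1L] <- X[k] + dt * dX
      P[k + 1L] <- P[k] + dt * (spec$lp_a * dX + spec$lp_b * X[k])
      if (X[k + 1L] < 0 || P[k + 1L] < 0) {
        warning("negative state clipped to 0 in batch ", b)
        X[k + 1L] <- max(X[k + 1L], 0)
        P[k + 1L] <- max(P[k + 1L], 0)
      }
    }
    mask <- (seq_len(n_t) - 1L) %% obs_every == 0L
    mask[n_t] <- TRUE     # close the interpolation interval at the batch end
    y <- cbind(X = X, P = P)
    y[!mask, ] <- NA
    raw[[b]] <- batch_ts(paste0("ferm_", b), u = u, y = y, y_observed = mask,
                         step_minutes = spec$step_minutes)
  }
  interp <- lapply(raw, interpolate_outputs)
  norm <- minmax_normalize(interp)
  keep <- seq(1L, by = max(1L, n_t %/% spec$keep_per_batch),
              length.out = spec$keep_per_batch)
  thinned <- lapply(norm$batches, function(b) {
    batch_ts(b$batch_id, u = b$u[keep, , drop = FALSE],
             y = b$y[keep, , drop = FALSE],
             y_observed = b$y_observed[keep],
             step_minutes = b$step_minutes * (keep[2] - keep[1]))
  })
  # sequential per-sample split labels across the concatenated batches
  lab <- rep(names(spec$split), times = spec$split)
  off <- 0L
  for (b in seq_along(thinned)) {
    n_b <- nrow(thinned[[b]]$u)
    thinned[[b]]$split <- lab[off + seq_len(n_b)]
    off <- off + n_b
  }
  list(batches = thinned, batches_raw = raw, transform = norm$transform,
       spec = spec)
}

#' Two-regime noiseless benchmark system
#'
#' A single-input, single-output-lag piecewise-affine system with two
#' center-separated regimes: the input alternates between two levels (square
#' wave with AR(1) jitter) so the regressor cloud forms two compact, well
#' separated clusters, each governed by its own affine law, and the true
#' partition is exactly a nearest-center rule. Noiseless, so exact parameter
#' recovery is attainable; the standard parameter-recovery benchmark.
#'
#' @param seed Integer seed.
#' @param n_samples Samples in the single batch (default 300).
#' @return As [gen_pwarx_dataset()].
#' @export
make_two_regime_benchmark <- function(seed = 1L, n_samples = 300) {
  orders <- list(n_y = 1L, n_u = 1L, p = 0L, r = 1L)
  theta <- list(c(0.4, 0.5, -0.2), c(-0.3, 0.6, 0.4))
  partition <- list(type = "centers",
                    centers = rbind(c(-0.75, -0.5), c(0.55, 0.5)))
  u_gen <- function(n, r) {
    lev <- rep(rep(c(-0.5, 0.5), length.out = 6), each = ceiling(n / 6))[seq_len(n)]
    matrix(lev + ar1_series(n, 0.8, 0.05), ncol = 1)
  }
  spec <- pwarx_spec(theta, partition, orders, noise_sd = 0,
                     n_samples = n_samples, n_batches = 1, u_gen = u_gen,
                     y0 = -0.75)
  gen_pwarx_dataset(spec, seed = seed)
}

#' Three-phase piecewise-affine fixture
#'
#' A synthetic six-input system whose regime follows the dissolved-oxygen
#' trajectory: DO ramps from high to low over the batch, and the active local
#' model switches at DO thresholds, emulating the adjustment (lag),
#' logarithmic-growth and stationary phases of a batch fermentation. Orders
#' are one output lag and one input lag, so each local parameter vector has
#' 8 entries. The three regimes occupy contiguous time segments and their
#' parameter vectors differ strongly enough to be identifiable.
#'
#' @param seed Integer seed.
#' @param n_batches Number of batches (default 10).
#' @param n_samples Samples per batch (default 96).
#' @param noise_sd Output noise sd (default 0.01).
#' @return As [gen_pwarx_dataset()], with per-sample split labels
#'   (576/204/180 under the defaults) attached to the batches.
#' @export
make_three_phase_fixture <- function(seed = 1L, n_batches = 10,
                                     n_samples = 96, noise_sd = 0.01) {
  orders <- list(n_y = 1L, n_u = 1L, p = 0L, r = 6L)
  #        [y.l1,   T,    DO,    pH,    q,     v,     p,  1]
  theta <- list(
    lag        = c(0.10,  0.30,  0.20, -0.30,  0.30, -0.20,  0.20, -0.60),
    growth     = c(0.60, -0.30, -0.20,  0.30, -0.30,  0.20, -0.20,  0.00),
    stationary = c(-0.35, 0.30, -0.20, -0.30,  0.30, -0.20,  0.20,  0.90))
  # regressor coordinate 3 is DO(k-1); regions: DO < -0.3 (stationary),
  # [-0.3, 0.3) (growth), >= 0.3 (lag) -- ordered so the threshold rule maps
  # region 1 = stationary, 2 = growth, 3 = lag
  partition <- list(type = "threshold", coord = 3L, breaks = c(-0.3, 0.3))
  theta <- list(theta$stationary, theta$growth, theta$lag)
  u_gen <- function(n, r) {
    u <- sapply(seq_len(r), function(j) ar1_series(n, coef = 0.9, sd = 0.20))
    ramp <- seq(0.9, -0.9, length.out = n)
    u[, 2] <- ramp + ar1_series(n, coef = 0.9, sd = 0.05)
    u
  }
  spec <- pwarx_spec(theta = theta, partition = partition, orders = orders,
                     noise_sd = noise_sd, n_samples = n_samples,
                     n_batches = n_batches, u_gen = u_gen, y0 = -0.9)
  out <- gen_pwarx_dataset(spec, seed = seed)
  total <- n_batches * n_samples
  sizes <- round(total * c(train = 0.6, validation = 0.2125, test = 0.1875))
  sizes["test"] <- total - sizes["train"] - sizes["validation"]
  lab <- rep(names(sizes), times = sizes)
  off <- 0L
  for (b in seq_along(out$batches)) {
    n_b <- nrow(out$batches[[b]]$u)
    out$batches[[b]]$split <- lab[off + seq_len(n_b)]
    off <- off + n_b
  }
  out
}
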