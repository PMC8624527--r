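#' Particle swarm optimizer with an iteration-dependent compression factor
#'
#' Minimizes a fitness function over a box. The velocity update is
#' \deqn{v \leftarrow \mu \,(w v + c_1 r_1 (p^b - p) + c_2 r_2 (p^b_g - p))}
#' where the multiplier mu depends on `factor_mode`:
#' `"icf_printed"` uses the raw schedule
#' \eqn{\mu(G) = \delta\,\sigma^{G/(N+G-1)}}; `"icf_normalized"` (default)
#' divides that schedule by its value at G = 1 so it starts at exactly 1 and
#' decays towards 0 (the stated design intent of the schedule); `"clerc"`
#' uses the constant Clerc constriction factor; `"none"` uses mu = 1
#' (standard PSO). With sigma < 1 both ICF schedules are strictly decreasing
#' in G, fast early and flat late, which lets particles escape local optima
#' early and search finely later.
#'
#' @name icf_pso
NULL

#' Swarm configuration
#'
#' @param n_particles Swarm size N_S (>= 2; default 30).
#' @param w Inertia weight (default 0.729).
#' @param c1,c2 Acceleration coefficients (default 1.49 each).
#' @param icf_delta,icf_sigma Compression-factor constants (defaults 24 and
#'   0.01, the recommended regime with delta > 1 and sigma in (0, 1)).
#' @param icf_N Nominal iteration total N in the mu schedule (default 300).
#' @param n_iter Maximum iterations N_it (default 300).
#' @param y_ts Fitness threshold: the run stops once the global best fitness
#'   is <= `y_ts` (default `-Inf`, i.e. run all iterations).
#' @param factor_mode One of `"icf_normalized"`, `"icf_printed"`, `"clerc"`,
#'   `"none"`.
#' @param lower,upper Position bounds (scalars or length-D vectors).
#' @param v_max Optional velocity clamp (absolute, per dimension).
#' @param seed Optional RNG seed for a reproducible run.
#' @return An object of class `swarm_config`.
#' @export
swarm_config <- function(n_particles = 30, w = 0.729, c1 = 1.49, c2 = 1.49,
                         icf_delta = 24, icf_sigma = 0.01, icf_N = 300,
                         n_iter = 300, y_ts = -Inf,
                         factor_mode = c("icf_normalized", "icf_printed",
                                         "clerc", "none"),
                         lower = -10, upper = 10, v_max = NULL, seed = NULL) {
  factor_mode <- match.arg(factor_mode)
  stopifnot(n_particles >= 2, c1 > 0, c2 > 0, icf_delta > 0, icf_sigma > 0,
            n_iter >= 1, icf_N >= 1)
  structure(list(n_particles = n_particles, w = w, c1 = c1, c2 = c2,
                 icf_delta = icf_delta, icf_sigma = icf_sigma, icf_N = icf_N,
                 n_iter = n_iter, y_ts = y_ts, factor_mode = factor_mode,
                 lower = lower, upper = upper, v_max = v_max, seed = seed),
            class = "swarm_config")
}

#' Compression factor schedule
#'
#' @param G Current iteration (scalar or vector, >= 1).
#' @param icf_delta,icf_sigma Schedule constants delta and sigma (> 0).
#' @param N Nominal iteration total.
#' @param mode `"printed"` returns `delta * sigma^(G / (N + G - 1))` exactly;
#'   `"normalized"` divides by the value at G = 1 so the schedule starts at 1.
#' @return mu(G), strictly decreasing in G when sigma < 1.
#' @export
compression_factor <- function(G, icf_delta = 24, icf_sigma = 0.01, N = 300,
                               mode = c("normalized", "printed")) {
  mode <- match.arg(mode)
  if (any(G < 1) || N < 1 || icf_delta <= 0 || icf_sigma <= 0) {
    stop("compression_factor: G, N must be >= 1 and delta, sigma > 0")
  }
  mu <- icf_delta * icf_sigma^(G / (N + G - 1))
  if (mode == "normalized") {
    mu <- mu / (icf_delta * icf_sigma^(1 / N))
  }
  mu
}

#' Clerc constriction factor
#'
#' phi = 2 / |2 - rho - sqrt(rho^2 - 4 rho)| with rho = c1 + c2, defined for
#' rho > 4.
#'
#' @param c1,c2 Acceleration coefficients.
#' @return The constriction factor phi.
#' @export
clerc_factor <- function(c1, c2) {
  rho <- c1 + c2
  if (rho <= 4) stop("clerc_factor requires c1 + c2 > 4")
  2 / abs(2 - rho - sqrt(rho^2 - 4 * rho))
}

#' Plot compression-factor schedules
#'
#' Draws mu(G) over the iteration range for a set of (delta, sigma) pairs,
#' covering both admissible regimes (delta in (0,1) with sigma > 1, and
#' delta > 1 with sigma in (0,1)).
#'
#' @param pairs Two-column matrix or data.frame of (delta, sigma) values;
#'   default: six representative pairs spanning both regimes.
#' @param N Iteration total (default 300).
#' @param mode `"printed"` or `"normalized"`.
#' @return Invisibly, the matrix of schedules (iterations x pairs).
#' @export
plot_compression_schedules <- function(pairs = NULL, N = 300,
                                       mode = "printed") {
  if (is.null(pairs)) {
    pairs <- rbind(c(0.5, pi), c(0.5, 2 * pi), c(0.1, 2 * pi),
                   c(2 * pi, 0.5), c(24, 0.5), c(24, 0.01))
  }
  G <- seq_len(N)
  M <- sapply(seq_len(nrow(pairs)), function(i) {
    compression_factor(G, pairs[i, 1], pairs[i, 2], N, mode)
  })
  graphics::matplot(G, M, type = "l", lty = 1, col = seq_len(ncol(M)),
                    xlab = "iteration G", ylab = expression(mu(G)),
                    main = "compression-factor schedules")
  graphics::legend("topright", lty = 1, col = seq_len(ncol(M)),
                   legend = apply(pairs, 1, function(p) {
                     sprintf("delta=%.3g, sigma=%.3g", p[1], p[2])
                   }), cex = 0.8)
  invisible(M)
}

expand_bound <- function(b, D) {
  if (length(b) == 1L) rep(b, D) else {
    stopifnot(length(b) == D)
    as.numeric(b)
  }
}

# Evaluate fitness for every particle row; non-finite values become +Inf.
eval_fitness <- function(fitness_fn, P) {
  f <- vapply(seq_len(nrow(P)), function(i) {
    v <- fitness_fn(P[i, ])
    if (!is.finite(v)) {
      pwa_log("non-finite fitness at particle ", i, "; set to +Inf")
      v <- Inf
    }
    v
  }, numeric(1))
  f
}

init_swarm <- function(fitness_fn, D, config, init = NULL) {
  lo <- expand_bound(config$lower, D)
  hi <- expand_bound(config$upper, D)
  n <- config$n_particles
  P <- if (is.null(init)) {
    matrix(stats::runif(n * D, rep(lo, each = n), rep(hi, each = n)), n, D)
  } else {
    stopifnot(nrow(init) == n, ncol(init) == D)
    init
  }
  fit <- eval_fitness(fitness_fn, P)
  g <- which.min(fit)
  list(P = P, V = matrix(0, n, D), pbest = P, pbest_fit = fit,
       gbest = P[g, ], gbest_fit = fit[g], G = 0L, trace = fit[g],
       lower = lo, upper = hi)
}

#' One swarm iteration
#'
#' Draws r1, r2 i.i.d. uniform(0,1) per particle and dimension, applies the
#' configured velocity multiplier, moves the particles, clips out-of-bounds
#' positions to the box (zeroing the velocity in the violated dimension),
#' re-evaluates fitness and refreshes the personal and global bests.
#'
#' @param state Swarm state from `init_swarm` / a previous call.
#' @param config A [swarm_config()].
#' @param fitness_fn Scalar fitness function of a position vector.
#' @return The updated state with `G` incremented.
#' @export
update_swarm <- function(state, config, fitness_fn) {
  n <- nrow(state$P)
  D <- ncol(state$P)
  G <- state$G + 1L
  mu <- switch(config$factor_mode,
    icf_printed = compression_factor(G, config$icf_delta, config$icf_sigma,
                                     config$icf_N, "printed"),
    icf_normalized = compression_factor(G, config$icf_delta, config$icf_sigma,
                                        config$icf_N, "normalized"),
    clerc = clerc_factor(config$c1, config$c2),
    none = 1)
  r1 <- matrix(stats::runif(n * D), n, D)
  r2 <- matrix(stats::runif(n * D), n, D)
  V <- mu * (config$w * state$V +
               config$c1 * r1 * (state$pbest - state$P) +
               config$c2 * r2 * (matrix(state$gbest, n, D, byrow = TRUE) - state$P))
  if (!is.null(config$v_max)) {
    V <- pmin(pmax(V, -config$v_max), config$v_max)
  }
  P <- state$P + V
  lo <- matrix(state$lower, n, D, byrow = TRUE)
  hi <- matrix(state$upper, n, D, byrow = TRUE)
  out <- P < lo | P > hi
  if (any(out)) {
    P <- pmin(pmax(P, lo), hi)
    V[out] <- 0
  }
  fit <- eval_fitness(fitness_fn, P)
  better <- fit < state$pbest_fit
  pbest <- state$pbest
  pbest[better, ] <- P[better, ]
  pbest_fit <- ifelse(better, fit, state$pbest_fit)
  g <- which.min(pbest_fit)
  state$P <- P
  state$V <- V
  state$pbest <- pbest
  state$pbest_fit <- pbest_fit
  state$gbest <- pbest[g, ]
  state$gbest_fit <- pbest_fit[g]
  state$G <- G
  state$trace <- c(state$trace, state$gbest_fit)
  state
}

#' Run the (ICF-)PSO optimizer
#'
#' Iterates [update_swarm()] until the global best fitness falls to the
#' threshold `y_ts` or the iteration budget is reached. Fully reproducible
#' given `config$seed`.
#'
#' @param fitness_fn Scalar fitness function of a position vector (minimized).
#' @param D Problem dimension.
#' @param config A [swarm_config()].
#' @param init Optional n_particles x D matrix of initial positions
#'   (default: uniform in the bounds).
#' @param repair_fn Optional function applied to each particle position after
#'   every move (e.g. a problem-specific repair step); must return a position
#'   of the same dimension.
#' @param local_search_fn Optional elitist local search: a function
#'   `(position, value)` returning `list(position, value)`; when it improves
#'   on the global best, the candidate replaces the current worst personal
#'   best and becomes the global best.
#' @return List with `par` (best position), `value` (best fitness), `trace`
#'   (per-iteration global best, starting at initialization),
#'   `iterations`, `threshold_met`, and the final `state`.
#' @export
pso_optimize <- function(fitness_fn, D, config = swarm_config(), init = NULL,
                         repair_fn = NULL, local_search_fn = NULL) {
  if (!is.null(config$seed)) set.seed(config$seed)
  state <- init_swarm(fitness_fn, D, config, init)
  met <- state$gbest_fit <= config$y_ts
  while (!met && state$G < config$n_iter) {
    state <- update_swarm(state, config, fitness_fn)
    if (!is.null(repair_fn)) {
      for (i in seq_len(nrow(state$P))) {
        state$P[i, ] <- repair_fn(state$P[i, ])
      }
    }
    if (!is.null(local_search_fn)) {
      cand <- local_search_fn(state$gbest, state$gbest_fit)
      if (!is.null(cand) && cand$value < state$gbest_fit) {
        j <- which.max(state$pbest_fit)
        state$pbest[j, ] <- cand$position
        state$pbest_fit[j] <- cand$value
        state$gbest <- cand$position
        state$gbest_fit <- cand$value
        state$trace[length(state$trace)] <- cand$value
      }
    }
    met <- state$gbest_fit <= config$y_ts
  }
  list(par = state$gbest, value = state$gbest_fit, trace = state$trace,
       iterations = state$G, threshold_met = met, state = state)
}
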