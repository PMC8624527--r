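test_that("one-step prediction reduces to the active local law", {
  # S = 1: a plain global affine ARX prediction
  m1 <- pwarx_model(list(n_y = 1L, n_u = 1L, p = 0L, r = 1L), "X",
                    theta = list(c(0.5, 0.3, -0.1)))
  expect_equal(predict_one_step(m1, c(2, 1))$y_hat, 0.5 * 2 + 0.3 * 1 - 0.1)
  expect_error(predict_one_step(m1, c(1, 2, 3)), "dimension")
  # boundary point: the lower-indexed region's law applies
  s <- structure(list(pair = c(1L, 2L), w = c(1, 0), v = 0),
                 class = "dividing_surface")
  m2 <- pwarx_model(list(n_y = 1L, n_u = 1L, p = 0L, r = 1L), "X",
                    theta = list(c(1, 0, 0), c(2, 0, 0)),
                    surfaces = list(s),
                    centers = rbind(c(1, 0, 1), c(-1, 0, -2)))
  expect_equal(predict_one_step(m2, c(0, 3))$region, 1L)
  # batch prediction equals the brute-force indicator sum
  set.seed(26)
  cen <- matrix(rnorm(9), 3, 3)
  surfs <- list(
    structure(list(pair = c(1L, 2L), w = rnorm(2), v = 0.1),
              class = "dividing_surface"),
    structure(list(pair = c(2L, 3L), w = rnorm(2), v = -0.2),
              class = "dividing_surface"))
  theta <- list(rnorm(3), rnorm(3), rnorm(3))
  m3 <- pwarx_model(list(n_y = 1L, n_u = 1L, p = 0L, r = 1L), "X",
                    theta = theta, surfaces = surfs, centers = cen)
  X <- matrix(rnorm(100), 50, 2)
  got <- predict_one_step(m3, X)
  regions <- oracle_assign_region(X, surfs, cen, 3)
  want <- sapply(seq_len(50), function(i) {
    sum(sapply(1:3, function(s) {
      sum(c(X[i, ], 1) * theta[[s]]) * (regions[i] == s)
    }))
  })
  expect_equal(got$y_hat, want)
})

test_that("error metrics follow their closed forms and homogeneity", {
  ev <- error_metrics(c(1, 2, 4), c(1.1, 1.8, 4.4))
  expect_equal(ev$mape, 0.1)
  expect_equal(ev$rmse, sqrt(mean(c(-0.1, 0.2, -0.4)^2)))
  # perfect prediction
  ev0 <- error_metrics(c(1, 2), c(1, 2))
  expect_equal(ev0$mape, 0)
  expect_equal(ev0$rmse, 0)
  # scaling both series leaves MAPE unchanged and scales RMSE
  ev3 <- error_metrics(3 * c(1, 2, 4), 3 * c(1.1, 1.8, 4.4))
  expect_equal(ev3$mape, 0.1)
  expect_equal(ev3$rmse, 3 * ev$rmse)
  # near-zero targets are excluded from MAPE, not from RMSE
  ev4 <- error_metrics(c(0, 1), c(0.5, 1.1), floor = 1e-8)
  expect_equal(ev4$n_excluded, 1)
  expect_equal(ev4$mape, 0.1, tolerance = 1e-12)
  expect_error(error_metrics(c(0, 0), c(1, 1)), "floor")
})

test_that("model evaluation recomputes from stored predictions and reports the size table", {
  gen <- make_three_phase_fixture(seed = 6)
  ds <- build_regression_vectors(gen$batches, "X", 1, 1)
  tr <- which(ds$split == "train")
  dst <- pwasoft:::subset_dataset(ds, tr)
  theta <- refine_local_parameters(gen$truth$labels[tr], dst, 3)
  centers <- do.call(rbind, lapply(1:3, function(i) {
    colMeans(dst$z[gen$truth$labels[tr] == i, ])
  }))
  surfs <- build_surfaces(dst$X, gen$truth$labels[tr], centers)
  model <- pwarx_model(list(n_y = 1L, n_u = 1L, p = 0L, r = 6L), "X",
                       theta, surfs, centers)
  ev <- evaluate_model(model, gen$batches, split = "test")
  # the table covers 20-sample increments up to the split size
  expect_equal(ev$rmse_by_size$n[1], 20)
  expect_equal(max(ev$rmse_by_size$n), length(ev$y))
  # metrics equal brute-force recomputation from the prediction series
  keep <- abs(ev$y) >= 1e-8
  expect_equal(ev$normalized$mape,
               mean(abs((ev$y[keep] - ev$y_hat[keep]) / ev$y[keep])))
  expect_equal(ev$normalized$rmse, sqrt(mean((ev$y - ev$y_hat)^2)))
  expect_error(evaluate_model(model, gen$batches, split = "nope"), "split")
})

test_that("the ground-truth model reproduces its own noiseless data", {
  fx <- make_three_phase_fixture(seed = 9, n_batches = 2, n_samples = 60,
                                 noise_sd = 0)
  ds <- build_regression_vectors(fx$batches, "X", 1, 1)
  pred <- sapply(seq_along(ds$y), function(i) {
    sum(c(ds$X[i, ], 1) * fx$truth$theta[[fx$truth$labels[i]]])
  })
  expect_lt(max(abs(pred - ds$y)), 1e-10)
})

test_that("model JSON serialization round-trips losslessly", {
  gen <- make_two_regime_benchmark(seed = 10, n_samples = 120)
  ds <- build_regression_vectors(gen$batches, "X", 1, 1)
  fit <- identify_pwarx(ds, swarm_config(n_particles = 10, n_iter = 30),
                        S_max = 2, seed = 2)
  tf <- fit_scaling(gen$batches)
  surfs <- if (fit$S > 1) build_surfaces(ds$X, fit$labels, fit$centers) else list()
  m <- pwarx_model(list(n_y = 1L, n_u = 1L, p = 0L, r = 1L), "X",
                   fit$theta, surfs, fit$centers, scaling = tf,
                   metadata = list(seed = 2))
  path <- withr::local_tempfile(fileext = ".json")
  write_pwarx_model(m, path)
  m2 <- read_pwarx_model(path)
  expect_identical(m2$theta, m$theta)
  expect_identical(m2$centers, unname(m$centers))
  expect_identical(lapply(m2$surfaces, unclass), lapply(m$surfaces, unclass))
  expect_equal(m2$scaling$lo, m$scaling$lo)
  expect_identical(m2$orders, m$orders)
})

test_that("free-run simulation stays on the model's trajectory for an exact model", {
  gen <- make_two_regime_benchmark(seed = 12, n_samples = 100)
  ds <- build_regression_vectors(gen$batches, "X", 1, 1)
  centers <- do.call(rbind, lapply(1:2, function(i) {
    colMeans(ds$z[gen$truth$labels == i, ])
  }))
  surfs <- build_surfaces(ds$X, gen$truth$labels, centers)
  m <- pwarx_model(list(n_y = 1L, n_u = 1L, p = 0L, r = 1L), "X",
                   gen$truth$theta, surfs, centers)
  sim <- simulate_free_run(m, gen$batches[[1]])
  err <- abs(sim[-1] - gen$batches[[1]]$y[-1, "X"])
  expect_lt(stats::median(err), 0.05)
})
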