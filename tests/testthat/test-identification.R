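test_that("cluster assignment is nearest-center with low-index ties, matching brute force", {
  centers <- rbind(c(0, 0), c(1, 0), c(2, 2))
  expect_equal(assign_clusters(rbind(c(1, 0)), centers)$labels, 2L)
  # equidistant between centers 1 and 2: the lower index wins
  expect_equal(assign_clusters(rbind(c(0.5, 0)), centers)$labels, 1L)
  expect_error(assign_clusters(matrix(0, 1, 3), centers), "dimension mismatch")
  set.seed(14)
  z <- matrix(rnorm(400), 100, 4)
  cen <- matrix(rnorm(16), 4, 4)
  got <- assign_clusters(z, cen)
  expect_equal(got$labels, oracle_assign_clusters(z, cen))
  expect_equal(got$sizes, tabulate(got$labels, 4))
  expect_equal(sum(got$sizes), 100)
})

test_that("J1 fitness is the clustered sum of squared residuals", {
  set.seed(15)
  X <- matrix(rnorm(60), 30, 2)
  theta_true <- c(0.5, -0.3, 0.2)
  y <- as.numeric(cbind(X, 1) %*% theta_true)
  ds <- structure(list(X = X, y = y, z = cbind(X, y)),
                  class = "regression_dataset")
  # exact fit: zero objective
  enc1 <- list(theta = list(theta_true), centers = matrix(colMeans(ds$z), 1))
  expect_equal(fitness_J1(enc1, ds, 1), 0)
  # constant offset c on every prediction adds M * c^2
  enc2 <- list(theta = list(theta_true + c(0, 0, 0.25)),
               centers = matrix(colMeans(ds$z), 1))
  expect_equal(fitness_J1(enc2, ds, 1), 30 * 0.25^2)
  # random 2-cluster instance equals the double-loop oracle
  theta2 <- list(rnorm(3), rnorm(3))
  cen2 <- ds$z[c(3, 17), ]
  enc3 <- list(theta = theta2, centers = cen2)
  expect_equal(fitness_J1(enc3, ds, 2),
               oracle_J1(theta2, cen2, X, y, ds$z))
})

test_that("empty clusters are penalized", {
  X <- matrix(seq(-1, 1, length.out = 20), ncol = 1)
  y <- as.numeric(0.5 * X + 0.1)
  ds <- structure(list(X = X, y = y, z = cbind(X, y)),
                  class = "regression_dataset")
  far <- rbind(colMeans(ds$z), c(100, 100))
  enc <- list(theta = list(c(0.5, 0.1), c(0, 0)), centers = far)
  base <- sum((y - cbind(X, 1) %*% c(0.5, 0.1))^2)
  expect_equal(fitness_J1(enc, ds, 2), base * 11)
})

test_that("per-cluster least squares recovers exact laws and handles degeneracy", {
  set.seed(16)
  X <- matrix(rnorm(80), 40, 2)
  th1 <- c(1, -2, 0.5)
  th2 <- c(-0.5, 0.3, 1.2)
  lab <- rep(1:2, each = 20)
  y <- ifelse(lab == 1, cbind(X, 1) %*% th1, cbind(X, 1) %*% th2)
  ds <- structure(list(X = X, y = as.numeric(y), z = cbind(X, y)),
                  class = "regression_dataset")
  th <- refine_local_parameters(lab, ds, 2)
  expect_equal(th[[1]], th1, tolerance = 1e-10)
  expect_equal(th[[2]], th2, tolerance = 1e-10)
  # overdetermined noisy cluster matches the normal equations
  yn <- as.numeric(cbind(X, 1) %*% th1 + rnorm(40, 0, 0.1))
  dsn <- structure(list(X = X, y = yn, z = cbind(X, yn)),
                   class = "regression_dataset")
  thn <- refine_local_parameters(rep(1, 40), dsn, 1)[[1]]
  A <- cbind(X, 1)
  expect_equal(thn, as.numeric(solve(t(A) %*% A, t(A) %*% yn)),
               tolerance = 1e-8)
  # single-point cluster: minimum-norm solution with a warning
  lab1 <- c(1, rep(2, 39))
  expect_warning(th_min <- refine_local_parameters(lab1, dsn, 2),
                 "minimum-norm")
  expect_equal(as.numeric(cbind(X, 1)[1, ] %*% th_min[[1]]), yn[1],
               tolerance = 1e-8)
})

test_that("particle encoding round-trips", {
  theta <- list(1:4 / 2, 4:1 / 4, rep(0.3, 4))
  centers <- matrix(rnorm(12), 3, 4)
  pos <- pwasoft:::encode_particle(theta, centers)
  expect_length(pos, 3 * 8)
  dec <- pwasoft:::decode_particle(pos, 3, 4, 4)
  expect_equal(dec$theta, theta)
  expect_equal(dec$centers, centers)
})

test_that("a single affine law terminates the outer loop at S = 1", {
  set.seed(17)
  u <- matrix(pwasoft:::ar1_series(100, 0.8, 0.3), ncol = 1)
  y <- numeric(100)
  for (k in 2:100) y[k] <- 0.5 * y[k - 1] + 0.4 * u[k - 1] + 0.2
  b <- batch_ts("one", u = u, y = cbind(X = y, P = 0))
  ds <- build_regression_vectors(list(b), "X", 1, 1)
  fit <- identify_pwarx(ds, S_max = 3, seed = 3)
  expect_equal(fit$S, 1L)
  expect_true(fit$threshold_met)
  expect_lte(fit$J1, fit$y_ts)
})

test_that("identification is deterministic and partitions every modeling vector", {
  gen <- make_two_regime_benchmark(seed = 5, n_samples = 150)
  ds <- build_regression_vectors(gen$batches, "X", 1, 1)
  cfg <- swarm_config(n_particles = 15, n_iter = 60)
  f1 <- identify_pwarx(ds, cfg, S_max = 3, seed = 8)
  f2 <- identify_pwarx(ds, cfg, S_max = 3, seed = 8)
  expect_identical(f1$S, f2$S)
  expect_identical(f1$labels, f2$labels)
  expect_identical(f1$theta, f2$theta)
  expect_equal(sum(f1$sizes), length(ds$y))
  expect_true(all(f1$labels >= 1 & f1$labels <= f1$S))
  # inner traces never increase
  for (tr in f1$traces) expect_true(all(diff(tr) <= 1e-12))
})

test_that("two-regime benchmark is recovered with near-exact parameters", {
  gen <- make_two_regime_benchmark(seed = 23)
  ds <- build_regression_vectors(gen$batches, "X", 1, 1)
  fit <- identify_pwarx(ds, S_max = 4, seed = 23, polish = TRUE)
  expect_equal(fit$S, 2L)
  err <- min(sapply(list(1:2, 2:1), function(p) {
    max(sapply(1:2, function(i) {
      max(abs(fit$theta[[p[i]]] - gen$truth$theta[[i]]))
    }))
  }))
  expect_lt(err, 0.05)
})
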