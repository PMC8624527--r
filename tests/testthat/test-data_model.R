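test_that("min-max normalization maps training extremes to +/-1 and handles degenerate channels", {
  u <- cbind(T = c(2, 4, 6), DO = c(7, 7, 7), pH = c(0, 1, 2),
             q = 1:3, v = 3:1, p = c(-1, 0, 1))
  b <- batch_ts("b1", u = u, y = cbind(X = c(0, 5, 10), P = c(1, 2, 3)))
  out <- minmax_normalize(list(b))
  expect_equal(unname(out$batches[[1]]$u[, "T"]), c(-1, 0, 1))
  expect_equal(unname(out$batches[[1]]$u[, "DO"]), c(0, 0, 0))
  expect_true(out$transform$constant[match("DO", out$transform$channel)])
  expect_equal(unname(out$batches[[1]]$y[, "X"]), c(-1, 0, 1))
  # all channels within [-1, 1]
  expect_true(all(abs(out$batches[[1]]$u) <= 1))
})

test_that("scaling round-trips and is idempotent through its own transform", {
  set.seed(1)
  u <- matrix(runif(60, -3, 9), 10, 6)
  colnames(u) <- c("T", "DO", "pH", "q", "v", "p")
  b <- batch_ts("rt", u = u, y = cbind(X = rnorm(10), P = runif(10, 2, 5)))
  out <- minmax_normalize(list(b))
  back <- apply_scaling(out$batches[[1]], out$transform, inverse = TRUE)
  expect_equal(back$u, b$u, tolerance = 1e-12)
  expect_equal(back$y, b$y, tolerance = 1e-12)
  # re-applying the fitted transform to already-normalized data: extremes
  # are again mapped to +/-1, i.e. normalization is idempotent in law
  again <- minmax_normalize(out$batches)
  expect_equal(again$batches[[1]]$u, out$batches[[1]]$u, tolerance = 1e-12)
})

test_that("normalization rejects empty collections and non-finite values with channel info", {
  expect_error(minmax_normalize(list()), "empty")
  u <- matrix(1, 3, 6)
  u[2, 3] <- NA
  colnames(u) <- c("T", "DO", "pH", "q", "v", "p")
  b <- batch_ts("bad", u = u, y = cbind(X = 1:3, P = 1:3))
  expect_error(minmax_normalize(list(b)), "pH")
})

test_that("output interpolation fills the fast grid linearly and preserves observations", {
  n <- 13                      # one hour at 5-min steps
  y <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("X", "P")))
  obs <- c(1L, 13L)
  y[obs, ] <- cbind(c(0, 12), c(5, 5))
  b <- batch_ts("hr", u = matrix(0, n, 6), y = y,
                y_observed = seq_len(n) %in% obs)
  out <- interpolate_outputs(b)
  expect_equal(unname(out$y[, "X"]), as.numeric(0:12))
  expect_equal(unname(out$y[, "P"]), rep(5, n))
  expect_equal(out$y[obs, ], y[obs, ])
  # fully observed batch passes through unchanged
  b2 <- batch_ts("full", u = matrix(0, 5, 6),
                 y = cbind(X = 1:5, P = 5:1))
  expect_equal(interpolate_outputs(b2)$y, b2$y)
})

test_that("interpolation matches an independent piecewise-linear evaluator on random data", {
  set.seed(3)
  n <- 97
  obs <- seq(1, n, by = 12)
  y <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("X", "P")))
  y[obs, ] <- matrix(rnorm(2 * length(obs)), ncol = 2)
  b <- batch_ts("rand", u = matrix(0, n, 6), y = y,
                y_observed = seq_len(n) %in% obs)
  out <- interpolate_outputs(b)
  for (ch in c("X", "P")) {
    expect_equal(unname(out$y[, ch]),
                 oracle_linear_interp(obs, y[obs, ch], seq_len(n)),
                 tolerance = 1e-12)
  }
})

test_that("interpolation refuses too few observations and silent extrapolation", {
  y <- matrix(NA_real_, 5, 2, dimnames = list(NULL, c("X", "P")))
  y[1, ] <- 1
  b <- batch_ts("one", u = matrix(0, 5, 6), y = y,
                y_observed = c(TRUE, rep(FALSE, 4)))
  expect_error(interpolate_outputs(b), "at least 2")
  y[3, ] <- 2
  b2 <- batch_ts("tail", u = matrix(0, 5, 6), y = y,
                 y_observed = c(TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_error(interpolate_outputs(b2), "extrapolat")
  expect_silent(out <- interpolate_outputs(b2, extrapolate = TRUE))
  expect_false(anyNA(out$y))
})

test_that("regression vectors follow the lag layout and match the indexing oracle", {
  # constant series: every regressor equals the constants
  b <- batch_ts("const", u = matrix(2, 10, 1, dimnames = list(NULL, "T")),
                y = cbind(X = rep(3, 10), P = 0))
  ds <- build_regression_vectors(list(b), "X", n_y = 1, n_u = 1)
  expect_equal(nrow(ds$X), 9)
  expect_true(all(ds$X[, 1] == 3 & ds$X[, 2] == 2))
  # r = 6, one output and one input lag: regressor-plus-bias dimension 8
  b6 <- batch_ts("r6", u = matrix(rnorm(60), 10, 6),
                 y = cbind(X = rnorm(10), P = 0))
  ds6 <- build_regression_vectors(list(b6), "X", 1, 1)
  expect_equal(ncol(ds6$X) + 1L, 8L)
  expect_equal(ncol(ds6$z), 8L)
  # random series against the exhaustive indexing oracle
  set.seed(9)
  u <- matrix(rnorm(30), 10, 3)
  y <- rnorm(10)
  br <- batch_ts("rand", u = u, y = cbind(X = y, P = 0))
  for (ords in list(c(1, 1, 0), c(2, 1, 0), c(2, 2, 1), c(0, 2, 2))) {
    ds_r <- build_regression_vectors(list(br), "X", ords[1], ords[2], ords[3])
    orc <- oracle_regression_vectors(y, u, ords[1], ords[2], ords[3])
    expect_equal(unname(ds_r$X), orc$X)
    expect_equal(ds_r$y, orc$y)
    expect_equal(unname(ds_r$z), unname(cbind(orc$X, orc$y)))
  }
})

test_that("pair counts are conserved and lag windows never cross batch boundaries", {
  set.seed(4)
  lens <- c(12, 7, 30)
  batches <- lapply(seq_along(lens), function(i) {
    batch_ts(paste0("b", i), u = matrix(rnorm(lens[i] * 2), ncol = 2),
             y = cbind(X = rnorm(lens[i]), P = 0))
  })
  n_y <- 2; n_u <- 2; p <- 1
  w <- max(n_y, p + n_u)
  ds <- build_regression_vectors(batches, "X", n_y, n_u, p)
  expect_equal(nrow(ds$X), sum(pmax(0, lens - w)))
  # provenance: the first emitted time index of every batch is w + 1
  expect_true(all(tapply(ds$time_index, ds$batch_id, min) == w + 1))
  # a batch shorter than the window is skipped with a warning
  short <- batch_ts("tiny", u = matrix(rnorm(4), 2, 2),
                    y = cbind(X = rnorm(2), P = 0))
  expect_warning(ds2 <- build_regression_vectors(c(batches, list(short)),
                                                 "X", n_y, n_u, p),
                 "skipped")
  expect_equal(nrow(ds2$X), nrow(ds$X))
  expect_error(
    suppressWarnings(build_regression_vectors(list(short), "X", n_y, n_u, p)),
    "all batches")
})

test_that("batch CSV round-trips through the reader and writer", {
  sim <- make_three_phase_fixture(seed = 2, n_batches = 2, n_samples = 20)
  path <- withr::local_tempfile(fileext = ".csv")
  write_batches(sim$batches, path)
  back <- read_batches(path)
  expect_length(back, 2)
  expect_equal(back[[1]]$u, sim$batches[[1]]$u, tolerance = 1e-12)
  expect_equal(back[[2]]$y, sim$batches[[2]]$y, tolerance = 1e-12)
  expect_equal(back[[1]]$split, sim$batches[[1]]$split)
})
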