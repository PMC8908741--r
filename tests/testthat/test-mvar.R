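test_that("scalar AR(1) moments match the closed-form autocovariance", {
  # x(t) = 0.8 x(t-1) + eta, unit innovation: Gamma(0) = 1/(1 - 0.64)
  s <- simulate_var(var_spec(matrix(0.8), matrix(1), length = 1e5, seed = 5))
  m <- estimate_moments(centered(s), 2)
  expect_equal(m$gamma[[1]][1, 1], 1 / (1 - 0.64), tolerance = 0.05)
  expect_equal(m$gamma[[2]][1, 1] / m$gamma[[1]][1, 1], 0.8,
               tolerance = 0.02)
  # and the scalar Yule-Walker closed form recovers the coefficient
  f <- fit_yule_walker(m, 1)
  expect_equal(f$coeffs[[1]][1, 1], 0.8, tolerance = 0.01)
  expect_equal(f$noise_cov[1, 1], 1, tolerance = 0.03)
})

test_that("white-noise moments at positive lag vanish at the sampling rate", {
  s <- simulate_var(var_spec(matrix(0, 2, 2), diag(2), length = 1e5, seed = 9))
  m <- estimate_moments(centered(s), 1)
  expect_lt(max(abs(m$gamma[[2]])), 3 / sqrt(1e5))
  f <- fit_yule_walker(m, 1)
  expect_lt(max(abs(f$coeffs[[1]])), 3 / sqrt(1e5))
  expect_equal(f$noise_cov, m$gamma[[1]], tolerance = 1e-3)
})

test_that("degenerate and break-crossing inputs are rejected", {
  s <- channel_series(matrix(rnorm(10), 10, 1))
  expect_error(estimate_moments(s, 10), "shortest segment")
  sb <- channel_series(matrix(rnorm(20), 20, 1), segment_breaks = 3L)
  expect_error(estimate_moments(sb, 5), "shortest segment")
})

test_that("moments exclude lag products crossing segment breaks", {
  # two independent segments stitched together: the break must prevent
  # the artificial jump from contaminating Gamma(1)
  set.seed(11)
  a <- cumsum(rnorm(300)); b <- 1000 + cumsum(rnorm(300))
  joined <- channel_series(matrix(c(a, b) - mean(c(a, b))), "w",
                           segment_breaks = 300L)
  m <- estimate_moments(joined, 1)
  ac <- c(a, b) - mean(c(a, b))
  expected <- (sum(ac[2:300] * ac[1:299]) + sum(ac[302:600] * ac[301:599])) /
    (2 * 299)
  expect_equal(m$gamma[[2]][1, 1], expected, tolerance = 1e-12)
})

test_that("Yule-Walker recovers VAR(1) parameters from simulated data", {
  A <- matrix(c(0.9, 0.5, 0, 0), 2, 2)
  V <- diag(c(1, 0.01))
  s <- simulate_var(var_spec(A, V, length = 1e5, seed = 23))
  f <- fit_yule_walker(estimate_moments(centered(s), 1), 1)
  expect_lt(max(abs(f$coeffs[[1]] - A)), 0.02)
  expect_lt(max(abs(f$noise_cov - V)), 0.03)
})

test_that("coefficient error decreases monotonically with trajectory length", {
  A <- matrix(c(0.9, 0.5, 0, 0), 2, 2)
  V <- diag(c(1, 0.01))
  err <- sapply(c(1e3, 1e4, 1e5), function(Tn) {
    s <- simulate_var(var_spec(A, V, length = Tn, seed = 31))
    f <- fit_yule_walker(estimate_moments(centered(s), 1), 1)
    median(abs(f$coeffs[[1]] - A))
  })
  expect_true(all(diff(err) < 0))
})

test_that("SBC order selection finds the generating order", {
  s1 <- simulate_var(var_spec(matrix(c(0.6, 0.4, -0.3, 0.5), 2, 2), diag(2),
                              length = 1e5, seed = 2))
  sel1 <- select_order(normalize_channels(s1), 1:3)
  expect_equal(sel1$order, 1L)
  A1 <- matrix(c(0.2, 0.1, 0, 0.2), 2, 2)
  A2 <- matrix(c(0.5, 0.25, 0, 0.4), 2, 2)
  s2 <- simulate_var(var_spec(list(A1, A2), diag(2), length = 1e5, seed = 4))
  sel2 <- select_order(normalize_channels(s2), 1:3)
  expect_equal(sel2$order, 2L)
  # flat criterion (huge tie tolerance) falls back to the smallest order
  sel_tie <- select_order(normalize_channels(s1), 1:3, tol = 1e6)
  expect_equal(sel_tie$order, 1L)
})

test_that("training-data residuals reproduce the fitted noise covariance", {
  spec <- var_spec(matrix(c(0.5, 0.3, 0.1, 0.4), 2, 2), diag(2),
                   length = 2e4, seed = 3)
  s <- centered(simulate_var(spec))
  f <- fit_yule_walker(estimate_moments(s, 1), 1)
  r <- predict_residuals(f, s)
  Vhat <- crossprod(r$values) / nrow(r$values)
  expect_lt(max(abs(Vhat - f$noise_cov)) / max(abs(f$noise_cov)), 1e-3)
  # whiteness of residuals
  ac <- apply(r$values, 2, function(z)
    cor(z[-1], z[-length(z)]))
  expect_lt(max(abs(ac)), 3 / sqrt(nrow(r$values)))
  expect_error(predict_residuals(f, channel_series(s$values,
                                                   c("p", "q"))), "labels")
})

test_that("a noise-free lagged copy is predicted almost perfectly", {
  set.seed(8)
  Tn <- 2e4
  x1 <- rnorm(Tn); x2 <- c(0, x1[-Tn])
  s <- channel_series(cbind(a = x1, b = x2))
  f <- fit_yule_walker(estimate_moments(s, 1), 1)
  r <- predict_residuals(f, s)
  expect_lt(mean(r$values[, 2]^2), 1e-7)
})

test_that("prediction never increases error and fits are permutation-equivariant", {
  s <- simulate_var(var_spec(matrix(c(0.7, 0.2, 0.1, 0.6), 2, 2),
                             matrix(c(1, 0.3, 0.3, 1), 2, 2),
                             length = 2e4, seed = 12))
  sc <- centered(s)
  m <- estimate_moments(sc, 1)
  f <- fit_yule_walker(m, 1)
  expect_true(all(diag(f$noise_cov) <= diag(m$gamma[[1]]) + 1e-9))
  perm <- c(2L, 1L)
  sp <- channel_series(sc$values[, perm], sc$labels[perm])
  fp <- fit_yule_walker(estimate_moments(sp, 1), 1)
  expect_equal(unname(fp$coeffs[[1]]), unname(f$coeffs[[1]][perm, perm]),
               tolerance = 1e-10)
  expect_equal(unname(fp$noise_cov), unname(f$noise_cov[perm, perm]),
               tolerance = 1e-10)
})

test_that("MVAR JSON round trip preserves the model", {
  s <- simulate_var(var_spec(list(diag(0.3, 2), diag(0.2, 2)), diag(2),
                             length = 5000, seed = 6))
  f <- fit_yule_walker(estimate_moments(centered(s), 2), 2)
  tf <- tempfile(fileext = ".json")
  write_mvar(f, tf)
  g <- read_mvar(tf)
  expect_equal(g$coeffs, f$coeffs, tolerance = 1e-12)
  expect_equal(g$noise_cov, f$noise_cov, tolerance = 1e-12)
  expect_identical(g$order, f$order)
})
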