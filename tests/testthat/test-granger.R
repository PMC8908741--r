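test_that("Granger couplings reach their limiting values", {
  set.seed(21)
  Tn <- 1e5
  x1 <- rnorm(Tn)
  x2 <- c(0, x1[-Tn]) + 0.01 * rnorm(Tn)   # near-exact lagged copy
  s <- normalize_channels(channel_series(cbind(a = x1, b = x2)))
  J <- gc_matrix(s, 1)$J
  expect_gt(J["a", "b"], 0.99)
  expect_lt(J["b", "a"], 0.01)
  wn <- normalize_channels(channel_series(
    matrix(rnorm(2 * Tn), ncol = 2, dimnames = list(NULL, c("u", "v")))))
  Jw <- gc_matrix(wn, 1)$J
  expect_lt(max(Jw), 0.01)
  expect_true(all(diag(J) == 0))
  expect_true(all(J >= 0 & J <= 1))
})

test_that("a causal chain produces the expected coupling ordering", {
  A <- matrix(c(0.5, 0, 0,
                0.5, 0.5, 0,
                0, 0.5, 0.5), 3, 3, byrow = TRUE)  # 1 -> 2 -> 3
  s <- simulate_var(var_spec(A, diag(3), length = 1e5, seed = 33))
  J <- gc_matrix(normalize_channels(s), 1)$J
  expect_gt(J[1, 2], J[2, 1])
  expect_gt(J[2, 3], J[3, 2])
  expect_gt(J[1, 2], J[1, 3])
  expect_gt(J[2, 3], J[1, 3])
})

test_that("moment-submatrix reduction equals brute-force reduced refits", {
  for (K in 2:5) {
    A <- matrix(0, K, K)
    A[lower.tri(A)] <- 0.3 / K
    diag(A) <- 0.4
    s <- normalize_channels(
      simulate_var(var_spec(A, diag(K), length = 5000, seed = 40 + K)))
    moments <- estimate_moments(s, 1)
    full <- fit_yule_walker(moments, 1)
    J <- gc_matrix(s, 1)$J
    for (j in seq_len(K)) {
      keep <- setdiff(seq_len(K), j)
      # oracle: re-estimate moments from the raw reduced data and refit
      red_series <- channel_series(s$values[, keep, drop = FALSE],
                                   s$labels[keep])
      red_fit <- fit_yule_walker(estimate_moments(red_series, 1), 1)
      J_oracle <- 1 - diag(full$noise_cov)[keep] / diag(red_fit$noise_cov)
      expect_lt(max(abs(J[j, keep] - pmax(J_oracle, 0))), 1e-10)
    }
  }
})

test_that("descriptors follow their closed forms and identities", {
  J0 <- structure(list(J = matrix(0, 3, 3,
                                  dimnames = list(letters[1:3], letters[1:3])),
                       labels = letters[1:3]), class = "gc_matrix")
  d0 <- gc_descriptors(J0)
  expect_true(all(d0$g_in == 0 & d0$g_out == 0 &
                    d0$g_origin == 0 & d0$g_total == 0))
  Jm <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  Jm["a", "b"] <- 0.8
  d <- gc_descriptors(structure(list(J = Jm, labels = c("a", "b")),
                                class = "gc_matrix"))
  expect_equal(d$g_out[1], 0.8)
  expect_equal(d$g_in[1], 0)
  expect_equal(d$g_origin, c(0.8, -0.8))
  expect_identical(sum(d$g_origin), 0)          # exact algebraic identity
  expect_true(all(d$g_total >= abs(d$g_origin)))
})

test_that("the Granger matrix is channel-permutation equivariant", {
  s <- normalize_channels(std_toy()$channels)
  J <- gc_matrix(s, 1)$J
  perm <- c(3L, 1L, 2L, 6L, 5L, 4L)
  sp <- channel_series(s$values[, perm], s$labels[perm])
  Jp <- gc_matrix(sp, 1)$J
  expect_equal(unname(Jp), unname(J[perm, perm]), tolerance = 1e-10)
})

test_that("split-half errors vanish for duplicated halves and shrink with T", {
  toy <- std_toy()
  X <- toy$channels$values[1:5000, ]
  dup <- channel_series(rbind(X, X), toy$channels$labels,
                        segment_breaks = 5000L)
  d_dup <- split_half_convergence(dup, 1)
  expect_lt(max(d_dup$g_total_err), 1e-12)
  short <- channel_series(toy$channels$values[1:2e4, ], toy$channels$labels)
  long <- toy$channels
  err_short <- median(split_half_convergence(short, 1)$g_total_err)
  err_long <- median(split_half_convergence(long, 1)$g_total_err)
  expect_lt(err_long, err_short)
})

test_that("nonstationary drift inflates split-half error bars", {
  set.seed(3)
  Tn <- 2e4
  base <- matrix(rnorm(3 * Tn), ncol = 3)
  stat <- channel_series(base, c("a", "b", "c"))
  drift <- channel_series(base + cbind(seq(0, 6, length.out = Tn), 0, 0),
                          c("a", "b", "c"))
  e_stat <- mean(split_half_convergence(stat, 1)$g_total_err)
  e_drift <- suppressWarnings(
    mean(split_half_convergence(drift, 1)$g_total_err))
  expect_gt(e_drift, e_stat)
})

test_that("shuffle-null test is deterministic and guards its preconditions", {
  toy_small <- simulate_toy_folder(toy_folder_spec(length = 5000, seed = 3))
  cats <- toy_folder_categories(toy_folder_spec(length = 5000, seed = 3))
  p1 <- suppressWarnings(shuffle_null_test(toy_small$channels, 1,
                                           n_shuffles = 20,
                                           categories = cats, seed = 9))
  p2 <- suppressWarnings(shuffle_null_test(toy_small$channels, 1,
                                           n_shuffles = 20,
                                           categories = cats, seed = 9))
  expect_identical(p1$p_value, p2$p_value)
  expect_error(shuffle_null_test(toy_small$channels, 1, n_shuffles = 10),
               "underpowered")
})
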