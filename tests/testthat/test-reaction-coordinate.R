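test_that("TICA finds the slow process among planted timescales", {
  set.seed(14)
  Tn <- 2e4
  slow <- as.numeric(stats::arima.sim(list(ar = exp(-1 / 100)), Tn))
  fast <- as.numeric(stats::arima.sim(list(ar = exp(-1 / 5)), Tn))
  X <- cbind(slow = slow, fast = fast)
  m <- fit_tica(X, 50)
  v <- m$components[, 1]
  expect_gt(abs(v["slow"]) / sqrt(sum(v^2)), 0.99)
  expect_true(all(diff(m$eigenvalues) <= 1e-12))
  expect_true(all(abs(m$eigenvalues) <= 1 + 1e-6))
  # invariance of eigenvalues under invertible linear maps of the features
  th <- 0.6
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  m2 <- fit_tica(X %*% R, 50)
  expect_equal(m2$eigenvalues, m$eigenvalues, tolerance = 1e-8)
  # time reversal leaves the symmetrized estimator unchanged
  m3 <- fit_tica(X[Tn:1, ], 50)
  expect_equal(m3$eigenvalues, m$eigenvalues, tolerance = 1e-10)
})

test_that("TICA rejects invalid lags and rank-deficient features", {
  X <- matrix(rnorm(200), 100, 2)
  expect_error(fit_tica(X, 0), "positive")
  Xc <- cbind(a = rnorm(100), flat = rep(1, 100))
  expect_error(fit_tica(Xc, 5), "flat")
})

test_that("kinetic map scales projections by eigenvalues", {
  set.seed(2)
  X <- cbind(as.numeric(stats::arima.sim(list(ar = 0.9), 5000)),
             rnorm(5000))
  mk <- fit_tica(X, 20, kinetic_map = TRUE)
  mp <- fit_tica(X, 20, kinetic_map = FALSE)
  pk <- project_tica(mk, X)
  pp <- project_tica(mp, X)
  expect_equal(pk, sweep(pp, 2, mk$eigenvalues, "*"), tolerance = 1e-10)
  # serialization round trip
  tf <- tempfile(fileext = ".json")
  write_tica(mk, tf)
  mk2 <- read_tica(tf)
  expect_equal(project_tica(mk2, X), pk, tolerance = 1e-9)
})

test_that("Gromos clustering handles degenerate and constructed geometries", {
  # all frames identical -> a single cluster
  d0 <- matrix(0, 5, 5)
  g0 <- gromos_cluster(d0, 0.3)
  expect_length(g0$clusters, 1L)
  expect_length(g0$clusters[[1L]], 5L)
  # two tight bundles of 7 and 3 frames, 1 nm apart
  set.seed(5)
  pos <- c(rnorm(7, 0, 0.02), rnorm(3, 1, 0.02))
  d <- abs(outer(pos, pos, "-"))
  g <- gromos_cluster(d, 0.3)
  expect_length(g$clusters, 2L)
  expect_true(g$reference %in% 1:7)
  # brute-force check: the first center has the most neighbours
  counts <- rowSums(d <= 0.3)
  expect_equal(counts[g$centers[1]], max(counts))
  # cutoff below all pairwise distances -> singletons
  g1 <- gromos_cluster(d + diag(0, 10), 1e-6)
  expect_length(g1$clusters, 10L)
})

test_that("transition paths are flanked by opposite cores with clean interiors", {
  toy <- std_toy()
  lab <- core_labels(toy$coordinate, toy_folder_cores())
  tps <- identify_transition_paths(lab)
  expect_gt(nrow(tps), 10)
  for (k in seq_len(nrow(tps))) {
    seg <- lab[tps$start[k]:tps$end[k]]
    expect_true(all(seg == 0L))
    expect_true(lab[tps$start[k] - 1L] != lab[tps$end[k] + 1L])
    expect_true(all(c(lab[tps$start[k] - 1L], lab[tps$end[k] + 1L]) %in% 1:2))
  }
})

test_that("p(TP|xi) stays within bounds and fails cleanly without transitions", {
  toy <- std_toy()
  prof <- p_tp_profile(toy$coordinate, toy_folder_cores())
  ok <- !is.na(prof$value)
  expect_true(all(prof$value[ok] >= 0 & prof$value[ok] <= 1))
  # reversible diffusive dynamics cannot exceed the 0.5 limit materially
  err_at_max <- prof$err_hi[which.max(ifelse(ok, prof$value, -1))]
  expect_lte(attr(prof, "maximum"), 0.5 + 3 * err_at_max)
  stuck <- rnorm(5000, -1, 0.05)  # never leaves the U well
  expect_error(p_tp_profile(stuck, toy_folder_cores()), "never visited")
})

test_that("trial-coordinate ranking prefers the true coordinate", {
  toy <- std_toy()
  x <- toy$coordinate
  lab <- core_labels(x, toy_folder_cores())
  set.seed(77)
  scrambled <- x[sample(length(x))]
  rk <- rank_trial_coordinates(list(true = x, scrambled = scrambled), lab)
  expect_identical(rk$ranking$name[1], "true")
  expect_gt(rk$ranking$score[1], 3 * rk$ranking$score[2])
  # equal candidates tie stably in input order
  rk2 <- rank_trial_coordinates(list(first = x, second = x), lab)
  expect_identical(rk2$ranking$name, c("first", "second"))
  expect_equal(rk2$ranking$score[1], rk2$ranking$score[2])
  # single candidate is trivially first
  rk3 <- rank_trial_coordinates(list(only = x), lab)
  expect_identical(rk3$ranking$name, "only")
})
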