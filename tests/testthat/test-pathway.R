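test_that("PMF conventions: flat for uniform samples, minimum exactly 0", {
  set.seed(4)
  u <- runif(2e5)
  prof <- pmf_profile(u, 20)
  expect_identical(min(prof$value, na.rm = TRUE), 0)
  expect_lt(max(prof$value, na.rm = TRUE), 0.15)  # flat within sampling noise
  single <- pmf_profile(rep(0.5, 100), 1)
  expect_identical(single$value, 0)
})

test_that("PMF recovers a known Boltzmann barrier", {
  # rejection sampling from exp(-U), U = (x^2 - 1)^2: barrier U(0)-U(1) = 1
  set.seed(10)
  n <- 0; xs <- numeric(0)
  while (length(xs) < 2e5) {
    cand <- runif(5e5, -2, 2)
    keep <- runif(5e5) < exp(-(cand^2 - 1)^2)
    xs <- c(xs, cand[keep])
  }
  xs <- xs[1:2e5]
  prof <- pmf_profile(xs, 50, limits = c(-1.6, 1.6))
  mins <- locate_pmf_minima(prof)
  mid <- which.min(abs(prof$center))
  barrier <- prof$value[mid] - min(prof$value[c(mins$f_bin, mins$u_bin)])
  sd_mid <- prof$err_hi[mid]
  expect_lt(abs(barrier - 1), 3 * max(sd_mid, 0.05))
  expect_lt(abs(mins$f) , 1.15)
  expect_gt(abs(mins$f), 0.8)
})

test_that("state discretization assigns nearest centers with lower-index ties", {
  centers6 <- seq(0, 1, length.out = 6)
  sm <- discretize_and_medoids(centers6, NULL, 0, 1)
  expect_identical(sm$labels, 1:6)
  expect_identical(sm$medoid_frames, 1:6)
  # equidistant frame goes to the lower-index state
  sm2 <- discretize_and_medoids(c(0, 1, 0.1), NULL, 0, 0.2, n_states = 2)
  expect_identical(sm2$labels[3], 1L)
  expect_error(discretize_and_medoids(1:5, NULL, 1, 1), "differ")
})

test_that("medoids match a brute-force pairwise-distance search", {
  proj <- rbind(c(0, 0), c(0.1, 0), c(0.05, 0.02),
                c(5, 5), c(5.1, 5), c(5.2, 5.3))
  xi <- c(0, 0, 0, 1, 1, 1)
  sm <- discretize_and_medoids(xi, proj, 0, 1, n_states = 2)
  for (s in 1:2) {
    frames <- which(sm$labels == s)
    dsums <- sapply(frames, function(i)
      sum(sqrt(colSums((t(proj[frames, ]) - proj[i, ])^2))))
    expect_identical(sm$medoid_frames[s], frames[which.min(dsums)])
  }
})

test_that("median filtering removes spikes and enforces odd widths", {
  expect_identical(median_filter_states(rep(2L, 10), 5), rep(2L, 10))
  spike <- c(0L, 0L, 0L, 1L, 0L, 0L, 0L)
  expect_identical(median_filter_states(spike, 5), rep(0L, 7))
  # direct evaluation: an odd window over a perfectly alternating sequence
  # always holds a 3-2 majority for the center's value, so the filter is a
  # fixed point there (any isolated deviation from alternation is removed)
  alt <- rep(c(0L, 1L), 10)
  expect_identical(median_filter_states(alt, 5)[3:18], alt[3:18])
  expect_error(median_filter_states(spike, 4), "odd")
})

test_that("transition matrices are row-stochastic and recover known chains", {
  tm <- transition_matrix(rep(1L, 10), n_states = 2)
  expect_equal(tm$P[1, ], c(1, 0))
  expect_true(all(is.na(tm$P[2, ])))
  cyc <- transition_matrix(rep(c(1L, 2L, 3L), 20), n_states = 3)
  expect_equal(cyc$counts > 0, matrix(c(FALSE, TRUE, FALSE,
                                        FALSE, FALSE, TRUE,
                                        TRUE, FALSE, FALSE), 3, 3,
                                      byrow = TRUE))
  rows <- rowSums(cyc$P)
  expect_lt(max(abs(rows - 1)), 1e-12)
  expect_equal(sum(cyc$populations), 1, tolerance = 1e-12)
  # two-state Markov chain with known rates
  set.seed(6)
  p01 <- 0.1; p10 <- 0.3
  lab <- integer(5e4); lab[1] <- 1L
  flips <- runif(5e4)
  for (t in 2:5e4)
    lab[t] <- if (lab[t - 1] == 1L) (if (flips[t] < p01) 2L else 1L)
              else (if (flips[t] < p10) 1L else 2L)
  tm2 <- transition_matrix(lab, 2)
  n1 <- sum(lab[-5e4] == 1L)
  expect_lt(abs(tm2$P[1, 2] - p01), 3 * sqrt(p01 * (1 - p01) / n1))
  expect_lt(abs(tm2$P[2, 1] - p10),
            3 * sqrt(p10 * (1 - p10) / (5e4 - 1 - n1)))
  # segment break excludes the stitched pair
  tm3 <- transition_matrix(c(1L, 1L, 2L, 2L), n_states = 2,
                           segment_breaks = 2L)
  expect_equal(tm3$counts[1, 2], 0)
})

test_that("committor obeys boundary conventions and the gambler's ruin law", {
  # deterministic staircase U -> ... -> F gives CF = 1 in the interior
  stair <- rep(rep(6:1, each = 2), 30)
  cf_det <- committor_states(stair, f_state = 1, u_state = 6)
  expect_true(all(cf_det$cf[2:5] == 1))
  expect_equal(cf_det$cf[1], 1)
  expect_equal(cf_det$cf[6], 0)
  # unbiased nearest-neighbour walk, F = 6, U = 1: CF(i) = (i - 1) / 5
  set.seed(9)
  Tn <- 1e5
  lab <- integer(Tn); lab[1] <- 3L
  steps <- sample(c(-1L, 1L), Tn, replace = TRUE)
  for (t in 2:Tn) {
    nxt <- lab[t - 1] + steps[t]
    lab[t] <- min(max(nxt, 1L), 6L)
  }
  cf <- committor_states(lab, f_state = 6, u_state = 1)
  for (s in 2:5) {
    expected <- (s - 1) / 5
    se <- sqrt(expected * (1 - expected) / cf$n_visits[s])
    expect_lt(abs(cf$cf[s] - expected), 3 * se)
  }
  expect_true(all(cf$cf_min <= cf$cf & cf$cf <= cf$cf_max, na.rm = TRUE))
})

test_that("event counting follows the last-exit / first-entry convention", {
  # U U T F: one folding event spanning the T and F frames
  lab1 <- c(6L, 6L, 3L, 1L)
  ev1 <- count_events(lab1, f_state = 1, u_state = 6, dt = 1)
  expect_equal(ev1$summary$n_events[1], 1L)
  expect_equal(ev1$folding$duration, 2)
  # U T U T F: the event restarts at the second U exit
  lab2 <- c(6L, 3L, 6L, 3L, 1L)
  ev2 <- count_events(lab2, f_state = 1, u_state = 6, dt = 1)
  expect_equal(ev2$summary$n_events[1], 1L)
  expect_equal(ev2$folding$start, 4)
  # long toy trajectory: folding and unfolding alternate
  toy <- long_toy()
  lab <- ifelse(toy$coordinate > 0.75, 1L,
                ifelse(toy$coordinate < -0.75, 6L, 3L))
  ev <- count_events(lab, f_state = 1, u_state = 6, dt = 0.2)
  expect_lte(abs(ev$summary$n_events[1] - ev$summary$n_events[2]), 1L)
  expect_gt(ev$summary$n_events[1], 50)
})

test_that("Gaussian overlap matches closed forms and numerical integration", {
  expect_equal(gaussian_overlap(1, 2, 1, 2), 1)
  expect_lt(gaussian_overlap(0, 1, 60, 1), 1e-12)
  # equal variances, means two sigma apart: 2 Phi(-1)
  expect_equal(gaussian_overlap(0, 1, 2, 1), 2 * pnorm(-1), tolerance = 1e-12)
  num <- integrate(function(x) pmin(dnorm(x, 0, 1), dnorm(x, 2, 1)),
                   -Inf, Inf, rel.tol = 1e-10)$value
  expect_equal(gaussian_overlap(0, 1, 2, 1), num, tolerance = 1e-8)
  # unequal variances against numerical integration
  num2 <- integrate(function(x) pmin(dnorm(x, 0, 1), dnorm(x, 1.5, 2.5)),
                    -Inf, Inf, rel.tol = 1e-10)$value
  expect_equal(gaussian_overlap(0, 1, 1.5, 2.5), num2, tolerance = 1e-8)
  expect_error(gaussian_overlap(0, 0, 1, 1), "positive")
})

test_that("the overlap profile normalizes to span [0, 1]", {
  toy <- std_toy()
  x <- toy$coordinate
  prof <- overlap_profile(toy$channels$values[, 3], x, -1, 1)
  ok <- !is.na(prof$value)
  expect_equal(min(prof$value[ok]), 0)
  expect_equal(max(prof$value[ok]), 1)
  raw <- attr(prof, "raw")
  expect_true(all(raw[ok] >= 0 & raw[ok] <= 1))
  # the reference bin has raw overlap 1 with itself
  expect_equal(raw[1], 1)
  expect_error(overlap_profile(rep(1, length(x)), x, -1, 1), "zero-SD")
})
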