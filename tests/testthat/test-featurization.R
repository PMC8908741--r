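test_that("a 10-residue peptide yields 45 distance channels and 37 features", {
  g <- generate_mini_trajectory(mini_structure_spec(10, n_noise_frames = 1))
  d <- residue_min_distances(g$trajectory)
  expect_equal(ncol(d$values), 45L)
  ref <- as_md_trajectory(g$trajectory$xyz[1, ], g$trajectory$atoms)
  bf <- backbone_features(g$trajectory, ref)
  expect_equal(ncol(bf$values), 37L)
  expect_equal(choose(ncol(d$values), 2), 990)
  # sin/cos column pairs lie on the unit circle
  sins <- grep("_sin$", bf$labels); coss <- grep("_cos$", bf$labels)
  expect_lt(max(abs(bf$values[, sins]^2 + bf$values[, coss]^2 - 1)), 1e-9)
})

test_that("two single-atom residues give their exact point distance", {
  traj <- point_residue_traj(c(0, 0, 0), c(0, 0, 0.3))
  d <- residue_min_distances(traj)
  expect_equal(ncol(d$values), 1L)
  expect_equal(as.numeric(d$values), 0.3, tolerance = 1e-12)
})

test_that("minimum distances match a brute-force loop over all atom pairs", {
  g <- generate_mini_trajectory(mini_structure_spec(4, seed = 3))
  traj <- g$trajectory
  d <- residue_min_distances(traj)
  at <- traj$atoms
  for (f in c(1L, 3L)) {
    co <- matrix(traj$xyz[f, ], ncol = 3, byrow = TRUE)
    k <- 0L
    for (i in 1:3) for (j in (i + 1):4) {
      k <- k + 1L
      ai <- which(at$resno == i & at$elem != "H")
      aj <- which(at$resno == j & at$elem != "H")
      best <- Inf
      for (a in ai) for (b in aj)
        best <- min(best, sqrt(sum((co[a, ] - co[b, ])^2)))
      expect_equal(as.numeric(d$values[f, k]), best, tolerance = 1e-12)
    }
  }
})

test_that("distances are invariant to global rotation and translation", {
  g <- generate_mini_trajectory(mini_structure_spec(3, seed = 9))
  traj <- g$trajectory
  th <- 1.1
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz2 <- t(apply(traj$xyz, 1, function(row) {
    co <- matrix(row, ncol = 3, byrow = TRUE) %*% R
    as.vector(t(sweep(co, 2, c(1, -2, 0.5), "+")))
  }))
  traj2 <- as_md_trajectory(xyz2, traj$atoms)
  expect_equal(residue_min_distances(traj2)$values,
               residue_min_distances(traj)$values, tolerance = 1e-9)
  # RMSD to a transformed reference is zero after superposition
  ref <- as_md_trajectory(traj$xyz[1, ], traj$atoms)
  expect_equal(unname(backbone_features(as_md_trajectory(xyz2[1, ], traj$atoms),
                                        ref)$values[1, "rmsd"]),
               0, tolerance = 1e-9)
})

test_that("hydrogen-bond criteria act independently and fractions are flagged", {
  g <- generate_mini_trajectory(mini_structure_spec(4, seed = 1))
  hb <- suppressWarnings(detect_hbonds(g$trajectory))
  k <- which(hb$labels == "R1:N-H...R4:O")
  # a 100-frame state with the bond in 4 frames sits below the 5% threshold
  ind <- matrix(0, 100, length(hb$labels))
  colnames(ind) <- hb$labels
  ind[1:4, k] <- 1
  fr <- hbond_state_fractions(list(indicators = ind, labels = hb$labels),
                              rep(1L, 100))
  row <- fr[fr$bond == hb$labels[k], ]
  expect_equal(row$fraction, 0.04)
  expect_true(row$below_threshold)
})

test_that("topology mismatch and missing heavy atoms raise errors", {
  g <- generate_mini_trajectory(mini_structure_spec(3))
  traj <- g$trajectory
  small <- generate_mini_trajectory(mini_structure_spec(2))$trajectory
  ref_bad <- as_md_trajectory(small$xyz[1, ], small$atoms)
  expect_error(backbone_features(traj, ref_bad), "topology")
  ghost <- as_md_trajectory(c(0, 0, 0, 0, 0, 0.3),
                            data.frame(elety = c("CA", "H1"),
                                       resno = c(1L, 2L),
                                       resid = "GLY", elem = c("C", "H")))
  expect_error(residue_min_distances(ghost), "2")
})

test_that("frame RMSDs obey the triangle inequality", {
  g <- generate_mini_trajectory(mini_structure_spec(3, n_noise_frames = 4,
                                                    noise_sd = 0.02, seed = 6))
  d <- rmsd_matrix(g$trajectory)
  n <- nrow(d)
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n)
    expect_lte(d[i, k], d[i, j] + d[j, k] + 1e-9)
})
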