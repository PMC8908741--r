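# Shared fixtures, computed lazily and cached for the whole test run.
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, .fixture_cache))
    assign(name, builder(), .fixture_cache)
  get(name, .fixture_cache)
}

# Long toy-folder run shared by occupancy / p(TP|xi) / event tests.
long_toy <- function() fixture("long_toy", function() {
  spec <- toy_folder_spec(length = 1e6, seed = 101)
  c(simulate_toy_folder(spec), list(spec = spec))
})

# Standard-length toy folder for Granger tests.
std_toy <- function() fixture("std_toy", function() {
  spec <- toy_folder_spec(length = 2e5, seed = 101)
  c(simulate_toy_folder(spec), list(spec = spec))
})

# Centered (but unscaled) copy of a channel series, for moment estimation.
centered <- function(series) {
  channel_series(sweep(series$values, 2L, colMeans(series$values)),
                 series$labels, series$dt, series$segment_breaks)
}

# Independent Lyapunov oracle for the stationary covariance blocks of a
# VAR process, via the companion-form Kronecker identity. Deliberately a
# separate implementation from the package's var_stationary_cov().
lyapunov_oracle <- function(coeffs, noise_cov) {
  if (is.matrix(coeffs)) coeffs <- list(coeffs)
  P <- length(coeffs); K <- nrow(coeffs[[1]])
  C <- matrix(0, K * P, K * P)
  for (p in seq_len(P)) C[1:K, ((p - 1) * K + 1):(p * K)] <- coeffs[[p]]
  if (P > 1) C[(K + 1):(K * P), 1:(K * (P - 1))] <- diag(K * (P - 1))
  Q <- matrix(0, K * P, K * P); Q[1:K, 1:K] <- noise_cov
  S <- matrix(solve(diag((K * P)^2) - kronecker(C, C), as.vector(Q)),
              K * P, K * P)
  S  # block (1,1) is Gamma(0); block (1,r+1) is Gamma(r) for VAR(1) stacking
}

# Tiny two-residue trajectory with single heavy atoms at given positions.
point_residue_traj <- function(pos1, pos2) {
  atoms <- data.frame(elety = c("CA", "CA"), resno = c(1L, 2L),
                      resid = c("GLY", "GLY"), elem = c("C", "C"))
  as_md_trajectory(c(pos1, pos2), atoms)
}
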