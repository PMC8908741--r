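#' Specification of a stationary VAR process
#'
#' Holds the order P, the P coefficient matrices \eqn{A_p} (K x K), the
#' innovation covariance V, the output length and the seed. The constructor
#' verifies that V is symmetric positive definite and that the companion-form
#' matrix of the coefficients has spectral radius < 1 (stationarity); a
#' non-stationary specification is rejected with the offending radius.
#'
#' @param coeffs a K x K matrix (order 1) or list of P K x K matrices.
#' @param noise_cov symmetric positive-definite K x K innovation covariance.
#' @param length number of output frames T (after burn-in).
#' @param seed integer RNG seed.
#' @param labels optional channel labels.
#' @param dt frame stride in ns attached to the output (default 1).
#' @return An object of class `var_spec`.
#' @export
var_spec <- function(coeffs, noise_cov, length, seed = 1L,
                     labels = NULL, dt = 1) {
  if (is.matrix(coeffs)) coeffs <- list(coeffs)
  coeffs <- lapply(coeffs, as.matrix)
  K <- nrow(coeffs[[1L]])
  if (any(!vapply(coeffs, function(a) all(dim(a) == c(K, K)), logical(1))))
    stop("all coefficient matrices must be K x K with the same K")
  noise_cov <- as.matrix(noise_cov)
  if (!all(dim(noise_cov) == c(K, K)))
    stop("noise_cov must be K x K")
  if (max(abs(noise_cov - t(noise_cov))) > 1e-12)
    stop("noise_cov must be symmetric (tolerance 1e-12)")
  ev <- eigen(noise_cov, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0))
    stop("noise_cov must be positive definite (min eigenvalue ",
         signif(min(ev), 4), ")")
  rho <- companion_spectral_radius(coeffs)
  if (rho >= 1)
    stop("non-stationary VAR specification: companion spectral radius = ",
         signif(rho, 6), " (must be < 1)")
  length <- as.integer(length)
  if (length < 1L) stop("length must be >= 1")
  if (is.null(labels)) labels <- paste0("ch", seq_len(K))
  structure(list(order = length(coeffs), coeffs = coeffs,
                 noise_cov = noise_cov, length = length,
                 seed = as.integer(seed), labels = labels, dt = dt),
            class = "var_spec")
}

#' Spectral radius of the VAR companion matrix
#'
#' @param coeffs list of P K x K coefficient matrices.
#' @return The largest eigenvalue modulus of the PK x PK companion matrix.
#' @export
companion_spectral_radius <- function(coeffs) {
  if (is.matrix(coeffs)) coeffs <- list(coeffs)
  P <- length(coeffs)
  K <- nrow(coeffs[[1L]])
  C <- matrix(0, K * P, K * P)
  for (p in seq_len(P))
    C[1:K, ((p - 1L) * K + 1L):(p * K)] <- coeffs[[p]]
  if (P > 1L)
    C[(K + 1L):(K * P), 1L:(K * (P - 1L))] <- diag(K * (P - 1L))
  max(Mod(eigen(C, only.values = TRUE)$values))
}

#' Stationary covariance of a VAR process
#'
#' Solves the discrete Lyapunov equation of the companion form,
#' \eqn{\Sigma = C \Sigma C^\top + Q}, via the Kronecker identity
#' \eqn{\mathrm{vec}(\Sigma) = (I - C \otimes C)^{-1} \mathrm{vec}(Q)},
#' and returns the stacked-lag covariance blocks
#' \eqn{\Gamma(0), \dots, \Gamma(P-1)} of the process.
#'
#' @param spec a [var_spec].
#' @return list of K x K matrices `gamma0 .. gamma(P-1)` (named `gamma`),
#'   the first being the stationary covariance \eqn{\Gamma(0)}.
#' @export
var_stationary_cov <- function(spec) {
  stopifnot(inherits(spec, "var_spec"))
  P <- spec$order
  K <- nrow(spec$coeffs[[1L]])
  C <- matrix(0, K * P, K * P)
  for (p in seq_len(P))
    C[1:K, ((p - 1L) * K + 1L):(p * K)] <- spec$coeffs[[p]]
  if (P > 1L)
    C[(K + 1L):(K * P), 1L:(K * (P - 1L))] <- diag(K * (P - 1L))
  Q <- matrix(0, K * P, K * P)
  Q[1:K, 1:K] <- spec$noise_cov
  n <- K * P
  vecS <- solve(diag(n * n) - kronecker(C, C), as.vector(Q))
  S <- matrix(vecS, n, n)
  lapply(seq_len(P), function(r)
    S[1:K, ((r - 1L) * K + 1L):(r * K), drop = FALSE])
}

#' Simulate a stationary VAR process
#'
#' Generates a T x K series by the VAR recursion
#' \eqn{x(t) = \sum_p A_p x(t-p) + \eta(t)} with Gaussian innovations drawn
#' from `noise_cov`. The first `max(100, 10 P)` burn-in frames are discarded
#' so the output is effectively stationary; output is bit-reproducible for a
#' fixed seed.
#'
#' @param spec a [var_spec] (already validated by its constructor).
#' @return A [channel_series] of `spec$length` frames.
#' @export
simulate_var <- function(spec) {
  stopifnot(inherits(spec, "var_spec"))
  P <- spec$order
  K <- nrow(spec$coeffs[[1L]])
  burn <- max(100L, 10L * P)
  Tn <- spec$length + burn + P
  R <- chol(spec$noise_cov)
  rs <- local_rng(spec$seed)
  eta <- rs$norm_matrix(Tn, K) %*% R
  x <- matrix(0, Tn, K)
  A <- lapply(spec$coeffs, t)  # pre-transpose: row-vector recursion
  for (t in (P + 1L):Tn) {
    xt <- eta[t, ]
    for (p in seq_len(P))
      xt <- xt + x[t - p, ] %*% A[[p]]
    x[t, ] <- xt
  }
  channel_series(x[(burn + P + 1L):Tn, , drop = FALSE],
                 spec$labels, spec$dt)
}

# Seeded RNG helper: draws from an isolated stream without touching the
# global .Random.seed, so simulators are reproducible and side-effect-free.
local_rng <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    st <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    st
  })
  with_state <- function(fn) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    fn()
  }
  list(
    norm_matrix = function(n, k) with_state(function() matrix(stats::rnorm(n * k), n, k)),
    norm_vec = function(n) with_state(function() stats::rnorm(n)),
    unif = function(n) with_state(function() stats::runif(n)),
    perm = function(n) with_state(function() sample.int(n)),
    sample_int = function(n, size) with_state(function() sample.int(n, size))
  )
}
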