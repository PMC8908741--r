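#' Specification of the toy two-state folder
#'
#' An overdamped Langevin walker on the symmetric double well
#' \eqn{U(x) = d\,(x^2 - 1)^2} (depth `d` in kT units, minima at x = -1 and
#' x = +1, barrier of height `d` at x = 0) observed through K distance-like
#' channels. Channel i is a smooth sigmoid of `(x - switch_points[i])` plus
#' Gaussian noise, so channels switching near the barrier top change while
#' the walker is on a transition path, and channels switching deep inside a
#' well change only after commitment — a planted causal ordering with known
#' ground truth.
#'
#' @param well_depth barrier height in kT (default 4).
#' @param step Euler-Maruyama time step (dimensionless, friction = kT = 1;
#'   default 0.005).
#' @param switch_points per-channel sigmoid midpoints; must lie strictly
#'   between the minima at -1 and +1. The default places one pair near the
#'   barrier top (+/-0.15) and two pairs inside the wells (+/-0.6, +/-0.85).
#' @param n_channels number of observable channels (derived from
#'   `switch_points`).
#' @param channel_noise per-channel Gaussian noise SD (> 0); recycled.
#' @param switch_width sigmoid width (default 0.5, wide enough that every
#'   channel carries information over most of the inter-well range, so
#'   lag-driven directed couplings act between all channel pairs).
#' @param response_lags per-channel response delay in frames: channel i
#'   reads the coordinate `response_lags[i]` frames in the past. The
#'   default, `round(10 * |switch_points|)`, makes barrier-top channels
#'   respond promptly and well channels sluggishly — contacts deeper in
#'   the folding funnel report later in the causal cascade. This delay is
#'   what actually plants a directed ordering: purely instantaneous
#'   functions of a reversible equilibrium diffusion form a time-reversible
#'   joint process whose lagged moments are symmetric, so linear Granger
#'   couplings would be symmetric and every true origin predictability
#'   would vanish.
#' @param length number of recorded frames.
#' @param seed integer RNG seed.
#' @param dt frame stride in ns attached to the output (default 0.2).
#' @return An object of class `toy_folder_spec`.
#' @export
toy_folder_spec <- function(well_depth = 4, step = 0.005,
                            switch_points = c(-0.85, -0.6, -0.15,
                                              0.15, 0.6, 0.85),
                            n_channels = length(switch_points),
                            channel_noise = 0.1, switch_width = 0.5,
                            response_lags = round(10 * abs(switch_points)),
                            length = 2e5, seed = 1L, dt = 0.2) {
  if (well_depth <= 0) stop("well_depth must be positive (kT units)")
  if (n_channels != length(switch_points))
    stop("n_channels must equal length(switch_points)")
  if (any(switch_points <= -1) || any(switch_points >= 1))
    stop("switch_points must lie strictly between the potential minima (-1, 1)")
  channel_noise <- rep_len(channel_noise, length(switch_points))
  if (any(channel_noise <= 0)) stop("channel_noise must be > 0 for all channels")
  if (step <= 0) stop("step must be positive")
  response_lags <- rep_len(as.integer(response_lags), length(switch_points))
  if (any(response_lags < 0)) stop("response_lags must be >= 0")
  # Unstable integration guard: deterministic displacement at |x| = 1.5
  # exceeding the well separation means the walker overshoots both wells.
  if (step * 4 * well_depth * 1.5 * (1.5^2 - 1) > 2)
    stop("step size yields unstable integration (|dx| per step exceeds the ",
         "well separation); reduce `step` or `well_depth`")
  structure(list(well_depth = well_depth, step = step,
                 n_channels = length(switch_points),
                 switch_points = switch_points,
                 channel_noise = channel_noise,
                 switch_width = switch_width,
                 response_lags = response_lags,
                 length = as.integer(length), seed = as.integer(seed),
                 dt = dt),
            class = "toy_folder_spec")
}

#' Simulate the toy folder
#'
#' Integrates the overdamped Langevin equation
#' \eqn{x_{t+1} = x_t - U'(x_t)\,h + \sqrt{2h}\,\eta_t} on the double well
#' (Euler-Maruyama, kT = 1), discards 2000 burn-in steps from a start at the
#' x = -1 minimum, and maps the hidden coordinate through per-channel
#' sigmoids with additive noise; channel i reads the coordinate
#' `response_lags[i]` frames in the past (delays are served from the
#' burn-in, so every output frame is well defined).
#'
#' @param spec a [toy_folder_spec].
#' @return list with `channels` (a [channel_series]) and `coordinate`
#'   (numeric vector, the hidden coordinate trace x(t)).
#' @export
simulate_toy_folder <- function(spec) {
  stopifnot(inherits(spec, "toy_folder_spec"))
  h <- spec$step
  d <- spec$well_depth
  burn <- 2000L
  Tn <- spec$length + burn
  rs <- local_rng(spec$seed)
  noise <- sqrt(2 * h) * rs$norm_vec(Tn)
  x <- numeric(Tn)
  x[1] <- -1
  for (t in 2:Tn)
    x[t] <- x[t - 1] - 4 * d * x[t - 1] * (x[t - 1]^2 - 1) * h + noise[t]
  K <- spec$n_channels
  out_idx <- (burn + 1L):Tn
  levels <- vapply(seq_len(K), function(i)
    stats::plogis((x[out_idx - spec$response_lags[i]] -
                     spec$switch_points[i]) / spec$switch_width),
    numeric(spec$length))
  x <- x[out_idx]
  obs <- levels + rs$norm_matrix(spec$length, K) %*% diag(spec$channel_noise, K)
  labels <- sprintf("s%+.2f", spec$switch_points)
  list(channels = channel_series(obs, labels, spec$dt),
       coordinate = x)
}

#' Default core-state intervals for the toy folder
#'
#' Core states for transition-path identification, placed symmetrically
#' around the two minima: the folded core F is `x >= threshold`, the
#' unfolded core U is `x <= -threshold`. The default threshold 0.75 lies
#' between the minima (at 1) and the barrier top (at 0).
#'
#' @param threshold positive core boundary (default 0.75).
#' @return list with elements `F` and `U`, each an interval `c(lo, hi)`.
#' @export
toy_folder_cores <- function(threshold = 0.75) {
  stopifnot(threshold > 0, threshold < 1)
  list(F = c(threshold, Inf), U = c(-Inf, -threshold))
}

#' Planted causal categories of toy-folder channels
#'
#' Labels each channel "barrier" if its switch point lies within
#' `barrier_zone` of the barrier top (x = 0), else "well". Used as the
#' ground-truth category map when testing descriptor ranking and the
#' shuffle-null significance test.
#'
#' @param spec a [toy_folder_spec].
#' @param barrier_zone half-width of the barrier region (default 0.3).
#' @return named character vector of categories, one per channel.
#' @export
toy_folder_categories <- function(spec, barrier_zone = 0.3) {
  stopifnot(inherits(spec, "toy_folder_spec"))
  cats <- ifelse(abs(spec$switch_points) <= barrier_zone, "barrier", "well")
  names(cats) <- sprintf("s%+.2f", spec$switch_points)
  cats
}
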