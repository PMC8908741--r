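#' Potential of mean force along a coordinate
#'
#' Histograms the coordinate, converts occupation probabilities to free
#' energies via \eqn{PMF(\xi) = -\ln p(\xi) + F_0} (kT units) with the
#' constant \eqn{F_0} chosen so the global minimum is exactly 0. Empty bins
#' are undefined (NA). Uncertainty is the SD over `block_count` consecutive
#' trajectory blocks, each block normalized with its own \eqn{F_0}.
#'
#' @param xi per-frame coordinate values.
#' @param n_bins number of bins (default 50).
#' @param block_count error blocks (default 5).
#' @param limits optional c(lo, hi) histogram range (default data range).
#' @return A [fold_profile] of kind `"PMF"`.
#' @export
pmf_profile <- function(xi, n_bins = 50L, block_count = 5L, limits = NULL) {
  if (!length(xi)) stop("empty coordinate")
  if (is.null(limits)) limits <- range(xi)
  edges <- seq(limits[1], limits[2], length.out = n_bins + 1L)
  centers <- (edges[-1L] + edges[-length(edges)]) / 2
  binner <- function(x) {
    b <- findInterval(x, edges, rightmost.closed = TRUE)
    b[b < 1L | b > n_bins] <- NA_integer_
    tabulate(b[!is.na(b)], nbins = n_bins)
  }
  pmf_of <- function(counts) {
    p <- counts / sum(counts)
    v <- ifelse(p > 0, -log(p), NA_real_)
    v - min(v, na.rm = TRUE)
  }
  value <- pmf_of(binner(xi))
  Tn <- length(xi)
  bounds <- floor(seq(0, Tn, length.out = block_count + 1L))
  bp <- matrix(NA_real_, block_count, n_bins)
  for (b in seq_len(block_count)) {
    cnt <- binner(xi[seq.int(bounds[b] + 1L, bounds[b + 1L])])
    if (sum(cnt) > 0) bp[b, ] <- pmf_of(cnt)
  }
  err <- apply(bp, 2L, stats::sd, na.rm = TRUE)
  fold_profile(centers, value, err, err, kind = "PMF")
}

#' Locate the folded and unfolded free-energy minima
#'
#' Finds local minima of a PMF profile and selects the pair separated by the
#' highest intervening barrier (barrier = max PMF between the two minima
#' minus the higher of the two minimum values). The lower-valued minimum of
#' the pair is reported as the folded (F) minimum, matching the convention
#' that the global PMF minimum is the native state; for a symmetric
#' double well the assignment is arbitrary. Manual override: pass the
#' minima directly to downstream functions.
#'
#' @param profile a PMF [fold_profile].
#' @return list with `f`, `u` (coordinates of the minima), `f_bin`, `u_bin`
#'   (their bin indices) and `barrier` (height in kT).
#' @export
locate_pmf_minima <- function(profile) {
  stopifnot(inherits(profile, "fold_profile"))
  v <- profile$value
  n <- length(v)
  vpad <- c(Inf, ifelse(is.na(v), Inf, v), Inf)
  is_min <- vapply(seq_len(n), function(i)
    is.finite(vpad[i + 1]) && vpad[i + 1] < vpad[i] && vpad[i + 1] < vpad[i + 2],
    logical(1))
  mins <- which(is_min)
  if (length(mins) < 2L)
    stop("fewer than two local PMF minima found")
  best <- NULL; best_barrier <- -Inf
  for (i in seq_along(mins)) for (j in seq_along(mins)) {
    if (j <= i) next
    a <- mins[i]; b <- mins[j]
    barrier <- max(v[a:b], na.rm = TRUE) - max(v[a], v[b])
    if (barrier > best_barrier) {
      best_barrier <- barrier
      best <- c(a, b)
    }
  }
  f_bin <- if (v[best[1]] <= v[best[2]]) best[1] else best[2]
  u_bin <- setdiff(best, f_bin)
  list(f = profile$center[f_bin], u = profile$center[u_bin],
       f_bin = f_bin, u_bin = u_bin, barrier = best_barrier)
}

#' Discretize the reaction coordinate into states with medoid structures
#'
#' Places `n_states` equidistant centers spanning the interval from the
#' folded to the unfolded free-energy minimum and assigns every frame to its
#' closest center (ties to the lower-index state). Each state's
#' representative frame is its medoid — the member frame minimizing the
#' summed Euclidean distance to all frames of the state — computed in the
#' (kinetically weighted) TICA projection space when projections are given.
#' States with more than `medoid_max_frames` frames are subsampled
#' (deterministically, by the seed) before the O(m^2) medoid search.
#'
#' @param xi per-frame coordinate.
#' @param tica_projections optional frames x d projection matrix for medoid
#'   distances; without it medoids are computed on `xi` itself.
#' @param f_min,u_min coordinates of the folded / unfolded minima.
#' @param n_states number of states (default 6).
#' @param medoid_max_frames subsampling cap for the medoid search
#'   (default 2000).
#' @param seed seed for the subsampling.
#' @return An object of class `state_model`: `centers`, `labels` (per-frame
#'   state index 1..n_states), `medoid_frames` (NA for empty states, which
#'   are also flagged with a warning), `xi`.
#' @export
discretize_and_medoids <- function(xi, tica_projections = NULL, f_min, u_min,
                                   n_states = 6L, medoid_max_frames = 2000L,
                                   seed = 1L) {
  if (f_min == u_min) stop("f_min and u_min must differ")
  centers <- seq(f_min, u_min, length.out = n_states)
  dmat <- abs(outer(xi, centers, "-"))
  labels <- max.col(-dmat, ties.method = "first")
  proj <- if (is.null(tica_projections)) matrix(xi, ncol = 1L)
          else as.matrix(tica_projections)
  if (nrow(proj) != length(xi))
    stop("tica_projections must have one row per frame")
  rs <- local_rng(seed)
  medoid_frames <- rep(NA_integer_, n_states)
  for (s in seq_len(n_states)) {
    frames <- which(labels == s)
    if (!length(frames)) {
      warning("state ", s, " is empty; medoid undefined")
      next
    }
    if (length(frames) > medoid_max_frames)
      frames <- sort(frames[rs$sample_int(length(frames), medoid_max_frames)])
    P <- proj[frames, , drop = FALSE]
    dsum <- rowSums(as.matrix(stats::dist(P)))
    medoid_frames[s] <- frames[which.min(dsum)]
  }
  structure(list(centers = centers, labels = labels,
                 medoid_frames = medoid_frames, xi = xi),
            class = "state_model")
}

#' @export
print.state_model <- function(x, ...) {
  cat(sprintf("state_model: %d states, %d frames\n",
              length(x$centers), length(x$labels)))
  pop <- tabulate(x$labels, nbins = length(x$centers)) / length(x$labels)
  cat("  populations:", paste(signif(pop, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Median-filter a discrete state sequence
#'
#' Sliding-window median of the integer labels; the window width must be
#' odd (a 1 ns filter at 0.2 ns stride is 5 frames) so every window has a
#' unique integer median. Edges use shrunken (still odd) windows.
#'
#' @param labels integer state labels.
#' @param width_frames odd window width in frames.
#' @return filtered integer labels.
#' @export
median_filter_states <- function(labels, width_frames) {
  width_frames <- as.integer(width_frames)
  if (width_frames %% 2L == 0L)
    stop("median filter width must be odd in frames (got ", width_frames,
         "); choose an odd width so the integer median is unique")
  if (width_frames == 1L) return(as.integer(labels))
  as.integer(stats::runmed(as.numeric(labels), width_frames,
                           endrule = "median"))
}

#' Empirical transition matrix between discrete states
#'
#' Counts consecutive-frame label pairs (pairs spanning a segment break are
#' excluded) and row-normalizes. Rows of states that are never observed as a
#' transition origin are NA. Populations are overall label frequencies.
#'
#' @param labels integer state labels in 1..n_states.
#' @param n_states number of states (default `max(labels)`).
#' @param segment_breaks optional indices after which continuity is broken.
#' @return list with `P` (row-stochastic n x n matrix), `counts`,
#'   `populations`.
#' @export
transition_matrix <- function(labels, n_states = max(labels),
                              segment_breaks = integer(0)) {
  Tn <- length(labels)
  if (Tn < 2L) stop("need at least 2 frames")
  from <- labels[-Tn]; to <- labels[-1L]
  if (length(segment_breaks)) {
    drop <- segment_breaks
    from <- from[-drop]; to <- to[-drop]
  }
  counts <- matrix(0, n_states, n_states)
  for (k in seq_along(from))
    counts[from[k], to[k]] <- counts[from[k], to[k]] + 1
  rs <- rowSums(counts)
  P <- counts / ifelse(rs > 0, rs, NA_real_)
  list(P = P, counts = counts,
       populations = tabulate(labels, nbins = n_states) / Tn)
}

#' Committor function over discrete states
#'
#' For every visit to an intermediate state, follows the label sequence
#' after the visit ends and records whether the folded state F is reached
#' before the unfolded state U; the committor CF of the state is the
#' fraction of such visits committing to F. By the boundary convention
#' CF(F) = 1 and CF(U) = 0. Visits after which the trajectory ends without
#' reaching either core are excluded; a state with no countable visits is
#' undefined (NA) and flagged. Uncertainty is the min-max range over
#' `block_count` consecutive trajectory blocks (a visit belongs to the
#' block containing its first frame).
#'
#' @param labels integer state labels.
#' @param f_state,u_state the folded / unfolded state indices.
#' @param n_states number of states (default `max(labels)`).
#' @param block_count error blocks (default 5).
#' @return data.frame with `state`, `cf`, `cf_min`, `cf_max`, `n_visits`.
#' @export
committor_states <- function(labels, f_state, u_state,
                             n_states = max(labels), block_count = 5L) {
  Tn <- length(labels)
  if (!any(labels == f_state) || !any(labels == u_state))
    stop("both the F and the U state must be visited")
  # first core (F/U) reached at or after each frame
  nxt <- integer(Tn + 1L)  # 0 = none
  for (t in Tn:1)
    nxt[t] <- if (labels[t] == f_state || labels[t] == u_state) labels[t]
              else nxt[t + 1L]
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  visits <- data.frame(state = r$values, start = starts, end = ends)
  visits <- visits[!(visits$state %in% c(f_state, u_state)), , drop = FALSE]
  outcome <- nxt[pmin(visits$end + 1L, Tn + 1L)]
  counted <- outcome != 0L & visits$end < Tn
  cf_of <- function(sel) {
    vapply(seq_len(n_states), function(s) {
      use <- sel & counted & visits$state == s
      if (!any(use)) return(NA_real_)
      mean(outcome[use] == f_state)
    }, numeric(1))
  }
  cf <- cf_of(rep(TRUE, nrow(visits)))
  bounds <- floor(seq(0, Tn, length.out = block_count + 1L))
  block_cf <- matrix(NA_real_, block_count, n_states)
  for (b in seq_len(block_count))
    block_cf[b, ] <- cf_of(visits$start > bounds[b] &
                             visits$start <= bounds[b + 1L])
  cf[f_state] <- 1; cf[u_state] <- 0
  cf_min <- suppressWarnings(apply(block_cf, 2L, min, na.rm = TRUE))
  cf_max <- suppressWarnings(apply(block_cf, 2L, max, na.rm = TRUE))
  cf_min[!is.finite(cf_min)] <- NA_real_
  cf_max[!is.finite(cf_max)] <- NA_real_
  cf_min[c(f_state, u_state)] <- cf_max[c(f_state, u_state)] <-
    cf[c(f_state, u_state)]
  n_visits <- vapply(seq_len(n_states), function(s)
    sum(counted & visits$state == s), integer(1))
  und <- is.na(cf) & !(seq_len(n_states) %in% c(f_state, u_state))
  if (any(und))
    warning("committor undefined for state(s) ",
            paste(which(und), collapse = ", "),
            " (no countable visits)")
  data.frame(state = seq_len(n_states), cf = cf,
             cf_min = cf_min, cf_max = cf_max, n_visits = n_visits)
}

#' Count folding and unfolding events
#'
#' A folding event is a trajectory segment that leaves the unfolded state U
#' and reaches the folded state F prior to coming back to U; re-entering U
#' restarts the candidate event. Its duration is measured from the first
#' frame after the last U frame to the first F frame, inclusive, times the
#' frame stride. Unfolding events are defined symmetrically.
#'
#' @param labels integer state labels.
#' @param f_state,u_state folded / unfolded state indices.
#' @param dt frame stride in ns.
#' @return list with `folding` and `unfolding` (data.frames of `start`,
#'   `end`, `duration`), and `summary` (counts, mean and SD durations).
#' @export
count_events <- function(labels, f_state, u_state, dt = 1) {
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  scan <- function(from_state, to_state) {
    exit_frame <- NA_integer_
    ev <- list()
    for (k in seq_along(r$values)) {
      v <- r$values[k]
      if (v == from_state) {
        exit_frame <- ends[k] + 1L
      } else if (v == to_state) {
        if (!is.na(exit_frame))
          ev[[length(ev) + 1L]] <-
            data.frame(start = exit_frame, end = starts[k],
                       duration = (starts[k] - exit_frame + 1L) * dt)
        exit_frame <- NA_integer_
      }
    }
    if (!length(ev))
      return(data.frame(start = integer(0), end = integer(0),
                        duration = numeric(0)))
    do.call(rbind, ev)
  }
  folding <- scan(u_state, f_state)
  unfolding <- scan(f_state, u_state)
  list(folding = folding, unfolding = unfolding,
       summary = data.frame(
         process = c("folding", "unfolding"),
         n_events = c(nrow(folding), nrow(unfolding)),
         mean_duration = c(mean(folding$duration), mean(unfolding$duration)),
         sd_duration = c(stats::sd(folding$duration),
                         stats::sd(unfolding$duration))))
}

#' Overlap area of two normal distributions
#'
#' The integral of the pointwise minimum of two Gaussian densities,
#' computed analytically via their intersection points (for equal SDs this
#' reduces to \eqn{2\Phi(-|\mu_1-\mu_2|/(2\sigma))}). Equal distributions
#' give 1; infinitely separated means give 0.
#'
#' @param m1,s1 mean and SD of the first distribution (s1 > 0).
#' @param m2,s2 mean and SD of the second distribution (s2 > 0).
#' @return overlap area in [0, 1].
#' @export
gaussian_overlap <- function(m1, s1, m2, s2) {
  if (s1 <= 0 || s2 <= 0) stop("standard deviations must be positive")
  if (isTRUE(all.equal(s1, s2))) {
    if (m1 == m2) return(1)
    return(2 * stats::pnorm(-abs(m1 - m2) / (2 * s1)))
  }
  # intersection points of the two densities: quadratic in x
  a <- 1 / (2 * s2^2) - 1 / (2 * s1^2)
  b <- m1 / s1^2 - m2 / s2^2
  cc <- m2^2 / (2 * s2^2) - m1^2 / (2 * s1^2) + log(s2 / s1)
  disc <- b^2 - 4 * a * cc
  roots <- if (disc <= 0) numeric(0) else sort((-b + c(-1, 1) * sqrt(disc)) / (2 * a))
  pts <- c(-Inf, roots, Inf)
  total <- 0
  for (k in seq_len(length(pts) - 1L)) {
    mid <- if (is.finite(pts[k]) && is.finite(pts[k + 1L]))
      (pts[k] + pts[k + 1L]) / 2
    else if (is.finite(pts[k + 1L])) pts[k + 1L] - 1
    else if (is.finite(pts[k])) pts[k] + 1
    else (m1 + m2) / 2
    use1 <- stats::dnorm(mid, m1, s1) <= stats::dnorm(mid, m2, s2)
    m <- if (use1) m1 else m2
    s <- if (use1) s1 else s2
    total <- total + (stats::pnorm(pts[k + 1L], m, s) - stats::pnorm(pts[k], m, s))
  }
  min(max(total, 0), 1)
}

#' Native-ensemble overlap profile Omega(xi)
#'
#' Discretizes the coordinate into `n_bins` nearest-center bins between the
#' folded and unfolded free-energy minima, fits a normal distribution
#' (mean, SD) to the channel values in every bin, and computes the overlap
#' area between each bin's distribution and that of the reference (folded)
#' bin — the bin centered on the global PMF minimum. The raw overlap is then
#' normalized so that its range of variation along the transition path
#' spans exactly [0, 1].
#'
#' @param channel per-frame values of one distance channel.
#' @param xi per-frame reaction coordinate.
#' @param f_min,u_min coordinates of the folded / unfolded minima.
#' @param n_bins number of bins (default 21).
#' @param ref_bin index of the reference folded bin (default 1, the
#'   `f_min` end).
#' @return A [fold_profile] of kind `"overlap"` with attribute `raw` (the
#'   unnormalized overlap values).
#' @export
overlap_profile <- function(channel, xi, f_min, u_min, n_bins = 21L,
                            ref_bin = 1L) {
  if (length(channel) != length(xi))
    stop("channel and xi must have the same length")
  centers <- seq(f_min, u_min, length.out = n_bins)
  h <- abs(centers[2] - centers[1])
  inside <- xi >= min(f_min, u_min) - h / 2 & xi <= max(f_min, u_min) + h / 2
  bins <- max.col(-abs(outer(xi, centers, "-")), ties.method = "first")
  bins[!inside] <- NA_integer_
  mu <- sdv <- rep(NA_real_, n_bins)
  for (b in seq_len(n_bins)) {
    v <- channel[!is.na(bins) & bins == b]
    if (length(v) >= 2L) {
      mu[b] <- mean(v)
      sdv[b] <- stats::sd(v)
      if (sdv[b] <= 0)
        stop("zero-SD channel distribution in bin ", b)
    }
  }
  if (is.na(mu[ref_bin]))
    stop("reference bin ", ref_bin, " has fewer than 2 frames")
  raw <- vapply(seq_len(n_bins), function(b) {
    if (is.na(mu[b])) return(NA_real_)
    gaussian_overlap(mu[b], sdv[b], mu[ref_bin], sdv[ref_bin])
  }, numeric(1))
  rng <- range(raw, na.rm = TRUE)
  if (diff(rng) <= 0)
    stop("overlap profile is constant; cannot normalize to [0, 1]")
  value <- (raw - rng[1]) / diff(rng)
  prof <- fold_profile(centers, value, kind = "overlap")
  attr(prof, "raw") <- raw
  prof
}
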