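#' Label frames by core-state membership
#'
#' @param xi per-frame coordinate values.
#' @param cores list of two intervals, e.g.
#'   `list(F = c(0.75, Inf), U = c(-Inf, -0.75))`; intervals are closed and
#'   must not overlap.
#' @return integer vector: 1 for the first core, 2 for the second, 0
#'   elsewhere.
#' @export
core_labels <- function(xi, cores) {
  if (length(cores) != 2L) stop("cores must be a list of two intervals")
  a <- cores[[1L]]; b <- cores[[2L]]
  if (max(a[1], b[1]) <= min(a[2], b[2]))
    stop("core intervals must not overlap")
  lab <- integer(length(xi))
  lab[xi >= a[1] & xi <= a[2]] <- 1L
  lab[xi >= b[1] & xi <= b[2]] <- 2L
  lab
}

#' Identify transition paths between two core states
#'
#' A transition path (TP) is a maximal run of non-core frames whose flanking
#' core visits belong to different cores: the trajectory leaves one core and
#' reaches the other with no interior core visit (no recrossing). Runs
#' before the first or after the last core visit are not TPs.
#'
#' @param labels integer core labels from [core_labels()].
#' @return data.frame with columns `start`, `end` (first and last frame of
#'   the TP, inclusive) and `direction` (`"1->2"` or `"2->1"`).
#' @export
identify_transition_paths <- function(labels) {
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (k in seq_along(r$values)) {
    if (r$values[k] != 0L || k == 1L || k == length(r$values)) next
    prev <- r$values[k - 1L]
    nxt <- r$values[k + 1L]
    if (prev != 0L && nxt != 0L && prev != nxt)
      out[[length(out) + 1L]] <-
        data.frame(start = starts[k], end = ends[k],
                   direction = paste0(prev, "->", nxt))
  }
  if (!length(out))
    return(data.frame(start = integer(0), end = integer(0),
                      direction = character(0)))
  do.call(rbind, out)
}

#' Conditional transition-path probability profile p(TP|xi)
#'
#' Bins the coordinate into `n_bins` equal bins spanning the region between
#' the two core states (from the inner edge of one core to the inner edge of
#' the other) and estimates, per bin i, the probability of being on a
#' transition path as \eqn{p(TP|\xi_i) = N_i^{TP} / N_i}, where \eqn{N_i}
#' counts all frames in the bin and \eqn{N_i^{TP}} the frames belonging to
#' TP segments. For an ideal diffusive coordinate the profile maximum
#' approaches the theoretical limit 0.5. Empty bins are undefined (NA) and
#' excluded from the maximum. Uncertainty is the SD of per-bin estimates
#' over `block_count` consecutive trajectory blocks.
#'
#' @param xi per-frame coordinate.
#' @param cores either a core-interval definition on `xi` itself (see
#'   [core_labels()]) — core membership and transition paths are then
#'   derived from `xi` — or a precomputed integer core-label vector
#'   (0/1/2, one per frame) from a reference state assignment. The label
#'   form is what [rank_trial_coordinates()] uses: candidate coordinates
#'   are binned along their own scale while transition paths stay fixed by
#'   the system's actual state definitions, so an uninformative candidate
#'   cannot score well by mislabelling its own cores.
#' @param n_bins number of bins (default 50).
#' @param block_count number of consecutive error blocks (default 5).
#' @return A [fold_profile] of kind `"pTP"`, with attributes `tp_segments`
#'   (the transition-path table) and `maximum` (profile maximum over defined
#'   bins).
#' @export
p_tp_profile <- function(xi, cores, n_bins = 50L, block_count = 5L) {
  labels_given <- !is.list(cores)
  labels <- if (labels_given) {
    if (length(cores) != length(xi))
      stop("core label vector must have one entry per frame")
    as.integer(cores)
  } else core_labels(xi, cores)
  if (!any(labels == 1L) || !any(labels == 2L)) {
    missing <- c("first", "second")[!c(any(labels == 1L), any(labels == 2L))]
    stop("core state(s) never visited: ", paste(missing, collapse = ", "))
  }
  tps <- identify_transition_paths(labels)
  on_tp <- logical(length(xi))
  for (k in seq_len(nrow(tps)))
    on_tp[tps$start[k]:tps$end[k]] <- TRUE
  if (labels_given) {
    # inter-core region along the candidate: between the per-core medians
    lo <- stats::median(xi[labels == 1L])
    hi <- stats::median(xi[labels == 2L])
    if (lo > hi) { tmp <- lo; lo <- hi; hi <- tmp }
  } else {
    # region between the cores: inner edge of each
    lo_core <- if (min(cores[[1L]]) < min(cores[[2L]])) cores[[1L]] else cores[[2L]]
    hi_core <- if (min(cores[[1L]]) < min(cores[[2L]])) cores[[2L]] else cores[[1L]]
    lo <- lo_core[2]; hi <- hi_core[1]
  }
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi)
    stop("cannot determine the inter-core region from the core definition")
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  centers <- (edges[-1L] + edges[-length(edges)]) / 2
  bin_of <- function(x) {
    b <- findInterval(x, edges, rightmost.closed = TRUE)
    b[b < 1L | b > n_bins] <- NA_integer_
    b
  }
  bins <- bin_of(xi)
  count_bins <- function(sel) tabulate(bins[sel], nbins = n_bins)
  N <- count_bins(!is.na(bins))
  Ntp <- count_bins(!is.na(bins) & on_tp)
  p <- ifelse(N > 0L, Ntp / N, NA_real_)
  # block errors
  Tn <- length(xi)
  bounds <- floor(seq(0, Tn, length.out = block_count + 1L))
  block_p <- matrix(NA_real_, block_count, n_bins)
  for (b in seq_len(block_count)) {
    sel <- seq.int(bounds[b] + 1L, bounds[b + 1L])
    inblk <- logical(Tn); inblk[sel] <- TRUE
    Nb <- count_bins(inblk & !is.na(bins))
    Nbtp <- count_bins(inblk & !is.na(bins) & on_tp)
    block_p[b, ] <- ifelse(Nb > 0L, Nbtp / Nb, NA_real_)
  }
  err <- apply(block_p, 2L, stats::sd, na.rm = TRUE)
  prof <- fold_profile(centers, p, err, err, kind = "pTP")
  attr(prof, "tp_segments") <- tps
  attr(prof, "maximum") <- if (any(!is.na(p))) max(p, na.rm = TRUE) else NA_real_
  prof
}

#' Rank trial reaction coordinates by their p(TP|xi) maximum
#'
#' Scores every candidate coordinate by the maximum of its 50-bin
#' transition-path probability profile and returns them in descending score
#' order; ties preserve the input order (stable). Candidates whose profile
#' computation fails are ranked last and flagged.
#'
#' @param candidates named list of per-frame coordinate vectors.
#' @param cores shared core definition — normally a per-frame core-label
#'   vector from the reference state assignment, so every candidate is
#'   scored against the same transition paths — or a list of per-candidate
#'   interval definitions of the same length as `candidates`.
#' @param n_bins bins per profile (default 50).
#' @return list with `ranking` (data.frame: name, score, ok, in rank order)
#'   and `profiles` (named list of [fold_profile]s or NULL for failures).
#' @export
rank_trial_coordinates <- function(candidates, cores, n_bins = 50L) {
  if (!length(candidates)) stop("need at least one candidate")
  if (is.null(names(candidates)))
    names(candidates) <- paste0("candidate", seq_along(candidates))
  per_cand <- length(cores) == length(candidates) &&
    all(vapply(cores, is.list, logical(1)))
  profiles <- vector("list", length(candidates))
  names(profiles) <- names(candidates)
  score <- rep(NA_real_, length(candidates))
  ok <- logical(length(candidates))
  for (i in seq_along(candidates)) {
    ci <- if (per_cand) cores[[i]] else cores
    prof <- tryCatch(p_tp_profile(candidates[[i]], ci, n_bins = n_bins),
                     error = function(e) e)
    if (inherits(prof, "error")) {
      warning("candidate '", names(candidates)[i], "' failed: ",
              conditionMessage(prof))
      next
    }
    profiles[[i]] <- prof
    score[i] <- attr(prof, "maximum")
    ok[i] <- TRUE
  }
  key <- ifelse(ok, score, -Inf)
  ord <- order(-key, seq_along(key))  # stable descending, failures last
  list(ranking = data.frame(name = names(candidates)[ord],
                            score = score[ord], ok = ok[ord],
                            stringsAsFactors = FALSE),
       profiles = profiles)
}
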