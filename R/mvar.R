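#' Lagged second-moment matrices
#'
#' Estimates the mixed second statistical moments
#' \eqn{\Gamma(r)[i,j] = \langle x_i(t)\, x_j(t - r)\rangle} for
#' \eqn{r = 0, \dots, max\_lag}, averaging over all valid frame pairs.
#' Lag products that would span a segment break are excluded, so moments of
#' concatenated or split trajectories carry no stitching artifacts. Each
#' \eqn{\Gamma(r)} is divided by the number of valid products at that lag.
#' Only non-negative lags are stored; \eqn{\Gamma(-r) = \Gamma(r)^\top}.
#'
#' The series is used as-is (no centering): channels are expected to be
#' normalized to zero mean beforehand, as in the Granger pipeline.
#'
#' @param series a [channel_series].
#' @param max_lag largest lag (in frames) to estimate.
#' @return An object of class `moment_set` with elements `gamma` (list of
#'   K x K matrices indexed by lag `0..max_lag`), `max_lag`, `n_products`
#'   (valid products per lag), `n_frames`, `labels`.
#' @export
estimate_moments <- function(series, max_lag) {
  stopifnot(inherits(series, "channel_series"))
  max_lag <- as.integer(max_lag)
  if (max_lag < 0L) stop("max_lag must be >= 0")
  segs <- series_segments(series)
  shortest <- min(lengths(segs))
  if (max_lag >= shortest)
    stop("max_lag (", max_lag, ") must be smaller than the shortest segment length (",
         shortest, ")")
  if (n_frames(series) <= max_lag + n_channels(series))
    stop("too few frames (need T > max_lag + K)")
  x <- series$values
  K <- ncol(x)
  gamma <- vector("list", max_lag + 1L)
  n_products <- integer(max_lag + 1L)
  for (r in 0:max_lag) {
    acc <- matrix(0, K, K)
    n <- 0L
    for (seg in segs) {
      len <- length(seg)
      if (len > r) {
        it <- seg[(r + 1L):len]
        is <- seg[1L:(len - r)]
        acc <- acc + crossprod(x[it, , drop = FALSE], x[is, , drop = FALSE])
        n <- n + len - r
      }
    }
    g <- acc / n
    if (r == 0L) g <- (g + t(g)) / 2
    dimnames(g) <- list(series$labels, series$labels)
    gamma[[r + 1L]] <- g
    n_products[r + 1L] <- n
  }
  structure(list(gamma = gamma, max_lag = max_lag, n_products = n_products,
                 n_frames = n_frames(series), labels = series$labels),
            class = "moment_set")
}

moment_lag <- function(moments, r) {
  if (r >= 0) moments$gamma[[r + 1L]] else t(moments$gamma[[-r + 1L]])
}

# Restrict a moment_set to a channel subset (used for leave-one-out refits;
# identical to re-estimating moments on the reduced channel set).
moment_subset <- function(moments, keep) {
  structure(list(gamma = lapply(moments$gamma,
                                function(g) g[keep, keep, drop = FALSE]),
                 max_lag = moments$max_lag,
                 n_products = moments$n_products,
                 n_frames = moments$n_frames,
                 labels = moments$labels[keep]),
            class = "moment_set")
}

#' Fit an MVAR model by the Yule-Walker method
#'
#' Solves the block Yule-Walker system for a multivariate autoregressive
#' model of order P: for \eqn{r = 1..P},
#' \eqn{\Gamma(r) = \sum_p A_p \Gamma(r - p)}, a set of P + 1 linear matrix
#' equations whose r = 0 member gives the residual white-noise covariance
#' \eqn{V = \Gamma(0) - \sum_p A_p \Gamma(-p)}. V is symmetrized as
#' \eqn{(V + V^\top)/2} before return.
#'
#' @param moments a `moment_set` from [estimate_moments()] with
#'   `max_lag >= order`.
#' @param order model order P (>= 1).
#' @return An object of class `mvar_model` with `order`, `coeffs` (list of P
#'   K x K matrices), `noise_cov`, `labels`, `n_frames_used`.
#' @export
fit_yule_walker <- function(moments, order) {
  stopifnot(inherits(moments, "moment_set"))
  P <- as.integer(order)
  if (P < 1L) stop("order must be >= 1")
  if (P > moments$max_lag)
    stop("order (", P, ") exceeds available max_lag (", moments$max_lag, ")")
  K <- nrow(moments$gamma[[1L]])
  # Block-Toeplitz matrix M with block (p, q) = Gamma(q - p), p, q in 1..P.
  M <- matrix(0, K * P, K * P)
  for (p in seq_len(P)) for (q in seq_len(P)) {
    M[((p - 1L) * K + 1L):(p * K), ((q - 1L) * K + 1L):(q * K)] <-
      moment_lag(moments, q - p)
  }
  G <- do.call(cbind, lapply(seq_len(P), function(r) moment_lag(moments, r)))
  A_stack <- tryCatch(t(solve(M, t(G))),
                      error = function(e)
                        stop("singular Yule-Walker block system (rank-deficient ",
                             "moments; duplicated or collinear channels?): ",
                             conditionMessage(e)))
  coeffs <- lapply(seq_len(P), function(p)
    A_stack[, ((p - 1L) * K + 1L):(p * K), drop = FALSE])
  V <- moment_lag(moments, 0L)
  for (p in seq_len(P))
    V <- V - coeffs[[p]] %*% moment_lag(moments, -p)
  V <- (V + t(V)) / 2
  dimnames(V) <- list(moments$labels, moments$labels)
  coeffs <- lapply(coeffs, function(a) {
    dimnames(a) <- list(moments$labels, moments$labels); a })
  structure(list(order = P, coeffs = coeffs, noise_cov = V,
                 labels = moments$labels, n_frames_used = moments$n_frames),
            class = "mvar_model")
}

#' @export
print.mvar_model <- function(x, ...) {
  cat(sprintf("mvar_model: order P = %d, K = %d channels, fitted on N = %d frames\n",
              x$order, length(x$labels), x$n_frames_used))
  cat(sprintf("  residual variances: %s\n",
              paste(signif(diag(x$noise_cov), 4), collapse = ", ")))
  invisible(x)
}

#' Select the MVAR order by the Schwarz-Bayes criterion
#'
#' Fits every candidate order and scores it with
#' \eqn{SBC(P) = \ln\det \hat V_P + P K^2 \ln N / N}: the first term rewards
#' predictive accuracy, the second penalizes the P K^2 model parameters.
#' Returns the argmin; ties (scores equal within `tol`) break toward the
#' smaller order, so a criterion that is flat with growing P yields the most
#' parsimonious model. Candidates that fail to fit are excluded with a
#' warning.
#'
#' @param series a [channel_series] (normally normalized).
#' @param candidate_orders integer vector of orders to try.
#' @param tol score differences below this count as ties (default `1e-10`).
#' @return list with `order` (chosen P) and `table` (data.frame of order,
#'   sbc, ok).
#' @export
select_order <- function(series, candidate_orders, tol = 1e-10) {
  stopifnot(inherits(series, "channel_series"))
  candidate_orders <- sort(unique(as.integer(candidate_orders)))
  if (!length(candidate_orders) || any(candidate_orders < 1L))
    stop("candidate_orders must be positive integers")
  K <- n_channels(series)
  N <- n_frames(series)
  moments <- estimate_moments(series, max(candidate_orders))
  sbc <- rep(NA_real_, length(candidate_orders))
  ok <- logical(length(candidate_orders))
  for (i in seq_along(candidate_orders)) {
    P <- candidate_orders[i]
    fit <- tryCatch(fit_yule_walker(moments, P), error = function(e) e)
    if (inherits(fit, "error")) {
      warning("order ", P, " unfittable, excluded: ", conditionMessage(fit))
      next
    }
    ld <- determinant(fit$noise_cov, logarithm = TRUE)
    if (ld$sign <= 0) {
      warning("order ", P, " gave a non-positive-definite residual covariance, excluded")
      next
    }
    sbc[i] <- as.numeric(ld$modulus) + P * K^2 * log(N) / N
    ok[i] <- TRUE
  }
  if (!any(ok)) stop("no candidate order could be fitted")
  usable <- which(ok)
  best <- usable[which(sbc[usable] <= min(sbc[usable]) + tol)][1L]
  list(order = candidate_orders[best],
       table = data.frame(order = candidate_orders, sbc = sbc, ok = ok))
}

#' One-step-ahead residuals of an MVAR model
#'
#' Computes \eqn{\Delta x(t) = x(t) - \sum_p A_p x(t - p)} for every frame
#' with P predecessors inside its segment. On the training data these
#' residuals are white with covariance close to the model's `noise_cov`.
#'
#' @param model an `mvar_model`.
#' @param series a [channel_series] whose labels match the model.
#' @return A residual [channel_series] (P frames shorter per segment).
#' @export
predict_residuals <- function(model, series) {
  stopifnot(inherits(model, "mvar_model"), inherits(series, "channel_series"))
  if (!identical(model$labels, series$labels))
    stop("channel labels of series do not match the model")
  P <- model$order
  x <- series$values
  segs <- series_segments(series)
  out <- vector("list", length(segs))
  for (s in seq_along(segs)) {
    seg <- segs[[s]]
    Tn <- length(seg)
    if (Tn <= P)
      stop("segment of length ", Tn, " too short for order ", P)
    xs <- x[seg, , drop = FALSE]
    pred <- matrix(0, Tn - P, ncol(x))
    for (p in seq_len(P))
      pred <- pred + xs[(P + 1L - p):(Tn - p), , drop = FALSE] %*% t(model$coeffs[[p]])
    out[[s]] <- xs[(P + 1L):Tn, , drop = FALSE] - pred
  }
  lens <- vapply(out, nrow, integer(1))
  breaks <- if (length(lens) > 1L) cumsum(lens[-length(lens)]) else integer(0)
  channel_series(do.call(rbind, out), series$labels, series$dt, breaks)
}

#' Serialize / deserialize an MVAR model as JSON
#'
#' Self-describing text representation holding the channel labels, order,
#' coefficient matrices, residual covariance and frame count.
#'
#' @param model an `mvar_model`.
#' @param path file path.
#' @export
write_mvar <- function(model, path) {
  stopifnot(inherits(model, "mvar_model"))
  obj <- list(order = model$order,
              labels = model$labels,
              coeffs = lapply(model$coeffs, function(a) unname(as.matrix(a))),
              noise_cov = unname(as.matrix(model$noise_cov)),
              n_frames_used = model$n_frames_used)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_mvar
#' @export
read_mvar <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  labels <- obj$labels
  raw <- obj$coeffs
  coeffs <- if (is.array(raw) && length(dim(raw)) == 3L) {
    lapply(seq_len(dim(raw)[1L]), function(p) raw[p, , ])  # P > 1 stack
  } else if (is.list(raw)) {
    lapply(raw, as.matrix)
  } else {
    list(as.matrix(raw))
  }
  coeffs <- lapply(coeffs, function(a) {
    dimnames(a) <- list(labels, labels); a })
  V <- as.matrix(obj$noise_cov)
  dimnames(V) <- list(labels, labels)
  structure(list(order = as.integer(obj$order), coeffs = coeffs,
                 noise_cov = V, labels = labels,
                 n_frames_used = as.integer(obj$n_frames_used)),
            class = "mvar_model")
}
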