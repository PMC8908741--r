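#' Granger causality matrix by leave-one-channel-out refitting
#'
#' Fits the full K-channel MVAR model of the given order, obtaining the
#' residual covariance V, and then for every channel j refits the reduced
#' (K-1)-channel model with channel j excluded, obtaining \eqn{V^{(j)}}.
#' The Granger coupling from j to i is
#' \deqn{J_{j \to i} = 1 - V_i / V_i^{(j)},}
#' which varies between 0 (omitting j does not degrade the prediction of i)
#' and 1 (without j the model loses all ability to predict i). Reduced
#' models are fitted from the (K-1) x (K-1) submatrices of the already
#' estimated moment matrices — mathematically identical to re-estimating
#' moments on the reduced channel set and O(K) cheaper. Entries in
#' `(-1e-6, 0)` arising from floating point are clipped to 0; anything more
#' negative raises an internal-consistency error. The diagonal is undefined
#' and stored as 0.
#'
#' @param series a normalized [channel_series] with K >= 2 channels (a
#'   warning is issued if channel variances deviate from 1 by more than
#'   10%).
#' @param order MVAR model order P.
#' @return An object of class `gc_matrix`: list with `J` (K x K, row j /
#'   column i holds \eqn{J_{j\to i}}) and `labels`.
#' @export
gc_matrix <- function(series, order) {
  stopifnot(inherits(series, "channel_series"))
  K <- n_channels(series)
  if (K < 2L) stop("Granger analysis needs at least 2 channels")
  v <- colMeans(series$values^2) - colMeans(series$values)^2
  if (any(abs(v - 1) > 0.1))
    warning("channel variance deviates from 1 by more than 10%; ",
            "did you forget normalize_channels()?")
  moments <- estimate_moments(series, order)
  full <- fit_yule_walker(moments, order)
  Vd <- diag(full$noise_cov)
  J <- matrix(0, K, K, dimnames = list(series$labels, series$labels))
  for (j in seq_len(K)) {
    keep <- setdiff(seq_len(K), j)
    red <- tryCatch(fit_yule_walker(moment_subset(moments, keep), order),
                    error = function(e)
                      stop("reduced model excluding channel '",
                           series$labels[j], "' unfittable: ",
                           conditionMessage(e)))
    Jrow <- 1 - Vd[keep] / diag(red$noise_cov)
    if (any(Jrow < -1e-6))
      stop("internal consistency error: J entry ", signif(min(Jrow), 4),
           " below -1e-6 for source channel '", series$labels[j], "'")
    J[j, keep] <- pmax(Jrow, 0)
  }
  structure(list(J = J, labels = series$labels), class = "gc_matrix")
}

#' @export
print.gc_matrix <- function(x, ...) {
  cat(sprintf("gc_matrix: %d channels, max off-diagonal coupling %.4g\n",
              length(x$labels), max(x$J)))
  invisible(x)
}

#' Per-channel predictability descriptors
#'
#' Collapses the K x K Granger matrix into four per-channel measures:
#' * `g_in`  — predictability to, \eqn{G^{\leftarrow}_i = \sum_{k \ne i} J_{k \to i}};
#' * `g_out` — predictability from, \eqn{G^{\rightarrow}_i = \sum_{k \ne i} J_{i \to k}};
#' * `g_origin` — origin predictability, \eqn{G^{\circ}_i = G^{\rightarrow}_i - G^{\leftarrow}_i}
#'   (positive for initiators of events, negative for terminators);
#' * `g_total`  — predictability indicator, \eqn{G^{+}_i = G^{\rightarrow}_i + G^{\leftarrow}_i}.
#' The diagonal (self-causality) is excluded from all sums, so
#' \eqn{\sum_i G^{\circ}_i = 0} holds exactly.
#'
#' @param J a `gc_matrix`.
#' @param categories optional named character vector (or unnamed, in channel
#'   order) of category labels carried through for reporting.
#' @return data.frame with one row per channel.
#' @export
gc_descriptors <- function(J, categories = NULL) {
  stopifnot(inherits(J, "gc_matrix"))
  g_out <- rowSums(J$J)
  g_in <- colSums(J$J)
  out <- data.frame(channel = J$labels,
                    g_in = as.numeric(g_in),
                    g_out = as.numeric(g_out),
                    g_origin = as.numeric(g_out - g_in),
                    g_total = as.numeric(g_out + g_in),
                    stringsAsFactors = FALSE)
  if (!is.null(categories)) {
    out$category <- if (!is.null(names(categories)))
      unname(categories[J$labels]) else unname(categories)
  }
  out
}

#' Split-half convergence of the descriptors
#'
#' Splits the series into two consecutive, equal parts (an odd frame count
#' gives the first half the extra frame), processes each independently
#' (normalization, MVAR fit, Granger matrix, descriptors), and reports the
#' mean of the halves together with half-range error bars. Shrinking error
#' bars with growing trajectory length indicate convergence of the
#' analysis.
#'
#' @inheritParams gc_matrix
#' @param categories optional category labels, as in [gc_descriptors()].
#' @return data.frame with columns `channel`, the four descriptor means, a
#'   matching set of `*_err` half-ranges, and optionally `category`.
#' @export
split_half_convergence <- function(series, order, categories = NULL) {
  stopifnot(inherits(series, "channel_series"))
  Tn <- n_frames(series)
  cut <- ceiling(Tn / 2)
  halves <- list(seq_len(cut), seq.int(cut + 1L, Tn))
  desc <- lapply(halves, function(idx) {
    half <- channel_series(series$values[idx, , drop = FALSE],
                           series$labels, series$dt)
    gc_descriptors(gc_matrix(normalize_channels(half), order))
  })
  out <- desc[[1L]][, "channel", drop = FALSE]
  for (col in c("g_in", "g_out", "g_origin", "g_total")) {
    a <- desc[[1L]][[col]]; b <- desc[[2L]][[col]]
    out[[col]] <- (a + b) / 2
    out[[paste0(col, "_err")]] <- abs(a - b) / 2
  }
  if (!is.null(categories))
    out$category <- if (!is.null(names(categories)))
      unname(categories[out$channel]) else unname(categories)
  out
}

#' Frame-shuffle significance test for the descriptors
#'
#' Destroys all temporal correlations by randomly permuting entire frames
#' (all channels together, preserving instantaneous cross-correlations),
#' recomputes the per-category mean descriptors for each of `n_shuffles`
#' independent permutations, checks the normality of the null ensemble
#' (Shapiro-Wilk), and reports a two-sided Student-t probability that the
#' observed category mean belongs to the null ensemble:
#' \deqn{t = \frac{\bar G_{obs} - \bar G_{null}}{s_{null}\sqrt{1 + 1/n}}, \quad df = n - 1.}
#' The `sqrt(1 + 1/n)` factor is the prediction-interval scaling for a
#' single new draw; without it the p-values would shrink spuriously with
#' growing `n_shuffles`. Because the permutations reuse the observed
#' sample, the test is mildly conservative under a true null.
#'
#' @inheritParams gc_matrix
#' @param n_shuffles number of independent frame permutations (>= 20; fewer
#'   give an underpowered null and are rejected).
#' @param categories named character vector of per-channel categories.
#' @param seed integer seed controlling the permutations.
#' @return data.frame with one row per category x descriptor: observed and
#'   null statistics, the Shapiro-Wilk normality p-value, and the two-sided
#'   `p_value`.
#' @export
shuffle_null_test <- function(series, order, n_shuffles = 50L,
                              categories = NULL, seed = 1L) {
  stopifnot(inherits(series, "channel_series"))
  n_shuffles <- as.integer(n_shuffles)
  if (n_shuffles < 20L)
    stop("n_shuffles must be >= 20 (underpowered null otherwise)")
  if (is.null(categories))
    categories <- stats::setNames(rep("all", n_channels(series)),
                                  series$labels)
  if (is.null(names(categories))) names(categories) <- series$labels
  norm <- normalize_channels(series)
  desc_cols <- c("g_in", "g_out", "g_origin", "g_total")
  cat_means <- function(desc) {
    cats <- unname(categories[desc$channel])
    sapply(desc_cols, function(col)
      tapply(desc[[col]], cats, mean))
  }
  obs <- cat_means(gc_descriptors(gc_matrix(norm, order)))
  if (is.null(dim(obs)))  # single category collapses to a vector
    obs <- matrix(obs, nrow = 1L,
                  dimnames = list(unique(unname(categories)), desc_cols))
  rs <- local_rng(seed)
  Tn <- n_frames(norm)
  null_arr <- array(NA_real_, c(n_shuffles, nrow(obs), length(desc_cols)),
                    dimnames = list(NULL, rownames(obs), desc_cols))
  for (s in seq_len(n_shuffles)) {
    perm <- rs$perm(Tn)
    shuffled <- channel_series(norm$values[perm, , drop = FALSE],
                               norm$labels, norm$dt)
    m <- cat_means(gc_descriptors(gc_matrix(shuffled, order)))
    if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
    null_arr[s, , ] <- m
  }
  res <- expand.grid(category = rownames(obs), descriptor = desc_cols,
                     stringsAsFactors = FALSE)
  res$observed <- res$null_mean <- res$null_sd <- res$shapiro_p <-
    res$p_value <- NA_real_
  for (r in seq_len(nrow(res))) {
    nul <- null_arr[, res$category[r], res$descriptor[r]]
    ob <- obs[res$category[r], res$descriptor[r]]
    sw <- tryCatch(stats::shapiro.test(nul)$p.value,
                   error = function(e) NA_real_)
    if (!is.na(sw) && sw < 0.01)
      warning("null ensemble for ", res$category[r], "/", res$descriptor[r],
              " deviates from normality (Shapiro-Wilk p = ", signif(sw, 3),
              "); t test proceeds regardless")
    tstat <- (ob - mean(nul)) / (stats::sd(nul) * sqrt(1 + 1 / n_shuffles))
    res$observed[r] <- ob
    res$null_mean[r] <- mean(nul)
    res$null_sd[r] <- stats::sd(nul)
    res$shapiro_p[r] <- sw
    res$p_value[r] <- 2 * stats::pt(-abs(tstat), df = n_shuffles - 1L)
  }
  res
}

#' Write a Granger matrix or descriptor table as delimited text
#'
#' @param x a `gc_matrix` or a descriptor data.frame.
#' @param path output path.
#' @export
write_gc <- function(x, path) {
  if (inherits(x, "gc_matrix")) {
    utils::write.table(x$J, path, sep = "\t", quote = FALSE,
                       row.names = TRUE, col.names = NA)
  } else {
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
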