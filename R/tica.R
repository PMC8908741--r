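#' Time-lagged independent component analysis
#'
#' Estimates the mean-free instantaneous covariance \eqn{C_0} and the
#' symmetrized time-lagged covariance \eqn{C_\tau} (average of forward and
#' backward lagged products, guaranteeing real eigenvalues as for a
#' reversible-dynamics estimator) and solves the generalized eigenproblem
#' \eqn{C_\tau v = \lambda C_0 v}. Components are sorted by descending
#' eigenvalue; the dominant independent component is the slowest linear
#' collective coordinate and the usual reaction-coordinate candidate. With
#' `kinetic_map = TRUE` projections are scaled by their eigenvalues (the
#' kinetic mapping weighting scheme), making Euclidean distances in
#' projection space approximate kinetic distances.
#'
#' @param features a `feature_set` from [backbone_features()], a
#'   [channel_series], or a plain numeric matrix (frames x features).
#' @param lag_frames positive lag time in frames.
#' @param kinetic_map scale projections by eigenvalues (default `TRUE`).
#' @return An object of class `tica_model`: `lag`, `means`, `eigenvalues`
#'   (descending), `components` (D x D, columns are C0-orthonormal
#'   generalized eigenvectors), `kinetic_map`, `labels`.
#' @export
fit_tica <- function(features, lag_frames, kinetic_map = TRUE) {
  X <- feature_matrix(features)
  lag_frames <- as.integer(lag_frames)
  if (lag_frames < 1L) stop("lag_frames must be a positive integer")
  Tn <- nrow(X)
  D <- ncol(X)
  if (Tn <= lag_frames + D)
    stop("too few frames: need T > lag + D (T = ", Tn, ", lag = ",
         lag_frames, ", D = ", D, ")")
  means <- colMeans(X)
  Xc <- sweep(X, 2L, means, "-")
  X0 <- Xc[1:(Tn - lag_frames), , drop = FALSE]
  X1 <- Xc[(lag_frames + 1L):Tn, , drop = FALSE]
  n <- nrow(X0)
  C0 <- (crossprod(X0) + crossprod(X1)) / (2 * n)
  Ct <- (crossprod(X0, X1) + crossprod(X1, X0)) / (2 * n)
  e0 <- eigen(C0, symmetric = TRUE)
  tol <- max(e0$values) * 1e-10
  if (any(e0$values < tol)) {
    null_dirs <- e0$vectors[, e0$values < tol, drop = FALSE]
    offenders <- unique(unlist(lapply(seq_len(ncol(null_dirs)), function(k) {
      w <- abs(null_dirs[, k])
      colnames(X)[w > 0.5 * max(w)]
    })))
    stop("rank-deficient instantaneous covariance (constant or collinear ",
         "features): ", paste(offenders, collapse = ", "))
  }
  W <- e0$vectors %*% diag(1 / sqrt(e0$values), D)  # C0 whitener
  M <- t(W) %*% Ct %*% W
  M <- (M + t(M)) / 2
  ee <- eigen(M, symmetric = TRUE)
  comps <- W %*% ee$vectors
  # deterministic sign: largest-|loading| entry of each component positive
  for (k in seq_len(D)) {
    i <- which.max(abs(comps[, k]))
    if (comps[i, k] < 0) comps[, k] <- -comps[, k]
  }
  rownames(comps) <- colnames(X)
  structure(list(lag = lag_frames, means = means,
                 eigenvalues = ee$values, components = comps,
                 kinetic_map = isTRUE(kinetic_map), labels = colnames(X)),
            class = "tica_model")
}

feature_matrix <- function(features) {
  X <- if (inherits(features, "feature_set") ||
           inherits(features, "channel_series")) features$values
       else as.matrix(features)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  X
}

#' @export
print.tica_model <- function(x, ...) {
  cat(sprintf("tica_model: %d features, lag %d frames, kinetic map %s\n",
              length(x$means), x$lag, if (x$kinetic_map) "on" else "off"))
  cat("  leading eigenvalues:",
      paste(signif(utils::head(x$eigenvalues, 5), 4), collapse = ", "), "\n")
  invisible(x)
}

#' Project data onto TICA components
#'
#' @param model a `tica_model`.
#' @param features data with the same feature layout used for fitting.
#' @param n_components number of leading components to return (default all).
#' @return numeric matrix of projections (frames x components); with a
#'   kinetic-map model each column is scaled by its eigenvalue.
#' @export
project_tica <- function(model, features, n_components = NULL) {
  stopifnot(inherits(model, "tica_model"))
  X <- feature_matrix(features)
  if (ncol(X) != length(model$means))
    stop("feature dimension mismatch with the fitted model")
  if (is.null(n_components)) n_components <- ncol(model$components)
  Xc <- sweep(X, 2L, model$means, "-")
  Y <- Xc %*% model$components[, seq_len(n_components), drop = FALSE]
  if (model$kinetic_map)
    Y <- sweep(Y, 2L, model$eigenvalues[seq_len(n_components)], "*")
  colnames(Y) <- paste0("IC", seq_len(n_components))
  Y
}

#' Serialize / deserialize a TICA model as JSON
#'
#' @param model a `tica_model`.
#' @param path file path.
#' @export
write_tica <- function(model, path) {
  stopifnot(inherits(model, "tica_model"))
  obj <- list(lag = model$lag, means = unname(model$means),
              eigenvalues = model$eigenvalues,
              components = unname(as.matrix(model$components)),
              kinetic_map = model$kinetic_map, labels = model$labels)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_tica
#' @export
read_tica <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  comps <- as.matrix(obj$components)
  rownames(comps) <- obj$labels
  structure(list(lag = as.integer(obj$lag),
                 means = stats::setNames(obj$means, obj$labels),
                 eigenvalues = obj$eigenvalues, components = comps,
                 kinetic_map = isTRUE(obj$kinetic_map), labels = obj$labels),
            class = "tica_model")
}
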