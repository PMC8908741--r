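#' Pairwise RMSD matrix of trajectory frames
#'
#' All-against-all RMSD (nm) after optimal superposition, via \pkg{bio3d}.
#'
#' @param traj an `md_trajectory`.
#' @param heavy_only use heavy atoms only (default `TRUE`).
#' @param fit superpose before measuring (default `TRUE`).
#' @return symmetric numeric matrix (frames x frames).
#' @export
rmsd_matrix <- function(traj, heavy_only = TRUE, fit = TRUE) {
  stopifnot(inherits(traj, "md_trajectory"))
  sel <- if (heavy_only) heavy_atom_idx(traj) else seq_len(nrow(traj$atoms))
  xi <- bio3d::atom2xyz(sel)
  Tn <- traj_n_frames(traj)
  d <- matrix(0, Tn, Tn)
  for (i in seq_len(Tn))
    d[i, ] <- as.numeric(bio3d::rmsd(traj$xyz[i, ], traj$xyz,
                                     a.inds = xi, b.inds = xi, fit = fit))
  (d + t(d)) / 2
}

#' Gromos (Daura) clustering
#'
#' Greedy neighbour clustering: the frame with the most neighbours within
#' `cutoff` becomes a cluster center; it and its neighbours are removed and
#' the procedure repeats on the remainder. Ties in neighbour count break
#' toward the lowest frame index. The representative reference geometry is
#' the center of the largest cluster (size ties break toward the cluster
#' whose center has the lowest index).
#'
#' @param d symmetric pairwise distance matrix (e.g. from [rmsd_matrix()]).
#' @param cutoff neighbour cutoff in the same units as `d` (> 0).
#' @return list with `clusters` (list of member index vectors, in extraction
#'   order), `centers` (center index per cluster), `sizes`, and `reference`
#'   (center of the largest cluster).
#' @export
gromos_cluster <- function(d, cutoff) {
  d <- as.matrix(d)
  if (cutoff <= 0) stop("cutoff must be > 0")
  n <- nrow(d)
  if (n < 1L) stop("need at least one frame")
  alive <- rep(TRUE, n)
  clusters <- list(); centers <- integer(0)
  while (any(alive)) {
    idx <- which(alive)
    counts <- rowSums(d[idx, idx, drop = FALSE] <= cutoff)
    center <- idx[which.max(counts)]           # first max = lowest index
    members <- idx[d[center, idx] <= cutoff]
    clusters[[length(clusters) + 1L]] <- members
    centers <- c(centers, center)
    alive[members] <- FALSE
  }
  sizes <- lengths(clusters)
  best <- which(sizes == max(sizes))
  best <- best[which.min(centers[best])]
  list(clusters = clusters, centers = centers, sizes = sizes,
       reference = centers[best])
}
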