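#' Inter-residue minimum heavy-atom distances
#'
#' One channel per unordered residue pair (i < j), including covalently
#' adjacent neighbours: the per-frame value is the minimum over all pairs of
#' heavy atoms (one from each residue) of their Euclidean distance, in nm.
#' Neighbour channels are kept deliberately — in real peptides they carry
#' (nearly constant, near-zero-scoring) contact signal and the 45-channel
#' count of a 10-residue hairpin includes them. Channel labels follow
#' `R{i}{name}-R{j}{name}` with i < j.
#'
#' @param traj an `md_trajectory`.
#' @param heavy_atoms_only if `TRUE` (default) hydrogens are excluded from
#'   the atom sets.
#' @return A [channel_series] with `n (n - 1) / 2` channels.
#' @export
residue_min_distances <- function(traj, heavy_atoms_only = TRUE) {
  stopifnot(inherits(traj, "md_trajectory"))
  at <- traj$atoms
  resnos <- sort(unique(at$resno))
  n <- length(resnos)
  if (n < 2L) stop("need at least 2 residues")
  sel <- if (heavy_atoms_only) at$elem != "H" else rep(TRUE, nrow(at))
  idx <- lapply(resnos, function(r) which(sel & at$resno == r))
  empty <- lengths(idx) == 0L
  if (any(empty))
    stop("residue(s) with no heavy atoms: ",
         paste(resnos[empty], collapse = ", "))
  resname <- vapply(resnos, function(r) at$resid[at$resno == r][1L],
                    character(1))
  pairs <- utils::combn(n, 2L)
  labels <- sprintf("R%d%s-R%d%s",
                    resnos[pairs[1L, ]], resname[pairs[1L, ]],
                    resnos[pairs[2L, ]], resname[pairs[2L, ]])
  Tn <- traj_n_frames(traj)
  out <- matrix(NA_real_, Tn, ncol(pairs))
  for (f in seq_len(Tn)) {
    co <- frame_coords(traj, f)
    for (k in seq_len(ncol(pairs))) {
      A <- co[idx[[pairs[1L, k]]], , drop = FALSE]
      B <- co[idx[[pairs[2L, k]]], , drop = FALSE]
      d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
      out[f, k] <- sqrt(max(min(d2), 0))
    }
  }
  channel_series(out, labels, traj$dt)
}

#' Geometric hydrogen-bond detection
#'
#' A bond is present in a frame iff the donor-acceptor distance is at most
#' `dist_cutoff` (0.32 nm) and the D-H...A angle lies in `angle_range`
#' ([130, 180] degrees). The angle is measured at the hydrogen by default
#' (the standard geometric criterion); `angle_at = "donor"` measures it at
#' the donor instead. Donor-hydrogen pairing is resolved from topology: each
#' hydrogen is assigned the nearest heavy atom within 0.125 nm in the first
#' frame; hydrogens with no such atom are skipped with a warning. Acceptors
#' are all oxygen atoms; same-residue donor-acceptor pairs are excluded.
#'
#' @param traj an `md_trajectory` containing hydrogens.
#' @param dist_cutoff donor-acceptor distance cutoff in nm.
#' @param angle_range permitted D-H...A angle interval in degrees.
#' @param angle_at `"hydrogen"` (default) or `"donor"`.
#' @return list with `indicators` (T x n_bonds 0/1 matrix), `labels`, and
#'   `pairs` (data.frame of donor/hydrogen/acceptor atom indices).
#' @export
detect_hbonds <- function(traj, dist_cutoff = 0.32,
                          angle_range = c(130, 180),
                          angle_at = c("hydrogen", "donor")) {
  stopifnot(inherits(traj, "md_trajectory"))
  angle_at <- match.arg(angle_at)
  at <- traj$atoms
  hyd <- which(at$elem == "H")
  if (!length(hyd)) stop("no hydrogen atoms in topology")
  co1 <- frame_coords(traj, 1L)
  heavy <- which(at$elem != "H")
  donors <- hydrogens <- integer(0)
  for (h in hyd) {
    d2 <- rowSums(sweep(co1[heavy, , drop = FALSE], 2L, co1[h, ], "-")^2)
    j <- which.min(d2)
    if (sqrt(d2[j]) > 0.125) {
      warning("hydrogen atom ", h, " has no bonded donor within 0.125 nm; skipped")
      next
    }
    donors <- c(donors, heavy[j])
    hydrogens <- c(hydrogens, h)
  }
  acceptors <- which(at$elem == "O")
  pairs <- expand.grid(k = seq_along(donors), a = acceptors)
  pairs <- data.frame(donor = donors[pairs$k], hydrogen = hydrogens[pairs$k],
                      acceptor = pairs$a)
  pairs <- pairs[at$resno[pairs$donor] != at$resno[pairs$acceptor], ,
                 drop = FALSE]
  if (!nrow(pairs)) stop("no donor-acceptor pairs across residues")
  labels <- sprintf("R%d:%s-%s...R%d:%s",
                    at$resno[pairs$donor], at$elety[pairs$donor],
                    at$elety[pairs$hydrogen],
                    at$resno[pairs$acceptor], at$elety[pairs$acceptor])
  Tn <- traj_n_frames(traj)
  ind <- matrix(0, Tn, nrow(pairs))
  for (f in seq_len(Tn)) {
    co <- frame_coords(traj, f)
    D <- co[pairs$donor, , drop = FALSE]
    H <- co[pairs$hydrogen, , drop = FALSE]
    A <- co[pairs$acceptor, , drop = FALSE]
    da <- sqrt(rowSums((D - A)^2))
    if (angle_at == "hydrogen") {
      v1 <- D - H; v2 <- A - H
    } else {
      v1 <- H - D; v2 <- A - D
    }
    cosang <- rowSums(v1 * v2) /
      (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
    ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
    ind[f, ] <- as.numeric(da <= dist_cutoff &
                             ang >= angle_range[1] & ang <= angle_range[2])
  }
  colnames(ind) <- labels
  list(indicators = ind, labels = labels, pairs = pairs)
}

#' Per-state hydrogen-bond fractions
#'
#' Computes, for each bond and each discrete state, the fraction of the
#' state's frames in which the bond is present, and flags fractions below
#' the reporting threshold (bonds formed in fewer than 5% of a state's
#' frames are conventionally not shown).
#'
#' @param hbonds result of [detect_hbonds()].
#' @param state_labels integer per-frame state labels.
#' @param threshold reporting threshold (default 0.05).
#' @return data.frame with columns `bond`, `state`, `fraction`,
#'   `below_threshold`.
#' @export
hbond_state_fractions <- function(hbonds, state_labels, threshold = 0.05) {
  if (length(state_labels) != nrow(hbonds$indicators))
    stop("state_labels length must match the number of frames")
  states <- sort(unique(state_labels))
  out <- do.call(rbind, lapply(states, function(s) {
    frac <- colMeans(hbonds$indicators[state_labels == s, , drop = FALSE])
    data.frame(bond = hbonds$labels, state = s, fraction = as.numeric(frac))
  }))
  out$below_threshold <- out$fraction < threshold
  rownames(out) <- NULL
  out
}

# Signed dihedral (degrees) from four T x 3 coordinate matrices.
dihedral_deg <- function(p1, p2, p3, p4) {
  cross3 <- function(a, b)
    cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
          a[, 3] * b[, 1] - a[, 1] * b[, 3],
          a[, 1] * b[, 2] - a[, 2] * b[, 1])
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  b2n <- b2 / sqrt(rowSums(b2^2))
  m1 <- cross3(n1, b2n)
  atan2(rowSums(m1 * n2), rowSums(n1 * n2)) * 180 / pi
}

#' RMSD and backbone-dihedral features
#'
#' Builds the feature set used for reaction-coordinate construction:
#' column 1 is the heavy-atom RMSD (nm) to the reference after optimal
#' least-squares (Kabsch) superposition, followed by the sine and cosine of
#' every defined backbone phi (residues 2..n) and psi (residues 1..n-1)
#' dihedral. Feature count is `1 + 4 (n - 1)` (37 for a 10-residue peptide).
#'
#' @param traj an `md_trajectory`.
#' @param reference an `md_trajectory` with identical topology whose first
#'   frame is the reference structure.
#' @param heavy_only use heavy atoms only for the RMSD (default `TRUE`).
#' @return An object of class `feature_set`: list with `values` (T x D
#'   matrix) and `labels`.
#' @export
backbone_features <- function(traj, reference, heavy_only = TRUE) {
  stopifnot(inherits(traj, "md_trajectory"),
            inherits(reference, "md_trajectory"))
  if (!identical(traj$atoms$elety, reference$atoms$elety) ||
      !identical(traj$atoms$resno, reference$atoms$resno))
    stop("reference topology does not match the trajectory")
  at <- traj$atoms
  sel <- if (heavy_only) which(at$elem != "H") else seq_len(nrow(at))
  xi <- bio3d::atom2xyz(sel)
  rms <- as.numeric(bio3d::rmsd(reference$xyz[1L, ], traj$xyz,
                                a.inds = xi, b.inds = xi, fit = TRUE))
  resnos <- sort(unique(at$resno))
  n <- length(resnos)
  pick <- function(name, r) {
    i <- which(at$elety == name & at$resno == r)
    if (length(i) != 1L)
      stop("expected exactly one ", name, " atom in residue ", r)
    i
  }
  coord <- function(i) {
    m <- traj$xyz[, bio3d::atom2xyz(i), drop = FALSE]
    if (traj_n_frames(traj) == 1L) m <- matrix(m, nrow = 1L)
    m
  }
  vals <- list(rmsd = rms)
  labels <- "rmsd"
  for (r in resnos[-1L]) {  # phi: C(r-1) - N(r) - CA(r) - C(r)
    phi <- dihedral_deg(coord(pick("C", r - 1L)), coord(pick("N", r)),
                        coord(pick("CA", r)), coord(pick("C", r))) * pi / 180
    vals[[paste0("phi", r, "_sin")]] <- sin(phi)
    vals[[paste0("phi", r, "_cos")]] <- cos(phi)
    labels <- c(labels, paste0("phi", r, c("_sin", "_cos")))
  }
  for (r in resnos[-n]) {  # psi: N(r) - CA(r) - C(r) - N(r+1)
    psi <- dihedral_deg(coord(pick("N", r)), coord(pick("CA", r)),
                        coord(pick("C", r)), coord(pick("N", r + 1L))) * pi / 180
    vals[[paste0("psi", r, "_sin")]] <- sin(psi)
    vals[[paste0("psi", r, "_cos")]] <- cos(psi)
    labels <- c(labels, paste0("psi", r, c("_sin", "_cos")))
  }
  values <- do.call(cbind, vals)
  colnames(values) <- labels
  structure(list(values = values, labels = labels), class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("feature_set: %d frames x %d features\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}
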