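#' Specification of a miniature test structure
#'
#' A tiny polypeptide-like chain used to exercise geometric featurization:
#' each residue carries the named backbone set (N, H, CA, C, O) plus one
#' sidechain heavy atom (CB). Frames share a fixed topology. The generated
#' trajectory always contains, after the reference and noise frames, three
#' planted frames probing the hydrogen-bond criteria: a textbook geometry
#' (donor-acceptor 0.29 nm, D-H...A angle 165 deg), one violating only the
#' distance criterion (0.35 nm), and one violating only the angle criterion
#' (120 deg).
#'
#' @param n_residues number of residues (>= 2).
#' @param n_noise_frames number of randomly perturbed frames after the
#'   reference frame (default 3).
#' @param noise_sd per-coordinate perturbation SD in nm (default 0.005).
#' @param seed integer RNG seed.
#' @return An object of class `mini_structure_spec`.
#' @export
mini_structure_spec <- function(n_residues, n_noise_frames = 3L,
                                noise_sd = 0.005, seed = 1L) {
  n_residues <- as.integer(n_residues)
  if (n_residues < 2L) stop("n_residues must be >= 2")
  structure(list(n_residues = n_residues,
                 n_noise_frames = as.integer(n_noise_frames),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "mini_structure_spec")
}

# Idealized-ish toy geometry, nm. Residues spaced 0.42 nm along x with a
# small alternating y offset and out-of-plane z shifts so that no backbone
# dihedral is degenerate.
mini_base_coords <- function(n_residues) {
  per_res <- rbind(N  = c(0.00,  0.00,  0.00),
                   H  = c(-0.06, 0.08,  0.00),
                   CA = c(0.15,  0.05,  0.02),
                   C  = c(0.25, -0.05,  0.05),
                   O  = c(0.25, -0.26,  0.06),
                   CB = c(0.16,  0.16, -0.08))
  coords <- NULL
  atoms <- NULL
  for (r in seq_len(n_residues)) {
    base <- c(0.42 * (r - 1), 0.03 * (-1)^r, 0)
    coords <- rbind(coords, sweep(per_res, 2L, base, "+"))
    atoms <- rbind(atoms,
                   data.frame(elety = rownames(per_res),
                              resno = r, resid = "ALA",
                              elem = substr(rownames(per_res), 1L, 1L),
                              stringsAsFactors = FALSE))
  }
  rownames(coords) <- NULL
  list(coords = coords, atoms = atoms)
}

# Place an acceptor at distance `dist_nm` from donor D such that the
# D-H...A angle at the hydrogen equals `angle_deg`.
place_acceptor <- function(D, H, dist_nm, angle_deg) {
  u <- (D - H) / sqrt(sum((D - H)^2))          # H -> D direction
  w <- c(-u[2], u[1], 0)
  if (sum(w^2) < 1e-12) w <- c(1, 0, 0)
  w <- w / sqrt(sum(w^2))
  d <- sqrt(sum((D - H)^2))
  a <- (180 - angle_deg) * pi / 180
  rho <- -d * cos(a) + sqrt(d^2 * cos(a)^2 - d^2 + dist_nm^2)
  H + rho * (-cos(a) * u + sin(a) * w)
}

#' Generate a miniature multi-model trajectory
#'
#' Builds the frames described in [mini_structure_spec()]: the unperturbed
#' reference, `n_noise_frames` seeded Gaussian perturbations of it, and the
#' three hydrogen-bond probe frames, in which the carbonyl O of the last
#' residue is repositioned relative to the N-H of residue 1.
#'
#' @param spec a [mini_structure_spec].
#' @param path optional path; if given the multi-model PDB text is written
#'   there.
#' @return list with `trajectory` (an [as_md_trajectory()] object),
#'   `pdb_lines` (the multi-model PDB content), and `probe_frames` (named
#'   indices of the planted frames: `hbond`, `far`, `bent`).
#' @export
generate_mini_trajectory <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "mini_structure_spec"))
  base <- mini_base_coords(spec$n_residues)
  co <- base$coords
  at <- base$atoms
  rs <- local_rng(spec$seed)
  frames <- list(co)
  for (i in seq_len(spec$n_noise_frames))
    frames[[length(frames) + 1L]] <-
      co + matrix(rs$norm_vec(length(co)), nrow(co), 3L) * spec$noise_sd
  D <- co[at$elety == "N" & at$resno == 1L, ]
  H <- co[at$elety == "H" & at$resno == 1L, ]
  o_last <- which(at$elety == "O" & at$resno == spec$n_residues)
  probe <- function(dist_nm, angle_deg) {
    f <- co
    f[o_last, ] <- place_acceptor(D, H, dist_nm, angle_deg)
    f
  }
  frames[[length(frames) + 1L]] <- probe(0.29, 165)  # textbook H-bond
  frames[[length(frames) + 1L]] <- probe(0.35, 165)  # too far
  frames[[length(frames) + 1L]] <- probe(0.29, 120)  # too bent
  probe_frames <- c(hbond = length(frames) - 2L,
                    far = length(frames) - 1L,
                    bent = length(frames))
  xyz <- do.call(rbind, lapply(frames, function(f) as.vector(t(f))))
  traj <- as_md_trajectory(xyz, at, dt = 1)
  lines <- write_multimodel_pdb(traj, path)
  list(trajectory = traj, pdb_lines = lines, probe_frames = probe_frames)
}
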