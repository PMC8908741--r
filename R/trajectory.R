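#' Coordinate trajectory container and adapter contract
#'
#' A fixed-topology multi-frame coordinate trajectory. This constructor is
#' the documented adapter contract for plugging in readers of other formats:
#' any reader that can produce (a) a T x 3N coordinate matrix in nanometres
#' laid out `x1 y1 z1 x2 y2 z2 ...` (one row per frame) and (b) an atom
#' table with columns `elety` (atom name), `resno` (residue number), `resid`
#' (residue name) and optionally `elem` (element symbol) can feed the
#' featurization stage.
#'
#' @param xyz numeric T x 3N matrix of coordinates in nm (a single frame may
#'   be given as a length-3N vector).
#' @param atoms data.frame with columns `elety`, `resno`, `resid`, and
#'   optionally `elem`. If `elem` is missing it is derived from `elety`
#'   (leading digits stripped, first character).
#' @param dt frame stride in ns.
#' @return An object of class `md_trajectory`.
#' @export
as_md_trajectory <- function(xyz, atoms, dt = 1) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  atoms <- as.data.frame(atoms)
  req <- c("elety", "resno", "resid")
  if (!all(req %in% names(atoms)))
    stop("atom table must have columns: ", paste(req, collapse = ", "))
  if (ncol(xyz) != 3L * nrow(atoms))
    stop("xyz has ", ncol(xyz), " columns; expected 3 x ", nrow(atoms),
         " for the ", nrow(atoms), "-atom topology")
  if (anyNA(xyz)) stop("coordinates must not contain missing values")
  if (is.null(atoms$elem))
    atoms$elem <- substr(sub("^[0-9]+", "", atoms$elety), 1L, 1L)
  structure(list(xyz = xyz, atoms = atoms, dt = as.numeric(dt)),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("md_trajectory: %d frame(s), %d atoms, %d residues, dt = %g ns\n",
              nrow(x$xyz), nrow(x$atoms), length(unique(x$atoms$resno)), x$dt))
  invisible(x)
}

traj_n_frames <- function(traj) nrow(traj$xyz)

# N x 3 coordinate matrix of one frame.
frame_coords <- function(traj, frame) {
  matrix(traj$xyz[frame, ], ncol = 3L, byrow = TRUE)
}

heavy_atom_idx <- function(traj) which(traj$atoms$elem != "H")

#' Read a multi-model PDB file as a trajectory
#'
#' Parses MODEL/ENDMDL frames via \pkg{bio3d} and converts coordinates from
#' Angstrom to nm. The topology (atom naming, residue numbering) of the
#' first model is used for all frames; bio3d enforces the fixed-topology
#' requirement while reading.
#'
#' @param path PDB file path.
#' @param dt frame stride in ns.
#' @return An [as_md_trajectory()] object.
#' @export
read_pdb_trajectory <- function(path, dt = 1) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(as.numeric(xyz), nrow = 1L)
  atoms <- data.frame(elety = pdb$atom$elety,
                      resno = pdb$atom$resno,
                      resid = pdb$atom$resid,
                      stringsAsFactors = FALSE)
  if (!is.null(pdb$atom$elesy) && !all(is.na(pdb$atom$elesy)) &&
      !all(trimws(pdb$atom$elesy) == ""))
    atoms$elem <- trimws(pdb$atom$elesy)
  as_md_trajectory(unclass(xyz) / 10, atoms, dt)
}

#' Write a trajectory as multi-model PDB text
#'
#' Emits standard MODEL/ENDMDL records with PDB v3 fixed-column ATOM lines;
#' coordinates are converted from nm to Angstrom.
#'
#' @param traj an `md_trajectory`.
#' @param path optional output path; if `NULL` the text is returned
#'   invisibly as a character vector of lines.
#' @return The PDB lines, invisibly.
#' @export
write_multimodel_pdb <- function(traj, path = NULL) {
  stopifnot(inherits(traj, "md_trajectory"))
  at <- traj$atoms
  name4 <- ifelse(nchar(at$elety) >= 4L, substr(at$elety, 1L, 4L),
                  sprintf(" %-3s", at$elety))
  lines <- character(0)
  for (f in seq_len(traj_n_frames(traj))) {
    co <- frame_coords(traj, f) * 10  # nm -> Angstrom
    rec <- sprintf("ATOM  %5d %s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   seq_len(nrow(at)), name4, at$resid, "A", at$resno,
                   co[, 1], co[, 2], co[, 3], 1, 0, at$elem)
    lines <- c(lines, sprintf("MODEL     %4d", f), rec, "ENDMDL")
  }
  lines <- c(lines, "END")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
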