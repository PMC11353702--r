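# Trajectory container, readers (multi-model PDB, DCD, text fixture) and
# writers (fixture, single-frame PDB snapshot).

#' Construct a Trajectory
#'
#' @param coords numeric array `n_frames x n_atoms x 3` of coordinates
#'   (Angstrom).
#' @param box per-frame orthorhombic box lengths: length-3 vector (constant
#'   box) or `n_frames x 3` matrix (Angstrom).
#' @param dt time between frames (ns).
#' @param t0 time of the first frame (ns).
#' @return object of class `Trajectory`.
#' @export
new_trajectory <- function(coords, box, dt = 1, t0 = 0) {
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  n_frames <- dim(coords)[1]
  if (is.null(dim(box))) box <- matrix(as.numeric(box), nrow = n_frames,
                                       ncol = 3L, byrow = TRUE)
  box <- as.matrix(box)
  stopifnot(nrow(box) == n_frames, ncol(box) == 3L)
  if (!all(box > 0)) stop("box lengths must be > 0")
  if (!(dt > 0)) stop("dt must be > 0")
  structure(list(coords = coords, box = box, n_frames = n_frames,
                 n_atoms = dim(coords)[2], dt = dt, t0 = t0),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat("Trajectory:", x$n_frames, "frames x", x$n_atoms, "atoms, dt =",
      x$dt, "ns, span", x$t0, "-", x$t0 + (x$n_frames - 1) * x$dt, "ns\n")
  invisible(x)
}

#' Frame times of a trajectory (ns)
#' @param traj a [new_trajectory()] object.
#' @export
frame_times <- function(traj) traj$t0 + (seq_len(traj$n_frames) - 1) * traj$dt

# ---------------------------------------------------------------------------
# Text fixture format: self-describing, line oriented.
#   # solvshell-trajectory v1
#   natoms <n>
#   nframes <f>
#   dt <ns>
#   t0 <ns>
#   frame <i>
#   box <bx> <by> <bz>
#   <x> <y> <z>          (natoms lines)
# ---------------------------------------------------------------------------

#' Write a trajectory in the plain-text fixture format
#'
#' @param traj a [new_trajectory()] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_fixture <- function(traj, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("# solvshell-trajectory v1",
               paste("natoms", traj$n_atoms),
               paste("nframes", traj$n_frames),
               paste("dt", format(traj$dt, digits = 17)),
               paste("t0", format(traj$t0, digits = 17))), con)
  for (f in seq_len(traj$n_frames)) {
    writeLines(paste("frame", f), con)
    writeLines(paste("box",
                     paste(sprintf("%.6f", traj$box[f, ]), collapse = " ")),
               con)
    xyz <- traj$coords[f, , , drop = FALSE]
    writeLines(sprintf("%.6f %.6f %.6f", xyz[1, , 1], xyz[1, , 2],
                       xyz[1, , 3]), con)
  }
  invisible(path)
}

.read_fixture <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!grepl("^# solvshell-trajectory", lines[1]))
    stop("not a solvshell trajectory fixture: ", path)
  kv <- function(key) {
    ln <- grep(paste0("^", key, " "), lines[2:5], value = TRUE)
    if (!length(ln)) stop("fixture missing header field '", key, "'")
    as.numeric(strsplit(ln[1], " +")[[1]][2])
  }
  n_atoms <- as.integer(kv("natoms")); n_frames <- as.integer(kv("nframes"))
  dt <- kv("dt"); t0 <- kv("t0")
  body <- lines[-(1:5)]
  per_frame <- n_atoms + 2L
  if (length(body) != n_frames * per_frame)
    stop("fixture body length inconsistent with header")
  coords <- array(NA_real_, dim = c(n_frames, n_atoms, 3L))
  box <- matrix(NA_real_, n_frames, 3L)
  for (f in seq_len(n_frames)) {
    blk <- body[((f - 1L) * per_frame + 1L):(f * per_frame)]
    box[f, ] <- as.numeric(strsplit(blk[2], " +")[[1]][2:4])
    xyz <- matrix(scan(text = blk[-(1:2)], quiet = TRUE), ncol = 3L,
                  byrow = TRUE)
    coords[f, , ] <- xyz
  }
  new_trajectory(coords, box, dt = dt, t0 = t0)
}

.read_multimodel_pdb <- function(path, topology, dt, t0) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1L)
  n_atoms <- ncol(xyz) / 3L
  n_frames <- nrow(xyz)
  coords <- array(NA_real_, dim = c(n_frames, n_atoms, 3L))
  for (k in 1:3) coords[, , k] <- xyz[, seq(k, by = 3L,
                                            length.out = n_atoms),
                                      drop = FALSE]
  box <- .parse_cryst1(path)
  if (is.null(box)) box <- topology$box_hint
  if (is.null(box))
    stop("no box information: neither CRYST1 nor topology box_hint present")
  new_trajectory(coords, box, dt = dt, t0 = t0)
}

.read_dcd <- function(path, topology, dt, t0) {
  dcd <- bio3d::read.dcd(path, cell = FALSE, verbose = FALSE)
  cell <- tryCatch(bio3d::read.dcd(path, cell = TRUE, verbose = FALSE),
                   error = function(e) NULL)
  xyz <- if (is.matrix(dcd)) dcd else matrix(dcd, nrow = 1L)
  n_atoms <- ncol(xyz) / 3L
  n_frames <- nrow(xyz)
  coords <- array(NA_real_, dim = c(n_frames, n_atoms, 3L))
  for (k in 1:3) coords[, , k] <- xyz[, seq(k, by = 3L,
                                            length.out = n_atoms),
                                      drop = FALSE]
  if (!is.null(cell) && is.matrix(cell) && ncol(cell) >= 3L) {
    ang <- if (ncol(cell) >= 6L) cell[, 4:6, drop = FALSE] else NULL
    if (!is.null(ang) && any(abs(ang - 90) > 1e-3))
      stop("triclinic DCD cells are not supported")
    box <- cell[, 1:3, drop = FALSE]
  } else if (!is.null(topology$box_hint)) {
    box <- topology$box_hint
  } else {
    stop("DCD carries no unit cell and topology has no box_hint")
  }
  new_trajectory(coords, box, dt = dt, t0 = t0)
}

#' Read a coordinate trajectory
#'
#' Supported on-disk formats: multi-model PDB (`"pdb"`), CHARMM/NAMD binary
#' DCD (`"dcd"`, read via bio3d) and the package's plain-text fixture format
#' (`"fixture"`).  GROMACS XTC is recognised but not parsed by any installed
#' reader and raises an explicit error.  Coordinates are returned in
#' Angstrom; the per-frame box comes from the file where the format carries
#' one, else from the topology's `box_hint`.
#'
#' @param path trajectory file.
#' @param topology the matching [read_topology()] object (atom counts are
#'   cross-checked).
#' @param format one of `"pdb"`, `"dcd"`, `"fixture"`, `"xtc"`, or
#'   `"auto"` (by file extension).
#' @param dt,t0 frame spacing and first-frame time in ns (these formats do
#'   not carry a reliable time base).
#' @return a [new_trajectory()] object.
#' @export
read_trajectory <- function(path, topology, format = "auto", dt = 1, t0 = 0) {
  if (!file.exists(path)) stop("no such file: ", path)
  format <- match.arg(format, c("auto", "pdb", "dcd", "xtc", "fixture"))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", dcd = "dcd", xtc = "xtc", "fixture")
  }
  traj <- switch(format,
    pdb     = .read_multimodel_pdb(path, topology, dt, t0),
    dcd     = .read_dcd(path, topology, dt, t0),
    fixture = .read_fixture(path),
    xtc     = stop("XTC input is not supported; convert to DCD, ",
                   "multi-model PDB or the text fixture format"))
  if (!missing(topology) && !is.null(topology) &&
      traj$n_atoms != topology$n_atoms)
    stop("atom-count mismatch: trajectory has ", traj$n_atoms,
         " atoms, topology has ", topology$n_atoms)
  traj
}

#' Export one frame as a PDB snapshot
#'
#' @param traj a [new_trajectory()] object.
#' @param topology matching topology.
#' @param frame 1-based frame index.
#' @param path output PDB path.
#' @export
export_pdb_snapshot <- function(traj, topology, frame, path) {
  stopifnot(frame >= 1L, frame <= traj$n_frames)
  a <- topology$atoms
  xyz <- as.numeric(t(traj$coords[frame, , ]))
  bio3d::write.pdb(file = path, xyz = xyz, resno = a$residue_id,
                   resid = a$residue_name, eleno = a$atom_id + 1L,
                   elety = a$atom_name, chain = a$chain_id)
  invisible(path)
}
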