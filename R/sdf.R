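# Spatial distribution functions: 3-D number-density grids of a selection
# in the body-fixed frame of a reference residue, normalised to bulk,
# exported as OpenDX or Gaussian cube volumetric files.

BOHR_PER_ANGSTROM <- 1.8897259886

#' Define a residue-fixed local frame
#'
#' Three atoms define an orthonormal right-handed frame per trajectory
#' frame: the origin atom, an atom fixing the +x direction, and a third
#' atom fixing the xy plane (z is the plane normal).
#'
#' @param origin_atom,x_atom,plane_atom 1-based atom indices.
#' @return object of class `LocalFrameDef`.
#' @export
local_frame <- function(origin_atom, x_atom, plane_atom) {
  idx <- c(origin_atom, x_atom, plane_atom)
  stopifnot(length(idx) == 3L, !anyDuplicated(idx))
  structure(list(origin = origin_atom, x_atom = x_atom,
                 plane_atom = plane_atom), class = "LocalFrameDef")
}

#' Per-frame rigid transforms into a residue-fixed frame
#'
#' For each frame, builds the rotation matrix whose rows are the local
#' basis (ex toward the x atom, ez normal to the three-atom plane,
#' ey = ez x ex) and the local origin.  A point p maps to
#' `R (p - origin)`.
#'
#' @param traj a [new_trajectory()] object.
#' @param frame_def a [local_frame()] definition.
#' @return list with `rotations` (3 x 3 x n_frames) and `origins`
#'   (n_frames x 3).
#' @export
local_frame_transform <- function(traj, frame_def) {
  n <- traj$n_frames
  R <- array(NA_real_, dim = c(3L, 3L, n))
  O <- matrix(NA_real_, n, 3L)
  for (f in seq_len(n)) {
    box <- traj$box[f, ]
    o <- traj$coords[f, frame_def$origin, ]
    vx <- minimum_image_displacement(o, traj$coords[f, frame_def$x_atom, ],
                                     box)
    vp <- minimum_image_displacement(o, traj$coords[f, frame_def$plane_atom, ],
                                     box)
    ez <- c(vx[2] * vp[3] - vx[3] * vp[2],
            vx[3] * vp[1] - vx[1] * vp[3],
            vx[1] * vp[2] - vx[2] * vp[1])
    nz <- sqrt(sum(ez^2))
    if (nz < 1e-8 || sqrt(sum(vx^2)) < 1e-8)
      stop("collinear frame atoms at frame ", f)
    ex <- vx / sqrt(sum(vx^2)); ez <- ez / nz
    ey <- c(ez[2] * ex[3] - ez[3] * ex[2],
            ez[3] * ex[1] - ez[1] * ex[3],
            ez[1] * ex[2] - ez[2] * ex[1])
    R[, , f] <- rbind(ex, ey, ez)
    O[f, ] <- o
  }
  list(rotations = R, origins = O)
}

#' Accumulate a spatial distribution function
#'
#' Maps the selection positions of every frame through the residue-fixed
#' transform (periodic images folded relative to the frame origin first)
#' and bins them on a cubic grid of side `extent` centred on the local
#' origin.  `relative_density` is the voxel count rate divided by the bulk
#' number density of the selection (whole-box average), so bulk voxels
#' read 1.
#'
#' @param traj a [new_trajectory()] object.
#' @param frame_def a [local_frame()] definition.
#' @param sel 1-based atom indices of the binned species, non-empty.
#' @param extent cube side length (Angstrom), at most the smallest box
#'   length.
#' @param spacing isotropic voxel edge (Angstrom).
#' @return object of class `DensityGrid`: `origin` (local corner), `spacing`,
#'   `dims`, `counts` (3-D array), `relative_density`, `n_frames`,
#'   `rho_bulk`, and `isovalue_hint` metadata (10 for water, 3 for
#'   potassium, by convention).
#' @export
accumulate_sdf <- function(traj, frame_def, sel, extent = 12, spacing = 0.5) {
  if (!length(sel)) stop("empty selection")
  stopifnot(spacing > 0, extent <= min(traj$box))
  tf <- local_frame_transform(traj, frame_def)
  nvox <- as.integer(round(extent / spacing))
  half <- extent / 2
  counts <- array(0L, dim = rep(nvox, 3L))
  for (f in seq_len(traj$n_frames)) {
    box <- traj$box[f, ]
    P <- .wrap_relative(matrix(traj$coords[f, sel, ], ncol = 3L),
                        tf$origins[f, ], box)
    local <- P %*% t(tf$rotations[, , f])
    ix <- floor((local + half) / spacing) + 1
    keep <- ix[, 1] >= 1 & ix[, 1] <= nvox & ix[, 2] >= 1 &
            ix[, 2] <= nvox & ix[, 3] >= 1 & ix[, 3] <= nvox
    if (any(keep)) {
      ixk <- ix[keep, , drop = FALSE]
      lin <- (ixk[, 3] - 1) * nvox * nvox + (ixk[, 2] - 1) * nvox + ixk[, 1]
      tab <- tabulate(lin, nbins = nvox^3)
      counts <- counts + array(tab, dim = rep(nvox, 3L))
    }
  }
  rho_bulk <- length(sel) / mean(apply(traj$box, 1L, prod))
  rel <- counts / (spacing^3 * traj$n_frames * rho_bulk)
  structure(list(origin = rep(-half, 3L), spacing = spacing,
                 dims = rep(nvox, 3L), counts = counts,
                 relative_density = rel, n_frames = traj$n_frames,
                 rho_bulk = rho_bulk,
                 isovalue_hint = c(water = 10, potassium = 3)),
            class = "DensityGrid")
}

#' Export a density grid as OpenDX or Gaussian cube
#'
#' Values are written in the standard order of both formats (z varying
#' fastest).  Cube files use Bohr for lengths per the format definition.
#'
#' @param grid a [accumulate_sdf()] object.
#' @param path output file.
#' @param format `"dx"` or `"cube"`.
#' @param field which field to write: `"relative_density"` or `"counts"`.
#' @return `path`, invisibly.
#' @export
export_grid <- function(grid, path, format = c("dx", "cube"),
                        field = "relative_density") {
  format <- match.arg(format)
  vals <- grid[[field]]
  d <- grid$dims
  # both formats: x slowest, z fastest
  flat <- as.numeric(aperm(vals, c(3L, 2L, 1L)))
  con <- file(path, "wt"); on.exit(close(con))
  if (format == "dx") {
    writeLines(c(
      "# OpenDX density written by solvshell",
      sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
      sprintf("origin %.6f %.6f %.6f", grid$origin[1], grid$origin[2],
              grid$origin[3]),
      sprintf("delta %.6f 0.000000 0.000000", grid$spacing),
      sprintf("delta 0.000000 %.6f 0.000000", grid$spacing),
      sprintf("delta 0.000000 0.000000 %.6f", grid$spacing),
      sprintf("object 2 class gridconnections counts %d %d %d",
              d[1], d[2], d[3]),
      sprintf(paste0("object 3 class array type double rank 0 items %d",
                     " data follows"), prod(d))), con)
    full <- length(flat) %/% 3L
    if (full) writeLines(sprintf("%.10g %.10g %.10g",
                                 flat[seq(1, by = 3, length.out = full)],
                                 flat[seq(2, by = 3, length.out = full)],
                                 flat[seq(3, by = 3, length.out = full)]),
                         con)
    rest <- flat[(full * 3L + 1L):length(flat)]
    if (length(flat) %% 3L)
      writeLines(paste(sprintf("%.10g", rest), collapse = " "), con)
    writeLines(c("attribute \"dep\" string \"positions\"",
                 "object \"density\" class field",
                 "component \"positions\" value 1",
                 "component \"connections\" value 2",
                 "component \"data\" value 3"), con)
  } else {
    b <- BOHR_PER_ANGSTROM
    writeLines(c("solvshell density grid",
                 sprintf("field: %s", field),
                 sprintf("%5d %11.6f %11.6f %11.6f", 1L,
                         grid$origin[1] * b, grid$origin[2] * b,
                         grid$origin[3] * b),
                 sprintf("%5d %11.6f %11.6f %11.6f", d[1],
                         grid$spacing * b, 0, 0),
                 sprintf("%5d %11.6f %11.6f %11.6f", d[2], 0,
                         grid$spacing * b, 0),
                 sprintf("%5d %11.6f %11.6f %11.6f", d[3], 0, 0,
                         grid$spacing * b),
                 sprintf("%5d %11.6f %11.6f %11.6f %11.6f", 1L, 0, 0, 0, 0)),
               con)
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      row <- vals[i, j, ]
      writeLines(paste(sprintf("%.5E", row), collapse = " "), con)
    }
  }
  invisible(path)
}

#' Read back a volumetric grid written by [export_grid()]
#'
#' Minimal readers for the OpenDX and cube files this package writes;
#' round-trips recover values to the printed precision.
#'
#' @param path file path.
#' @param format `"dx"` or `"cube"`.
#' @return list with `origin`, `spacing`, `dims`, `values` (3-D array, in
#'   Angstrom units for both formats).
#' @export
read_grid <- function(path, format = c("dx", "cube")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  if (format == "dx") {
    hdr <- grep("gridpositions counts", lines, value = TRUE)[1]
    d <- as.integer(strsplit(trimws(sub(".*counts", "", hdr)), " +")[[1]])
    org <- as.numeric(strsplit(trimws(sub("^origin", "",
      grep("^origin", lines, value = TRUE)[1])), " +")[[1]])
    deltas <- grep("^delta", lines, value = TRUE)
    sp <- as.numeric(strsplit(trimws(sub("^delta", "", deltas[1])),
                              " +")[[1]])[1]
    start <- grep("data follows", lines) + 1L
    stopn <- grep("attribute", lines)[1] - 1L
    flat <- scan(text = lines[start:stopn], quiet = TRUE)
    vals <- aperm(array(flat, dim = rev(d)), c(3L, 2L, 1L))
  } else {
    b <- BOHR_PER_ANGSTROM
    l3 <- as.numeric(strsplit(trimws(lines[3]), " +")[[1]])
    org <- l3[2:4] / b
    ax <- lapply(4:6, function(i)
      as.numeric(strsplit(trimws(lines[i]), " +")[[1]]))
    d <- vapply(ax, function(a) as.integer(a[1]), 1L)
    sp <- ax[[1]][2] / b
    natoms <- abs(as.integer(l3[1]))
    flat <- scan(text = lines[(7L + natoms):length(lines)], quiet = TRUE)
    vals <- aperm(array(flat, dim = rev(d)), c(3L, 2L, 1L))
  }
  list(origin = org, spacing = sp, dims = d, values = vals)
}
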