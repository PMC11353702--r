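# Synthetic systems with exact ground truth: ideal-gas baths (RDF/SDF null),
# two-state Markov binders (residence kinetics), Gaussian-mode ensembles
# (PCA/FEL), and hand-built contact fixtures (salt bridges, ring stacks).
# All generators are seed-deterministic.

#' Expected ion count for a periodic box at a given concentration
#'
#' Evaluates N = round(N_A * c * V), the molecule-number formula used to
#' compose simulation boxes, with V the box volume in litres
#' (`prod(box) * 1e-27`).  An optional `volume_fraction` scales V to a
#' solvent-accessible volume (e.g. to account for the protein-excluded
#' volume); default 1 (whole box).
#'
#' @param concentration mol/L.
#' @param box length-3 box lengths (Angstrom).
#' @param volume_fraction fraction of the box volume that counts as solvent.
#' @return integer count (half-up rounding).
#' @examples
#' expected_ion_count(0.15, c(100, 100, 100))  # 90
#' expected_ion_count(4,    c(100, 100, 100))  # 2409
#' @export
expected_ion_count <- function(concentration, box, volume_fraction = 1) {
  stopifnot(concentration >= 0, all(box > 0),
            volume_fraction > 0, volume_fraction <= 1)
  v_litre <- prod(as.numeric(box)) * 1e-27 * volume_fraction
  as.integer(floor(N_AVOGADRO * concentration * v_litre + 0.5))
}

#' Uniform (ideal-gas) particle bath
#'
#' Each frame is an independent uniform draw of `n_particles` positions in
#' the box: the exact null model for pair-structure and spatial-density
#' analyses (g(r) = 1, relative density = 1).
#'
#' @param n_particles number of particles (> 0).
#' @param box length-3 box (Angstrom).
#' @param n_frames number of frames.
#' @param dt frame spacing (ns).
#' @param seed RNG seed (fixed seed gives identical output).
#' @return a [new_trajectory()] object.
#' @export
generate_ideal_gas <- function(n_particles, box, n_frames, dt = 1,
                               seed = 1) {
  if (n_particles < 1L) stop("n_particles must be >= 1")
  box <- as.numeric(box)
  set.seed(seed)
  coords <- array(stats::runif(n_frames * n_particles * 3L),
                  dim = c(n_frames, n_particles, 3L))
  for (k in 1:3) coords[, , k] <- coords[, , k] * box[k]
  new_trajectory(coords, box, dt = dt)
}

# uniform point in a sphere of radius R about centre
.runif_sphere <- function(n, R, centre) {
  dir <- matrix(stats::rnorm(3L * n), ncol = 3L)
  dir <- dir / sqrt(rowSums(dir^2))
  r <- R * stats::runif(n)^(1 / 3)
  sweep(dir * r, 2L, centre, "+")
}

# uniform point in box but outside radius R of centre (rejection)
.runif_outside <- function(n, R, centre, box) {
  out <- matrix(NA_real_, n, 3L)
  need <- seq_len(n)
  while (length(need)) {
    cand <- cbind(stats::runif(length(need), 0, box[1]),
                  stats::runif(length(need), 0, box[2]),
                  stats::runif(length(need), 0, box[3]))
    d <- sqrt(rowSums(minimum_image_displacement(
      matrix(centre, length(need), 3L, byrow = TRUE), cand, box)^2))
    ok <- d > R
    out[need[ok], ] <- cand[ok, , drop = FALSE]
    need <- need[!ok]
  }
  out
}

#' Two-state Markov binder around a fixed reference site
#'
#' A fixed site sits at the box centre (atom 1 of the returned trajectory);
#' each of `n_particles` mobile particles (atoms 2..n+1) is an independent
#' two-state Markov chain with per-frame transition probabilities `k_on`
#' (free -> bound) and `k_off` (bound -> free).  Bound particles are placed
#' uniformly inside `shell_radius` of the site, free particles uniformly in
#' the box outside `shell_radius + buffer`.  The returned ground-truth
#' occupancy matrix records the true chain state, giving every residence
#' analysis an exact oracle.  Converting to a rate: k_off (1/ns) =
#' -log(1 - p_off) / dt.
#'
#' @param n_particles mobile particle count.
#' @param box length-3 box (Angstrom).
#' @param n_frames frames to generate.
#' @param k_on,k_off per-frame transition probabilities between 0 and 1.
#' @param shell_radius binding-shell radius (Angstrom); must be smaller
#'   than half the smallest box length.
#' @param buffer exclusion margin outside the shell for free particles
#'   (Angstrom).
#' @param dt frame spacing (ns).
#' @param seed RNG seed.
#' @param init initial state: `"stationary"` (Bernoulli with probability
#'   k_on/(k_on+k_off)), `"bound"` or `"free"`.
#' @return list with `trajectory`, logical `occupancy`
#'   (`n_frames x n_particles`, TRUE = bound), `site_index` (= 1) and
#'   `mobile_index` (= 2..n+1).
#' @export
generate_markov_binder <- function(n_particles, box, n_frames,
                                   k_on = 0.05, k_off = 0.05,
                                   shell_radius = 4, buffer = 1,
                                   dt = 1, seed = 1,
                                   init = c("stationary", "bound", "free")) {
  init <- match.arg(init)
  box <- as.numeric(box)
  stopifnot(k_on >= 0, k_on <= 1, k_off >= 0, k_off <= 1, n_particles >= 1)
  if (shell_radius >= min(box) / 2)
    stop("shell_radius must be < min(box)/2")
  centre <- box / 2
  set.seed(seed)
  occ <- matrix(FALSE, n_frames, n_particles)
  state <- switch(init,
    stationary = {
      p <- if (k_on + k_off > 0) k_on / (k_on + k_off) else 0
      stats::runif(n_particles) < p
    },
    bound = rep(TRUE, n_particles),
    free  = rep(FALSE, n_particles))
  coords <- array(NA_real_, dim = c(n_frames, n_particles + 1L, 3L))
  for (f in seq_len(n_frames)) {
    if (f > 1L) {
      u <- stats::runif(n_particles)
      state <- ifelse(state, u >= k_off, u < k_on)
    }
    occ[f, ] <- state
    coords[f, 1L, ] <- centre
    nb <- sum(state)
    if (nb) coords[f, 1L + which(state), ] <-
        .runif_sphere(nb, shell_radius, centre)
    if (nb < n_particles) coords[f, 1L + which(!state), ] <-
        .runif_outside(n_particles - nb, shell_radius + buffer, centre, box)
  }
  list(trajectory = new_trajectory(coords, box, dt = dt), occupancy = occ,
       site_index = 1L, mobile_index = seq_len(n_particles) + 1L)
}

#' Gaussian-mode pseudo-protein ensemble
#'
#' Frames are `mean + sum_i z_i sqrt(lambda_i) mode_i` with iid standard
#' normal `z_i`: an exactly low-rank Gaussian ensemble whose population
#' covariance has the supplied eigenvalues along the supplied orthonormal
#' modes and zero variance elsewhere.  Optional random rigid rotations and
#' translations per frame exercise downstream superposition.
#'
#' @param mean_structure M x 3 matrix of mean coordinates (Angstrom).
#' @param eigenvalues mode variances lambda_i (Angstrom^2, >= 0).
#' @param modes 3M x k matrix of orthonormal displacement modes (columns),
#'   in x1,y1,z1,x2,... layout.  Random orthonormal modes are drawn when
#'   omitted.
#' @param n_frames frames to generate.
#' @param rigid_motion add a random proper rotation and translation per
#'   frame (default FALSE).
#' @param box box lengths; defaults to a box comfortably containing the
#'   ensemble (periodicity is irrelevant for these ensembles).
#' @param dt frame spacing (ns).
#' @param seed RNG seed.
#' @return list with `trajectory`, `modes`, `eigenvalues`,
#'   `mean_structure`.
#' @export
generate_gaussian_modes <- function(mean_structure, eigenvalues,
                                    modes = NULL, n_frames = 1000,
                                    rigid_motion = FALSE, box = NULL,
                                    dt = 1, seed = 1) {
  mean_structure <- as.matrix(mean_structure)
  stopifnot(ncol(mean_structure) == 3L, all(eigenvalues >= 0))
  M <- nrow(mean_structure)
  k <- length(eigenvalues)
  set.seed(seed)
  if (is.null(modes)) {
    # random internal modes: orthogonal to the 6 rigid-body degrees of
    # freedom at the mean structure, so downstream superposition leaves
    # the injected variances untouched
    rigid <- .rigid_basis(mean_structure)
    raw <- matrix(stats::rnorm(3L * M * k), 3L * M, k)
    raw <- raw - rigid %*% crossprod(rigid, raw)
    modes <- qr.Q(qr(raw))[, seq_len(k), drop = FALSE]
  }
  modes <- as.matrix(modes)
  stopifnot(nrow(modes) == 3L * M, ncol(modes) == k)
  orth <- crossprod(modes)
  if (max(abs(orth - diag(k))) > 1e-8)
    stop("modes must be orthonormal columns")
  if (is.null(box)) {
    span <- max(abs(mean_structure)) + 6 * sqrt(max(eigenvalues, 1)) + 50
    box <- rep(2 * span, 3L)
  }
  z <- matrix(stats::rnorm(n_frames * k), n_frames, k)
  flat_mean <- as.numeric(t(mean_structure))  # x1 y1 z1 x2 ...
  disp <- z %*% (t(modes) * sqrt(eigenvalues))
  coords <- array(NA_real_, dim = c(n_frames, M, 3L))
  offset <- box / 2
  for (f in seq_len(n_frames)) {
    X <- matrix(flat_mean + disp[f, ], ncol = 3L, byrow = TRUE)
    if (rigid_motion) {
      R <- .random_rotation()
      tvec <- stats::rnorm(3L, 0, 3)
      X <- X %*% t(R) + matrix(tvec, M, 3L, byrow = TRUE)
    }
    coords[f, , ] <- sweep(X, 2L, offset, "+")
  }
  list(trajectory = new_trajectory(coords, box, dt = dt), modes = modes,
       eigenvalues = as.numeric(eigenvalues), mean_structure = mean_structure)
}

# Orthonormal basis of the 6 rigid-body modes (3 translations, 3
# infinitesimal rotations) of a structure, in flat x1,y1,z1,... layout.
.rigid_basis <- function(mean_structure) {
  M <- nrow(mean_structure)
  X0 <- sweep(mean_structure, 2L, colMeans(mean_structure))
  B <- matrix(0, 3L * M, 6L)
  for (k in 1:3) B[seq(k, by = 3L, length.out = M), k] <- 1
  # rotation generators: e_k x r_i
  B[, 4] <- as.numeric(t(cbind(0, -X0[, 3], X0[, 2])))
  B[, 5] <- as.numeric(t(cbind(X0[, 3], 0, -X0[, 1])))
  B[, 6] <- as.numeric(t(cbind(-X0[, 2], X0[, 1], 0)))
  qr.Q(qr(B))[, 1:6, drop = FALSE]
}

# Haar-uniform proper rotation via QR with sign fix
.random_rotation <- function() {
  qrr <- qr(matrix(stats::rnorm(9L), 3L))
  Q <- qr.Q(qrr)
  Q <- Q %*% diag(sign(diag(qr.R(qrr))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# ring template: regular polygon of given radius in the y-z plane
.ring_coords <- function(n, radius, centre) {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  cbind(centre[1], centre[2] + radius * cos(th), centre[3] + radius * sin(th))
}

#' Hand-built salt-bridge / aromatic-ring contact fixtures
#'
#' Constructs a minimal topology plus trajectory in which each requested
#' pair sits at its specified contact distance exactly in the frames where
#' its occupancy pattern is TRUE, and at a clearly non-contacting distance
#' (criterion threshold + 2 Angstrom) where FALSE.  Salt-bridge pairs are a
#' Glu carboxylate (CD/OE1/OE2) facing a Lys ammonium (CE/NZ) with the
#' OE1-NZ distance controlled; ring pairs are two parallel Phe-named
#' 6-atom rings with the centroid-centroid distance controlled.  Standard
#' PDB atom names are used so [classify_residues()] needs no overrides.
#'
#' @param pairs list of specs `list(type = "saltbridge"|"ring",
#'   distance = <Angstrom>, pattern = <logical vector>)`; all patterns must
#'   share one length (the frame count).
#' @param dt frame spacing (ns).
#' @param pair_spacing centre-to-centre spacing between successive pairs
#'   (Angstrom); placements that could overlap raise an error.
#' @return list with `topology`, `trajectory`, and `pairs` (the input,
#'   augmented with the residue ids used).
#' @export
build_contact_fixture <- function(pairs, dt = 1, pair_spacing = 40) {
  stopifnot(length(pairs) >= 1L)
  n_frames <- unique(vapply(pairs, function(p) length(p$pattern), 1L))
  if (length(n_frames) != 1L)
    stop("all occupancy patterns must have the same length")
  off_dist <- function(type) if (type == "saltbridge") 3.2 + 2 else 6 + 2
  max_ext <- max(vapply(pairs, function(p)
    max(p$distance, off_dist(p$type)) + 6, 1))
  if (2 * max_ext > pair_spacing)
    stop("overlapping placements: increase pair_spacing (pair extent ",
         round(max_ext, 1), " A)")
  for (p in pairs) if (p$distance <= 0) stop("distances must be > 0")

  atoms <- list(); n_pairs <- length(pairs)
  box <- c(pair_spacing * n_pairs, pair_spacing, pair_spacing)
  coords_t <- vector("list", n_pairs)   # per-pair: frames x atoms x 3
  rid <- 0L
  for (p in seq_len(n_pairs)) {
    pr <- pairs[[p]]
    cx <- pair_spacing * (p - 0.5); cy <- box[2] / 2; cz <- box[3] / 2
    d_on <- pr$distance; d_off <- off_dist(pr$type)
    if (pr$type == "saltbridge") {
      a <- data.frame(
        atom_name = c("CD", "OE1", "OE2", "CE", "NZ"),
        element = c("C", "O", "O", "C", "N"),
        residue_id = c(rid + 1L, rid + 1L, rid + 1L, rid + 2L, rid + 2L),
        residue_name = c("GLU", "GLU", "GLU", "LYS", "LYS"),
        stringsAsFactors = FALSE)
      base <- rbind(c(cx - 1.25, cy, cz),        # CD
                    c(cx, cy, cz),               # OE1 (contact atom)
                    c(cx - 1.60, cy + 1.1, cz),  # OE2
                    c(NA, NA, NA),               # CE (set per frame)
                    c(NA, NA, NA))               # NZ (set per frame)
      cc <- array(rep(base, each = n_frames),
                  dim = c(n_frames, nrow(base), 3L))
      dd <- ifelse(pr$pattern, d_on, d_off)
      cc[, 5L, 1] <- cx + dd; cc[, 5L, 2] <- cy; cc[, 5L, 3] <- cz
      cc[, 4L, 1] <- cx + dd + 1.5; cc[, 4L, 2] <- cy; cc[, 4L, 3] <- cz
    } else if (pr$type == "ring") {
      ring_names <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
      a <- data.frame(
        atom_name = rep(ring_names, 2L),
        element = rep("C", 12L),
        residue_id = rep(c(rid + 1L, rid + 2L), each = 6L),
        residue_name = rep("PHE", 12L),
        stringsAsFactors = FALSE)
      ring1 <- .ring_coords(6L, 1.39, c(cx, cy, cz))
      cc <- array(NA_real_, dim = c(n_frames, 12L, 3L))
      dd <- ifelse(pr$pattern, d_on, d_off)
      for (f in seq_len(n_frames)) {
        ring2 <- .ring_coords(6L, 1.39, c(cx + dd[f], cy, cz))
        cc[f, , ] <- rbind(ring1, ring2)
      }
    } else stop("unknown pair type: ", pr$type)
    rid <- rid + 2L
    pairs[[p]]$residue_ids <- unique(a$residue_id)
    atoms[[p]] <- a
    coords_t[[p]] <- cc
  }
  atoms <- do.call(rbind, atoms)
  atoms$atom_id <- seq_len(nrow(atoms)) - 1L
  atoms$chain_id <- "A"
  top <- new_topology(atoms, box_hint = box)
  coords <- array(NA_real_, dim = c(n_frames, nrow(atoms), 3L))
  at0 <- 0L
  for (p in seq_len(n_pairs)) {
    na <- dim(coords_t[[p]])[2]
    coords[, (at0 + 1L):(at0 + na), ] <- coords_t[[p]]
    at0 <- at0 + na
  }
  list(topology = top,
       trajectory = new_trajectory(coords, box, dt = dt),
       pairs = pairs)
}
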