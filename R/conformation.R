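# Conformational analysis: Kabsch superposition, RMSD/RMSF, Calpha PCA and
# 2-D free-energy landscapes with persistence-based minima detection.

#' Optimal rigid superposition (Kabsch)
#'
#' Returns the proper rotation R and translation that minimise the RMSD of
#' `P` onto `Q` (reflections excluded): `P_aligned = P R + t`.
#'
#' @param P,Q n x 3 coordinate matrices (paired points, n >= 3).
#' @return list with `R` (3 x 3, det = +1), `t` (length 3), `rmsd`.
#' @export
kabsch <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  stopifnot(nrow(P) == nrow(Q), ncol(P) == 3L, nrow(P) >= 3L)
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2L, cp); Q0 <- sweep(Q, 2L, cq)
  H <- crossprod(P0, Q0)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  R <- t(R)  # row-vector convention: aligned = P0 %*% R + cq
  aligned <- P0 %*% R
  rmsd <- sqrt(mean(rowSums((aligned - Q0)^2)))
  list(R = R, t = cq - cp %*% R, rmsd = rmsd)
}

#' Superpose every frame of a trajectory
#'
#' Kabsch superposition of each frame's selection atoms onto a reference
#' (proper rotations only); the fitted transform is applied to all atoms.
#' The default reference is the iterative mean structure: frames are
#' aligned to a running mean until the mean moves by less than `tol`.
#'
#' @param traj a [new_trajectory()] object.
#' @param sel 1-based indices of the fitting atoms (>= 3, non-collinear).
#' @param reference `"mean_iterative"` (default) or `"first_frame"`.
#' @param tol convergence threshold on the mean-structure shift (Angstrom).
#' @param max_iter iteration cap for the mean reference.
#' @return object of class `AlignmentResult`: `trajectory` (aligned),
#'   `rmsd` (per-frame, vs the reference over `sel`), `reference`,
#'   `ref_coords` (selection reference coordinates), `sel`.
#' @export
align_trajectory <- function(traj, sel,
                             reference = c("mean_iterative", "first_frame"),
                             tol = 1e-4, max_iter = 50) {
  reference <- match.arg(reference)
  if (length(sel) < 3L) stop("alignment selection needs >= 3 atoms")
  n <- traj$n_frames
  fit_once <- function(coords, ref_sel) {
    out <- array(NA_real_, dim = dim(coords))
    rmsd <- numeric(n)
    for (f in seq_len(n)) {
      k <- kabsch(coords[f, sel, , drop = TRUE], ref_sel)
      all_f <- coords[f, , , drop = TRUE]
      cp <- colMeans(coords[f, sel, , drop = TRUE])
      moved <- sweep(all_f, 2L, cp) %*% k$R
      out[f, , ] <- sweep(moved, 2L, colMeans(ref_sel), "+")
      rmsd[f] <- k$rmsd
    }
    list(coords = out, rmsd = rmsd)
  }
  ref_sel <- traj$coords[1, sel, , drop = TRUE]
  res <- fit_once(traj$coords, ref_sel)
  if (reference == "mean_iterative") {
    for (it in seq_len(max_iter)) {
      new_ref <- apply(res$coords[, sel, , drop = FALSE], c(2L, 3L), mean)
      shift <- sqrt(mean((new_ref - ref_sel)^2))
      ref_sel <- new_ref
      res <- fit_once(traj$coords, ref_sel)
      if (shift < tol) break
    }
  }
  structure(list(
    trajectory = new_trajectory(res$coords, traj$box, dt = traj$dt,
                                t0 = traj$t0),
    rmsd = res$rmsd, reference = reference, ref_coords = ref_sel,
    sel = sel), class = "AlignmentResult")
}

#' Per-frame RMSD to the alignment reference
#'
#' @param aligned an [align_trajectory()] result.
#' @param sel optional atom subset (default: the alignment selection).
#' @return numeric vector of per-frame RMSD (Angstrom).
#' @export
rmsd_series <- function(aligned, sel = NULL) {
  if (is.null(sel) || identical(sel, aligned$sel)) return(aligned$rmsd)
  ref <- apply(aligned$trajectory$coords[, sel, , drop = FALSE],
               c(2L, 3L), mean)
  vapply(seq_len(aligned$trajectory$n_frames), function(f)
    sqrt(mean(rowSums((aligned$trajectory$coords[f, sel, , drop = TRUE] -
                       ref)^2))), numeric(1))
}

#' Root-mean-square fluctuation per atom
#'
#' RMSF_i = sqrt(mean_f |x_i(f) - <x_i>|^2) on the aligned trajectory.
#' With `chain_groups`, per-atom values are aggregated position-wise
#' across symmetry-related chains and returned as mean and SD (the
#' convention for reporting tetramer fluctuations).
#'
#' @param aligned an [align_trajectory()] result.
#' @param sel 1-based atom indices.
#' @param chain_groups optional list of equal-length index vectors
#'   (one per chain) to aggregate across.
#' @return numeric RMSF vector (Angstrom), or a data.frame with `mean`
#'   and `sd` when `chain_groups` is given.
#' @export
rmsf <- function(aligned, sel, chain_groups = NULL) {
  coords <- aligned$trajectory$coords
  one <- function(idx) {
    mu <- apply(coords[, idx, , drop = FALSE], c(2L, 3L), mean)
    v <- 0
    for (k in 1:3) {
      xk <- matrix(coords[, idx, k], ncol = length(idx))
      v <- v + colMeans(sweep(xk, 2L, mu[, k])^2)
    }
    sqrt(v)
  }
  if (is.null(chain_groups)) return(one(sel))
  per_chain <- vapply(chain_groups, one,
                      numeric(length(chain_groups[[1]])))
  data.frame(mean = rowMeans(per_chain), sd = apply(per_chain, 1L, stats::sd))
}

#' Principal component analysis of Calpha coordinates
#'
#' Eigendecomposition of the covariance of the centred, aligned selection
#' coordinates (mass-unweighted).  Projections are the centred coordinates
#' along each eigenvector.
#'
#' @param aligned an [align_trajectory()] result.
#' @param ca_sel 1-based Calpha atom indices.
#' @param n_components number of components retained (default 10, capped
#'   by rank).
#' @return object of class `PCAModel`: `mean` (flat 3M vector),
#'   `eigenvalues` (Angstrom^2, descending, full spectrum),
#'   `eigenvectors` (3M x k), `projections` (frames x k),
#'   `variance_explained` (per retained component), `total_variance`.
#' @export
pca_ca <- function(aligned, ca_sel, n_components = 10) {
  coords <- aligned$trajectory$coords[, ca_sel, , drop = FALSE]
  n <- dim(coords)[1]
  if (n < 2L) stop("PCA needs at least 2 frames")
  X <- matrix(NA_real_, n, 3L * length(ca_sel))
  for (k in 1:3) X[, seq(k, by = 3L, length.out = length(ca_sel))] <-
    coords[, , k]
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  pr <- stats::prcomp(Xc, center = FALSE, scale. = FALSE)
  lam <- pr$sdev^2
  k <- min(n_components, sum(lam > 0), length(lam))
  k <- max(k, 1L)
  structure(list(mean = mu, eigenvalues = lam,
                 eigenvectors = pr$rotation[, seq_len(k), drop = FALSE],
                 projections = pr$x[, seq_len(k), drop = FALSE],
                 variance_explained = lam[seq_len(k)] / sum(lam),
                 total_variance = sum(lam)),
            class = "PCAModel")
}

#' Two-dimensional free-energy landscape over PC1/PC2
#'
#' Bins the first two projections into a 2-D histogram P and converts to
#' F = -kB T ln(P / P_max) (kJ/mol): the most populated bin is pinned at
#' zero, empty bins are masked.  The grid spans the sampled range padded
#' by 5 per cent.
#'
#' @param x a [pca_ca()] model (first two projections used) or a
#'   two-column matrix of collective coordinates.
#' @param bins bins per axis (>= 2).
#' @param temperature K.
#' @return object of class `FreeEnergyLandscape`: `pc1_edges`,
#'   `pc2_edges`, `P` (probability), `F` (kJ/mol, NA where masked),
#'   `mask`, `temperature`, `n_samples`.
#' @export
fel_2d <- function(x, bins = 50, temperature = DEFAULT_TEMPERATURE) {
  if (inherits(x, "PCAModel")) {
    if (ncol(x$projections) < 2L) stop("need at least 2 components")
    x <- x$projections[, 1:2]
  }
  x <- as.matrix(x)
  stopifnot(ncol(x) == 2L)
  if (bins < 2L) stop("bins must be >= 2")
  pad <- function(r) {
    w <- diff(r); if (w == 0) w <- 1
    r + c(-1, 1) * 0.05 * w
  }
  r1 <- pad(range(x[, 1])); r2 <- pad(range(x[, 2]))
  e1 <- seq(r1[1], r1[2], length.out = bins + 1L)
  e2 <- seq(r2[1], r2[2], length.out = bins + 1L)
  i1 <- pmin(pmax(findInterval(x[, 1], e1, all.inside = TRUE), 1L), bins)
  i2 <- pmin(pmax(findInterval(x[, 2], e2, all.inside = TRUE), 1L), bins)
  P <- matrix(tabulate((i2 - 1L) * bins + i1, nbins = bins * bins),
              bins, bins) / nrow(x)
  mask <- P == 0
  F <- matrix(NA_real_, bins, bins)
  F[!mask] <- -KB_KJMOL * temperature * log(P[!mask] / max(P))
  structure(list(pc1_edges = e1, pc2_edges = e2, P = P, F = F, mask = mask,
                 temperature = temperature, n_samples = nrow(x)),
            class = "FreeEnergyLandscape")
}

#' Build a free-energy landscape from an explicit probability grid
#'
#' Converts a supplied (possibly analytic) probability or density grid to
#' F = -kB T ln(P / P_max), yielding the same object as [fel_2d()]: the
#' noise-free route for constructed landscapes.
#'
#' @param P non-negative probability (or unnormalised density) matrix.
#' @param pc1_edges,pc2_edges bin edges (lengths nrow(P)+1, ncol(P)+1).
#' @param temperature K.
#' @return a `FreeEnergyLandscape`.
#' @export
fel_from_probability <- function(P, pc1_edges, pc2_edges,
                                 temperature = DEFAULT_TEMPERATURE) {
  P <- as.matrix(P)
  stopifnot(length(pc1_edges) == nrow(P) + 1L,
            length(pc2_edges) == ncol(P) + 1L, all(P >= 0), any(P > 0))
  P <- P / sum(P)
  mask <- P == 0
  F <- matrix(NA_real_, nrow(P), ncol(P))
  F[!mask] <- -KB_KJMOL * temperature * log(P[!mask] / max(P))
  structure(list(pc1_edges = pc1_edges, pc2_edges = pc2_edges, P = P,
                 F = F, mask = mask, temperature = temperature,
                 n_samples = NA_integer_),
            class = "FreeEnergyLandscape")
}

#' Locate and merge free-energy minima
#'
#' Finds local minima of the landscape over 8-connected bins and merges
#' basins whose separating barrier (saddle height above the shallower
#' basin's minimum) is below `depth_threshold`, i.e. topological
#' persistence filtering.  Deterministic tie-breaking: bins are processed
#' in increasing F, then row, then column order.  Masked (unsampled) bins
#' are by default treated as a traversable plateau just above the highest
#' sampled value, so shallow noise islands in sparsely sampled tails merge
#' like any other sub-threshold basin; with `connect_masked = FALSE` they
#' are impassable walls instead.
#'
#' @param fel a [fel_2d()] or [fel_from_probability()] landscape.
#' @param depth_threshold minimum barrier (kJ/mol) for two basins to count
#'   as separate minima.
#' @param connect_masked treat masked bins as a high plateau (default)
#'   rather than as walls.
#' @return data.frame with one row per surviving minimum: `i`, `j` (bin
#'   indices), `pc1`, `pc2` (bin centres), `F` (kJ/mol), `basin_size`
#'   (bins), ordered by F then bin index.
#' @export
find_minima <- function(fel, depth_threshold = 0, connect_masked = TRUE) {
  Fg <- fel$F
  nb1 <- nrow(Fg); nb2 <- ncol(Fg)
  if (all(fel$mask)) stop("fully masked landscape")
  plateau <- FALSE
  if (connect_masked && any(fel$mask)) {
    fmax <- max(Fg[!fel$mask])
    Fg[fel$mask] <- fmax + 1e-9 * (abs(fmax) + 1)
    plateau <- TRUE
  }
  cells <- which(!is.na(Fg), arr.ind = TRUE)
  vals <- Fg[cells]
  ord <- order(vals, cells[, 1], cells[, 2])
  cells <- cells[ord, , drop = FALSE]; vals <- vals[ord]
  basin <- matrix(0L, nb1, nb2)   # 0 = unassigned
  basin_min <- numeric(0)         # minimum F per basin
  basin_cell <- list()            # bin index of each basin's minimum
  alive <- logical(0)             # FALSE once merged away
  find_root <- function(b) { while (!alive[b]) b <- parent[b]; b }
  parent <- integer(0)
  size <- integer(0)
  for (c in seq_len(nrow(cells))) {
    i <- cells[c, 1]; j <- cells[c, 2]; fv <- vals[c]
    ni <- max(1L, i - 1L):min(nb1, i + 1L)
    nj <- max(1L, j - 1L):min(nb2, j + 1L)
    nbr <- unique(basin[ni, nj])
    nbr <- nbr[nbr > 0L]
    nbr <- unique(vapply(nbr, find_root, 1L))
    if (!length(nbr)) {
      # new local minimum
      bnew <- length(basin_min) + 1L
      basin_min[bnew] <- fv
      basin_cell[[bnew]] <- c(i, j)
      alive[bnew] <- TRUE; parent[bnew] <- bnew; size[bnew] <- 1L
      basin[i, j] <- bnew
    } else if (length(nbr) == 1L) {
      basin[i, j] <- nbr
      size[nbr] <- size[nbr] + 1L
    } else {
      # saddle joining several basins: keep the deepest, merge the
      # others whose persistence (fv - basin_min) is below threshold
      keep <- nbr[which.min(basin_min[nbr])]
      for (b in setdiff(nbr, keep)) {
        if (fv - basin_min[b] < depth_threshold) {
          alive[b] <- FALSE; parent[b] <- keep
          size[keep] <- size[keep] + size[b]
        }
      }
      basin[i, j] <- keep
      size[keep] <- size[keep] + 1L
    }
  }
  live <- which(alive)
  if (plateau) {
    # basins whose minimum sits on the masked plateau are artifacts
    on_grid <- vapply(basin_cell[live], function(cc)
      !fel$mask[cc[1], cc[2]], logical(1))
    live <- live[on_grid]
  }
  mid <- function(e) (e[-1] + e[-length(e)]) / 2
  c1 <- mid(fel$pc1_edges); c2 <- mid(fel$pc2_edges)
  out <- data.frame(
    i = vapply(basin_cell[live], `[`, 1L, 1L),
    j = vapply(basin_cell[live], `[`, 1L, 2L),
    F = basin_min[live],
    basin_size = size[live])
  out$pc1 <- c1[out$i]; out$pc2 <- c2[out$j]
  out <- out[order(out$F, out$i, out$j),
             c("i", "j", "pc1", "pc2", "F", "basin_size")]
  rownames(out) <- NULL
  out
}
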