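# Pair structure: radial distribution functions with minimum-image
# counting, shell decomposition, coordination numbers, the PMF transform
# and RDF-derived per-shell binding energies.

#' Radial distribution function g(r)
#'
#' Tallies minimum-image distances from every reference atom to every
#' selection atom into bins of width `dr` on (0, r_max], and normalises by
#' the ideal-gas expectation using exact shell volumes and the
#' instantaneous per-frame box (so constant-pressure trajectories are
#' handled correctly).  Atoms present in both selections are never paired
#' with themselves.
#'
#' @param traj a [new_trajectory()] object.
#' @param ref,sel integer atom index vectors (1-based), non-empty.
#' @param r_max largest distance binned (Angstrom); must not exceed half
#'   the smallest box length.
#' @param dr bin width (Angstrom).
#' @return object of class `RadialDistribution` with fields `bin_edges`,
#'   `r` (bin mid-points), `g`, `counts`, `rho_sel` (mean selection number
#'   density, 1/Angstrom^3), `n_frames`, `n_ref`, `n_sel`.
#' @export
compute_rdf <- function(traj, ref, sel, r_max = 15, dr = 0.1) {
  if (!length(ref) || !length(sel)) stop("empty selection")
  min_box <- min(traj$box)
  if (r_max > min_box / 2 + 1e-9)
    stop("r_max = ", r_max, " exceeds half the smallest box length (",
         min_box, " A)")
  edges <- seq(0, r_max, by = dr)
  n_bins <- length(edges) - 1L
  shell_vol <- (4 / 3) * pi * (edges[-1]^3 - edges[-length(edges)]^3)
  counts <- numeric(n_bins)
  expected <- numeric(n_bins)
  shared <- sum(ref %in% sel)
  n_pairs <- length(ref) * length(sel) - shared
  rho_acc <- 0
  for (f in seq_len(traj$n_frames)) {
    box <- traj$box[f, ]
    D <- min_image_dist(traj$coords[f, ref, , drop = FALSE],
                        traj$coords[f, sel, , drop = FALSE], box)
    if (shared) D[cbind(match(intersect(ref, sel), ref),
                        match(intersect(ref, sel), sel))] <- NA_real_
    d <- D[!is.na(D) & D > 0 & D <= r_max]
    idx <- pmin(pmax(ceiling(d / dr), 1L), n_bins)
    counts <- counts + tabulate(idx, nbins = n_bins)
    vol <- prod(box)
    rho <- length(sel) / vol
    rho_acc <- rho_acc + rho
    expected <- expected + n_pairs * shell_vol / vol
  }
  g <- ifelse(expected > 0, counts / expected, 0)
  structure(list(bin_edges = edges, r = (edges[-1] + edges[-length(edges)]) / 2,
                 g = g, counts = counts, rho_sel = rho_acc / traj$n_frames,
                 n_frames = traj$n_frames, n_ref = length(ref),
                 n_sel = length(sel), dr = dr, r_max = r_max),
            class = "RadialDistribution")
}

#' Brute-force per-bin pair counts over all periodic images (oracle)
#'
#' Reference tally that enumerates all 27 periodic images of each selection
#' atom and bins the smallest image distance; O(n_ref * n_sel * 27) per
#' frame.  Used to validate [compute_rdf()] counts bin-by-bin.
#'
#' @inheritParams compute_rdf
#' @return numeric vector of per-bin counts.
#' @export
rdf_counts_brute_force <- function(traj, ref, sel, r_max = 15, dr = 0.1) {
  edges <- seq(0, r_max, by = dr)
  n_bins <- length(edges) - 1L
  counts <- numeric(n_bins)
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  for (f in seq_len(traj$n_frames)) {
    box <- traj$box[f, ]
    A <- matrix(traj$coords[f, ref, ], ncol = 3L)
    B <- matrix(traj$coords[f, sel, ], ncol = 3L)
    Dmin <- NULL
    for (s in seq_len(nrow(shifts))) {
      Bs <- sweep(B, 2L, shifts[s, ] * box, "+")
      d2 <- outer(A[, 1], Bs[, 1], "-")^2 + outer(A[, 2], Bs[, 2], "-")^2 +
            outer(A[, 3], Bs[, 3], "-")^2
      Dmin <- if (is.null(Dmin)) d2 else pmin(Dmin, d2)
    }
    D <- sqrt(Dmin)
    shared <- intersect(ref, sel)
    if (length(shared))
      D[cbind(match(shared, ref), match(shared, sel))] <- NA_real_
    d <- D[!is.na(D) & D > 0 & D <= r_max]
    counts <- counts + tabulate(pmin(pmax(ceiling(d / dr), 1L), n_bins),
                                nbins = n_bins)
  }
  counts
}

#' Decompose an RDF into solvation shells
#'
#' Peaks of the (optionally smoothed) g(r) with prominence at least
#' `min_prominence` define shells; each shell is bounded by the flanking
#' local minima (or by r = 0 / r_max at the profile ends).
#'
#' @param rdf a [compute_rdf()] object.
#' @param smooth_window centred moving-average window in bins (odd; 1 =
#'   no smoothing).
#' @param min_prominence minimum peak height above the higher of its two
#'   bounding minima.
#' @return object of class `ShellSet`: data.frame with `peak_r`, `peak_g`,
#'   `left_min_r`, `right_min_r` (zero rows when no peak qualifies).
#' @export
detect_shells <- function(rdf, smooth_window = 3, min_prominence = 0.05) {
  g <- rdf$g
  if (smooth_window > 1) {
    w <- rep(1 / smooth_window, smooth_window)
    gs <- as.numeric(stats::filter(g, w, sides = 2))
    gs[is.na(gs)] <- g[is.na(gs)]
  } else gs <- g
  pk <- pracma::findpeaks(gs, nups = 1, ndowns = 1)
  empty <- structure(data.frame(peak_r = numeric(0), peak_g = numeric(0),
                                left_min_r = numeric(0),
                                right_min_r = numeric(0)),
                     class = c("ShellSet", "data.frame"))
  if (is.null(pk)) return(empty)
  pk <- pk[order(pk[, 2]), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(pk))) {
    p <- pk[i, 2]
    # walk to the flanking local minima of the smoothed profile
    l <- p; while (l > 1L && gs[l - 1L] <= gs[l]) l <- l - 1L
    r <- p; while (r < length(gs) && gs[r + 1L] <= gs[r]) r <- r + 1L
    prom <- gs[p] - max(gs[l], gs[r])
    if (prom < min_prominence) next
    out[[length(out) + 1L]] <- data.frame(
      peak_r = rdf$r[p], peak_g = g[p],
      left_min_r = if (l == 1L) 0 else rdf$r[l],
      right_min_r = if (r == length(gs)) rdf$r_max else rdf$r[r])
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$peak_r), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("ShellSet", "data.frame"))
}

#' Coordination number N(r_cut)
#'
#' Mean number of selection atoms within `r_cut` of a reference atom,
#' obtained from the raw RDF pair counts (equivalently
#' rho_sel * integral of 4 pi r^2 g(r) dr up to r_cut, with the binned
#' discretisation).
#'
#' @param rdf a [compute_rdf()] object.
#' @param r_cut cutoff radius (Angstrom, at most r_max).
#' @return mean neighbour count per reference atom.
#' @export
coordination_number <- function(rdf, r_cut) {
  stopifnot(r_cut <= rdf$r_max + 1e-9)
  keep <- rdf$bin_edges[-1] <= r_cut + 1e-9
  sum(rdf$counts[keep]) / (rdf$n_ref * rdf$n_frames)
}

#' Potential of mean force from an RDF
#'
#' W(r) = -kB T ln g(r), the reversible work to bring a pair from bulk to
#' separation r.  Bins with g = 0 are masked (W = NA).
#'
#' @param rdf a [compute_rdf()] object.
#' @param temperature temperature in K.
#' @return object of class `PMFProfile` with `r`, `W` (kJ/mol), `g`,
#'   `temperature`, `mask` (TRUE where g = 0).
#' @export
pmf_from_rdf <- function(rdf, temperature = DEFAULT_TEMPERATURE) {
  stopifnot(temperature > 0)
  mask <- rdf$g <= 0
  W <- rep(NA_real_, length(rdf$g))
  W[!mask] <- -KB_KJMOL * temperature * log(rdf$g[!mask])
  structure(list(r = rdf$r, W = W, g = rdf$g, temperature = temperature,
                 mask = mask),
            class = "PMFProfile")
}

#' RDF-derived binding energies (one shell / combined shells)
#'
#' Per-shell binding energy is the PMF well depth at the shell peak
#' relative to bulk, kB T ln g(peak) (positive for an attractive shell,
#' g > 1).  `mode = "one_shell"` reports the first shell only;
#' `mode = "combined_15A"` sums all shells whose peak lies within
#' `r_limit` (default 15 Angstrom).  The estimator is deliberately
#' pluggable via `estimator`; see the methods vignette for why absolute
#' magnitudes from other (unpublished) estimators are not comparable.
#'
#' @param pmf a [pmf_from_rdf()] object.
#' @param shells a [detect_shells()] object derived from the same RDF.
#' @param mode `"one_shell"` or `"combined_15A"`.
#' @param r_limit inclusion limit for combined mode (Angstrom).
#' @param estimator function(g_peak, temperature) -> kJ/mol; default
#'   PMF well depth.
#' @return object of class `BindingEnergy` with `per_shell` (kJ/mol, one
#'   per detected shell within r_limit), `value` (per mode), `combined`,
#'   `one_shell`, `mode`, `r_limit`, `warned` (TRUE when no shell found).
#' @export
binding_energy <- function(pmf, shells, mode = c("one_shell", "combined_15A"),
                           r_limit = 15, estimator = NULL) {
  mode <- match.arg(mode)
  if (is.null(estimator))
    estimator <- function(g_peak, temperature)
      KB_KJMOL * temperature * log(g_peak)
  warned <- FALSE
  if (!nrow(shells)) {
    warning("empty shell set: binding energy 0")
    warned <- TRUE
    per_shell <- numeric(0)
  } else {
    keep <- shells$peak_r <= r_limit + 1e-9
    per_shell <- vapply(shells$peak_g[keep], estimator, numeric(1),
                        temperature = pmf$temperature)
  }
  one_shell <- if (length(per_shell)) per_shell[1] else 0
  combined <- sum(per_shell)
  structure(list(per_shell = per_shell,
                 one_shell = one_shell, combined = combined,
                 value = if (mode == "one_shell") one_shell else combined,
                 mode = mode, r_limit = r_limit,
                 temperature = pmf$temperature, warned = warned),
            class = "BindingEnergy")
}

#' Block-averaged binding-energy uncertainty
#'
#' Splits the trajectory into `n_blocks` contiguous blocks, recomputes
#' RDF -> shells -> binding energy per block, and reports the mean and
#' standard deviation across blocks.
#'
#' @inheritParams compute_rdf
#' @param n_blocks number of contiguous blocks (>= 3).
#' @param mode,r_limit passed to [binding_energy()].
#' @param temperature K.
#' @param ... passed to [detect_shells()].
#' @return list with `mean`, `sd`, `per_block` (kJ/mol).
#' @export
binding_energy_blocked <- function(traj, ref, sel, r_max = 15, dr = 0.1,
                                   n_blocks = 3, mode = "one_shell",
                                   r_limit = 15,
                                   temperature = DEFAULT_TEMPERATURE, ...) {
  stopifnot(n_blocks >= 3, traj$n_frames >= n_blocks)
  bounds <- floor(seq(0, traj$n_frames, length.out = n_blocks + 1L))
  vals <- vapply(seq_len(n_blocks), function(b) {
    fr <- (bounds[b] + 1L):bounds[b + 1L]
    sub <- new_trajectory(traj$coords[fr, , , drop = FALSE],
                          traj$box[fr, , drop = FALSE], dt = traj$dt)
    rdf <- compute_rdf(sub, ref, sel, r_max = r_max, dr = dr)
    sh <- detect_shells(rdf, ...)
    suppressWarnings(
      binding_energy(pmf_from_rdf(rdf, temperature), sh, mode = mode,
                     r_limit = r_limit)$value)
  }, numeric(1))
  list(mean = mean(vals), sd = stats::sd(vals), per_block = vals)
}
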