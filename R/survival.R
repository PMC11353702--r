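# Residence kinetics: shell occupancy, survival probability SP(tau),
# exponential decay fits and cross-system ranking (rank 1 = longest SP).

#' Shell occupancy matrix
#'
#' `occupancy[f, i]` is TRUE when mobile atom i lies within `shell_radius`
#' (minimum-image) of any reference atom at frame f.
#'
#' @param traj a [new_trajectory()] object.
#' @param ref,mobile 1-based atom index vectors, non-empty.
#' @param shell_radius shell radius (Angstrom), at most half the smallest
#'   box length.
#' @param reference optional text describing the reference selection.
#' @return object of class `OccupancyMatrix`: logical matrix `occ`
#'   (frames x mobile), plus `shell_radius`, `reference`, `dt`, `t0`.
#' @export
shell_occupancy <- function(traj, ref, mobile, shell_radius,
                            reference = "reference selection") {
  if (!length(ref) || !length(mobile)) stop("empty selection")
  if (shell_radius > min(traj$box) / 2)
    stop("shell_radius exceeds half the smallest box length")
  occ <- matrix(FALSE, traj$n_frames, length(mobile))
  for (f in seq_len(traj$n_frames)) {
    D <- min_image_dist(traj$coords[f, ref, , drop = FALSE],
                        traj$coords[f, mobile, , drop = FALSE],
                        traj$box[f, ])
    occ[f, ] <- apply(D, 2L, min) <= shell_radius
  }
  structure(list(occ = occ, shell_radius = shell_radius,
                 reference = reference, dt = traj$dt, t0 = traj$t0),
            class = "OccupancyMatrix")
}

#' Wrap a raw logical matrix as an OccupancyMatrix
#'
#' Convenience for feeding ground-truth occupancy (e.g. from the Markov
#' binder generator) straight into [survival_probability()].
#'
#' @param occ logical frames x particles matrix.
#' @param dt frame spacing (ns).
#' @param shell_radius,reference metadata carried along.
#' @export
as_occupancy <- function(occ, dt = 1, shell_radius = NA_real_,
                         reference = "external") {
  structure(list(occ = as.matrix(occ), shell_radius = shell_radius,
                 reference = reference, dt = dt, t0 = 0),
            class = "OccupancyMatrix")
}

# fill FALSE-gaps of length <= tol that are flanked by TRUE on both sides
.fill_gaps <- function(x, tol) {
  if (tol <= 0L || !any(x)) return(x)
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (!r$values[k] && r$lengths[k] <= tol && k > 1L &&
        k < length(r$values))
      x[starts[k]:ends[k]] <- TRUE
  }
  x
}

#' Survival probability of shell residence
#'
#' SP(tau) is the average over time origins t of the fraction of particles
#' occupying the shell at t that remain continuously inside through t+tau.
#' With `intermittency > 0`, interior exits of at most that many frames
#' are tolerated (the occupancy series is gap-filled before the strict
#' computation).  Origins are every `origin_stride`-th frame in
#' `1 .. n_frames - max_lag`, so every lag is averaged over the same
#' origin set and SP is non-increasing by construction; SP(0) = 1.
#'
#' @param occ an [shell_occupancy()] / [as_occupancy()] object.
#' @param max_lag largest lag in frames (default `floor(n_frames / 2)`).
#' @param intermittency tolerated gap length in frames (default 0,
#'   strictly continuous residence).
#' @param origin_stride spacing between time origins in frames.
#' @return object of class `SurvivalCurve`: `lags` (ns), `lag_frames`,
#'   `sp`, `n_origins`, `auc` (ns, trapezoidal), `dt`.
#' @export
survival_probability <- function(occ, max_lag = NULL, intermittency = 0,
                                 origin_stride = 1) {
  M <- occ$occ
  n <- nrow(M); m <- ncol(M)
  if (is.null(max_lag)) max_lag <- max(1L, floor(n / 2))
  if (max_lag >= n) stop("max_lag must be < n_frames")
  if (intermittency > 0)
    M <- apply(M, 2L, .fill_gaps, tol = as.integer(intermittency))
  # L[t, i]: length of the continuous occupied run starting at frame t
  L <- matrix(0L, n, m)
  L[n, ] <- as.integer(M[n, ])
  for (t in (n - 1L):1L) L[t, ] <- ifelse(M[t, ], L[t + 1L, ] + 1L, 0L)
  origins <- seq.int(1L, n - max_lag, by = origin_stride)
  num <- numeric(max_lag + 1L)
  n_orig <- 0L
  for (t in origins) {
    Nt <- sum(M[t, ])
    if (Nt == 0L) next
    n_orig <- n_orig + 1L
    h <- tabulate(pmin(L[t, M[t, ]], max_lag + 1L), nbins = max_lag + 1L)
    # survivors beyond lag tau: Nt - #(runs of length <= tau)
    cum <- cumsum(h)
    num <- num + c(Nt, Nt - cum[seq_len(max_lag)]) / Nt
  }
  if (n_orig == 0L) stop("no occupants at any time origin")
  sp <- num / n_orig
  lags <- (0:max_lag) * occ$dt
  structure(list(lags = lags, lag_frames = 0:max_lag, sp = sp,
                 n_origins = rep(n_orig, max_lag + 1L),
                 auc = pracma::trapz(lags, sp), dt = occ$dt),
            class = "SurvivalCurve")
}

#' Exponential decay fit of a survival curve
#'
#' Least-squares fit of ln SP versus lag over the fit window; returns the
#' decay rate k (1/ns) and residence time tau = 1/k (ns).  The default
#' window runs from lag 0 to the first lag where SP drops below
#' `sp_floor`, keeping the fit in the regime where log-SP noise is small.
#'
#' @param curve a [survival_probability()] object.
#' @param fit_range optional length-2 lag window in ns.
#' @param sp_floor smallest SP included when `fit_range` is NULL.
#' @return list with `k` (1/ns), `tau` (ns), `n_points`, `r_squared`.
#' @export
fit_decay <- function(curve, fit_range = NULL, sp_floor = 0.1) {
  keep <- curve$sp > 0
  if (is.null(fit_range)) keep <- keep & curve$sp >= sp_floor
  else keep <- keep & curve$lags >= fit_range[1] & curve$lags <= fit_range[2]
  if (sum(keep) < 5L) {
    # fall back to every positive point before erroring out
    keep <- curve$sp > 0
    if (!is.null(fit_range))
      keep <- keep & curve$lags >= fit_range[1] & curve$lags <= fit_range[2]
  }
  if (sum(keep) < 5L)
    stop("fewer than 5 positive SP points in the fit window")
  x <- curve$lags[keep]; y <- log(curve$sp[keep])
  fit <- stats::lm(y ~ x)
  k <- -unname(stats::coef(fit)[2])
  if (!is.finite(k) || k < 0) k <- 0
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  list(k = k, tau = if (k > 0) 1 / k else Inf, n_points = sum(keep),
       r_squared = r2)
}

#' Rank systems by survival (1 = longest)
#'
#' Orders a named set of survival curves by decreasing area under SP(tau)
#' (ties broken by fitted residence time, then by name), assigning rank 1
#' to the longest-lived system.
#'
#' @param curves named list of [survival_probability()] objects on a
#'   common lag grid.
#' @param statistic `"auc"` (default) or `"tau"`.
#' @return data.frame with `name`, `auc` (ns), `tau` (ns), `rank`.
#' @export
rank_systems <- function(curves, statistic = c("auc", "tau")) {
  statistic <- match.arg(statistic)
  stopifnot(length(curves) >= 2L, !is.null(names(curves)),
            all(nzchar(names(curves))))
  grids <- lapply(curves, `[[`, "lags")
  if (!all(vapply(grids[-1], function(g)
        isTRUE(all.equal(g, grids[[1]])), logical(1))))
    stop("survival curves are on incomparable lag grids")
  auc <- vapply(curves, `[[`, numeric(1), "auc")
  tau <- vapply(curves, function(cu)
    tryCatch(fit_decay(cu)$tau, error = function(e) NA_real_), numeric(1))
  key <- if (statistic == "auc") auc else tau
  ord <- order(-key, -ifelse(is.na(tau), -Inf, tau), names(curves))
  out <- data.frame(name = names(curves)[ord], auc = auc[ord],
                    tau = tau[ord], rank = seq_along(curves),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
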