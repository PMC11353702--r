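# Interaction networks: salt-bridge detection and diffing, residue-pair
# and ring-centroid distance series, contact-event extraction and the
# duration/frequency classification of ion coordination.

#' Detect salt bridges over a trajectory
#'
#' For every acidic-basic residue pair, a frame qualifies when any
#' carboxylate-oxygen to basic-nitrogen minimum-image distance is at most
#' `cutoff` (default 3.2 Angstrom, the O-N criterion used throughout).
#' Occupancy is the qualifying-frame fraction; a bridge is listed when its
#' occupancy reaches `present_threshold`.  Intra- and inter-chain pairs
#' are both reported, tagged by chain pair.
#'
#' @param traj a [new_trajectory()] object.
#' @param topology matching topology.
#' @param classes a [classify_residues()] object.
#' @param cutoff O-N distance cutoff (Angstrom).
#' @param present_threshold minimum occupancy for a bridge to be listed.
#' @return object of class `SaltBridgeNetwork`: data.frame `bridges`
#'   (acidic_uid, basic_uid, chain_pair, occupancy, min_distance), plus
#'   `cutoff`, `present_threshold`, `n_frames`.
#' @export
detect_salt_bridges <- function(traj, topology, classes, cutoff = 3.2,
                                present_threshold = 0.05) {
  if (!length(classes$acidic) || !length(classes$basic)) {
    warning("no acidic or no basic residues: empty network")
    return(structure(list(
      bridges = data.frame(acidic_uid = character(0),
                           basic_uid = character(0),
                           chain_pair = character(0),
                           occupancy = numeric(0),
                           min_distance = numeric(0),
                           stringsAsFactors = FALSE),
      cutoff = cutoff, present_threshold = present_threshold,
      n_frames = traj$n_frames), class = "SaltBridgeNetwork"))
  }
  rows <- list()
  for (ac in classes$acidic) for (ba in classes$basic) {
    qual <- logical(traj$n_frames)
    dmin_all <- Inf
    for (f in seq_len(traj$n_frames)) {
      D <- min_image_dist(traj$coords[f, ac$atom_idx, , drop = FALSE],
                          traj$coords[f, ba$atom_idx, , drop = FALSE],
                          traj$box[f, ])
      dm <- min(D)
      qual[f] <- dm <= cutoff
      dmin_all <- min(dmin_all, dm)
    }
    occ <- mean(qual)
    if (occ >= present_threshold)
      rows[[length(rows) + 1L]] <- data.frame(
        acidic_uid = ac$uid, basic_uid = ba$uid,
        chain_pair = if (ac$chain_id == ba$chain_id)
          paste0("intra:", ac$chain_id)
        else paste0("inter:", ac$chain_id, "-", ba$chain_id),
        occupancy = occ, min_distance = dmin_all,
        stringsAsFactors = FALSE)
  }
  bridges <- if (length(rows)) do.call(rbind, rows) else
    data.frame(acidic_uid = character(0), basic_uid = character(0),
               chain_pair = character(0), occupancy = numeric(0),
               min_distance = numeric(0), stringsAsFactors = FALSE)
  bridges <- bridges[order(bridges$acidic_uid, bridges$basic_uid), ,
                     drop = FALSE]
  rownames(bridges) <- NULL
  structure(list(bridges = bridges, cutoff = cutoff,
                 present_threshold = present_threshold,
                 n_frames = traj$n_frames),
            class = "SaltBridgeNetwork")
}

#' @export
print.SaltBridgeNetwork <- function(x, ...) {
  cat("SaltBridgeNetwork:", nrow(x$bridges), "bridge(s), cutoff",
      x$cutoff, "A, occupancy threshold", x$present_threshold, "\n")
  invisible(x)
}

.bridge_key <- function(bridges)
  paste(bridges$acidic_uid, bridges$basic_uid, bridges$chain_pair,
        sep = "|")

#' Diff two salt-bridge networks
#'
#' Partitions the bridge sets of a native and a co-solvent network into
#' conserved (in both), lost (native only) and gained (other only),
#' keyed by (acidic residue, basic residue, chain pair).
#'
#' @param native,other [detect_salt_bridges()] networks built with
#'   identical cutoff and occupancy threshold.
#' @return object of class `NetworkDiff`: data.frames `conserved`,
#'   `gained`, `lost` and a `totals` named vector.
#' @export
diff_networks <- function(native, other) {
  if (!isTRUE(all.equal(native$cutoff, other$cutoff)) ||
      !isTRUE(all.equal(native$present_threshold, other$present_threshold)))
    stop("networks built with different cutoff/threshold parameters")
  kn <- .bridge_key(native$bridges); ko <- .bridge_key(other$bridges)
  conserved <- native$bridges[kn %in% ko, , drop = FALSE]
  lost <- native$bridges[!kn %in% ko, , drop = FALSE]
  gained <- other$bridges[!ko %in% kn, , drop = FALSE]
  rownames(conserved) <- rownames(lost) <- rownames(gained) <- NULL
  structure(list(conserved = conserved, gained = gained, lost = lost,
                 totals = c(native = nrow(native$bridges),
                            other = nrow(other$bridges),
                            conserved = nrow(conserved),
                            gained = nrow(gained), lost = nrow(lost))),
            class = "NetworkDiff")
}

#' @export
print.NetworkDiff <- function(x, ...) {
  cat("NetworkDiff:", x$totals["conserved"], "conserved,",
      x$totals["gained"], "gained,", x$totals["lost"], "lost\n")
  invisible(x)
}

#' Per-frame distance between two selections
#'
#' `"min_atom_pair"` reports the smallest minimum-image atom-pair distance
#' per frame; `"centroid"` the minimum-image distance between the
#' unweighted selection centroids.  The series range (max - min) is
#' attached for at-a-glance stability statements such as catalytic-triad
#' distances staying within 2 Angstrom.
#'
#' @param traj a [new_trajectory()] object.
#' @param sel_a,sel_b non-empty 1-based atom index vectors.
#' @param mode `"min_atom_pair"` or `"centroid"`.
#' @return object of class `DistanceSeries`: `t` (ns), `d` (Angstrom),
#'   `range`, `mode`, `dt`.
#' @export
distance_series <- function(traj, sel_a, sel_b,
                            mode = c("min_atom_pair", "centroid")) {
  mode <- match.arg(mode)
  if (!length(sel_a) || !length(sel_b)) stop("empty selection")
  d <- numeric(traj$n_frames)
  for (f in seq_len(traj$n_frames)) {
    box <- traj$box[f, ]
    if (mode == "min_atom_pair") {
      d[f] <- min(min_image_dist(traj$coords[f, sel_a, , drop = FALSE],
                                 traj$coords[f, sel_b, , drop = FALSE],
                                 box))
    } else {
      ca <- colMeans(matrix(traj$coords[f, sel_a, ], ncol = 3L))
      cb <- colMeans(matrix(traj$coords[f, sel_b, ], ncol = 3L))
      d[f] <- sqrt(sum(minimum_image_displacement(ca, cb, box)^2))
    }
  }
  structure(list(t = frame_times(traj), d = d, range = max(d) - min(d),
                 mode = mode, dt = traj$dt),
            class = "DistanceSeries")
}

#' Ring-centroid distance series
#'
#' Minimum-image distance between the unweighted centroids of two
#' registered aromatic rings, per frame: the quantity tested against the
#' 3.7-6 Angstrom pi-stacking window.
#'
#' @param traj a [new_trajectory()] object.
#' @param ring_a,ring_b ordered ring atom index vectors (>= 5 atoms), as
#'   stored in [classify_residues()] aromatic entries.
#' @return a `DistanceSeries` (centroid mode).
#' @export
ring_centroid_series <- function(traj, ring_a, ring_b) {
  if (length(ring_a) < 5L || length(ring_b) < 5L)
    stop("aromatic rings must have >= 5 atoms")
  distance_series(traj, ring_a, ring_b, mode = "centroid")
}

#' Extract contact events from a distance series
#'
#' A frame qualifies under `criterion = list(r_max = x)` when d <= x, or
#' under `criterion = list(window = c(lo, hi))` when lo <= d <= hi.
#' Events are maximal runs of qualifying frames; runs separated by at most
#' `gap_tolerance` disqualifying frames are merged.  Durations are frame
#' counts times dt.
#'
#' @param series a [distance_series()] object (or numeric vector with a
#'   `dt` attribute defaulting to 1 ns).
#' @param criterion list with `r_max` or `window`.
#' @param gap_tolerance merge gap (frames).
#' @return object of class `ContactEventSeries`: data.frame `events`
#'   (`start_frame`, `end_frame`, `start_ns`, `end_ns`, `duration_ns`),
#'   plus `criterion`, `gap_tolerance`, `qualifying` (logical per frame),
#'   `dt`.
#' @export
extract_events <- function(series, criterion, gap_tolerance = 0) {
  if (inherits(series, "DistanceSeries")) {
    d <- series$d; dt <- series$dt; t0 <- series$t[1]
  } else {
    d <- as.numeric(series)
    dt <- attr(series, "dt"); if (is.null(dt)) dt <- 1
    t0 <- 0
  }
  if (length(d) < 2L) stop("series must have >= 2 frames")
  qual <- if (!is.null(criterion$r_max)) d <= criterion$r_max
          else if (!is.null(criterion$window))
            d >= criterion$window[1] & d <= criterion$window[2]
          else stop("criterion must supply r_max or window")
  merged <- .fill_gaps(qual, as.integer(gap_tolerance))
  r <- rle(merged)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  on <- which(r$values)
  events <- data.frame(start_frame = starts[on], end_frame = ends[on])
  events$start_ns <- t0 + (events$start_frame - 1L) * dt
  events$end_ns <- t0 + (events$end_frame - 1L) * dt
  events$duration_ns <- (events$end_frame - events$start_frame + 1L) * dt
  structure(list(events = events, criterion = criterion,
                 gap_tolerance = gap_tolerance, qualifying = qual,
                 dt = dt),
            class = "ContactEventSeries")
}

#' Classify coordination behaviour from contact events
#'
#' Applies the duration/frequency rules used for ion coordination at
#' gating residues: `prolonged` when any event exceeds `prolonged_ns`;
#' `infrequent_short` when every event is shorter than `short_ns` and
#' there are fewer than `infrequent_count` events; `intermediate`
#' otherwise.
#'
#' @param events an [extract_events()] object.
#' @param short_ns short-event threshold (default 5 ns).
#' @param prolonged_ns prolonged-event threshold (default 50 ns).
#' @param infrequent_count event-count threshold (default 10).
#' @return object of class `CoordinationLabel`: `label`, `n_events`,
#'   `max_duration_ns`.
#' @export
classify_coordination <- function(events, short_ns = 5, prolonged_ns = 50,
                                  infrequent_count = 10) {
  ev <- events$events
  n <- nrow(ev)
  max_dur <- if (n) max(ev$duration_ns) else 0
  label <- if (max_dur > prolonged_ns) "prolonged"
           else if (max_dur < short_ns && n < infrequent_count)
             "infrequent_short"
           else "intermediate"
  structure(list(label = label, n_events = n, max_duration_ns = max_dur),
            class = "CoordinationLabel")
}

#' @export
print.CoordinationLabel <- function(x, ...) {
  cat("CoordinationLabel:", x$label, "(", x$n_events, "event(s), max",
      x$max_duration_ns, "ns )\n")
  invisible(x)
}
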