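# Shared fixtures, all generated in code.

kT_at <- function(temperature = 323.15) KB_KJMOL * temperature

# minimal PDB text: a Gly-Glu dipeptide-ish toy plus a Lys on chain B
toy_pdb_lines <- function(cryst = TRUE) {
  lines <- character(0)
  if (cryst)
    lines <- c(lines, sprintf("%-6s%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s%4d",
                              "CRYST1", 50, 60, 70, 90, 90, 90, "P 1", 1))
  atom <- function(serial, name, res, chain, resno, x, y, z, elem)
    sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial, name, res, chain, resno, x, y, z, 1, 0, elem)
  c(lines,
    atom(1, " CA ", "GLY", "A", 1, 10, 10, 10, "C"),
    atom(2, " CA ", "GLU", "A", 2, 13, 10, 10, "C"),
    atom(3, " OE1", "GLU", "A", 2, 14, 11, 10, "O"),
    atom(4, " OE2", "GLU", "A", 2, 14, 9, 10, "O"),
    atom(5, " CA ", "LYS", "B", 1, 20, 20, 20, "C"),
    atom(6, " NZ ", "LYS", "B", 1, 22, 20, 20, "N"),
    "END")
}

write_toy_pdb <- function(path = tempfile(fileext = ".pdb"), ...) {
  writeLines(toy_pdb_lines(...), path)
  path
}

# a trajectory with atoms pinned at fixed positions
pinned_trajectory <- function(positions, n_frames = 3, box = c(100, 100, 100),
                              dt = 1) {
  positions <- as.matrix(positions)
  coords <- array(NA_real_, dim = c(n_frames, nrow(positions), 3L))
  for (f in seq_len(n_frames)) coords[f, , ] <- positions
  new_trajectory(coords, box, dt = dt)
}

# hand-made RadialDistribution with a prescribed g profile
fake_rdf <- function(g, dr = 0.1, rho_sel = 0.01, n_ref = 1, n_frames = 1) {
  edges <- seq(0, length(g) * dr, by = dr)
  r <- (edges[-1] + edges[-length(edges)]) / 2
  shell_vol <- (4 / 3) * pi * (edges[-1]^3 - edges[-length(edges)]^3)
  counts <- g * rho_sel * shell_vol * n_ref * n_frames
  structure(list(bin_edges = edges, r = r, g = g, counts = counts,
                 rho_sel = rho_sel, n_frames = n_frames, n_ref = n_ref,
                 n_sel = 1, dr = dr, r_max = max(edges)),
            class = "RadialDistribution")
}

# survival curve from an exact SP(tau) function
fake_curve <- function(sp_fun, max_lag = 100, dt = 1) {
  lags <- (0:max_lag) * dt
  sp <- sp_fun(lags)
  structure(list(lags = lags, lag_frames = 0:max_lag, sp = sp,
                 n_origins = rep(1000L, max_lag + 1L),
                 auc = pracma::trapz(lags, sp), dt = dt),
            class = "SurvivalCurve")
}

# events object with prescribed durations
fake_events <- function(durations_ns) {
  structure(list(events = data.frame(duration_ns = durations_ns),
                 criterion = list(), gap_tolerance = 0,
                 qualifying = logical(0), dt = 1),
            class = "ContactEventSeries")
}
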