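test_that("binned RDF counts equal the all-images brute force", {
  tr <- generate_ideal_gas(60, c(18, 18, 18), 8, seed = 14)
  # disjoint reference/selection
  c1 <- compute_rdf(tr, 1:25, 26:60, r_max = 9, dr = 0.25)$counts
  expect_equal(c1, rdf_counts_brute_force(tr, 1:25, 26:60, r_max = 9,
                                          dr = 0.25))
  # overlapping sets: self-pairs must be excluded identically
  c2 <- compute_rdf(tr, 1:40, 20:60, r_max = 9, dr = 0.25)$counts
  expect_equal(c2, rdf_counts_brute_force(tr, 1:40, 20:60, r_max = 9,
                                          dr = 0.25))
})

test_that("two pinned atoms give a single populated bin at their distance", {
  tr <- pinned_trajectory(rbind(c(10, 10, 10), c(15, 10, 10)), n_frames = 4)
  rdf <- compute_rdf(tr, 1L, 2L, r_max = 10, dr = 0.1)
  hot <- which(rdf$counts > 0)
  expect_length(hot, 1L)
  expect_lt(abs(rdf$r[hot] - 5), 0.1)
  expect_equal(sum(rdf$counts), 4)  # one pair per frame
})

test_that("r_max beyond half the box is rejected, empty selections error", {
  tr <- generate_ideal_gas(10, c(20, 20, 20), 2, seed = 1)
  expect_error(compute_rdf(tr, 1:5, 6:10, r_max = 11), "half the smallest")
  expect_error(compute_rdf(tr, integer(0), 6:10, r_max = 5), "empty")
})

test_that("shell detection finds constructed peaks and ignores flat input", {
  # flat g = 1 has no shells
  expect_equal(nrow(detect_shells(fake_rdf(rep(1, 150)))), 0L)
  # two Gaussian shells at 2.7 and 4.0 A over a flat background
  r <- (1:150 - 0.5) * 0.1
  g <- 1 + 2.5 * exp(-(r - 2.7)^2 / (2 * 0.15^2)) +
       1.2 * exp(-(r - 4.0)^2 / (2 * 0.2^2))
  sh <- detect_shells(fake_rdf(g))
  expect_equal(nrow(sh), 2L)
  expect_lt(abs(sh$peak_r[1] - 2.7), 0.1 + 1e-9)
  expect_lt(abs(sh$peak_r[2] - 4.0), 0.1 + 1e-9)
  expect_true(all(sh$left_min_r < sh$peak_r & sh$peak_r < sh$right_min_r))
  # single delta-like shell is bracketed by its bounds
  g1 <- rep(1e-12, 100); g1[30] <- 8
  sh1 <- detect_shells(fake_rdf(g1), smooth_window = 1)
  expect_equal(nrow(sh1), 1L)
})

test_that("coordination numbers match the analytic ideal gas and a delta shell", {
  tr <- generate_ideal_gas(400, c(30, 30, 30), 60, seed = 9)
  rdf <- compute_rdf(tr, 1:400, 1:400, r_max = 10, dr = 0.1)
  rho <- 400 / 30^3
  expect_lt(abs(coordination_number(rdf, 5) -
                rho * (4 / 3) * pi * 125) / (rho * (4 / 3) * pi * 125), 0.05)
  # 6 neighbours pinned on a shell of radius 3
  centre <- c(15, 15, 15)
  nbrs <- rbind(c(3, 0, 0), c(-3, 0, 0), c(0, 3, 0), c(0, -3, 0),
                c(0, 0, 3), c(0, 0, -3))
  tr2 <- pinned_trajectory(rbind(centre, sweep(nbrs, 2, centre, "+")),
                           n_frames = 2, box = c(30, 30, 30))
  rdf2 <- compute_rdf(tr2, 1L, 2:7, r_max = 10, dr = 0.2)
  expect_equal(coordination_number(rdf2, 4), 6)
  # direct neighbour counting agrees with the binned integral
  direct <- mean(vapply(1:60, function(f) {
    D <- min_image_dist(matrix(tr$coords[f, 1:10, ], ncol = 3),
                        matrix(tr$coords[f, , ], ncol = 3), c(30, 30, 30))
    sum(D > 0 & D <= 5) / 10
  }, numeric(1)))
  rdf3 <- compute_rdf(tr, 1:10, 1:400, r_max = 10, dr = 0.1)
  expect_lt(abs(coordination_number(rdf3, 5) - direct), 0.2)
})

test_that("PMF transform hits the analytic kBT values and masks g = 0", {
  rdf <- fake_rdf(c(1, exp(1), exp(-1), 0))
  pmf <- pmf_from_rdf(rdf, temperature = 323.15)
  expect_equal(pmf$W[1], 0)
  expect_equal(pmf$W[2], -0.0083144621 * 323.15, tolerance = 1e-10)
  expect_equal(round(pmf$W[2], 3), -2.687)
  expect_equal(pmf$W[3], +0.0083144621 * 323.15, tolerance = 1e-10)
  expect_true(is.na(pmf$W[4]) && pmf$mask[4])
  # temperature scales every value linearly
  pmf2 <- pmf_from_rdf(rdf, temperature = 2 * 323.15)
  expect_equal(pmf2$W[2:3], 2 * pmf$W[2:3])
})

test_that("binding energies follow the per-shell PMF depth and sum within 15 A", {
  r <- (1:160 - 0.5) * 0.1
  g <- rep(1, 160)
  g[abs(r - 3) < 0.05] <- exp(1)   # shell of depth kB T at 3 A
  g[abs(r - 6) < 0.05] <- exp(1)   # and at 6 A
  rdf <- fake_rdf(g)
  sh <- detect_shells(rdf, smooth_window = 1)
  expect_equal(nrow(sh), 2L)
  pmf <- pmf_from_rdf(rdf, 323.15)
  kT <- kT_at(323.15)
  one <- binding_energy(pmf, sh, mode = "one_shell")
  both <- binding_energy(pmf, sh, mode = "combined_15A")
  expect_equal(one$value, kT, tolerance = 1e-9)
  expect_equal(both$value, 2 * kT, tolerance = 1e-9)
  expect_equal(both$one_shell, both$per_shell[1])
  # r_limit excludes the outer shell
  inner <- binding_energy(pmf, sh, mode = "combined_15A", r_limit = 4)
  expect_equal(inner$value, kT, tolerance = 1e-9)
  # flat profile: zero energy with a warning flag
  expect_warning(z <- binding_energy(pmf_from_rdf(fake_rdf(rep(1, 50))),
                                     detect_shells(fake_rdf(rep(1, 50)))),
                 "empty shell")
  expect_equal(z$value, 0)
  expect_true(z$warned)
})

test_that("block-averaged binding energy reports a spread over blocks", {
  b <- generate_markov_binder(100, c(40, 40, 40), 120, k_on = 0.3,
                              k_off = 0.05, shell_radius = 4, seed = 8)
  be <- binding_energy_blocked(b$trajectory, b$site_index, b$mobile_index,
                               r_max = 12, dr = 0.2, n_blocks = 3)
  expect_length(be$per_block, 3L)
  expect_true(is.finite(be$mean) && is.finite(be$sd))
  expect_gt(be$mean, 0)  # binding shell is attractive vs bulk
})
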