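test_that("salt-bridge detection applies the 3.2 A O-N cutoff exactly", {
  fx <- build_contact_fixture(list(
    list(type = "saltbridge", distance = 3.1, pattern = rep(TRUE, 8)),
    list(type = "saltbridge", distance = 3.3, pattern = rep(TRUE, 8)),
    list(type = "saltbridge", distance = 3.1,
         pattern = rep(c(TRUE, FALSE), 4))))
  cls <- classify_residues(fx$topology)
  net <- detect_salt_bridges(fx$trajectory, fx$topology, cls, cutoff = 3.2,
                             present_threshold = 0.05)
  expect_equal(nrow(net$bridges), 2L)
  expect_equal(sort(net$bridges$occupancy), c(0.5, 1.0))
  # the 3.3 A pair never qualifies
  expect_false("A:3" %in% net$bridges$acidic_uid)
  # presence threshold above the alternating occupancy drops it
  net2 <- detect_salt_bridges(fx$trajectory, fx$topology, cls,
                              present_threshold = 0.6)
  expect_equal(nrow(net2$bridges), 1L)
  # brute-force qualification for the persistent pair
  o <- cls$acidic[[1]]$atom_idx; n <- cls$basic[[1]]$atom_idx
  manual <- vapply(seq_len(fx$trajectory$n_frames), function(f)
    min(min_image_dist(matrix(fx$trajectory$coords[f, o, ], ncol = 3),
                       matrix(fx$trajectory$coords[f, n, ], ncol = 3),
                       fx$trajectory$box[f, ])) <= 3.2, logical(1))
  expect_equal(net$bridges$occupancy[net$bridges$acidic_uid == "A:1"],
               mean(manual))
})

test_that("empty residue classes give an empty network with a warning", {
  atoms <- data.frame(atom_id = 0:1, atom_name = c("CA", "CB"),
                      element = "C", residue_id = 1L, residue_name = "ALA",
                      chain_id = "A")
  top <- new_topology(atoms)
  tr <- pinned_trajectory(rbind(c(1, 1, 1), c(2, 1, 1)), box = c(10, 10, 10))
  expect_warning(net <- detect_salt_bridges(tr, top,
                                            classify_residues(top)),
                 "empty network")
  expect_equal(nrow(net$bridges), 0L)
})

test_that("network diffs partition into conserved, gained and lost", {
  mk <- function(uids) {
    structure(list(bridges = data.frame(
      acidic_uid = uids, basic_uid = paste0(uids, "b"),
      chain_pair = "intra:A", occupancy = 1, min_distance = 3,
      stringsAsFactors = FALSE),
      cutoff = 3.2, present_threshold = 0.05, n_frames = 10),
      class = "SaltBridgeNetwork")
  }
  d <- diff_networks(mk(c("A:1", "A:3")), mk(c("A:3", "A:5")))
  expect_equal(d$lost$acidic_uid, "A:1")
  expect_equal(d$conserved$acidic_uid, "A:3")
  expect_equal(d$gained$acidic_uid, "A:5")
  # identical networks: nothing gained or lost
  d0 <- diff_networks(mk(c("A:1", "A:2")), mk(c("A:1", "A:2")))
  expect_equal(unname(d0$totals[c("gained", "lost")]), c(0, 0))
  # random networks satisfy the partition identities
  set.seed(61)
  for (i in 1:10) {
    a <- mk(sample(paste0("A:", 1:12), 6))
    b <- mk(sample(paste0("A:", 1:12), 6))
    d <- diff_networks(a, b)
    expect_setequal(c(d$conserved$acidic_uid, d$lost$acidic_uid),
                    a$bridges$acidic_uid)
    expect_setequal(c(d$conserved$acidic_uid, d$gained$acidic_uid),
                    b$bridges$acidic_uid)
    expect_length(intersect(d$gained$acidic_uid, d$lost$acidic_uid), 0)
  }
  bad <- mk("A:1"); bad$cutoff <- 4
  expect_error(diff_networks(mk("A:1"), bad), "different cutoff")
})

test_that("distance series agree with brute-force scans and centroids", {
  tr <- pinned_trajectory(rbind(c(5, 5, 5), c(9, 5, 5)), n_frames = 3,
                          box = c(50, 50, 50))
  ds <- distance_series(tr, 1L, 2L)
  expect_equal(ds$d, rep(4, 3))
  expect_equal(ds$range, 0)
  # centroid of a symmetric pair is its midpoint
  tr2 <- pinned_trajectory(rbind(c(0, 1, 0), c(0, -1, 0), c(6, 0, 0)),
                           box = c(50, 50, 50))
  expect_equal(distance_series(tr2, 1:2, 3L, mode = "centroid")$d[1], 6)
  # min mode equals an all-pairs scan on random coordinates
  set.seed(67)
  coords <- array(runif(5 * 12 * 3, 0, 40), dim = c(5, 12, 3))
  tr3 <- new_trajectory(coords, c(40, 40, 40))
  ds3 <- distance_series(tr3, 1:5, 6:12)
  manual <- vapply(1:5, function(f)
    min(vapply(1:5, function(i) min(vapply(6:12, function(j)
      brute_force_min_distance(coords[f, i, ], coords[f, j, ],
                               c(40, 40, 40)), numeric(1))), numeric(1))),
    numeric(1))
  expect_equal(ds3$d, manual, tolerance = 1e-12)
})

test_that("ring centroid distances respect geometry and ring-size checks", {
  fx <- build_contact_fixture(list(
    list(type = "ring", distance = 4.5, pattern = rep(TRUE, 2))))
  cls <- classify_residues(fx$topology)
  rs <- ring_centroid_series(fx$trajectory, cls$aromatic[[1]]$atom_idx,
                             cls$aromatic[[2]]$atom_idx)
  expect_equal(rs$d, rep(4.5, 2))
  # concentric rings have zero centroid separation
  th <- 2 * pi * (0:5) / 6
  r1 <- cbind(1.4 * cos(th), 1.4 * sin(th), 0) + 10
  r2 <- cbind(2.8 * cos(th), 2.8 * sin(th), 0) + 10
  tr <- pinned_trajectory(rbind(r1, r2), box = c(50, 50, 50))
  expect_equal(ring_centroid_series(tr, 1:6, 7:12)$d[1], 0, tolerance = 1e-12)
  expect_error(ring_centroid_series(tr, 1:4, 7:12), ">= 5 atoms")
})

test_that("event extraction matches run-length brute force and merges gaps", {
  pat <- c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE)
  d <- ifelse(pat, 3, 10)
  ev0 <- extract_events(structure(d, dt = 1), list(r_max = 5))
  expect_equal(nrow(ev0$events), 2L)
  expect_equal(ev0$events$duration_ns, c(3, 2))
  ev2 <- extract_events(structure(d, dt = 1), list(r_max = 5),
                        gap_tolerance = 2)
  expect_equal(nrow(ev2$events), 1L)
  expect_equal(ev2$events$duration_ns, 7)
  # window criterion
  dw <- c(4.5, 4.5, 7, 2, 4.5)
  evw <- extract_events(structure(dw, dt = 1), list(window = c(3.7, 6)))
  expect_equal(evw$qualifying, c(TRUE, TRUE, FALSE, FALSE, TRUE))
  # random boolean series vs an rle-based oracle, with monotone merging
  set.seed(71)
  for (i in 1:10) {
    q <- runif(80) < 0.45
    dd <- ifelse(q, 1, 9)
    ev <- extract_events(structure(dd, dt = 0.5), list(r_max = 5))
    r <- rle(q)
    expect_equal(nrow(ev$events), sum(r$values))
    expect_equal(ev$events$duration_ns, r$lengths[r$values] * 0.5)
    n_by_gap <- vapply(0:4, function(gt)
      nrow(extract_events(structure(dd, dt = 0.5), list(r_max = 5),
                          gap_tolerance = gt)$events), numeric(1))
    expect_true(all(diff(n_by_gap) <= 0))
  }
})

test_that("coordination labels follow the 5 ns / 50 ns / 10-event rules", {
  expect_equal(classify_coordination(fake_events(rep(3, 4)))$label,
               "infrequent_short")
  expect_equal(classify_coordination(fake_events(60))$label, "prolonged")
  expect_equal(classify_coordination(fake_events(rep(8, 3)))$label,
               "intermediate")
  # boundary cases: thresholds are strict inequalities
  expect_equal(classify_coordination(fake_events(50))$label, "intermediate")
  expect_equal(classify_coordination(fake_events(rep(3, 10)))$label,
               "intermediate")
  expect_equal(classify_coordination(fake_events(numeric(0)))$label,
               "infrequent_short")
})
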