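test_that("PDB topology parsing preserves residues, chains and the cell", {
  path <- write_toy_pdb()
  top <- read_topology(path)
  expect_s3_class(top, "Topology")
  expect_equal(top$n_atoms, 6L)
  expect_equal(top$atoms$atom_id, 0:5)
  expect_equal(top$atoms$chain_id, c("A", "A", "A", "A", "B", "B"))
  expect_equal(top$atoms$residue_name[2], "GLU")
  # CRYST1 against an independent text parse of the same line
  cl <- grep("^CRYST1", readLines(path), value = TRUE)
  expect_equal(top$box_hint,
               as.numeric(strsplit(trimws(substr(cl, 7, 33)), " +")[[1]]))
  # no CRYST1 record -> no hint
  top2 <- read_topology(write_toy_pdb(cryst = FALSE))
  expect_null(top2$box_hint)
})

test_that("trajectory fixture format round-trips coordinates and metadata", {
  tr <- generate_ideal_gas(17, c(25, 30, 35), 5, dt = 0.25, seed = 4)
  path <- tempfile(fileext = ".sstrj")
  write_trajectory_fixture(tr, path)
  tr2 <- read_trajectory(path, format = "fixture")
  expect_equal(tr2$n_frames, 5L)
  expect_equal(tr2$dt, 0.25)
  expect_equal(tr2$coords, tr$coords, tolerance = 1e-5)
  expect_equal(tr2$box, tr$box)
})

test_that("multi-model PDB trajectories load with the CRYST1 box", {
  path <- tempfile(fileext = ".pdb")
  atom_line <- function(serial, x)
    sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
            serial, serial, x, 10, 10, 1, 0)
  writeLines(c(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1",
                       40, 40, 40, 90, 90, 90),
               "MODEL        1", atom_line(1, 1), atom_line(2, 2), "ENDMDL",
               "MODEL        2", atom_line(1, 1.5), atom_line(2, 2.5),
               "ENDMDL", "END"), path)
  top <- read_topology(path)
  tr <- read_trajectory(path, top, format = "pdb", dt = 0.5)
  expect_equal(tr$n_frames, 2L)
  expect_equal(tr$box[1, ], c(40, 40, 40))
  expect_equal(tr$coords[2, 1, 1], 1.5)
  expect_error(read_trajectory(path, top, format = "xtc"), "not supported")
})

test_that("atom-count mismatches between trajectory and topology error", {
  tr <- generate_ideal_gas(4, c(20, 20, 20), 2, seed = 1)
  path <- tempfile(fileext = ".sstrj")
  write_trajectory_fixture(tr, path)
  top <- read_topology(write_toy_pdb())  # 6 atoms
  expect_error(read_trajectory(path, top, format = "fixture"),
               "atom-count mismatch")
})

test_that("selections are ordered, set-algebra consistent and idempotent", {
  top <- read_topology(write_toy_pdb())
  glu <- select_atoms(top, sel(residue_name = "GLU"))
  expect_equal(glu, 2:4)
  carbox <- select_atoms(top, sel(residue_name = c("GLU", "ASP"),
                                  atom_name = c("OD1", "OD2", "OE1", "OE2")))
  expect_equal(top$atoms$atom_name[carbox], c("OE1", "OE2"))
  expect_equal(select_atoms(top, sel_not(sel_all())), integer(0))
  # AND distributes as intersection, OR as union
  a <- sel(residue_name = "GLU"); b <- sel(atom_name = "CA")
  expect_equal(select_atoms(top, sel_and(a, b)),
               intersect(select_atoms(top, a), select_atoms(top, b)))
  expect_equal(select_atoms(top, sel_or(a, b)),
               sort(union(select_atoms(top, a), select_atoms(top, b))))
  expect_equal(select_atoms(top, sel_and(a, a)), select_atoms(top, a))
  expect_error(sel(residue = "GLU"), "unknown selection field")
})

test_that("residue classification covers acidic, basic and aromatic defaults", {
  top <- read_topology(write_toy_pdb())
  cls <- classify_residues(top)
  expect_length(cls$acidic, 1L)
  expect_equal(cls$acidic[[1]]$residue_name, "GLU")
  expect_equal(top$atoms$atom_name[cls$acidic[[1]]$atom_idx],
               c("OE1", "OE2"))
  expect_length(cls$basic, 1L)
  expect_equal(top$atoms$atom_name[cls$basic[[1]]$atom_idx], "NZ")
  # Trp ring has the 9 indole atoms
  trp_names <- c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2")
  atoms <- data.frame(atom_id = 0:8, atom_name = trp_names,
                      element = rep("C", 9), residue_id = 1L,
                      residue_name = "TRP", chain_id = "A")
  cls2 <- classify_residues(new_topology(atoms))
  expect_length(cls2$aromatic[[1]]$atom_idx, 9L)
  # override registers a 5-atom imidazolium ring on a non-standard residue
  atoms3 <- data.frame(atom_id = 0:4,
                       atom_name = c("N1", "C2", "N3", "C4", "C5"),
                       element = c("N", "C", "N", "C", "C"),
                       residue_id = 1L, residue_name = "DIM", chain_id = "A")
  ov <- data.frame(residue_name = "DIM", role = "aromatic",
                   atom_names = "N1,C2,N3,C4,C5")
  cls3 <- classify_residues(new_topology(atoms3), overrides = ov)
  expect_length(cls3$aromatic, 1L)
  expect_error(classify_residues(new_topology(atoms3),
    overrides = data.frame(residue_name = "DIM", role = "aromatic",
                           atom_names = "N1,C2,N3,C4,XX")),
    "unknown atom")
})

test_that("minimum-image displacement wraps, is symmetric and bounded", {
  d <- minimum_image_displacement(c(1, 1, 1), c(99, 99, 99), c(100, 100, 100))
  expect_equal(sqrt(sum(d^2)), sqrt(12))
  expect_equal(minimum_image_displacement(c(5, 5, 5), c(5, 5, 5),
                                          c(50, 50, 50)), c(0, 0, 0))
  set.seed(11)
  box <- c(31, 47, 12)
  for (i in 1:50) {
    a <- runif(3) * box
    b <- runif(3) * box
    d <- minimum_image_displacement(a, b, box)
    # against enumeration of all 27 periodic images
    expect_equal(sqrt(sum(d^2)), brute_force_min_distance(a, b, box),
                 tolerance = 1e-12)
    # antisymmetry and component bound
    expect_equal(d, -minimum_image_displacement(b, a, box))
    expect_true(all(abs(d) <= box / 2 + 1e-12))
    expect_lte(sqrt(sum(d^2)), sqrt(3) / 2 * max(box) + 1e-12)
  }
})

test_that("trajectory construction rejects invalid geometry and time steps", {
  coords <- array(0, dim = c(2, 3, 3))
  expect_error(new_trajectory(coords, c(10, -1, 10)), "box")
  expect_error(new_trajectory(coords, c(10, 10, 10), dt = 0), "dt")
  coords[1, 1, 1] <- NaN
  expect_error(new_trajectory(coords, c(10, 10, 10)), "finite")
})
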