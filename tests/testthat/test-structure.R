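test_that("parsing the two-tripeptide fixture yields the hand-counted atoms", {
  toy <- leu_pair_fixture()
  s <- read_fixture(toy$pdb)
  # ALA has 5 heavy atoms (N, CA, C, O, CB), LEU has 8; two ALA-LEU-ALA
  # chains: 2 * (5 + 8 + 5) = 36
  expect_equal(nrow(s$atoms), 36)
  expect_setequal(unique(s$atoms$side), c("A", "B"))
  expect_equal(sum(s$atoms$is_backbone), 24)  # 4 backbone atoms x 6 residues
  expect_false(any(s$atoms$is_water))
})

test_that("a requested chain missing from the PDB is fatal", {
  toy <- leu_pair_fixture()
  expect_error(read_fixture(toy$pdb, side_a = "A", side_b = "C"),
               "not present")
})

test_that("waters are kept but belong to no side", {
  fx <- make_water_cage_fixture()
  s <- read_fixture(fx$pdb)
  expect_equal(sum(s$atoms$is_water), 1)
  expect_true(is.na(s$atoms$side[s$atoms$is_water]))
  expect_false(s$atoms$is_backbone[s$atoms$is_water])
})

test_that("alternate locations resolve to the highest occupancy", {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00 10.00           N",
    "ATOM      2  CA AALA A   1       1.458   0.000   0.000  0.30 11.00           C",
    "ATOM      3  CA BALA A   1       1.600   0.000   0.000  0.70 12.00           C",
    "ATOM      4  C   ALA A   1       2.200  -1.200   0.000  1.00 13.00           C",
    "ATOM      5  O   ALA A   1       2.850  -2.250   0.000  1.00 14.00           O",
    "ATOM      6  CB  ALA A   1       1.458   0.000   1.530  1.00 15.00           C",
    "ATOM      7  N   ALA B   1       0.000  10.000   0.000  1.00 10.00           N",
    "END")
  s <- read_fixture(lines)
  ca <- s$atoms[s$atoms$name == "CA", ]
  expect_equal(nrow(ca), 1)
  expect_equal(ca$x, 1.6)  # the 0.70-occupancy copy
  expect_equal(ca$b, 12)
})

test_that("covalent bonds of an ideal alanine follow the distance rule", {
  blk <- hotspotRF:::place_residue("ALA", "A", 1, 0, 0, 1)
  pdb <- c(hotspotRF:::format_pdb_lines(blk, rep(20, nrow(blk))), "END")
  # lone chain on side A needs a fake partner chain for parsing
  pdb <- append(pdb, sub(" A   1 ", " B   9 ",
                         sub("^ATOM      1", "ATOM     91", pdb[1])),
                after = 5)
  s <- read_fixture(pdb)
  bonds <- infer_covalent_bonds(s)
  el <- igraph::as_edgelist(bonds$graph)
  nm <- s$atoms$name[match(as.integer(el), s$atoms$atom_id)]
  got <- apply(matrix(nm, ncol = 2), 1,
               function(p) paste(sort(p), collapse = "-"))
  expect_setequal(got, c("CA-N", "C-CA", "C-O", "CA-CB"))
})

test_that("a chain break (C-N beyond 1.9 A) leaves no inter-residue bond", {
  b1 <- hotspotRF:::place_residue("ALA", "A", 1, 0, 0, 1)
  b2 <- hotspotRF:::place_residue("ALA", "A", 2, 10, 0, 1)  # 10 A away
  b3 <- hotspotRF:::place_residue("ALA", "B", 3, 0, 30, 1)
  df <- rbind(b1, b2, b3)
  s <- read_fixture(c(hotspotRF:::format_pdb_lines(df, rep(20, nrow(df))),
                      "END"))
  bonds <- infer_covalent_bonds(s)
  # only intra-residue bonds: 4 per ALA
  expect_equal(igraph::ecount(bonds$graph), 12)
  comp <- igraph::components(bonds$graph)
  expect_equal(comp$no, 3)
})

test_that("bond steps along a linear five-atom chain count as published", {
  # lysine side chain CB-CG-CD-CE-NZ is the chain i-j-k-l-m
  toy <- make_toy_complex(fixture_spec(
    n_residues = 3, seq_a = c("GLY", "LYS", "GLY"),
    seq_b = c("GLY", "LYS", "GLY"), gap = 3.5, seed = 3))
  s <- read_fixture(toy$pdb)
  bonds <- infer_covalent_bonds(s)
  a <- s$atoms[s$atoms$chain == "A" & s$atoms$resno == 2, ]
  id <- function(nm) a$atom_id[a$name == nm]
  expect_equal(bond_steps(bonds, id("CB"), id("CB")), 0L)
  expect_equal(bond_steps(bonds, id("CB"), id("CE"), max_steps = 3), 3L)
  expect_equal(bond_steps(bonds, id("CB"), id("NZ"), max_steps = 3), Inf)
  expect_equal(bond_steps(bonds, id("CB"), id("NZ"), max_steps = 4), 4L)
  # i, j, k, l are nearby atoms of i; m is not
  nb <- nearby_atoms(bonds, id("CB"))
  expect_true(all(c(id("CB"), id("CG"), id("CD"), id("CE")) %in% nb))
  expect_false(id("NZ") %in% nb)
})

test_that("bond_steps matches a Floyd-Warshall oracle and is a metric", {
  toy <- make_toy_complex(fixture_spec(n_residues = 4, seed = 11))
  s <- read_fixture(toy$pdb)
  bonds <- infer_covalent_bonds(s)
  ids <- s$atoms$atom_id
  el <- matrix(as.integer(igraph::as_edgelist(bonds$graph)), ncol = 2)
  d_oracle <- fw_steps(length(ids), el)
  set.seed(5)
  for (k in 1:40) {
    ij <- sample(length(ids), 2)
    expect_equal(bond_steps(bonds, ids[ij[1]], ids[ij[2]], max_steps = Inf),
                 d_oracle[ij[1], ij[2]])
  }
  # symmetry + triangle inequality on the oracle matrix (finite entries)
  expect_equal(d_oracle, t(d_oracle))
  fin <- which(is.finite(d_oracle[1, ]))
  for (i in fin) for (j in fin)
    expect_lte(d_oracle[1, j], d_oracle[1, i] + d_oracle[i, j])
})

test_that("nearby_atoms contains the atom itself and grows with steps", {
  toy <- leu_pair_fixture()
  s <- read_fixture(toy$pdb)
  bonds <- infer_covalent_bonds(s)
  for (a in s$atoms$atom_id[c(1, 8, 20)]) {
    n1 <- nearby_atoms(bonds, a, steps = 1)
    n2 <- nearby_atoms(bonds, a, steps = 2)
    n3 <- nearby_atoms(bonds, a, steps = 3)
    expect_true(a %in% n1)
    expect_true(all(n1 %in% n2) && all(n2 %in% n3))
  }
})

test_that("ring pseudo-atoms sit 0.5 A above and below the centroid", {
  # ideal hexagonal PHE ring in the xy-plane centered at the origin
  ang <- seq(0, 300, by = 60) * pi / 180
  ring <- data.frame(
    name = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
    element = "C", resname = "PHE", chain = "A", resno = 1,
    x = 1.39 * cos(ang), y = 1.39 * sin(ang), z = 0,
    stringsAsFactors = FALSE)
  other <- data.frame(name = "CB", element = "C", resname = "ALA",
                      chain = "B", resno = 2, x = 10, y = 0, z = 0,
                      stringsAsFactors = FALSE)
  df <- rbind(ring, other)
  b <- c(10, 20, 30, 40, 50, 60, 20)
  s <- read_fixture(c(hotspotRF:::format_pdb_lines(df, b), "END"))
  s2 <- add_ring_pseudo_atoms(s)
  ps <- s2$atoms[s2$atoms$is_pseudo, ]
  expect_equal(nrow(ps), 2)
  expect_equal(sort(ps$z), c(-0.5, 0.5))
  expect_equal(ps$x, c(0, 0), tolerance = 1e-9)
  expect_equal(ps$b, rep(mean(b[1:6]), 2))
  expect_false(any(ps$is_backbone))
  # midpoint of the pair is the centroid
  expect_equal(colMeans(as.matrix(ps[, c("x", "y", "z")])), c(x = 0, y = 0, z = 0),
               tolerance = 1e-9)
})

test_that("tryptophan gets four pseudo-atoms; a broken ring none", {
  toy <- make_toy_complex(fixture_spec(
    n_residues = 3, seq_a = c("GLY", "TRP", "GLY"),
    seq_b = c("GLY", "TYR", "GLY"), gap = 3.6, seed = 2))
  s <- add_ring_pseudo_atoms(read_fixture(toy$pdb))
  ps <- s$atoms[s$atoms$is_pseudo, ]
  expect_equal(sum(ps$chain == "A"), 4)  # two TRP rings x two
  expect_equal(sum(ps$chain == "B"), 2)
  # drop the TYR CZ: its ring must be skipped with a warning
  broken <- toy$pdb[!grepl(" CZ  TYR", toy$pdb)]
  expect_warning(s3 <- add_ring_pseudo_atoms(read_fixture(broken)),
                 "incomplete")
  expect_equal(sum(s3$atoms$is_pseudo & s3$atoms$chain == "B"), 0)
})

test_that("van der Waals radii come from the bundled table", {
  expect_equal(vdw_radius("C"), 1.70)
  expect_lt(vdw_radius("O"), vdw_radius("C"))
  expect_equal(vdw_radius("PI"), vdw_radius("C"))  # pseudo = aromatic carbon
  expect_error(vdw_radius("X"), "unknown element")
})

test_that("parse then re-serialize preserves atom count and B factors", {
  toy <- make_toy_complex(fixture_spec(n_residues = 5, seed = 9))
  s <- read_fixture(toy$pdb)
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_complex_pdb(s, tf)
  s2 <- read_complex(tf, "A", "B")
  expect_equal(nrow(s2$atoms), nrow(s$atoms))
  expect_identical(s2$atoms$b, s$atoms$b)
  expect_identical(s2$atoms$name, s$atoms$name)
})
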