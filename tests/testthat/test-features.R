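test_that("the triangular index over 14 contact types is a bijection onto 1..105", {
  idx <- integer()
  for (a in 0:13) for (b in a:13) idx <- c(idx, cooc_index(a, b))
  expect_equal(sort(idx), 1:105)
  expect_equal(cooc_index(3, 9), cooc_index(9, 3))  # order-free
  expect_equal(cooc_index(0, 0), 1L)
  expect_equal(cooc_index(13, 13), 105L)
})

test_that("the feature schema has 143 names in the documented block order", {
  fn <- feature_names()
  expect_equal(length(fn), 143)
  expect_equal(fn[1:2], c("dASA_log", "dASA_rel"))
  expect_equal(fn[3], "Bavg_g1")
  expect_equal(fn[10], "Bdif_g4")
  expect_equal(fn[11], "mut_t00")
  expect_equal(fn[25], "nbr_t00")
  expect_equal(fn[39], "cooc_t00_t00")
  # positional anchors of the compact labels: the mutated hydrophobic
  # element is V14, the neighborhood pi element V34, the (3,9)
  # co-occurrence V84 and the (3,10) co-occurrence V85
  expect_equal(fn[14], "mut_t03")
  expect_equal(fn[34], "nbr_t09")
  expect_equal(fn[84], "cooc_t03_t09")
  expect_equal(fn[85], "cooc_t03_t10")
  expect_equal(fn[94], "cooc_t04_t09")
})

test_that("contact typing is symmetric, total and anchored", {
  m <- hotspotRF:::contact_type_matrix()
  expect_true(all(m == t(m)))
  expect_true(all(m %in% 0:13))
  expect_setequal(unique(as.vector(m)), 0:13)  # all 14 types occur
  # anchored semantics
  expect_equal(contact_type(0, 0), 3L)   # C_c with C_c: hydrophobic
  expect_equal(contact_type(0, 1), 5L)   # C_on with C_c
  expect_equal(contact_type(1, 1), 1L)
  expect_equal(contact_type(0, 4), 2L)   # C_c with oxygen
  expect_equal(contact_type(1, 4), 4L)   # C_on with oxygen
  expect_equal(contact_type(2, 4), 0L)   # donor-acceptor: hydrogen bond
  expect_equal(contact_type(3, 6), 0L)
  expect_equal(contact_type(4, 4), 13L)  # acceptor-acceptor
  expect_equal(contact_type(8, 5), 9L)   # pi-involving
  expect_equal(contact_type(8, 8), 9L)
})

test_that("atoms are typed into the ten groups", {
  toy <- make_toy_complex(fixture_spec(
    n_residues = 5, seq_a = c("GLY", "LEU", "ALA", "SER", "GLY"),
    seq_b = c("GLY", "PHE", "ALA", "LYS", "GLY"), gap = 3.6, seed = 6))
  s <- add_ring_pseudo_atoms(read_fixture(toy$pdb))
  bonds <- bind_atom_table(infer_covalent_bonds(s), s$atoms)
  a <- s$atoms
  g <- atom_group(a, bonds)
  pick <- function(ch, res, nm) which(a$chain == ch & a$resno == res & a$name == nm)
  expect_equal(g[pick("A", 2, "CD1")], 0L)  # LEU CD1: no O/N neighbour
  expect_equal(g[pick("A", 4, "CB")], 1L)   # SER CB bonds OG
  expect_equal(g[pick("A", 4, "OG")], 6L)
  expect_equal(g[pick("A", 2, "N")], 2L)    # backbone N
  expect_equal(g[pick("A", 2, "O")], 4L)
  expect_equal(g[pick("A", 2, "CA")], 1L)   # CA bonds backbone N
  expect_equal(g[pick("B", 4, "NZ")], 3L)   # charged lysine head
  expect_true(all(g[a$is_pseudo] == 8L))
  # subsetted calls still resolve carbon topology via the bound atom table
  sub <- a[a$name == "CD1" & a$resname == "LEU", , drop = FALSE]
  expect_equal(atom_group(sub, bonds), 0L)
})

test_that("water oxygens map to the water group", {
  fx <- make_water_cage_fixture()
  s <- read_fixture(fx$pdb)
  bonds <- bind_atom_table(infer_covalent_bonds(s), s$atoms)
  g <- atom_group(s$atoms, bonds)
  expect_equal(g[s$atoms$is_water], 9L)
})

test_that("mutated-contact vector equals the hand enumeration on the LEU pair", {
  toy <- leu_pair_fixture()
  ctx <- prepare_complex(read_fixture(toy$pdb))
  v <- mutated_contact_vector(ctx, "A2")
  # independent enumeration: oracle contacts + typing + weight arithmetic
  truth <- fixture_truth(toy$pdb)
  a <- truth$structure$atoms
  bonds <- bind_atom_table(truth$bonds, a)
  grp <- atom_group(a, bonds)
  names(grp) <- a$atom_id
  mut <- mutated_atoms(truth$structure, "A2")
  st <- trimmed_bfactor_stats(a$b[!a$is_pseudo])
  bn <- setNames(clamp_bfactor(normalize_bfactor(a$b, st)), a$atom_id)
  expected <- setNames(numeric(14), names(v))
  ct <- truth$contacts
  for (r in which(ct$i %in% mut | ct$j %in% mut)) {
    tt <- contact_type(grp[as.character(ct$i[r])], grp[as.character(ct$j[r])])
    w <- (bn[as.character(ct$i[r])] + bn[as.character(ct$j[r])]) / 2
    expected[tt + 1] <- expected[tt + 1] + w
  }
  expect_equal(v, expected)
  expect_true(all(v <= 0))
  # residues with no mutated contacts give the zero vector
  v0 <- mutated_contact_vector(ctx, "A1")
  expect_equal(unname(v0), numeric(14))
})

test_that("co-occurrence follows shared-endpoint and bond-step semantics", {
  # two contacts sharing endpoint 1 co-occur even with no bonds at all
  ct <- data.frame(i = c(1L, 1L), j = c(2L, 3L))
  near3 <- list(`1` = 1L, `2` = 2L, `3` = 3L)
  expect_equal(cooccurring_pairs(ct, near3), cbind(1L, 2L))
  # endpoints farther than 3 covalent steps never co-occur
  ids <- 1:12
  chain <- cbind(1:11, 2:12)  # a 11-bond path: ends are 11 steps apart
  bonds <- bonds_from_edges(ids, chain)
  ct2 <- data.frame(i = c(1L, 11L), j = c(2L, 12L))
  near3b <- nearby_sets(bonds, ids, steps = 3)
  expect_equal(nrow(cooccurring_pairs(ct2, near3b)), 0)
  expect_equal(nrow(cooccurring_pairs_bruteforce(ct2, bonds)), 0)
  # within 3 steps they do: contacts at atoms (1,2) and (4,5): step(2,4)=2
  ct3 <- data.frame(i = c(1L, 4L), j = c(2L, 5L))
  expect_equal(cooccurring_pairs(ct3, near3b), cbind(1L, 2L))
  expect_equal(cooccurring_pairs_bruteforce(ct3, bonds), cbind(1L, 2L))
})

test_that("fast co-occurring-pair enumeration equals the double-loop oracle", {
  for (seed in c(61, 62)) {
    toy <- make_toy_complex(fixture_spec(n_residues = 10, seed = seed))
    ctx <- prepare_complex(read_fixture(toy$pdb))
    ct <- ctx$contacts
    expect_gte(nrow(ct), 2)
    fast <- cooccurring_pairs(ct, ctx$near3)
    slow <- cooccurring_pairs_bruteforce(ct, ctx$bonds)
    expect_equal(fast, slow[order(slow[, 1], slow[, 2]), , drop = FALSE])
  }
})

test_that("the hydrogen-bond network fixture plants counted co-occurrences", {
  for (size in 1:3) {
    fx <- make_hbond_network_fixture(size, seed = 7)
    ctx <- prepare_complex(read_fixture(fx$pdb))
    ct <- ctx$contacts
    expect_equal(sum(ct$type == 0), size)
    v <- cooccurrence_vector(ctx, "A2")
    mutc <- which(ct$i %in% mutated_atoms(ctx$structure, "A2") |
                    ct$j %in% mutated_atoms(ctx$structure, "A2"))
    pairs <- cooccurring_pairs(ct, ctx$near3, scope = mutc)
    n00 <- if (nrow(pairs) == 0) 0 else
      sum(ct$type[pairs[, 1]] == 0 & ct$type[pairs[, 2]] == 0)
    expect_equal(n00, choose(size, 2))
    if (size >= 2) {
      expect_lt(v[["cooc_t00_t00"]], 0)
      # value is the sum of both contacts' weights over qualifying pairs
      sel <- pairs[ct$type[pairs[, 1]] == 0 & ct$type[pairs[, 2]] == 0, ,
                   drop = FALSE]
      expect_equal(v[["cooc_t00_t00"]],
                   sum(ct$w[sel[, 1]] + ct$w[sel[, 2]]))
    } else {
      expect_equal(v[["cooc_t00_t00"]], 0)
    }
  }
})

test_that("assembled descriptors have 143 elements with non-positive contact blocks", {
  toy <- make_toy_complex(fixture_spec(n_residues = 6, seed = 42))
  s <- read_fixture(toy$pdb)
  # A2 faces the interface; B3 (SER) points away from it
  mut <- data.frame(chain = c("A", "B"), resno = c(2, 3),
                    wt = c(toy$seq_a[2], toy$seq_b[3]))
  f <- extract_features(s, mut)
  expect_equal(dim(f$X), c(2, 143))
  expect_equal(colnames(f$X), as.character(feature_names()))
  expect_true(all(f$X[, 11:143] <= 1e-12))
  # the residue pointing away from the interface: contact blocks all zero
  expect_true(all(f$X[2, 11:143] == 0))
  # but its B-factor slot pair is populated
  expect_true(any(f$X[2, 3:10] != 0))
})

test_that("wild-type validation rejects mismatches and Gly/Ala", {
  toy <- leu_pair_fixture()
  s <- read_fixture(toy$pdb)
  expect_error(extract_features(s, data.frame(chain = "A", resno = 2,
                                              wt = "VAL")), "mismatch")
  expect_error(extract_features(s, data.frame(chain = "A", resno = 1,
                                              wt = "ALA")), "not scored")
  expect_error(extract_features(s, data.frame(chain = "A", resno = 99,
                                              wt = "LEU")), "not found")
})

test_that("permuting atom order in the PDB leaves the descriptor bit-identical", {
  toy <- make_toy_complex(fixture_spec(n_residues = 6, seed = 13))
  body <- setdiff(toy$pdb, "END")
  set.seed(99)
  shuffled <- c(sample(body), "END")
  mut <- data.frame(chain = "A", resno = 2, wt = toy$seq_a[2])
  f1 <- extract_features(read_fixture(toy$pdb), mut)
  f2 <- extract_features(read_fixture(shuffled), mut)
  expect_identical(f1$X, f2$X)
})
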