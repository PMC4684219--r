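# Independent test-side oracles and small builders.

# dense Floyd-Warshall shortest paths over an explicit edge list;
# independent of the igraph-backed bond_steps implementation
fw_steps <- function(n, edges) {
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  if (nrow(edges) > 0) {
    for (r in seq_len(nrow(edges))) {
      d[edges[r, 1], edges[r, 2]] <- 1
      d[edges[r, 2], edges[r, 1]] <- 1
    }
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# minimal atom table from a coordinate matrix
mk_atoms <- function(xyz, element = "C", is_water = FALSE, side = "A",
                     resname = "ALA", name = "CB") {
  n <- nrow(xyz)
  data.frame(
    name = rep_len(name, n), element = rep_len(element, n),
    resname = rep_len(resname, n), chain = rep_len(side, n),
    resno = seq_len(n), insert = "",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    b = 20, occ = 1, res_key = paste0(rep_len(side, n), seq_len(n)),
    is_water = rep_len(is_water, n), is_pseudo = FALSE,
    is_backbone = FALSE, side = rep_len(side, n),
    vdw = vdw_radius(rep_len(element, n)),
    atom_id = seq_len(n), stringsAsFactors = FALSE)
}

# random atom cloud at roughly protein-like heavy-atom spacing, with a
# mix of elements, two sides and a few waters
random_cloud <- function(n, seed) {
  set.seed(seed)
  side_len <- (n * 60)^(1 / 3)
  xyz <- matrix(runif(3 * n, 0, side_len), ncol = 3)
  ele <- sample(c("C", "N", "O", "S"), n, replace = TRUE,
                prob = c(0.6, 0.15, 0.2, 0.05))
  at <- mk_atoms(xyz, element = ele)
  at$side <- sample(c("A", "B"), n, replace = TRUE)
  wat <- runif(n) < 0.05 & ele == "O"
  at$is_water[wat] <- TRUE
  at$side[wat] <- NA
  at$resname[wat] <- "HOH"
  at
}

# an empty bond graph over the given atom ids (class bond_graph)
empty_bonds <- function(ids) {
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(as.character(ids))
  structure(list(graph = g), class = "bond_graph")
}

# bond graph from an explicit id-pair edge matrix
bonds_from_edges <- function(ids, edges) {
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(as.character(ids))
  if (nrow(edges) > 0)
    g <- igraph::add_edges(g, as.character(t(edges)))
  structure(list(graph = g), class = "bond_graph")
}

# the standard LEU-LEU two-tripeptide fixture used across tests
leu_pair_fixture <- function(seed = 1) {
  make_toy_complex(fixture_spec(
    n_residues = 3, seq_a = c("ALA", "LEU", "ALA"),
    seq_b = c("ALA", "LEU", "ALA"), gap = 3.8, seed = seed))
}
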