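#' Infer the covalent bond graph of a complex
#'
#' Bonds are inferred from distances rather than residue templates: two
#' heavy atoms of the same residue are bonded iff their distance is at most
#' 1.9 Angstrom (2.2 if either atom is sulfur); consecutive residues of a
#' chain are joined by a C(i)-N(i+1) bond under the same 1.9 cutoff (a
#' larger gap is a chain break); waters carry no bonds; each aromatic-ring
#' pseudo-atom is bonded (one step) to every atom of its parent ring so
#' that nearby-atom semantics reach pi contacts.
#'
#' @param structure a `complex_structure` (pseudo-atoms may or may not have
#'   been added).
#' @return An object of class `bond_graph` wrapping an igraph whose vertex
#'   names are atom ids.
#' @export
infer_covalent_bonds <- function(structure) {
  atoms <- structure$atoms
  real <- atoms[!atoms$is_pseudo & !atoms$is_water, , drop = FALSE]
  edges <- list()

  # intra-residue bonds by distance
  for (idx in split(seq_len(nrow(real)), real$res_key)) {
    if (length(idx) < 2) next
    sub <- real[idx, , drop = FALSE]
    d <- as.matrix(stats::dist(atom_xyz(sub)))
    s <- sub$element == "S"
    cutoff <- matrix(1.9, length(idx), length(idx))
    cutoff[s, ] <- 2.2
    cutoff[, s] <- 2.2
    hit <- which(d <= cutoff & upper.tri(d), arr.ind = TRUE)
    if (nrow(hit) > 0)
      edges[[length(edges) + 1L]] <-
        cbind(sub$atom_id[hit[, 1]], sub$atom_id[hit[, 2]])
  }

  # peptide bonds between consecutive residues of a chain (file order)
  for (ch in unique(real$chain)) {
    sub <- real[real$chain == ch, , drop = FALSE]
    keys <- unique(sub$res_key)
    if (length(keys) < 2) next
    for (k in seq_len(length(keys) - 1L)) {
      ci <- sub[sub$res_key == keys[k] & sub$name == "C", , drop = FALSE]
      ni <- sub[sub$res_key == keys[k + 1L] & sub$name == "N", , drop = FALSE]
      if (nrow(ci) == 1 && nrow(ni) == 1) {
        d <- sqrt(sum((as.numeric(ci[1, c("x", "y", "z")]) -
                       as.numeric(ni[1, c("x", "y", "z")]))^2))
        if (d <= 1.9)
          edges[[length(edges) + 1L]] <- cbind(ci$atom_id, ni$atom_id)
      }
    }
  }

  # pseudo-atoms: step 1 to every parent-ring atom
  if (!is.null(structure$rings)) {
    for (ring in structure$rings) {
      for (p in ring$pseudo_ids)
        edges[[length(edges) + 1L]] <- cbind(p, ring$atom_ids)
    }
  }

  em <- if (length(edges) > 0) do.call(rbind, edges) else
    matrix(integer(), 0, 2)
  g <- igraph::graph_from_edgelist(
    matrix(as.character(em), ncol = 2), directed = FALSE)
  g <- g + igraph::vertices(setdiff(as.character(atoms$atom_id),
                                    igraph::V(g)$name))
  structure(list(graph = g), class = "bond_graph")
}

#' Covalent-bond steps between two atoms
#'
#' The number of bonds on the shortest covalent path: 0 for the atom
#' itself, 1 for a bonded neighbour, and so on. Atoms farther apart than
#' `max_steps` (or in different connected components) report `Inf`
#' ("beyond").
#'
#' @param bonds a `bond_graph`.
#' @param a,b atom ids.
#' @param max_steps cap beyond which the result is `Inf`.
#' @return integer number of steps, or `Inf`.
#' @export
bond_steps <- function(bonds, a, b, max_steps = 3) {
  d <- igraph::distances(bonds$graph, v = as.character(a),
                         to = as.character(b))[1, 1]
  if (is.infinite(d) || d > max_steps) return(Inf)
  as.integer(d)
}

#' Covalently-bonded nearby atoms
#'
#' All atoms within `steps` covalent-bond steps of `a`, including `a`
#' itself.
#'
#' @param bonds a `bond_graph`.
#' @param a atom id.
#' @param steps maximum number of bond steps (default 3).
#' @return integer vector of atom ids.
#' @export
nearby_atoms <- function(bonds, a, steps = 3) {
  nb <- igraph::ego(bonds$graph, order = steps,
                    nodes = as.character(a))[[1]]
  sort(as.integer(names(nb)))
}

#' Nearby-atom sets for many atoms at once
#' @param bonds a `bond_graph`.
#' @param ids atom ids.
#' @param steps maximum bond steps.
#' @return named list of integer vectors, one per id.
#' @keywords internal
nearby_sets <- function(bonds, ids, steps = 3) {
  nb <- igraph::ego(bonds$graph, order = steps, nodes = as.character(ids))
  out <- lapply(nb, function(v) sort(as.integer(names(v))))
  names(out) <- as.character(ids)
  out
}
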