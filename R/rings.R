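AROMATIC_RINGS <- list(
  PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2")),
  TRP = list(c("CG", "CD1", "NE1", "CE2", "CD2"),
             c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3")))

#' Add aromatic-ring pseudo-atoms
#'
#' Each aromatic ring of PHE, TYR, HIS and both TRP rings is represented by
#' two pseudo-atoms placed at the ring centroid plus/minus 0.5 Angstrom
#' along the unit normal of the ring's least-squares plane. A pseudo-atom
#' carries the mean B factor of its ring atoms, the element symbol "PI",
#' and is flagged `is_pseudo`; rings with missing atoms are skipped with a
#' warning. Ring membership is recorded in `structure$rings` so that
#' [infer_covalent_bonds()] can bond each pseudo-atom to its parent ring.
#'
#' @param structure a `complex_structure`.
#' @return The structure with pseudo-atom rows appended.
#' @export
add_ring_pseudo_atoms <- function(structure) {
  atoms <- structure$atoms
  if (any(atoms$is_pseudo)) return(structure)
  rings <- list()
  new_rows <- list()
  next_id <- max(atoms$atom_id)
  arom <- atoms[!atoms$is_water & atoms$resname %in% names(AROMATIC_RINGS), ,
                drop = FALSE]
  for (rk in unique(arom$res_key)) {
    res <- arom[arom$res_key == rk, , drop = FALSE]
    defs <- AROMATIC_RINGS[[res$resname[1]]]
    for (ri in seq_along(defs)) {
      members <- res[match(defs[[ri]], res$name), , drop = FALSE]
      if (anyNA(members$atom_id)) {
        warning("incomplete aromatic ring in ", res$resname[1], " ", rk,
                "; no pseudo-atoms placed")
        next
      }
      xyz <- atom_xyz(members)
      ctr <- colMeans(xyz)
      cen <- sweep(xyz, 2, ctr)
      normal <- svd(cen)$v[, 3]
      normal <- normal / sqrt(sum(normal^2))
      b_ring <- mean(members$b)
      for (s in c(1, -1)) {
        next_id <- next_id + 1L
        pos <- ctr + 0.5 * s * normal
        row <- members[1, , drop = FALSE]
        row$name <- sprintf("PI%d%s", ri, if (s > 0) "A" else "B")
        row$element <- "PI"
        row$x <- pos[1]; row$y <- pos[2]; row$z <- pos[3]
        row$b <- b_ring
        row$occ <- 1
        row$is_pseudo <- TRUE
        row$is_backbone <- FALSE
        row$vdw <- vdw_radius("PI")
        row$atom_id <- next_id
        new_rows[[length(new_rows) + 1L]] <- row
      }
      rings[[length(rings) + 1L]] <-
        list(res_key = rk, atom_ids = members$atom_id,
             pseudo_ids = c(next_id - 1L, next_id))
    }
  }
  if (length(new_rows) > 0) {
    structure$atoms <- rbind(atoms, do.call(rbind, new_rows))
    rownames(structure$atoms) <- NULL
  }
  structure$rings <- rings
  structure
}
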