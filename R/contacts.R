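# Beta contacts: a pair (i, j) is in contact when dist(i,j) <= td_factor *
# (vdw_i + vdw_j) and no third atom k sees the pair under an angle
# >= beta_angle (the "forbidden region" is empty). Pseudo-atoms can be
# contact endpoints but never interrupt; waters can interrupt; water-water
# pairs are never contacts; pairs within 2 covalent-bond steps are bonds
# or angle-coupled neighbours, not contacts.

#' Test a single beta contact
#'
#' @param atoms atom data frame; all rows other than the two endpoints act
#'   as interruption candidates (pseudo-atoms excepted).
#' @param i,j atom ids of the endpoints.
#' @param td_factor distance factor: the cutoff is
#'   `td_factor * (vdw_i + vdw_j)`.
#' @param beta_angle_deg interruption angle in degrees.
#' @return TRUE when the pair forms a beta contact.
#' @export
is_beta_contact <- function(atoms, i, j, td_factor = 1.25,
                            beta_angle_deg = 85) {
  stopifnot(beta_angle_deg > 0, beta_angle_deg < 180)
  ai <- atoms[match(i, atoms$atom_id), , drop = FALSE]
  aj <- atoms[match(j, atoms$atom_id), , drop = FALSE]
  if (anyNA(ai$atom_id) || anyNA(aj$atom_id)) stop("endpoint not in atom table")
  if (i == j) stop("identical endpoints")
  pi_ <- as.numeric(ai[1, c("x", "y", "z")])
  pj <- as.numeric(aj[1, c("x", "y", "z")])
  d <- sqrt(sum((pi_ - pj)^2))
  if (d == 0) stop("coincident atom centers")
  if (d > td_factor * (ai$vdw + aj$vdw)) return(FALSE)
  cand <- atoms[!atoms$is_pseudo & !(atoms$atom_id %in% c(i, j)), ,
                drop = FALSE]
  if (nrow(cand) == 0) return(TRUE)
  xyz <- atom_xyz(cand)
  dki <- sqrt(rowSums(sweep(xyz, 2, pi_)^2))
  dkj <- sqrt(rowSums(sweep(xyz, 2, pj)^2))
  if (any(dki == 0 | dkj == 0)) stop("coincident atom centers")
  cosang <- (dki^2 + dkj^2 - d^2) / (2 * dki * dkj)
  !any(cosang <= cos(beta_angle_deg * pi / 180))
}

#' Enumerate all beta contacts of an atom set (grid-accelerated)
#'
#' Production path: candidate pairs come from a spatial cell grid sized to
#' the largest possible contact distance, and interruption candidates are
#' restricted to the geometrically admissible ball around each pair. The
#' result is identical to [beta_contacts_bruteforce()] by construction
#' (property-tested).
#'
#' @param atoms atom data frame.
#' @param td_factor,beta_angle_deg contact thresholds (published defaults
#'   1.25 and 85).
#' @param bonds optional `bond_graph`; when given, pairs within 2
#'   covalent-bond steps are excluded from contact enumeration.
#' @return data frame with columns `i`, `j` (atom ids, i < j), `dist`,
#'   `cross` (endpoints on opposite interface sides).
#' @export
beta_contacts <- function(atoms, td_factor = 1.25, beta_angle_deg = 85,
                          bonds = NULL) {
  stopifnot(beta_angle_deg > 0, beta_angle_deg < 180)
  n <- nrow(atoms)
  empty <- data.frame(i = integer(), j = integer(), dist = numeric(),
                      cross = logical())
  if (n < 2) return(empty)
  xyz <- atom_xyz(atoms)
  # admissible interrupters lie within reach_factor * d of both endpoints
  reach <- if (beta_angle_deg >= 90) 1.0 else
    1 / sin(beta_angle_deg * pi / 180)
  reach <- reach * 1.000001
  max_td <- td_factor * 2 * max(atoms$vdw)
  cutoff <- max_td * max(1, reach)
  pairs <- grid_pairs(xyz, cutoff)
  if (nrow(pairs) == 0) return(empty)

  # neighbour lists within cutoff (for interruption candidates)
  nbr <- vector("list", n)
  for (r in seq_len(nrow(pairs))) {
    a <- pairs[r, 1]; b <- pairs[r, 2]
    nbr[[a]] <- c(nbr[[a]], b)
    nbr[[b]] <- c(nbr[[b]], a)
  }

  d <- sqrt(rowSums((xyz[pairs[, 1], , drop = FALSE] -
                     xyz[pairs[, 2], , drop = FALSE])^2))
  if (any(d == 0)) stop("coincident atom centers")
  td <- td_factor * (atoms$vdw[pairs[, 1]] + atoms$vdw[pairs[, 2]])
  ok <- d <= td
  # water-water pairs are never contacts
  ok <- ok & !(atoms$is_water[pairs[, 1]] & atoms$is_water[pairs[, 2]])
  pairs <- pairs[ok, , drop = FALSE]
  d <- d[ok]
  if (nrow(pairs) == 0) return(empty)

  if (!is.null(bonds)) {
    near2 <- nearby_sets(bonds, atoms$atom_id, steps = 2)
    idi <- atoms$atom_id[pairs[, 1]]
    idj <- atoms$atom_id[pairs[, 2]]
    bonded <- mapply(function(a, b) b %in% near2[[as.character(a)]], idi, idj)
    pairs <- pairs[!bonded, , drop = FALSE]
    d <- d[!bonded]
    if (nrow(pairs) == 0) return(empty)
  }

  cosbeta <- cos(beta_angle_deg * pi / 180)
  keep <- logical(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    a <- pairs[r, 1]; b <- pairs[r, 2]
    cand <- intersect(nbr[[a]], nbr[[b]])
    cand <- cand[cand != a & cand != b & !atoms$is_pseudo[cand]]
    if (length(cand) == 0) { keep[r] <- TRUE; next }
    dki <- sqrt(rowSums(sweep(xyz[cand, , drop = FALSE], 2, xyz[a, ])^2))
    dkj <- sqrt(rowSums(sweep(xyz[cand, , drop = FALSE], 2, xyz[b, ])^2))
    lim <- d[r] * reach
    adm <- dki <= lim & dkj <= lim
    if (!any(adm)) { keep[r] <- TRUE; next }
    dki <- dki[adm]; dkj <- dkj[adm]
    if (any(dki == 0 | dkj == 0)) stop("coincident atom centers")
    cosang <- (dki^2 + dkj^2 - d[r]^2) / (2 * dki * dkj)
    keep[r] <- !any(cosang <= cosbeta)
  }
  pairs <- pairs[keep, , drop = FALSE]
  d <- d[keep]
  ids <- atoms$atom_id
  i <- pmin(ids[pairs[, 1]], ids[pairs[, 2]])
  j <- pmax(ids[pairs[, 1]], ids[pairs[, 2]])
  side_i <- atoms$side[match(i, ids)]
  side_j <- atoms$side[match(j, ids)]
  res <- data.frame(i = i, j = j, dist = d,
                    cross = !is.na(side_i) & !is.na(side_j) & side_i != side_j)
  res <- res[order(res$i, res$j), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Brute-force beta-contact oracle
#'
#' Reference implementation: every pair is tested against every third atom
#' with no spatial acceleration. Used to validate [beta_contacts()] and to
#' define the planted truth of synthetic fixtures.
#'
#' @inheritParams beta_contacts
#' @return Same layout as [beta_contacts()].
#' @export
beta_contacts_bruteforce <- function(atoms, td_factor = 1.25,
                                     beta_angle_deg = 85, bonds = NULL) {
  n <- nrow(atoms)
  rows <- list()
  cosbeta <- cos(beta_angle_deg * pi / 180)
  xyz <- atom_xyz(atoms)
  dm <- as.matrix(stats::dist(xyz))
  near2 <- if (!is.null(bonds))
    nearby_sets(bonds, atoms$atom_id, steps = 2) else NULL
  for (a in seq_len(max(0, n - 1))) {
    for (b in seq.int(a + 1L, n)) {
      if (atoms$is_water[a] && atoms$is_water[b]) next
      d <- dm[a, b]
      if (d > td_factor * (atoms$vdw[a] + atoms$vdw[b])) next
      if (!is.null(near2) &&
          atoms$atom_id[b] %in% near2[[as.character(atoms$atom_id[a])]]) next
      k <- setdiff(which(!atoms$is_pseudo), c(a, b))
      interrupted <- FALSE
      if (length(k) > 0) {
        dki <- dm[k, a]; dkj <- dm[k, b]
        cosang <- (dki^2 + dkj^2 - d^2) / (2 * dki * dkj)
        interrupted <- any(cosang <= cosbeta)
      }
      if (!interrupted)
        rows[[length(rows) + 1L]] <- c(a, b, d)
    }
  }
  if (length(rows) == 0)
    return(data.frame(i = integer(), j = integer(), dist = numeric(),
                      cross = logical()))
  m <- do.call(rbind, rows)
  ids <- atoms$atom_id
  i <- pmin(ids[m[, 1]], ids[m[, 2]])
  j <- pmax(ids[m[, 1]], ids[m[, 2]])
  side_i <- atoms$side[match(i, ids)]
  side_j <- atoms$side[match(j, ids)]
  res <- data.frame(i = i, j = j, dist = m[, 3],
                    cross = !is.na(side_i) & !is.na(side_j) & side_i != side_j)
  res <- res[order(res$i, res$j), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# unique unordered index pairs within `cutoff`, via a cell grid
grid_pairs <- function(xyz, cutoff) {
  n <- nrow(xyz)
  cell <- floor(sweep(xyz, 2, apply(xyz, 2, min)) / cutoff)
  key <- cell[, 1] + 1e4 * cell[, 2] + 1e8 * cell[, 3]
  cells <- split(seq_len(n), key)
  cell_of <- match(key, names(cells))
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  out <- list()
  for (ci in seq_along(cells)) {
    idx <- cells[[ci]]
    base <- cell[idx[1], ]
    cand <- integer()
    for (r in seq_len(nrow(offs))) {
      k2 <- (base[1] + offs[r, 1]) + 1e4 * (base[2] + offs[r, 2]) +
        1e8 * (base[3] + offs[r, 3])
      hit <- cells[[as.character(k2)]]
      if (!is.null(hit)) cand <- c(cand, hit)
    }
    for (a in idx) {
      b <- cand[cand > a]
      if (length(b) == 0) next
      dd <- sqrt(rowSums(sweep(xyz[b, , drop = FALSE], 2, xyz[a, ])^2))
      b <- b[dd <= cutoff]
      if (length(b) > 0)
        out[[length(out) + 1L]] <- cbind(a, b)
    }
  }
  if (length(out) == 0) matrix(integer(), 0, 2) else do.call(rbind, out)
}

#' Identify qualified (structural) water molecules
#'
#' A water oxygen joins the contact graph when it is buried (ASA below
#' 1 squared Angstrom in the crystallized complex, waters included) and
#' makes at least 3 beta contacts with hydrogen-bond donor or acceptor
#' atoms (protein N or O); water-water contacts never count.
#'
#' @param atoms atom data frame.
#' @param contacts beta-contact data frame over the same atoms.
#' @param asa named per-atom ASA vector for the full complex (waters
#'   included as occluders).
#' @return integer vector of qualified water atom ids.
#' @export
qualified_waters <- function(atoms, contacts, asa) {
  wat <- atoms$atom_id[atoms$is_water]
  if (length(wat) == 0) return(integer())
  donor_acceptor <- atoms$atom_id[!atoms$is_water & !atoms$is_pseudo &
                                    atoms$element %in% c("N", "O")]
  buried <- wat[!is.na(asa[as.character(wat)]) & asa[as.character(wat)] < 1]
  keep <- vapply(buried, function(w) {
    partners <- c(contacts$j[contacts$i == w], contacts$i[contacts$j == w])
    sum(partners %in% donor_acceptor) >= 3
  }, logical(1))
  sort(buried[keep])
}

#' Build the interface contact graph of a complex
#'
#' Pipeline: enumerate beta contacts over protein atoms, ring
#' pseudo-atoms and waters; keep only qualified waters as contact
#' endpoints; interfacial atoms are those with a cross-interface contact;
#' supporting atoms contact an interfacial atom; the neighborhood adds
#' every non-backbone atom within 3 covalent-bond steps of an interfacial
#' or supporting atom; the graph keeps every contact touching the
#' neighborhood.
#'
#' @param structure a `complex_structure` with pseudo-atoms added.
#' @param bonds the structure's `bond_graph`.
#' @param params a [hotspot_params()] list.
#' @param asa_full optional precomputed full-complex ASA (for the water
#'   rule); computed when missing.
#' @return An object of class `contact_graph`: `contacts` (data frame),
#'   `interfacial`, `supporting`, `neighborhood`, `qualified_waters`
#'   (atom-id vectors) and `params`.
#' @export
build_contact_graph <- function(structure, bonds, params = hotspot_params(),
                                asa_full = NULL) {
  atoms <- structure$atoms
  contacts <- beta_contacts(atoms, params$td_factor, params$beta_angle_deg,
                            bonds)
  if (any(atoms$is_water)) {
    if (is.null(asa_full))
      asa_full <- compute_asa(atoms, params$probe_radius, params$n_points)
    qw <- qualified_waters(atoms, contacts, asa_full)
    bad_water <- setdiff(atoms$atom_id[atoms$is_water], qw)
    keep <- !(contacts$i %in% bad_water) & !(contacts$j %in% bad_water)
    contacts <- contacts[keep, , drop = FALSE]
  } else qw <- integer()

  interfacial <- sort(unique(c(contacts$i[contacts$cross],
                               contacts$j[contacts$cross])))
  if (length(interfacial) == 0) {
    warning("empty interface: no cross-interface beta contacts")
    return(structure(list(contacts = contacts[0, , drop = FALSE],
                          interfacial = integer(), supporting = integer(),
                          neighborhood = integer(), qualified_waters = qw,
                          params = params,
                          structure_id = structure$structure_id),
                     class = "contact_graph"))
  }
  touch_int <- contacts$i %in% interfacial | contacts$j %in% interfacial
  supporting <- setdiff(sort(unique(c(contacts$i[touch_int],
                                      contacts$j[touch_int]))), interfacial)
  core <- c(interfacial, supporting)
  near <- unique(unlist(nearby_sets(bonds, core, steps = 3), use.names = FALSE))
  backbone <- atoms$atom_id[atoms$is_backbone]
  neighborhood <- sort(unique(c(core, setdiff(near, backbone))))
  keep <- contacts$i %in% neighborhood | contacts$j %in% neighborhood
  graph_contacts <- contacts[keep, , drop = FALSE]
  rownames(graph_contacts) <- NULL
  structure(list(contacts = graph_contacts, interfacial = interfacial,
                 supporting = supporting, neighborhood = neighborhood,
                 qualified_waters = qw, params = params,
                 structure_id = structure$structure_id),
            class = "contact_graph")
}

#' @export
print.contact_graph <- function(x, ...) {
  cat(sprintf(paste0("contact_graph '%s': %d contacts (%d cross-interface), ",
                     "%d interfacial / %d supporting / %d neighborhood atoms, ",
                     "%d qualified waters\n"),
              x$structure_id %||% "?", nrow(x$contacts), sum(x$contacts$cross),
              length(x$interfacial), length(x$supporting),
              length(x$neighborhood), length(x$qualified_waters)))
  invisible(x)
}

#' Export a contact graph as a tabular edge list
#' @param graph a `contact_graph`.
#' @param atoms the atom table the graph was built from.
#' @param path optional TSV output file.
#' @return data frame of contacts with residue annotation.
#' @export
contact_edge_list <- function(graph, atoms, path = NULL) {
  ci <- match(graph$contacts$i, atoms$atom_id)
  cj <- match(graph$contacts$j, atoms$atom_id)
  out <- data.frame(
    atom_i = graph$contacts$i, atom_j = graph$contacts$j,
    name_i = atoms$name[ci], name_j = atoms$name[cj],
    res_i = paste(atoms$resname[ci], atoms$res_key[ci]),
    res_j = paste(atoms$resname[cj], atoms$res_key[cj]),
    dist = round(graph$contacts$dist, 3), cross = graph$contacts$cross)
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  out
}
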