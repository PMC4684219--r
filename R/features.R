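# order-independent reductions: summation follows value order, not input
# order, so feature vectors are bit-identical under atom permutations
ssum <- function(x) sum(sort(x))
smean <- function(x) if (length(x) == 0) NaN else ssum(x) / length(x)

#' Prepare a complex for feature extraction
#'
#' Runs the full per-complex pipeline once: ring pseudo-atoms, covalent
#' bonds, trimmed B-factor statistics and clamped-normalized B values,
#' ASA tables (bound complex, each side unbound, and the water-inclusive
#' table for the water rule), the interface contact graph, and per-contact
#' typing and weights.
#'
#' @param structure a `complex_structure` fresh from [read_complex()].
#' @param params a [hotspot_params()] list.
#' @return A list of class `complex_context` with everything downstream
#'   feature operations need.
#' @export
prepare_complex <- function(structure, params = hotspot_params()) {
  structure <- add_ring_pseudo_atoms(structure)
  atoms <- structure$atoms
  bonds <- bind_atom_table(infer_covalent_bonds(structure), atoms)

  real <- atoms[!atoms$is_pseudo, , drop = FALSE]
  stats <- trimmed_bfactor_stats(real$b, params$trim_low, params$trim_high)
  bnorm <- stats::setNames(clamp_bfactor(normalize_bfactor(atoms$b, stats)),
                           atoms$atom_id)

  asa_full <- if (any(atoms$is_water))
    compute_asa(atoms, params$probe_radius, params$n_points) else NULL
  graph <- build_contact_graph(structure, bonds, params, asa_full = asa_full)

  prot <- atoms[!atoms$is_pseudo & !atoms$is_water, , drop = FALSE]
  asa_bound <- compute_asa(prot, params$probe_radius, params$n_points)
  asa_unbound <- list(
    A = compute_asa(prot[prot$side == "A", , drop = FALSE],
                    params$probe_radius, params$n_points),
    B = compute_asa(prot[prot$side == "B", , drop = FALSE],
                    params$probe_radius, params$n_points))

  groups <- atom_group(atoms, bonds)
  names(groups) <- atoms$atom_id
  ct <- graph$contacts
  if (nrow(ct) > 0) {
    gi <- groups[as.character(ct$i)]
    gj <- groups[as.character(ct$j)]
    ct$type <- contact_type(gi, gj)
    ct$w <- (bnorm[as.character(ct$i)] + bnorm[as.character(ct$j)]) / 2
  } else {
    ct$type <- integer()
    ct$w <- numeric()
  }
  near3 <- nearby_sets(bonds, atoms$atom_id, steps = 3)

  structure(list(structure = structure, bonds = bonds, graph = graph,
                 contacts = ct, stats = stats, bnorm = bnorm,
                 groups = groups, asa_bound = asa_bound,
                 asa_unbound = asa_unbound, near3 = near3, params = params),
            class = "complex_context")
}

# rows of ctx$contacts touching any of the given atom ids
contacts_touching <- function(contacts, ids) {
  which(contacts$i %in% ids | contacts$j %in% ids)
}

# sum contact weights into a named 14-vector by type
type_vector <- function(contacts, rows, prefix) {
  out <- stats::setNames(numeric(14), paste0(prefix, sprintf("_t%02d", 0:13)))
  if (length(rows) > 0) {
    for (t in unique(contacts$type[rows])) {
      sel <- rows[contacts$type[rows] == t]
      out[t + 1L] <- ssum(contacts$w[sel])
    }
  }
  out
}

#' Mutated-contact feature vector (14 elements)
#'
#' Element k sums the weight `(Bi + Bj)/2` (clamped-normalized B factors)
#' of every graph contact of type k that touches a mutated atom of the
#' residue.
#'
#' @param ctx a `complex_context` from [prepare_complex()].
#' @param res_key residue key of the mutation.
#' @return named numeric vector of length 14.
#' @export
mutated_contact_vector <- function(ctx, res_key) {
  mut <- mutated_atoms(ctx$structure, res_key)
  type_vector(ctx$contacts, contacts_touching(ctx$contacts, mut), "mut")
}

#' Neighborhood cross-interface contact vector (14 elements)
#'
#' The mutation's neighborhood is its mutated atoms, their beta-contact
#' partners, and every non-backbone atom within 3 covalent-bond steps of
#' those; element k sums the weights of cross-interface contacts of type k
#' with at least one endpoint in that neighborhood.
#'
#' @inheritParams mutated_contact_vector
#' @return named numeric vector of length 14.
#' @export
neighborhood_interface_vector <- function(ctx, res_key) {
  nb <- mutation_neighborhood(ctx, res_key)
  ct <- ctx$contacts
  rows <- intersect(contacts_touching(ct, nb), which(ct$cross))
  type_vector(ct, rows, "nbr")
}

# mutated atoms + their contact partners + non-backbone atoms <= 3 steps
mutation_neighborhood <- function(ctx, res_key) {
  mut <- mutated_atoms(ctx$structure, res_key)
  ct <- ctx$contacts
  rows <- contacts_touching(ct, mut)
  core <- unique(c(mut, ct$i[rows], ct$j[rows]))
  near <- unique(unlist(ctx$near3[as.character(core)], use.names = FALSE))
  atoms <- ctx$structure$atoms
  backbone <- atoms$atom_id[atoms$is_backbone]
  sort(unique(c(core, setdiff(near, backbone))))
}

#' Enumerate co-occurring contact pairs
#'
#' Two contacts co-occur when an endpoint of one lies within 3
#' covalent-bond steps (including 0: a shared atom) of an endpoint of the
#' other. Returns unordered pairs of row indices into `contacts`; when
#' `scope` is given, only pairs with at least one member in `scope` are
#' returned.
#'
#' @param contacts contact data frame (columns `i`, `j`).
#' @param near3 named list of 3-step nearby-atom sets (see
#'   [nearby_sets()]), covering every endpoint.
#' @param scope optional integer vector of contact row indices.
#' @return two-column integer matrix of row-index pairs (first < second).
#' @export
cooccurring_pairs <- function(contacts, near3, scope = NULL) {
  m <- nrow(contacts)
  if (m < 2) return(matrix(integer(), 0, 2))
  if (is.null(scope)) scope <- seq_len(m)
  # incidence: atom id -> contact rows touching it
  ids <- c(contacts$i, contacts$j)
  rows <- rep(seq_len(m), 2)
  inc <- split(rows, ids)
  out <- list()
  for (c1 in scope) {
    reach <- unique(c(near3[[as.character(contacts$i[c1])]],
                      near3[[as.character(contacts$j[c1])]]))
    partners <- unique(unlist(inc[as.character(reach)], use.names = FALSE))
    partners <- partners[!is.na(partners) & partners != c1]
    if (length(partners) > 0)
      out[[length(out) + 1L]] <- cbind(pmin(c1, partners),
                                       pmax(c1, partners))
  }
  if (length(out) == 0) return(matrix(integer(), 0, 2))
  pairs <- unique(do.call(rbind, out))
  pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
}

#' Brute-force co-occurring-pair oracle
#'
#' Reference double loop over all contact pairs, deciding co-occurrence
#' from pairwise covalent-bond distances. Validates [cooccurring_pairs()].
#'
#' @param contacts contact data frame.
#' @param bonds a `bond_graph`.
#' @param scope optional contact row indices (as in [cooccurring_pairs()]).
#' @return two-column integer matrix of row-index pairs.
#' @export
cooccurring_pairs_bruteforce <- function(contacts, bonds, scope = NULL) {
  m <- nrow(contacts)
  if (m < 2) return(matrix(integer(), 0, 2))
  if (is.null(scope)) scope <- seq_len(m)
  ends <- unique(c(contacts$i, contacts$j))
  dm <- igraph::distances(bonds$graph, v = as.character(ends),
                          to = as.character(ends))
  st <- function(a, b) dm[as.character(a), as.character(b)]
  out <- list()
  for (a in seq_len(m - 1)) {
    for (b in seq.int(a + 1L, m)) {
      if (!(a %in% scope) && !(b %in% scope)) next
      i <- contacts$i[a]; j <- contacts$j[a]
      ip <- contacts$i[b]; jp <- contacts$j[b]
      shared <- length(intersect(c(i, j), c(ip, jp))) > 0
      if (shared ||
          min(st(i, ip), st(i, jp), st(j, ip), st(j, jp)) <= 3)
        out[[length(out) + 1L]] <- c(a, b)
    }
  }
  if (length(out) == 0) return(matrix(integer(), 0, 2))
  do.call(rbind, out)
}

#' Co-occurrence feature vector (105 elements)
#'
#' Over all co-occurring pairs in which at least one member is a mutated
#' contact of the residue, the element for the unordered type pair
#' (t, t') accumulates the sum of the two contacts' weights; each
#' unordered pair contributes once.
#'
#' @inheritParams mutated_contact_vector
#' @return named numeric vector of length 105.
#' @export
cooccurrence_vector <- function(ctx, res_key) {
  nm <- feature_names()[39:143]
  out <- stats::setNames(numeric(105), nm)
  ct <- ctx$contacts
  mut <- mutated_atoms(ctx$structure, res_key)
  scope <- contacts_touching(ct, mut)
  if (length(scope) == 0 || nrow(ct) < 2) return(out)
  pairs <- cooccurring_pairs(ct, ctx$near3, scope = scope)
  if (nrow(pairs) == 0) return(out)
  idx <- cooc_index(ct$type[pairs[, 1]], ct$type[pairs[, 2]])
  val <- ct$w[pairs[, 1]] + ct$w[pairs[, 2]]
  for (k in unique(idx)) out[k] <- ssum(val[idx == k])
  out
}

#' Assemble the full 143-element mutation descriptor
#'
#' Concatenates the ASA-loss features (2), the B-factor sub-vector (8),
#' the mutated-contact vector (14), the neighborhood cross-interface
#' vector (14) and the co-occurrence vector (105), in that order, under
#' the stable schema of [feature_names()].
#'
#' @inheritParams mutated_contact_vector
#' @return named numeric vector of length 143.
#' @export
assemble_features <- function(ctx, res_key) {
  atoms <- ctx$structure$atoms
  side <- atoms$side[match(res_key, atoms$res_key)]
  if (is.na(side)) stop("mutation residue not found or is water: ", res_key)
  dasa <- delta_asa_features(res_key, ctx$asa_bound,
                             ctx$asa_unbound[[side]], atoms)
  v <- c(dasa,
         bfactor_vector(ctx$structure, res_key, ctx$bnorm),
         mutated_contact_vector(ctx, res_key),
         neighborhood_interface_vector(ctx, res_key),
         cooccurrence_vector(ctx, res_key))
  names(v) <- feature_names()
  v
}

#' Extract the feature matrix for a set of mutations
#'
#' @param structure a `complex_structure`.
#' @param mutations data frame with columns `chain`, `resno`, `wt`
#'   (3-letter wild-type name) and optionally `insert`, `ddg`
#'   (kcal/mol) and/or `label` (Strong/Intermediate/Weak/Insignificant).
#'   Gly and Ala positions are rejected (Gly-to-Ala is never scored and
#'   Ala-to-Ala is vacuous).
#' @param params a [hotspot_params()] list.
#' @param ctx optionally a precomputed [prepare_complex()] context.
#' @return list of class `hotspot_features`: `X` (n x 143 matrix, one row
#'   per mutation), `mutations` (annotated input), `ctx`.
#' @export
extract_features <- function(structure, mutations, params = hotspot_params(),
                             ctx = NULL) {
  if (is.null(ctx)) ctx <- prepare_complex(structure, params)
  atoms <- ctx$structure$atoms
  ins <- if ("insert" %in% names(mutations)) mutations$insert else ""
  res_keys <- paste0(mutations$chain, mutations$resno, ins)
  X <- matrix(NA_real_, nrow(mutations), 143,
              dimnames = list(res_keys, feature_names()))
  for (r in seq_len(nrow(mutations))) {
    rk <- res_keys[r]
    row <- atoms[atoms$res_key == rk & !atoms$is_water, , drop = FALSE]
    if (nrow(row) == 0)
      stop("mutation residue not found in structure: ", rk)
    wt <- toupper(mutations$wt[r])
    if (row$resname[1] != wt)
      stop("wild-type mismatch at ", rk, ": structure has ", row$resname[1],
           ", mutation table says ", wt)
    if (wt %in% c("GLY", "ALA"))
      stop("alanine mutation of ", wt, " at ", rk, " is not scored")
    X[r, ] <- assemble_features(ctx, rk)
  }
  mutations$res_key <- res_keys
  structure(list(X = X, mutations = mutations, ctx = ctx),
            class = "hotspot_features")
}
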