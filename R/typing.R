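#' Atom group (0..9) of each atom
#'
#' Types atoms into the 10 groups used for contact classification (see
#' `extdata/atom_groups.tsv`): carbons are split by covalent topology into
#' C_c (group 0, no bond to O/N) and C_on (group 1, bonded to O or N);
#' nitrogen donors split neutral/charged (2/3); oxygens split
#' carbonyl/carboxylate/hydroxyl (4/5/6); sulfur is 7, ring pseudo-atoms 8
#' and water oxygens 9.
#'
#' @param atoms atom data frame (any subset of rows).
#' @param bonds `bond_graph` of the full structure (resolves C_c vs C_on).
#' @return integer vector of group indices, same length as `nrow(atoms)`.
#' @export
atom_group <- function(atoms, bonds) {
  tab <- atom_group_table()
  out <- rep(NA_integer_, nrow(atoms))
  out[atoms$is_pseudo] <- 8L
  wat <- atoms$is_water & !atoms$is_pseudo
  out[wat] <- 9L
  todo <- which(is.na(out))
  if (length(todo) == 0) return(out)
  spec <- tab$group[match(paste(atoms$resname[todo], atoms$name[todo]),
                          paste(tab$res_name, tab$atom_name))]
  wild <- tab$group[match(paste("*", atoms$name[todo]),
                          paste(tab$res_name, tab$atom_name))]
  g <- ifelse(is.na(spec), wild, spec)
  carbon <- (is.na(g) & atoms$element[todo] == "C") |
    (!is.na(g) & g == "C")
  bad <- is.na(g) & !carbon
  if (any(bad))
    stop("unmapped atom(s): ",
         paste(unique(paste(atoms$resname[todo][bad], atoms$name[todo][bad])),
               collapse = ", "))
  out[todo[!carbon]] <- as.integer(g[!carbon])
  if (any(carbon)) {
    ids <- atoms$atom_id[todo[carbon]]
    nb <- nearby_sets(bonds, ids, steps = 1)
    full <- get_full_atoms(atoms, bonds)
    out[todo[carbon]] <- vapply(seq_along(ids), function(k) {
      partners <- setdiff(nb[[as.character(ids[k])]], ids[k])
      ele <- full$element[match(partners, full$atom_id)]
      if (any(ele %in% c("N", "O"), na.rm = TRUE)) 1L else 0L
    }, integer(1))
  }
  out
}

# atom_group may be called on a subset of atoms; C_c/C_on needs bonded
# partners' elements, which the caller's subset may lack. The bond graph
# only stores ids, so the full atom table travels alongside via attribute.
get_full_atoms <- function(atoms, bonds) {
  full <- attr(bonds, "atoms")
  if (is.null(full)) atoms else full
}

#' Attach the full atom table to a bond graph
#'
#' Lets [atom_group()] resolve carbon topology when called on atom
#' subsets.
#' @param bonds a `bond_graph`.
#' @param atoms the full atom table of the structure.
#' @return the annotated `bond_graph`.
#' @export
bind_atom_table <- function(bonds, atoms) {
  attr(bonds, "atoms") <- atoms
  bonds
}

atom_group_table <- function() {
  if (is.null(.hotspot_env$atom_groups)) {
    df <- utils::read.delim(hotspot_extdata("atom_groups.tsv"),
                            comment.char = "#", stringsAsFactors = FALSE,
                            colClasses = "character")
    .hotspot_env$atom_groups <- df
  }
  .hotspot_env$atom_groups
}

#' Contact type (0..13) of an atom-group pair
#'
#' Symmetric lookup in the bundled contact-type table
#' (`extdata/contact_types.tsv`).
#'
#' @param group_a,group_b atom group indices (0..9), vectorized.
#' @return integer contact type(s) in 0..13.
#' @export
contact_type <- function(group_a, group_b) {
  m <- contact_type_matrix()
  m[cbind(group_a + 1L, group_b + 1L)]
}

contact_type_matrix <- function() {
  if (is.null(.hotspot_env$ctypes)) {
    df <- utils::read.delim(hotspot_extdata("contact_types.tsv"),
                            comment.char = "#", stringsAsFactors = FALSE)
    m <- matrix(NA_integer_, 10, 10)
    m[cbind(df$group_a + 1L, df$group_b + 1L)] <- df$type
    m[cbind(df$group_b + 1L, df$group_a + 1L)] <- df$type
    if (anyNA(m)) stop("contact type table does not cover all group pairs")
    .hotspot_env$ctypes <- m
  }
  .hotspot_env$ctypes
}

#' Triangular index of an unordered contact-type pair
#'
#' Maps an unordered pair of contact types (0..13) to its position (1..105)
#' in the co-occurrence block, row-major over the upper triangle:
#' (0,0), (0,1), ..., (0,13), (1,1), ..., (13,13).
#'
#' @param t_a,t_b contact types (order-free), vectorized.
#' @return integer index in 1..105.
#' @export
cooc_index <- function(t_a, t_b) {
  t1 <- pmin(t_a, t_b)
  t2 <- pmax(t_a, t_b)
  t1 * 14L - (t1 * (t1 - 1L)) %/% 2L + (t2 - t1) + 1L
}

#' Names of the 143 features, in model order
#'
#' Layout: 2 ASA-loss features, 8 B-factor features, 14 mutated-contact
#' types, 14 neighborhood cross-interface contact types, 105 co-occurrence
#' type pairs. The compact positional label of feature k is simply "Vk"
#' (1-based), so e.g. V14 is the mutated hydrophobic-contact element and
#' V84 the (3,9) co-occurrence element.
#'
#' @return character vector of length 143.
#' @export
feature_names <- function() {
  tt <- sprintf("t%02d", 0:13)
  pairs <- character(105)
  for (a in 0:13) for (b in a:13)
    pairs[cooc_index(a, b)] <- sprintf("cooc_t%02d_t%02d", a, b)
  c("dASA_log", "dASA_rel",
    paste0(c("Bavg_g", "Bdif_g"), rep(1:4, each = 2)),
    paste0("mut_", tt), paste0("nbr_", tt), pairs)
}
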