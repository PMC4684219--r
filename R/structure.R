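STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")
WATER_RES <- c("HOH", "WAT", "DOD")
BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' Read a protein complex from a PDB file
#'
#' Parses ATOM/HETATM records with bio3d, discards hydrogens, resolves
#' alternate locations to the highest-occupancy copy (ties broken by file
#' order), keeps water molecules (HOH) separately from the two protein
#' sides, and attaches van der Waals radii and backbone flags. Non-standard
#' residues are skipped with a warning. Atoms without a B factor are fatal:
#' the method requires crystallographic B factors.
#'
#' @param path PDB file.
#' @param side_a,side_b chain identifiers of the two interacting sides,
#'   either as character vectors (`c("A","B")`) or compact strings (`"AB"`).
#' @param structure_id optional identifier; defaults to the file name.
#' @return An object of class `complex_structure`: a list with
#'   `structure_id`, `side_a`, `side_b` and `atoms`, a data frame with one
#'   row per heavy atom carrying `atom_id`, `name`, `element`, `resname`,
#'   `chain`, `resno`, `insert`, `res_key`, coordinates `x,y,z`, B factor
#'   `b`, occupancy `occ`, flags `is_water`, `is_pseudo`, `is_backbone`,
#'   side assignment `side` ("A"/"B", NA for water) and `vdw` radius.
#' @export
read_complex <- function(path, side_a, side_b, structure_id = NULL) {
  side_a <- parse_chain_set(side_a)
  side_b <- parse_chain_set(side_b)
  if (length(intersect(side_a, side_b)) > 0)
    stop("side_a and side_b share chains: ",
         paste(intersect(side_a, side_b), collapse = ","))
  pdb <- bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  # element symbol: PDB columns 77-78 when present, else from the atom name
  ele <- toupper(trimws(as.character(at$elesy)))
  miss <- is.na(ele) | ele == ""
  if (any(miss))
    ele[miss] <- toupper(suppressWarnings(bio3d::atom2ele(at$elety[miss])))
  at$element <- ele
  at <- at[!(at$element %in% c("H", "D")), , drop = FALSE]

  resname <- toupper(trimws(at$resid))
  is_water <- resname %in% WATER_RES
  known <- resname %in% STANDARD_AA | is_water
  if (any(!known)) {
    warning("skipping non-standard residue(s): ",
            paste(unique(resname[!known]), collapse = ", "))
    at <- at[known, , drop = FALSE]
    resname <- resname[known]
    is_water <- is_water[known]
  }

  chains <- unique(at$chain[!is_water])
  missing_chains <- setdiff(c(side_a, side_b), chains)
  if (length(missing_chains) > 0)
    stop("chain(s) not present in ", path, ": ",
         paste(missing_chains, collapse = ","))
  unassigned <- setdiff(chains, c(side_a, side_b))
  if (length(unassigned) > 0)
    stop("protein chain(s) not assigned to a side: ",
         paste(unassigned, collapse = ","))

  if (anyNA(at$b))
    stop("atom(s) with missing B factor; the method requires B factors")

  insert <- at$insert
  insert[is.na(insert)] <- ""
  occ <- at$o
  occ[is.na(occ)] <- 1

  atoms <- data.frame(
    name = trimws(at$elety), element = at$element,
    resname = resname, chain = at$chain,
    resno = at$resno, insert = insert,
    x = at$x, y = at$y, z = at$z, b = at$b, occ = occ,
    is_water = is_water, stringsAsFactors = FALSE)

  # alternate locations: keep highest occupancy, tie -> first in file order
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$resname,
               atoms$name, sep = "|")
  keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(idx) {
    idx[which.max(atoms$occ[idx])]
  }), use.names = FALSE)
  atoms <- atoms[sort(keep), , drop = FALSE]

  atoms$res_key <- paste0(atoms$chain, atoms$resno, atoms$insert)
  atoms$is_pseudo <- FALSE
  atoms$is_backbone <- !atoms$is_water & atoms$name %in% BACKBONE_ATOMS
  atoms$side <- ifelse(atoms$is_water, NA_character_,
                       ifelse(atoms$chain %in% side_a, "A", "B"))
  atoms$vdw <- vdw_radius(atoms$element)
  atoms$atom_id <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates in ", path)

  structure(list(structure_id = structure_id %||% basename(path),
                 side_a = side_a, side_b = side_b, atoms = atoms),
            class = "complex_structure")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse a chain-side specification
#'
#' Accepts `c("A","B")`, `"AB"` or `"A,B"`; the CLI form `"AB:CD"` is split
#' by [parse_side_spec()].
#' @param x chain set in any accepted form.
#' @return character vector of single-character chain ids.
#' @keywords internal
parse_chain_set <- function(x) {
  x <- unlist(strsplit(as.character(x), ",", fixed = TRUE))
  x <- unlist(strsplit(x, "", fixed = TRUE))
  x <- unique(x[nzchar(trimws(x))])
  if (length(x) == 0) stop("empty chain set")
  x
}

#' Split a "A:B" / "AB:CD" side specification into two chain sets
#' @param spec string with the two sides separated by ":".
#' @return list with elements `side_a`, `side_b`.
#' @export
parse_side_spec <- function(spec) {
  parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop("side specification must be like 'A:B' or 'AB:CD'")
  list(side_a = parse_chain_set(parts[1]), side_b = parse_chain_set(parts[2]))
}

#' @export
print.complex_structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("complex_structure '%s': %d atoms (%d water, %d pseudo)\n",
              x$structure_id, nrow(a), sum(a$is_water), sum(a$is_pseudo)))
  cat(sprintf("  side A chains: %s   side B chains: %s\n",
              paste(x$side_a, collapse = ","), paste(x$side_b, collapse = ",")))
  invisible(x)
}

#' Write a complex back to PDB text
#'
#' Pseudo-atoms are bookkeeping constructs and are not written.
#'
#' @param structure a `complex_structure`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_complex_pdb <- function(structure, path) {
  a <- structure$atoms[!structure$atoms$is_pseudo, , drop = FALSE]
  lines <- vapply(seq_len(nrow(a)), function(i) {
    rec <- if (a$is_water[i]) "HETATM" else "ATOM"
    nm <- a$name[i]
    nm_fmt <- if (nchar(nm) >= 4) substr(nm, 1, 4) else sprintf(" %-3s", nm)
    sprintf("%-6s%5d %4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            rec, a$atom_id[i], nm_fmt, a$resname[i], a$chain[i], a$resno[i],
            ifelse(nzchar(a$insert[i]), a$insert[i], " "),
            a$x[i], a$y[i], a$z[i], a$occ[i], a$b[i], a$element[i])
  }, character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Coordinates of an atom table as a matrix
#' @param atoms atom data frame.
#' @return n x 3 numeric matrix.
#' @keywords internal
atom_xyz <- function(atoms) {
  as.matrix(atoms[, c("x", "y", "z")])
}
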