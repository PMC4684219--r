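#' Amino-acid group of a residue (1..4)
#'
#' The 20 standard residues fall into four groups for the B-factor
#' features: group 1 small/hydrophobic (ILE, VAL, LEU, MET, ALA, GLY),
#' group 2 polar/other (CYS, THR, SER, PRO, HIS, GLN, ASN), group 3
#' charged (GLU, ASP, LYS, ARG), group 4 aromatic (PHE, TRP, TYR).
#'
#' @param resname 3-letter residue name(s).
#' @return integer group index in 1..4.
#' @export
residue_group <- function(resname) {
  groups <- list(
    c("ILE", "VAL", "LEU", "MET", "ALA", "GLY"),
    c("CYS", "THR", "SER", "PRO", "HIS", "GLN", "ASN"),
    c("GLU", "ASP", "LYS", "ARG"),
    c("PHE", "TRP", "TYR"))
  idx <- rep(NA_integer_, length(resname))
  for (g in seq_along(groups)) idx[toupper(resname) %in% groups[[g]]] <- g
  if (anyNA(idx))
    stop("unknown residue name(s): ",
         paste(unique(resname[is.na(idx)]), collapse = ", "))
  idx
}

#' Trimmed B-factor statistics of a complex
#'
#' After sorting all atomic B factors ascending, the smallest
#' `floor(trim_low * n)` values are dropped (guards deposited B = 0
#' errors) and the largest `floor(trim_high * n)` values are dropped
#' (outliers); the mean and population standard deviation of the remainder
#' define the per-complex normalization.
#'
#' @param b numeric vector of raw B factors (squared Angstrom); at least
#'   10 values.
#' @param trim_low,trim_high trim fractions (defaults 0.01 and 0.09).
#' @return list of class `bfactor_stats` with `mean`, `std`, `n_used`,
#'   `trim_low`, `trim_high`.
#' @export
trimmed_bfactor_stats <- function(b, trim_low = 0.01, trim_high = 0.09) {
  n <- length(b)
  if (n < 10) stop("need at least 10 B factors, got ", n)
  b <- sort(b)  # ties keep original (file) order: sort is stable on values
  lo <- floor(trim_low * n)
  hi <- floor(trim_high * n)
  kept <- b[seq.int(lo + 1L, n - hi)]
  m <- mean(kept)
  s <- sqrt(mean((kept - m)^2))
  if (s == 0) stop("degenerate B factors: zero spread after trimming")
  structure(list(mean = m, std = s, n_used = length(kept),
                 trim_low = trim_low, trim_high = trim_high),
            class = "bfactor_stats")
}

#' Normalize a B factor
#'
#' `(b - mean) / (std * 1.645)`: the factor 1.645 maps the 90% confidence
#' interval of a normal distribution onto [-1, 1].
#'
#' @param b raw B factor(s).
#' @param stats a `bfactor_stats`.
#' @return normalized B factor(s), dimensionless.
#' @export
normalize_bfactor <- function(b, stats) {
  (b - stats$mean) / (stats$std * 1.645)
}

#' Clamp a normalized B factor to [-2, 0]
#'
#' The working value is `(b_norm - 1)` clamped to [-2, 0]: an atom at the
#' complex mean maps to -1, the upper end of the 90% interval to 0, the
#' lower end to -2, and anything outside the interval snaps to whichever
#' bound is closer.
#'
#' @param b_norm normalized B factor(s) from [normalize_bfactor()].
#' @return clamped value(s) in [-2, 0].
#' @export
clamp_bfactor <- function(b_norm) {
  pmin(pmax(b_norm - 1, -2), 0)
}

#' The 8-element B-factor feature sub-vector of a mutation
#'
#' For a mutated residue of amino-acid group g (1..4), positions
#' (2g-1, 2g) of the 8-vector hold `Bavg` (mean clamped-normalized B over
#' the mutated atoms) and `Bdif` (`Bavg` minus the mean over the residue's
#' backbone N and C atoms); all other positions are exactly zero.
#'
#' @param structure a `complex_structure`.
#' @param res_key residue key of the mutated residue.
#' @param bnorm named vector of clamped-normalized B factors by atom id
#'   (see [clamp_bfactor()]).
#' @return named numeric vector of length 8
#'   (`Bavg_g1, Bdif_g1, ..., Bavg_g4, Bdif_g4`).
#' @export
bfactor_vector <- function(structure, res_key, bnorm) {
  atoms <- structure$atoms
  res <- atoms[atoms$res_key == res_key & !atoms$is_water, , drop = FALSE]
  if (nrow(res) == 0) stop("residue not found: ", res_key)
  g <- residue_group(res$resname[1])
  mut <- mutated_atoms(structure, res_key, include_pseudo = FALSE)
  if (length(mut) == 0)
    stop("no mutated atoms for ", res_key, " (", res$resname[1], ")")
  bb <- res$atom_id[res$name %in% c("N", "C")]
  if (length(bb) < 2)
    stop("missing backbone N/C atoms for ", res_key)
  b_avg <- mean(bnorm[as.character(mut)])
  b_dif <- b_avg - mean(bnorm[as.character(bb)])
  out <- stats::setNames(numeric(8),
                         paste0(c("Bavg_g", "Bdif_g"), rep(1:4, each = 2)))
  out[2 * g - 1] <- b_avg
  out[2 * g] <- b_dif
  out
}

#' Atoms removed by an X-to-Ala substitution
#'
#' The side-chain heavy atoms of the wild-type residue beyond CB (the
#' standard alanine-scanning convention), plus the residue's aromatic-ring
#' pseudo-atoms when `include_pseudo` is set (the ring vanishes with the
#' side chain).
#'
#' @param structure a `complex_structure`.
#' @param res_key residue key.
#' @param include_pseudo include ring pseudo-atoms (default TRUE).
#' @return integer vector of atom ids.
#' @export
mutated_atoms <- function(structure, res_key, include_pseudo = TRUE) {
  res <- structure$atoms[structure$atoms$res_key == res_key, , drop = FALSE]
  keep <- !res$is_backbone & res$name != "CB" & !res$is_water
  if (!include_pseudo) keep <- keep & !res$is_pseudo
  res$atom_id[keep]
}
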