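#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Numeric ASA: each atom's sphere of radius (vdw + probe) is sampled with
#' `n_points` quasi-uniform points (golden-spiral construction); a point is
#' accessible when it lies outside every other atom's expanded sphere, and
#' the atom's ASA is the accessible fraction times the sphere area.
#' Pseudo-atoms are bookkeeping constructs and are ignored both as targets
#' and as occluders.
#'
#' @param atoms atom data frame (see [read_complex()]); rows define both
#'   the atoms scored and the occluding environment.
#' @param probe_radius solvent probe radius in Angstrom (default 1.4).
#' @param n_points sphere sample points per atom (default 960).
#' @return Named numeric vector of ASA values in squared Angstrom, indexed
#'   by `atom_id`.
#' @export
compute_asa <- function(atoms, probe_radius = 1.4, n_points = 960) {
  if (n_points < 1) stop("n_points must be >= 1")
  atoms <- atoms[!atoms$is_pseudo, , drop = FALSE]
  n <- nrow(atoms)
  out <- stats::setNames(numeric(n), atoms$atom_id)
  if (n == 0) return(out)
  xyz <- atom_xyz(atoms)
  radii <- atoms$vdw + probe_radius
  pts <- sphere_points(n_points)
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    ri <- radii[i]
    nb <- which(d2[i, ] < (ri + radii)^2)
    nb <- nb[nb != i]
    acc_area <- 4 * pi * ri^2
    if (length(nb) == 0) { out[i] <- acc_area; next }
    p <- sweep(pts * ri, 2, xyz[i, ], "+")
    buried <- rep(FALSE, n_points)
    for (j in nb) {
      rj2 <- radii[j]^2
      dx <- p[, 1] - xyz[j, 1]
      dy <- p[, 2] - xyz[j, 2]
      dz <- p[, 3] - xyz[j, 3]
      buried <- buried | (dx * dx + dy * dy + dz * dz < rj2)
      if (all(buried)) break
    }
    out[i] <- acc_area * mean(!buried)
  }
  out
}

#' Quasi-uniform points on the unit sphere (golden spiral)
#' @param n number of points.
#' @return n x 3 matrix of unit vectors.
#' @keywords internal
sphere_points <- function(n) {
  k <- seq_len(n) - 0.5
  z <- 1 - 2 * k / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (1 + sqrt(5)) * k
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Sum per-atom ASA to residues
#' @param asa named ASA vector from [compute_asa()].
#' @param atoms atom data frame containing the same atoms.
#' @return named numeric vector by `res_key`.
#' @export
residue_asa <- function(asa, atoms) {
  atoms <- atoms[match(as.integer(names(asa)), atoms$atom_id), , drop = FALSE]
  tapply(asa, atoms$res_key, sum)
}

#' ASA-loss features of a mutated residue
#'
#' The loss of accessible surface upon complex formation for the mutated
#' residue: `dASA = ASA_unbound - ASA_bound` (clamped at 0 against
#' numerical noise). Returns the two features used by the model,
#' `f_log = log(dASA + 1)` (natural log; the +1 guards dASA = 0) and
#' `f_rel = dASA / ASA_unbound` (0 when the unbound ASA is 0).
#'
#' @param res_key residue key of the mutated residue.
#' @param asa_bound,asa_unbound named per-atom ASA vectors for the bound
#'   complex and for the residue's own side unbound.
#' @param atoms atom data frame covering the residue's atoms.
#' @return numeric vector `c(f_log, f_rel)`.
#' @export
delta_asa_features <- function(res_key, asa_bound, asa_unbound, atoms) {
  ids <- atoms$atom_id[atoms$res_key == res_key & !atoms$is_pseudo &
                         !atoms$is_water]
  if (length(ids) == 0) stop("residue not found: ", res_key)
  bnd <- asa_bound[as.character(ids)]
  unb <- asa_unbound[as.character(ids)]
  if (anyNA(bnd) || anyNA(unb))
    stop("residue ", res_key, " missing from an ASA table")
  dasa <- max(sum(unb) - sum(bnd), 0)
  tot_unb <- sum(unb)
  c(f_log = log1p(dasa),
    f_rel = if (tot_unb > 0) dasa / tot_unb else 0)
}
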