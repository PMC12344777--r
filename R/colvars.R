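# The two metadynamics collective variables used for ligand ejection:
# binding-site COM distance and solvation coordination. Only the CVs are
# implemented; the well-tempered biasing engine is out of scope (the runs
# behind this package used bias factor 15, Gaussian widths 0.15 A / 0.03,
# initial height 1.2 kJ/mol in an external engine).

#' Solvation coordination parameters
#'
#' @param d0 reference distance, angstrom (default 2.5).
#' @param num_exp numerator exponent (positive even integer, default 6).
#' @param den_exp denominator exponent (positive even integer > `num_exp`,
#'   default 10).
#' @param cutoff hard pair-inclusion cutoff, angstrom (default 10).
#' @return object of class `pp_solvation_params`.
#' @export
solvation_params <- function(d0 = 2.5, num_exp = 6L, den_exp = 10L,
                             cutoff = 10) {
  stopifnot(d0 > 0, cutoff > d0,
            num_exp > 0, den_exp > num_exp,
            num_exp %% 2 == 0, den_exp %% 2 == 0)
  structure(list(d0 = d0, num_exp = as.integer(num_exp),
                 den_exp = as.integer(den_exp), cutoff = cutoff),
            class = "pp_solvation_params")
}

#' Centre-of-mass distance between two atom selections
#'
#' Euclidean distance between the mass-weighted centroids of the two
#' selections; masses from [atomic_mass()] of the element column.
#'
#' @param frame a `pp_frame`.
#' @param sel_a,sel_b integer atom index vectors (e.g. ligand atoms and
#'   binding-residue atoms).
#' @return distance in angstrom.
#' @export
com_distance <- function(frame, sel_a, sel_b) {
  if (!length(sel_a) || !length(sel_b)) stop("empty atom selection")
  com <- function(sel) {
    m <- atomic_mass(frame$atoms$elem[sel])
    colSums(frame$xyz[sel, , drop = FALSE] * m) / sum(m)
  }
  vec_norm(com(sel_a) - com(sel_b))
}

# One switching term (1 - r^p) / (1 - r^q) with r = d/d0, evaluated at its
# limit p/q at the removable singularity r = 1.
switch_term <- function(d, d0, p, q) {
  r <- d / d0
  out <- numeric(length(r))
  sing <- abs(r - 1) < 1e-9
  out[!sing] <- (1 - r[!sing]^p) / (1 - r[!sing]^q)
  out[sing] <- p / q
  out
}

#' Ligand solvation coordination number
#'
#' The sum over (ligand carbon, water oxygen) pairs within the cutoff of
#' `(1 - (d/d0)^6) / (1 - (d/d0)^10)` with `d0 = 2.5` angstrom by default.
#' Each term is 1 at contact, 6/10 at `d = d0`, and decays toward 0; pairs
#' beyond the hard cutoff are excluded.
#'
#' @param frame a `pp_frame`.
#' @param params a [solvation_params()] object.
#' @param ligand_carbons integer atom indices; default all ligand carbons.
#' @param water_oxygens integer atom indices; default all water oxygens.
#' @return dimensionless coordination number.
#' @export
solvation_coordination <- function(frame, params = solvation_params(),
                                   ligand_carbons = NULL,
                                   water_oxygens = NULL) {
  at <- frame$atoms
  if (is.null(ligand_carbons)) {
    ligand_carbons <- which(at$role == "ligand" & at$elem == "C")
  }
  if (is.null(water_oxygens)) {
    water_oxygens <- which(at$role == "water" & at$elem == "O")
  }
  if (!length(ligand_carbons) || !length(water_oxygens)) return(0)
  d <- cross_dist(frame$xyz[ligand_carbons, , drop = FALSE],
                  frame$xyz[water_oxygens, , drop = FALSE])
  d <- d[d <= params$cutoff]
  if (!length(d)) return(0)
  sum(switch_term(d, params$d0, params$num_exp, params$den_exp))
}

#' Collective-variable series over a trajectory
#'
#' @param trajectory a `pp_trajectory`.
#' @param site_atoms integer indices of the binding-residue atoms defining
#'   the site COM.
#' @param ligand_atoms integer indices of the ligand atoms.
#' @param params a [solvation_params()] object.
#' @return data frame: frame, com_distance_A, solvation.
#' @export
cv_series <- function(trajectory, site_atoms, ligand_atoms,
                      params = solvation_params()) {
  nf <- n_frames(trajectory)
  cd <- numeric(nf); sv <- numeric(nf)
  for (k in seq_len(nf)) {
    fr <- trajectory_frame(trajectory, k)
    cd[k] <- com_distance(fr, ligand_atoms, site_atoms)
    sv[k] <- solvation_coordination(fr, params,
                                    ligand_carbons = intersect(
                                      ligand_atoms,
                                      which(fr$atoms$elem == "C")))
  }
  data.frame(frame = trajectory$frame_index, com_distance_A = cd,
             solvation = sv)
}
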