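# Subunit-assembly metrics: channel axis, backbone RMSD, per-loop RMSF,
# intersubunit contact maps, planar intra-/interpocket centroid distances,
# Loop C angle correlations and push-pull distance analysis.

#' Pseudo-C5 channel axis of a frame
#'
#' Eigenvector of the protein CA gyration tensor with the unique eigenvalue
#' (the smallest-spread axis for a ring-like assembly), sign-oriented from
#' the restrained C-terminal tail centroid toward the overall CA centroid.
#'
#' @param frame a `pp_frame`.
#' @param topology a `pp_topology` (supplies the restrained-tail range).
#' @return unit length-3 vector.
#' @export
channel_axis <- function(frame, topology) {
  at <- frame$atoms
  ca <- which(at$role == "protein" & at$elety == "CA")
  if (length(ca) < 3L) stop("need at least 3 CA atoms per frame")
  xyz <- frame$xyz[ca, , drop = FALSE]
  gy <- stats::cov(xyz)
  eg <- eigen(gy, symmetric = TRUE)
  lam <- eg$values
  sep <- vapply(1:3, function(i) min(abs(lam[i] - lam[-i])), numeric(1))
  if (max(sep) < 1e-9 * max(abs(lam))) {
    stop("degenerate gyration tensor: no unique axis")
  }
  axis <- eg$vectors[, which.max(sep)]
  tail_rng <- topology$restrained_tail
  tail_ca <- ca[at$resno[ca] >= tail_rng[1] & at$resno[ca] <= tail_rng[2]]
  if (length(tail_ca)) {
    ref <- colMeans(xyz) - colMeans(frame$xyz[tail_ca, , drop = FALSE])
    if (sum(axis * ref) < 0) axis <- -axis
  }
  unit_vec(axis)
}

# Backbone atom indices (N, CA, C, O) of one subunit chain.
backbone_idx <- function(atoms, chain) {
  which(atoms$role == "protein" & atoms$chain == chain &
          atoms$elety %in% c("N", "CA", "C", "O"))
}

# Flatten trajectory coords for a subset of atoms into a bio3d-style
# n_frames x 3m xyz matrix.
traj_xyz_matrix <- function(trajectory, idx) {
  nf <- n_frames(trajectory)
  out <- matrix(NA_real_, nf, 3L * length(idx))
  for (k in seq_len(nf)) {
    out[k, ] <- as.vector(t(trajectory$coords[idx, , k]))
  }
  out
}

#' Backbone RMSD of one subunit along a trajectory
#'
#' Optimal-superposition (Kabsch) RMSD of the subunit backbone against a
#' reference frame (the first frame by default).
#'
#' @param trajectory a `pp_trajectory`.
#' @param subunit subunit index 0..4 or chain ID.
#' @param topology a `pp_topology` (for chain lookup by index).
#' @param reference reference frame position (1-based), default 1.
#' @return numeric RMSD series in angstrom, one value per frame.
#' @export
backbone_rmsd <- function(trajectory, subunit, topology, reference = 1L) {
  chain <- subunit_chain(topology, subunit)
  idx <- backbone_idx(trajectory$atoms, chain)
  if (length(idx) < 3L) stop("backbone atoms not resolvable for chain ", chain)
  xyz <- traj_xyz_matrix(trajectory, idx)
  inds <- seq_len(ncol(xyz))
  as.numeric(bio3d::rmsd(xyz[reference, ], xyz, a.inds = inds, b.inds = inds,
                         fit = TRUE))
}

subunit_chain <- function(topology, subunit) {
  if (is.character(subunit)) {
    if (!subunit %in% topology$chains) stop("unknown chain: ", subunit)
    return(subunit)
  }
  stopifnot(subunit %in% 0:4)
  topology$chains[subunit + 1L]
}

#' Per-residue CA RMSF of one subunit, grouped by binding-pocket loop
#'
#' Two-pass procedure: every frame's subunit backbone is first superposed
#' onto the initial frame, the average structure is computed, each frame is
#' re-superposed onto that average, and the per-residue CA RMSF about the
#' average is reported.
#'
#' @param trajectory a `pp_trajectory` with at least 2 frames.
#' @param subunit subunit index 0..4 or chain ID.
#' @param topology a `pp_topology`; `topology$loops` names the loop ranges.
#' @return data frame with columns `resno`, `loop` (NA outside all loops)
#'   and `rmsf` (angstrom).
#' @export
loop_rmsf <- function(trajectory, subunit, topology) {
  if (n_frames(trajectory) < 2L) stop("RMSF needs at least 2 frames")
  chain <- subunit_chain(topology, subunit)
  at <- trajectory$atoms
  bb <- backbone_idx(at, chain)
  ca <- which(at$role == "protein" & at$chain == chain & at$elety == "CA")
  xyz <- traj_xyz_matrix(trajectory, bb)
  inds <- seq_len(ncol(xyz))
  fit1 <- bio3d::fit.xyz(xyz[1L, ], xyz, fixed.inds = inds,
                         mobile.inds = inds)
  avg <- colMeans(fit1)
  fit2 <- bio3d::fit.xyz(avg, fit1, fixed.inds = inds, mobile.inds = inds)
  ca_pos <- match(ca, bb)
  cols <- as.vector(rbind(3 * ca_pos - 2, 3 * ca_pos - 1, 3 * ca_pos))
  r <- bio3d::rmsf(fit2[, cols, drop = FALSE])
  resno <- at$resno[ca]
  loop <- rep(NA_character_, length(resno))
  for (nm in names(topology$loops)) {
    rng <- topology$loops[[nm]]
    loop[resno >= rng[1] & resno <= rng[2]] <- nm
  }
  data.frame(resno = resno, loop = loop, rmsf = as.numeric(r))
}

#' Intersubunit CA contact map for one pocket
#'
#' Entry (i, j) is the fraction of frames in which the CA-CA distance
#' between residue i of the principal subunit and residue j of the
#' complementary subunit is strictly below the cutoff.
#'
#' @param trajectory a `pp_trajectory`.
#' @param pocket a `pp_pocket`.
#' @param cutoff distance cutoff in angstrom (default 11).
#' @return matrix of occurrence fractions in \[0, 1\], residue numbers as
#'   dimnames, with attribute `cutoff`.
#' @export
contact_map <- function(trajectory, pocket, cutoff = 11) {
  at <- trajectory$atoms
  ip <- which(at$role == "protein" & at$chain == pocket$principal_chain &
                at$elety == "CA")
  ic <- which(at$role == "protein" & at$chain == pocket$complementary_chain &
                at$elety == "CA")
  nf <- n_frames(trajectory)
  acc <- matrix(0, length(ip), length(ic))
  for (k in seq_len(nf)) {
    d <- cross_dist(trajectory$coords[ip, , k], trajectory$coords[ic, , k])
    acc <- acc + (d < cutoff)
  }
  m <- acc / nf
  dimnames(m) <- list(at$resno[ip], at$resno[ic])
  attr(m, "cutoff") <- cutoff
  m
}

# Planar (orthogonal to axis) distance between two points.
planar_dist <- function(p, q, axis) {
  v <- p - q
  v <- v - sum(v * axis) * axis
  vec_norm(v)
}

#' Intrapocket and interpocket centroid distances
#'
#' Per frame, the CA centroids of each pocket's principal (7 residues) and
#' complementary (4 residues) binding-residue groups are projected onto the
#' plane orthogonal to the channel axis. The intrapocket distance of pocket
#' X is the planar distance between its two centroids; the interpocket
#' distance labelled "x-y" is the planar distance between the
#' complementary-side centroid of pocket x and the principal-side centroid
#' of pocket y, both of which lie on the same subunit.
#'
#' @param trajectory a `pp_trajectory`.
#' @param topology a `pp_topology`.
#' @param axis optional fixed unit axis; default recomputed per frame.
#' @param between_means if `TRUE`, distances are measured once between
#'   time-averaged centroid positions instead of per frame.
#' @return list with data frames `intrapocket` (pocket, occupied, mean, sd)
#'   and `interpocket` (label, mean, sd), plus per-frame matrices
#'   `intrapocket_series` and `interpocket_series`.
#' @export
pocket_com_distances <- function(trajectory, topology, axis = NULL,
                                 between_means = FALSE) {
  nf <- n_frames(trajectory)
  pockets <- pocket_specs(topology)
  prin_c <- array(NA_real_, c(nf, 5L, 3L))
  comp_c <- array(NA_real_, c(nf, 5L, 3L))
  axes <- matrix(NA_real_, nf, 3L)
  for (k in seq_len(nf)) {
    fr <- trajectory_frame(trajectory, k)
    axes[k, ] <- if (is.null(axis)) channel_axis(fr, topology) else unit_vec(axis)
    for (p in 1:5) {
      prin_c[k, p, ] <- colMeans(fr$xyz[pockets[[p]]$ca_principal, , drop = FALSE])
      comp_c[k, p, ] <- colMeans(fr$xyz[pockets[[p]]$ca_complementary, , drop = FALSE])
    }
  }
  # interpocket pairing: pocket x's complementary centroid and pocket y's
  # principal centroid share subunit s = principal_subunit(y); y follows x.
  inter_pairs <- lapply(1:5, function(p) c(x = (p - 2L) %% 5L + 1L, y = p))
  inter_label <- vapply(inter_pairs, function(pr) {
    paste(POCKET_LABELS[pr["x"]], POCKET_LABELS[pr["y"]], sep = "-")
  }, character(1))

  if (between_means) {
    ax <- unit_vec(colMeans(axes))
    intra_s <- matrix(vapply(1:5, function(p) {
      planar_dist(colMeans(prin_c[, p, , drop = FALSE]),
                  colMeans(comp_c[, p, , drop = FALSE]), ax)
    }, numeric(1)), nrow = 1L)
    inter_s <- matrix(vapply(seq_along(inter_pairs), function(i) {
      pr <- inter_pairs[[i]]
      planar_dist(colMeans(comp_c[, pr["x"], , drop = FALSE]),
                  colMeans(prin_c[, pr["y"], , drop = FALSE]), ax)
    }, numeric(1)), nrow = 1L)
  } else {
    intra_s <- matrix(NA_real_, nf, 5L)
    inter_s <- matrix(NA_real_, nf, 5L)
    for (k in seq_len(nf)) {
      for (p in 1:5) {
        intra_s[k, p] <- planar_dist(prin_c[k, p, ], comp_c[k, p, ], axes[k, ])
      }
      for (i in seq_along(inter_pairs)) {
        pr <- inter_pairs[[i]]
        inter_s[k, i] <- planar_dist(comp_c[k, pr["x"], ],
                                     prin_c[k, pr["y"], ], axes[k, ])
      }
    }
  }
  colnames(intra_s) <- POCKET_LABELS
  colnames(inter_s) <- inter_label
  sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else NA_real_
  list(
    intrapocket = data.frame(
      pocket = POCKET_LABELS,
      occupied = topology$occupancy,
      mean = colMeans(intra_s),
      sd = apply(intra_s, 2L, sd0),
      row.names = NULL
    ),
    interpocket = data.frame(
      label = inter_label,
      mean = colMeans(inter_s),
      sd = apply(inter_s, 2L, sd0),
      row.names = NULL
    ),
    intrapocket_series = intra_s,
    interpocket_series = inter_s
  )
}

#' Pearson correlation between two Loop C angle series
#'
#' @param a,b equal-length numeric series (length >= 3, nonzero variance).
#' @return Pearson product-moment correlation coefficient.
#' @export
loopc_correlation <- function(a, b) {
  if (length(a) != length(b)) stop("series must have equal length")
  if (length(a) < 3L) stop("need at least 3 observations")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("undefined correlation: zero-variance series")
  }
  stats::cor(a, b)
}

#' Push-pull distance series and correlations
#'
#' For every consecutive-subunit triplet (s, s', s''): the CA-CA distance
#' between the Loop B' residue on s' (SER174 by default) and the Loop E''
#' residue on s'' (SER145), the distance between the Loop F' residue on s'
#' (LYS189) and the same Loop E'' residue, and the Pearson correlation of
#' the two series. A positive correlation means Loop B' motion transmits to
#' the covalently linked Loop F'.
#'
#' @param trajectory a `pp_trajectory`.
#' @param topology a `pp_topology` (`topology$pushpull` names the residues).
#' @return data frame with one row per triplet: `triplet` (label "x-y" of
#'   the two pockets sharing the middle subunit), the two mean distances and
#'   their correlation (`NA` with a warning if a series has zero variance);
#'   per-frame series attached as attribute `series`.
#' @export
pushpull_analysis <- function(trajectory, topology) {
  pp <- topology$pushpull
  at <- trajectory$atoms
  nf <- n_frames(trajectory)
  res_ca <- function(chain, resno) {
    hit <- which(at$chain == chain & at$resno == resno & at$elety == "CA" &
                   at$role == "protein")
    if (length(hit) != 1L) {
      stop(sprintf("cannot resolve residue %d CA in chain %s", resno, chain))
    }
    hit
  }
  out <- list()
  series <- list()
  undefined <- character(0)
  for (s in 0:4) {
    s1 <- (s + 1L) %% 5L
    s2 <- (s + 2L) %% 5L
    ch1 <- topology$chains[s1 + 1L]
    ch2 <- topology$chains[s2 + 1L]
    iB <- res_ca(ch1, pp$loopB_resno)
    iF <- res_ca(ch1, pp$loopF_resno)
    iE <- res_ca(ch2, pp$loopE_resno)
    dBE <- sqrt(colSums((trajectory$coords[iB, , ] - trajectory$coords[iE, , ])^2))
    dFE <- sqrt(colSums((trajectory$coords[iF, , ] - trajectory$coords[iE, , ])^2))
    lab <- paste(POCKET_LABELS[s + 1L], POCKET_LABELS[s1 + 1L], sep = "-")
    r <- if (nf >= 3L && stats::sd(dBE) > 0 && stats::sd(dFE) > 0) {
      stats::cor(dBE, dFE)
    } else {
      undefined <- c(undefined, lab)
      NA_real_
    }
    out[[length(out) + 1L]] <- data.frame(
      triplet = lab, dBE_mean = mean(dBE), dBE_sd = stats::sd(dBE),
      dFE_mean = mean(dFE), dFE_sd = stats::sd(dFE), correlation = r
    )
    series[[lab]] <- data.frame(frame = trajectory$frame_index,
                                dBE = dBE, dFE = dFE)
  }
  if (length(undefined)) {
    warning("push-pull correlation undefined (zero variance) for triplet(s): ",
            paste(undefined, collapse = ", "))
  }
  res <- do.call(rbind, out)
  attr(res, "series") <- series
  res
}

#' Hydrogen-bond occurrence for conserved interfacial residue pairs
#'
#' For each pocket interface and each configured (principal residue,
#' complementary residue) pair, the percentage of frames with at least one
#' hydrogen bond between the two residues under the standard criteria.
#'
#' @param trajectory a `pp_trajectory`.
#' @param topology a `pp_topology` (`topology$conserved_pairs`).
#' @param criteria an [interaction_criteria()] object.
#' @return data frame: pocket, pair label, occurrence_pct.
#' @export
conserved_pair_hbonds <- function(trajectory, topology,
                                  criteria = interaction_criteria()) {
  pairs <- topology$conserved_pairs
  at <- trajectory$atoms
  nf <- n_frames(trajectory)
  donors0 <- polar_hydrogens(trajectory_frame(trajectory, 1L))
  res_atoms <- function(chain, resno) {
    which(at$chain == chain & at$resno == resno & at$role == "protein")
  }
  out <- list()
  for (pk in pocket_specs(topology)) {
    for (i in seq_len(nrow(pairs))) {
      ap <- res_atoms(pk$principal_chain, pairs$principal_resno[i])
      ac <- res_atoms(pk$complementary_chain, pairs$complementary_resno[i])
      if (!length(ap) || !length(ac)) next
      hits <- 0L
      both <- c(ap, ac)
      dn <- donors0[donors0$donor %in% both, , drop = FALSE]
      acc <- both[at$elem[both] %in% c("N", "O")]
      for (k in seq_len(nf)) {
        fr <- trajectory_frame(trajectory, k)
        hb <- detect_hbonds(fr, donors = dn, acceptors = acc,
                            criteria = criteria)
        if (!nrow(hb)) next
        cross <- (hb$donor %in% ap & hb$acceptor %in% ac) |
          (hb$donor %in% ac & hb$acceptor %in% ap)
        if (any(cross)) hits <- hits + 1L
      }
      out[[length(out) + 1L]] <- data.frame(
        pocket = pk$label, pair = pairs$label[i],
        occurrence_pct = 100 * hits / nf
      )
    }
  }
  if (!length(out)) {
    return(data.frame(pocket = character(0), pair = character(0),
                      occurrence_pct = numeric(0)))
  }
  do.call(rbind, out)
}
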