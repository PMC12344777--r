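# Geometric interaction detectors: hydrogen bonds, water bridges and
# cation-pi contacts, plus their occurrence statistics.

#' Geometric interaction criteria
#'
#' @param hbond_dist donor-acceptor heavy-atom distance cutoff, angstrom.
#' @param hbond_angle donor-H-acceptor angle cutoff, degrees (180 = linear;
#'   a bond requires angle >= cutoff).
#' @param cationpi_dist cation to aromatic-ring-centre distance cutoff,
#'   angstrom.
#' @param cationpi_angle half-window, degrees: the angle between the ring
#'   normal and the centre-to-cation direction must be `< cationpi_angle` or
#'   `> 180 - cationpi_angle`.
#' @return object of class `pp_criteria`.
#' @export
interaction_criteria <- function(hbond_dist = 3.0, hbond_angle = 135,
                                 cationpi_dist = 6.0, cationpi_angle = 45) {
  stopifnot(hbond_dist > 0, cationpi_dist > 0,
            hbond_angle >= 0, hbond_angle <= 180,
            cationpi_angle > 0, cationpi_angle <= 90)
  structure(list(hbond_dist = hbond_dist, hbond_angle = hbond_angle,
                 cationpi_dist = cationpi_dist, cationpi_angle = cationpi_angle),
            class = "pp_criteria")
}

#' Polar hydrogens and their donor heavy atoms
#'
#' Pairs every hydrogen with the nearest N/O heavy atom within the covalent
#' bond cutoff. Hydrogens bonded to carbon (or unassignable) are dropped.
#'
#' @param frame a `pp_frame`.
#' @param bond_cutoff covalent X-H bond length cutoff, angstrom.
#' @return data frame with columns `donor` and `h` (atom row indices).
#' @export
polar_hydrogens <- function(frame, bond_cutoff = 1.2) {
  h_idx <- which(frame$atoms$elem == "H")
  heavy <- which(frame$atoms$elem %in% c("N", "O"))
  if (!length(h_idx) || !length(heavy)) {
    return(data.frame(donor = integer(0), h = integer(0)))
  }
  d <- cross_dist(frame$xyz[h_idx, , drop = FALSE],
                  frame$xyz[heavy, , drop = FALSE])
  nearest <- max.col(-d)
  keep <- d[cbind(seq_along(h_idx), nearest)] <= bond_cutoff
  data.frame(donor = heavy[nearest[keep]], h = h_idx[keep])
}

#' Detect hydrogen bonds in a frame
#'
#' A bond is recorded for every (donor-H, acceptor) pair whose heavy-atom
#' distance is at most `criteria$hbond_dist` and whose donor-H-acceptor angle
#' is at least `criteria$hbond_angle`. Donor and acceptor heavy atoms must be
#' distinct. Donors without a resolvable hydrogen are skipped with a warning.
#'
#' @param frame a `pp_frame`.
#' @param donors data frame with columns `donor`, `h` (atom indices); default
#'   [polar_hydrogens()] over the frame.
#' @param acceptors integer vector of acceptor heavy-atom indices; default
#'   all N/O atoms.
#' @param criteria an [interaction_criteria()] object.
#' @param donor_heavy optional integer vector restricting donor heavy atoms.
#' @return data frame of records: donor, h, acceptor atom indices, distance
#'   (angstrom), angle (degrees) plus donor/acceptor residue metadata.
#' @export
detect_hbonds <- function(frame, donors = NULL, acceptors = NULL,
                          criteria = interaction_criteria(),
                          donor_heavy = NULL) {
  at <- frame$atoms
  if (is.null(donors)) donors <- polar_hydrogens(frame)
  if (!is.null(donor_heavy)) {
    dropped <- setdiff(donor_heavy, donors$donor)
    if (length(dropped)) {
      warning("donor heavy atom(s) without resolvable hydrogen skipped: ",
              paste(at$elety[dropped], collapse = ", "))
    }
    donors <- donors[donors$donor %in% donor_heavy, , drop = FALSE]
  }
  if (is.null(acceptors)) acceptors <- which(at$elem %in% c("N", "O"))
  empty <- data.frame(
    kind = character(0), frame = integer(0), donor = integer(0),
    h = integer(0), acceptor = integer(0), distance = numeric(0),
    angle = numeric(0), donor_chain = character(0), donor_resno = integer(0),
    donor_resid = character(0), donor_role = character(0),
    acceptor_chain = character(0), acceptor_resno = integer(0),
    acceptor_resid = character(0), acceptor_role = character(0)
  )
  if (!nrow(donors) || !length(acceptors)) return(empty)

  dheavy <- unique(donors$donor)
  dd <- cross_dist(frame$xyz[dheavy, , drop = FALSE],
                   frame$xyz[acceptors, , drop = FALSE])
  cand <- which(dd <= criteria$hbond_dist, arr.ind = TRUE)
  if (!nrow(cand)) return(empty)
  cand_d <- dheavy[cand[, 1]]
  cand_a <- acceptors[cand[, 2]]
  ok <- cand_d != cand_a
  cand_d <- cand_d[ok]; cand_a <- cand_a[ok]
  cand_dist <- dd[cand][ok]
  if (!length(cand_d)) return(empty)

  # expand over the hydrogens of each candidate donor
  rows <- lapply(seq_along(cand_d), function(k) {
    hs <- donors$h[donors$donor == cand_d[k]]
    data.frame(donor = cand_d[k], h = hs, acceptor = cand_a[k],
               distance = cand_dist[k])
  })
  rec <- do.call(rbind, rows)
  u <- frame$xyz[rec$donor, , drop = FALSE] - frame$xyz[rec$h, , drop = FALSE]
  v <- frame$xyz[rec$acceptor, , drop = FALSE] - frame$xyz[rec$h, , drop = FALSE]
  cosang <- rowSums(u * v) /
    pmax(sqrt(rowSums(u^2)) * sqrt(rowSums(v^2)), 1e-12)
  rec$angle <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  rec <- rec[rec$angle >= criteria$hbond_angle & rec$acceptor != rec$h, ,
             drop = FALSE]
  if (!nrow(rec)) return(empty)
  data.frame(
    kind = "hbond", frame = frame$frame_index,
    donor = rec$donor, h = rec$h, acceptor = rec$acceptor,
    distance = rec$distance, angle = rec$angle,
    donor_chain = at$chain[rec$donor], donor_resno = at$resno[rec$donor],
    donor_resid = at$resid[rec$donor], donor_role = at$role[rec$donor],
    acceptor_chain = at$chain[rec$acceptor],
    acceptor_resno = at$resno[rec$acceptor],
    acceptor_resid = at$resid[rec$acceptor],
    acceptor_role = at$role[rec$acceptor],
    row.names = NULL
  )
}

#' Aromatic six-membered ring atom sets in a frame
#'
#' @param frame a `pp_frame`.
#' @param resnames residue names treated as aromatic.
#' @param ring_atoms atom names forming the six-membered ring.
#' @return list of integer atom-index vectors, named `chain:resno:resid`.
#' @export
aromatic_rings <- function(frame, resnames = c("PHE", "TYR"),
                           ring_atoms = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")) {
  at <- frame$atoms
  sel <- which(at$resid %in% resnames & at$elety %in% ring_atoms &
                 at$role == "protein")
  if (!length(sel)) return(list())
  key <- paste(at$chain[sel], at$resno[sel], at$resid[sel], sep = ":")
  out <- split(sel, key)
  out[vapply(out, length, integer(1)) >= 5L]
}

# Best-fit plane normal of a ring (unit vector): right singular vector of the
# centred coordinates with the smallest singular value.
ring_normal <- function(pts) {
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2L, ctr))
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1)) {
    stop("degenerate (collinear) ring atoms: no plane defined")
  }
  list(center = ctr, normal = sv$v[, 3L])
}

#' Detect cation-pi interactions in a frame
#'
#' A record is produced for every (cation, ring) pair whose cation to
#' ring-centre distance is at most the cutoff and whose angle between the
#' ring-plane normal and the centre-to-cation direction lies in the accepted
#' window (`< 45` or `> 135` degrees by default). The ring centre is the
#' unweighted centroid of the ring atoms; the normal is the best-fit plane
#' normal.
#'
#' @param frame a `pp_frame`.
#' @param cations integer atom indices of cationic centres (default: ligand
#'   nitrogen atoms).
#' @param rings list of ring atom-index vectors (default [aromatic_rings()]).
#' @param criteria an [interaction_criteria()] object.
#' @return data frame of records with distance and angle per pair.
#' @export
detect_cation_pi <- function(frame, cations = NULL, rings = NULL,
                             criteria = interaction_criteria()) {
  at <- frame$atoms
  if (is.null(cations)) cations <- which(at$role == "ligand" & at$elem == "N")
  if (is.null(rings)) rings <- aromatic_rings(frame)
  empty <- data.frame(
    kind = character(0), frame = integer(0), cation = integer(0),
    ring = character(0), ring_chain = character(0), ring_resno = integer(0),
    ring_resid = character(0), distance = numeric(0), angle = numeric(0)
  )
  if (!length(cations) || !length(rings)) return(empty)
  out <- list()
  for (rn in names(rings)) {
    geom <- ring_normal(frame$xyz[rings[[rn]], , drop = FALSE])
    first <- rings[[rn]][1L]
    for (ci in cations) {
      v <- frame$xyz[ci, ] - geom$center
      d <- vec_norm(v)
      if (d > criteria$cationpi_dist || d < 1e-9) next
      ang <- acos(min(1, max(-1, sum(geom$normal * v) / d))) * 180 / pi
      if (ang < criteria$cationpi_angle || ang > 180 - criteria$cationpi_angle) {
        out[[length(out) + 1L]] <- data.frame(
          kind = "cation_pi", frame = frame$frame_index, cation = ci,
          ring = rn, ring_chain = at$chain[first], ring_resno = at$resno[first],
          ring_resid = at$resid[first], distance = d, angle = ang
        )
      }
    }
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Detect water-bridged ligand-residue interactions in a frame
#'
#' One record per (residue, water molecule) where that single water forms at
#' least one hydrogen bond (water as donor or acceptor, standard criteria)
#' with the ligand and at least one with the residue in the same frame.
#' Direct ligand-residue hydrogen bonds are not counted as bridges.
#'
#' @param frame a `pp_frame`.
#' @param ligand integer atom indices of the ligand (default: all
#'   `role == "ligand"` atoms).
#' @param residues named list of protein atom-index vectors, one per residue
#'   (default: all protein residues with N/O atoms, named `chain:resno:resid`).
#' @param criteria an [interaction_criteria()] object.
#' @param hbonds optional precomputed [detect_hbonds()] table for this frame
#'   (all donors/acceptors); detected on the fly when `NULL`.
#' @return data frame of records with the bridging water identified.
#' @export
detect_water_bridges <- function(frame, ligand = NULL, residues = NULL,
                                 criteria = interaction_criteria(),
                                 hbonds = NULL) {
  at <- frame$atoms
  if (is.null(ligand)) ligand <- which(at$role == "ligand")
  if (is.null(residues)) {
    sel <- which(at$role == "protein" & at$elem %in% c("N", "O"))
    residues <- split(sel, paste(at$chain[sel], at$resno[sel], at$resid[sel],
                                 sep = ":"))
  }
  empty <- data.frame(
    kind = character(0), frame = integer(0), residue = character(0),
    residue_chain = character(0), residue_resno = integer(0),
    residue_resid = character(0), water = character(0)
  )
  wat <- which(at$role == "water")
  if (!length(wat) || !length(ligand) || !length(residues)) return(empty)

  hb <- hbonds %||% detect_hbonds(frame, criteria = criteria)
  if (!nrow(hb)) return(empty)
  role_d <- at$role[hb$donor]
  role_a <- at$role[hb$acceptor]
  water_key <- function(idx) paste(at$chain[idx], at$resno[idx], sep = ":")

  # water <-> ligand bonds
  wl <- hb[(role_d == "water" & hb$acceptor %in% ligand) |
             (role_a == "water" & hb$donor %in% ligand), , drop = FALSE]
  if (!nrow(wl)) return(empty)
  wl_water <- ifelse(at$role[wl$donor] == "water",
                     water_key(wl$donor), water_key(wl$acceptor))

  # water <-> residue bonds, residue membership via the supplied sets
  res_name <- names(residues)
  atom2res <- rep(NA_character_, nrow(at))
  for (rn in res_name) atom2res[residues[[rn]]] <- rn
  wr <- hb[(role_d == "water" & !is.na(atom2res[hb$acceptor])) |
             (role_a == "water" & !is.na(atom2res[hb$donor])), , drop = FALSE]
  if (!nrow(wr)) return(empty)
  wr_water <- ifelse(at$role[wr$donor] == "water",
                     water_key(wr$donor), water_key(wr$acceptor))
  wr_res <- ifelse(at$role[wr$donor] == "water",
                   atom2res[wr$acceptor], atom2res[wr$donor])

  pairs <- unique(data.frame(residue = wr_res, water = wr_water))
  pairs <- pairs[pairs$water %in% unique(wl_water), , drop = FALSE]
  if (!nrow(pairs)) return(empty)
  meta <- do.call(rbind, strsplit(pairs$residue, ":", fixed = TRUE))
  data.frame(
    kind = "water_bridge", frame = frame$frame_index, residue = pairs$residue,
    residue_chain = meta[, 1L], residue_resno = as.integer(meta[, 2L]),
    residue_resid = meta[, 3L], water = pairs$water, row.names = NULL
  )
}

#' Occurrence statistics over interaction records
#'
#' Per (pocket, residue, kind): occurrence % of frames with at least one
#' record. Per (pocket, kind): mean total record count per frame (multiple
#' simultaneous bonds with the same residue all count) and its standard
#' deviation over frames, frames with no records included as zeros.
#'
#' @param records data frame of interaction records; must carry columns
#'   `kind`, `frame`, and residue identity columns (any of
#'   `residue_resid`/`residue_resno` or donor/acceptor/ring equivalents), and
#'   optionally `pocket`.
#' @param n_frames total number of analysed frames.
#' @return list with data frames `residues` (occurrence_pct per residue) and
#'   `totals` (mean_count, sd_count per pocket and kind).
#' @export
occurrence_summary <- function(records, n_frames) {
  stopifnot(n_frames >= 1)
  if (is.null(records) || !nrow(records)) {
    return(list(
      residues = data.frame(pocket = character(0), residue = character(0),
                            kind = character(0), occurrence_pct = numeric(0)),
      totals = data.frame(pocket = character(0), kind = character(0),
                          mean_count = numeric(0), sd_count = numeric(0))
    ))
  }
  rec <- records
  if (is.null(rec$pocket)) rec$pocket <- "-"
  rec$residue_label <- interaction_residue_label(rec)

  key <- interaction(rec$pocket, rec$residue_label, rec$kind, drop = TRUE)
  occ <- tapply(rec$frame, key, function(f) 100 * length(unique(f)) / n_frames)
  parts <- do.call(rbind, strsplit(names(occ), ".", fixed = TRUE))
  residues <- data.frame(pocket = parts[, 1L], residue = parts[, 2L],
                         kind = parts[, 3L], occurrence_pct = as.numeric(occ),
                         row.names = NULL)
  residues <- residues[order(residues$pocket, residues$kind, residues$residue), ]

  key2 <- interaction(rec$pocket, rec$kind, drop = TRUE)
  totals <- do.call(rbind, lapply(levels(key2), function(lv) {
    f <- rec$frame[key2 == lv]
    counts <- tabulate(match(f, sort(unique(f))))
    counts <- c(counts, rep(0L, n_frames - length(counts)))
    parts <- strsplit(lv, ".", fixed = TRUE)[[1L]]
    data.frame(pocket = parts[1L], kind = parts[2L],
               mean_count = mean(counts), sd_count = stats::sd(counts))
  }))
  list(residues = residues, totals = totals)
}

# Human-readable residue label for a record (RESNAME+number), whichever side
# of the interaction is the protein residue.
interaction_residue_label <- function(rec) {
  if (!is.null(rec$residue_resid)) {
    return(paste0(rec$residue_resid, rec$residue_resno))
  }
  if (!is.null(rec$ring_resid)) {
    return(paste0(rec$ring_resid, rec$ring_resno))
  }
  # hydrogen bonds: label by the protein side (donor if protein, else acceptor)
  lab <- ifelse(!is.na(rec$donor_resno) & rec$donor_role == "protein",
                paste0(rec$donor_resid, rec$donor_resno),
                paste0(rec$acceptor_resid, rec$acceptor_resno))
  lab
}

#' Direct intersubunit hydrogen bonds over a trajectory
#'
#' Per frame, counts hydrogen bonds whose donor and acceptor heavy atoms are
#' protein atoms on different subunits (water and ligand excluded), assigns
#' each to its chain-pair interface, and reports per-interface means plus the
#' total across interfaces as mean and standard deviation over frames.
#'
#' @param trajectory a `pp_trajectory`.
#' @param topology a `pp_topology`.
#' @param criteria an [interaction_criteria()] object.
#' @return list with `per_interface` (data frame of means) and `total`
#'   (list mean, sd) and the per-frame `series`.
#' @export
intersubunit_hbond_total <- function(trajectory, topology,
                                     criteria = interaction_criteria()) {
  nf <- n_frames(trajectory)
  at <- trajectory$atoms
  donors0 <- polar_hydrogens(trajectory_frame(trajectory, 1L))
  prot <- at$role == "protein"
  donors0 <- donors0[prot[donors0$donor], , drop = FALSE]
  acceptors <- which(prot & at$elem %in% c("N", "O"))
  series <- numeric(nf)
  iface_counts <- list()
  for (k in seq_len(nf)) {
    fr <- trajectory_frame(trajectory, k)
    hb <- detect_hbonds(fr, donors = donors0, acceptors = acceptors,
                        criteria = criteria)
    inter <- hb[hb$donor_chain != hb$acceptor_chain, , drop = FALSE]
    series[k] <- nrow(inter)
    if (nrow(inter)) {
      pair <- apply(cbind(inter$donor_chain, inter$acceptor_chain), 1L,
                    function(p) paste(sort(p), collapse = "-"))
      tab <- table(pair)
      for (nm in names(tab)) {
        iface_counts[[nm]] <- (iface_counts[[nm]] %||% numeric(nf))
        iface_counts[[nm]][k] <- as.numeric(tab[[nm]])
      }
    }
  }
  per_iface <- data.frame(
    interface = names(iface_counts),
    mean_count = vapply(iface_counts, mean, numeric(1)),
    sd_count = vapply(iface_counts, stats::sd, numeric(1)),
    row.names = NULL
  )
  list(per_interface = per_iface,
       total = list(mean = mean(series), sd = stats::sd(series)),
       series = series)
}
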