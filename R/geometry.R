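# Convex-hull "atomic cage" of the 11 binding-residue CA atoms: water
# occupancy, hull volume, and the Loop C orientation angle.

#' 3D convex hull by supporting-plane enumeration
#'
#' Enumerates all point triples, keeps the planes that support the point set,
#' merges coplanar triples into polygonal faces, fan-triangulates each face,
#' and accumulates the volume from tetrahedra anchored at the interior
#' centroid. Intended for small point sets (the 11-vertex pocket cage); cost
#' is O(n^4).
#'
#' @param points n x 3 numeric matrix, n >= 4, not all coplanar.
#' @param tol relative coplanarity tolerance.
#' @return object of class `pp_hull`: list with `points`, `planes` (m x 4,
#'   outward unit normal and offset, interior satisfies `n.x <= d`),
#'   `faces` (triangle index matrix), `vertices` (hull vertex indices),
#'   `volume` (cubic angstrom).
#' @export
convex_hull3 <- function(points, tol = 1e-7) {
  pts <- as.matrix(points)
  n <- nrow(pts)
  if (n < 4L) stop("degenerate geometry: need at least 4 points for a 3D hull")
  scale <- max(apply(pts, 2L, function(x) diff(range(x))), 1e-12)
  eps <- tol * scale
  sv <- svd(sweep(pts, 2L, colMeans(pts)))$d
  if (sv[3L] < tol * max(sv[1L], 1)) {
    stop("degenerate geometry: points are coplanar")
  }

  planes <- list()
  triples <- utils::combn(n, 3L)
  for (t in seq_len(ncol(triples))) {
    i <- triples[1L, t]; j <- triples[2L, t]; k <- triples[3L, t]
    nrm <- cross3(pts[j, ] - pts[i, ], pts[k, ] - pts[i, ])
    ln <- vec_norm(nrm)
    if (ln < eps * scale) next           # collinear triple
    nrm <- nrm / ln
    d <- sum(nrm * pts[i, ])
    s <- drop(pts %*% nrm) - d
    if (all(s <= eps)) {
      planes[[length(planes) + 1L]] <- c(nrm, d)
    } else if (all(s >= -eps)) {
      planes[[length(planes) + 1L]] <- c(-nrm, -d)
    }
  }
  if (!length(planes)) stop("degenerate geometry: points are coplanar")
  pm <- do.call(rbind, planes)
  # deduplicate supporting planes
  keep <- rep(TRUE, nrow(pm))
  for (a in seq_len(nrow(pm) - 1L)) {
    if (!keep[a]) next
    for (b in (a + 1L):nrow(pm)) {
      if (keep[b] &&
          sum(pm[a, 1:3] * pm[b, 1:3]) > 1 - 1e-9 &&
          abs(pm[a, 4L] - pm[b, 4L]) < 10 * eps) {
        keep[b] <- FALSE
      }
    }
  }
  pm <- pm[keep, , drop = FALSE]
  if (nrow(pm) < 4L) stop("degenerate geometry: fewer than 4 hull faces")

  centroid <- colMeans(pts)
  faces <- list()
  verts <- integer(0)
  for (a in seq_len(nrow(pm))) {
    u <- pm[a, 1:3]; d <- pm[a, 4L]
    on <- which(abs(drop(pts %*% u) - d) <= 10 * eps)
    if (length(on) < 3L) next
    verts <- union(verts, on)
    # order the face polygon by angle in the plane
    fc <- colMeans(pts[on, , drop = FALSE])
    e1 <- unit_vec(pts[on[1L], ] - fc)
    e2 <- cross3(u, e1)
    rel <- sweep(pts[on, , drop = FALSE], 2L, fc)
    ang <- atan2(drop(rel %*% e2), drop(rel %*% e1))
    on <- on[order(ang)]
    for (q in 2L:(length(on) - 1L)) {
      faces[[length(faces) + 1L]] <- c(on[1L], on[q], on[q + 1L])
    }
  }
  faces <- do.call(rbind, faces)
  vol <- 0
  for (f in seq_len(nrow(faces))) {
    a3 <- pts[faces[f, 1L], ] - centroid
    b3 <- pts[faces[f, 2L], ] - centroid
    c3 <- pts[faces[f, 3L], ] - centroid
    vol <- vol + abs(sum(a3 * cross3(b3, c3))) / 6
  }
  structure(list(points = pts, planes = pm, faces = faces,
                 vertices = sort(verts), volume = vol),
            class = "pp_hull")
}

#' @export
print.pp_hull <- function(x, ...) {
  cat(sprintf("Convex hull: %d vertices, %d faces, volume %.3f A^3\n",
              length(x$vertices), nrow(x$faces), x$volume))
  invisible(x)
}

#' Test points for hull membership
#'
#' A point is inside if it satisfies every face half-space within `tol`
#' (boundary points count as inside).
#'
#' @param hull a `pp_hull`.
#' @param pts m x 3 matrix of query points.
#' @param tol boundary tolerance in angstrom.
#' @return logical vector of length m.
#' @export
points_in_hull <- function(hull, pts, tol = 1e-9) {
  pts <- rbind(pts)
  s <- pts %*% t(hull$planes[, 1:3, drop = FALSE])
  s <- sweep(s, 2L, hull$planes[, 4L])
  apply(s <= tol, 1L, all)
}

#' The atomic cage of one pocket in one frame
#'
#' Convex hull of the CA atoms of the pocket's 11 binding residues.
#'
#' @param frame a `pp_frame`.
#' @param pocket a `pp_pocket` from [pocket_specs()].
#' @return a `pp_hull` with the cage volume attached.
#' @export
pocket_cage <- function(frame, pocket) {
  idx <- c(pocket$ca_principal, pocket$ca_complementary)
  if (length(idx) != 11L) stop("pocket must carry 11 resolved binding residues")
  convex_hull3(frame$xyz[idx, , drop = FALSE])
}

#' Count water oxygens inside a cage
#'
#' @param frame a `pp_frame` with role-annotated waters.
#' @param cage a `pp_hull` (see [pocket_cage()]).
#' @param tol boundary tolerance, angstrom; boundary waters count as inside.
#' @return integer count.
#' @export
count_waters_in_cage <- function(frame, cage, tol = 1e-9) {
  ox <- which(frame$atoms$role == "water" & frame$atoms$elem == "O")
  if (!length(ox)) return(0L)
  sum(points_in_hull(cage, frame$xyz[ox, , drop = FALSE], tol = tol))
}

#' Loop C orientation angle of one pocket
#'
#' Let C be the centroid of the apex-pair CA atoms (ASN219/THR220 by
#' default), O the centroid of the hinge pair (THR215/THR224) and G the
#' centroid of the complementary reference pair (ASN58/ARG81). The angle at
#' vertex O between rays O->C and O->G is returned in degrees. Small angles
#' correspond to a capped (closed) Loop C, large angles to an open one.
#'
#' @param frame a `pp_frame`.
#' @param pocket a `pp_pocket`.
#' @param vertex which anchor acts as the angle vertex: `"hinge"` (default),
#'   `"apex"` or `"reference"` (exposed for sensitivity analysis).
#' @return angle in degrees.
#' @export
loopc_angle <- function(frame, pocket, vertex = c("hinge", "apex", "reference")) {
  vertex <- match.arg(vertex)
  C <- colMeans(frame$xyz[pocket$ca_apex, , drop = FALSE])
  O <- colMeans(frame$xyz[pocket$ca_hinge, , drop = FALSE])
  G <- colMeans(frame$xyz[pocket$ca_reference, , drop = FALSE])
  switch(vertex,
         hinge = point_angle(C, O, G),
         apex = point_angle(O, C, G),
         reference = point_angle(C, G, O))
}

#' Per-frame pocket descriptors over a trajectory
#'
#' For one pocket and every frame: interior water count, cage hull volume
#' and Loop C orientation angle. The cage is recomputed at every frame.
#'
#' @param trajectory a `pp_trajectory`.
#' @param pocket a `pp_pocket`.
#' @param display_offset if `TRUE` and the pocket is occupied, the *summary*
#'   water mean is also reported with a +5 display offset (an approximate
#'   stand-in for the volume of the bound ligand when comparing occupied and
#'   empty pockets in one panel); stored per-frame data are never offset.
#' @return object of class `pp_pocket_series`: data frame `series` with
#'   columns frame, water_count, hull_volume, loopc_angle, plus a `summary`
#'   list of means and standard deviations.
#' @export
pocket_timeseries <- function(trajectory, pocket, display_offset = FALSE) {
  nf <- n_frames(trajectory)
  wc <- integer(nf); hv <- numeric(nf); la <- numeric(nf)
  for (k in seq_len(nf)) {
    fr <- trajectory_frame(trajectory, k)
    cage <- pocket_cage(fr, pocket)
    wc[k] <- count_waters_in_cage(fr, cage)
    hv[k] <- cage$volume
    la[k] <- loopc_angle(fr, pocket)
  }
  series <- data.frame(frame = trajectory$frame_index, water_count = wc,
                       hull_volume = hv, loopc_angle = la)
  summ <- list(
    pocket = pocket$label, occupied = pocket$occupied,
    water_mean = mean(wc), water_sd = stats::sd(wc),
    volume_mean = mean(hv), volume_sd = stats::sd(hv),
    angle_mean = mean(la), angle_sd = stats::sd(la)
  )
  if (display_offset && pocket$occupied) {
    summ$water_mean_display <- summ$water_mean + 5
  }
  structure(list(series = series, summary = summ, pocket = pocket$label,
                 occupied = pocket$occupied),
            class = "pp_pocket_series")
}

#' @export
print.pp_pocket_series <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "Pocket (%s, %s): waters %.2f +/- %.2f, volume %.1f +/- %.1f A^3, Loop C %.1f +/- %.1f deg over %d frames\n",
    x$pocket, if (x$occupied) "occupied" else "empty",
    s$water_mean, s$water_sd, s$volume_mean, s$volume_sd,
    s$angle_mean, s$angle_sd, nrow(x$series)))
  invisible(x)
}
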