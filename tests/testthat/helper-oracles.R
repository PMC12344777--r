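`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force oracles. These deliberately re-derive every
# quantity with the most literal formula available (plain loops, explicit
# arccos, simplex decomposition) so that they share no code path with the
# package implementations they check.

oracle_hbonds <- function(frame, criteria = interaction_criteria()) {
  at <- frame$atoms
  xyz <- frame$xyz
  heavies <- which(at$elem %in% c("N", "O"))
  hs <- which(at$elem == "H")
  out <- list()
  for (h in hs) {
    # donor = nearest N/O within 1.2 A
    dmin <- Inf; don <- NA
    for (d in heavies) {
      dd <- sqrt(sum((xyz[h, ] - xyz[d, ])^2))
      if (dd < dmin) { dmin <- dd; don <- d }
    }
    if (!is.finite(dmin) || dmin > 1.2) next
    for (a in heavies) {
      if (a == don) next
      da <- sqrt(sum((xyz[don, ] - xyz[a, ])^2))
      if (da > criteria$hbond_dist) next
      v1 <- xyz[don, ] - xyz[h, ]
      v2 <- xyz[a, ] - xyz[h, ]
      ang <- acos(max(-1, min(1, sum(v1 * v2) /
                                (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))))) * 180 / pi
      if (ang >= criteria$hbond_angle) {
        out[[length(out) + 1L]] <- c(donor = don, h = h, acceptor = a)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(donor = integer(0), h = integer(0),
                      acceptor = integer(0)))
  }
  as.data.frame(do.call(rbind, out))
}

oracle_cation_pi <- function(frame, cations, rings,
                             criteria = interaction_criteria()) {
  out <- list()
  for (rn in names(rings)) {
    pts <- frame$xyz[rings[[rn]], , drop = FALSE]
    ctr <- colMeans(pts)
    a <- pts[2, ] - pts[1, ]
    b <- pts[3, ] - pts[1, ]
    n <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
           a[1] * b[2] - a[2] * b[1])
    n <- n / sqrt(sum(n^2))
    for (ci in cations) {
      v <- frame$xyz[ci, ] - ctr
      d <- sqrt(sum(v^2))
      if (d > criteria$cationpi_dist) next
      ang <- acos(max(-1, min(1, sum(n * v) / d))) * 180 / pi
      if (ang < criteria$cationpi_angle || ang > 180 - criteria$cationpi_angle) {
        out[[length(out) + 1L]] <- c(cation = ci, ring = rn)
      }
    }
  }
  if (!length(out)) return(data.frame(cation = integer(0), ring = character(0)))
  data.frame(cation = as.integer(vapply(out, `[[`, character(1), "cation")),
             ring = vapply(out, `[[`, character(1), "ring"))
}

# Caratheodory: q is inside conv(P) in 3D iff some tetrahedron of P contains
# it; containment by barycentric coordinates.
oracle_in_hull <- function(points, q, tol = 1e-9) {
  n <- nrow(points)
  tets <- utils::combn(n, 4L)
  for (t in seq_len(ncol(tets))) {
    v <- points[tets[, t], , drop = FALSE]
    A <- cbind(v[2, ] - v[1, ], v[3, ] - v[1, ], v[4, ] - v[1, ])
    if (abs(det(A)) < 1e-10) next
    lam <- solve(A, q - v[1, ])
    if (all(lam >= -tol) && sum(lam) <= 1 + tol) return(TRUE)
  }
  FALSE
}

oracle_contact_map <- function(trajectory, idx_p, idx_c, cutoff) {
  nf <- pentapocket::n_frames(trajectory)
  m <- matrix(0, length(idx_p), length(idx_c))
  for (k in seq_len(nf)) {
    for (i in seq_along(idx_p)) {
      for (j in seq_along(idx_c)) {
        d <- sqrt(sum((trajectory$coords[idx_p[i], , k] -
                         trajectory$coords[idx_c[j], , k])^2))
        if (d < cutoff) m[i, j] <- m[i, j] + 1
      }
    }
  }
  m / nf
}

oracle_solvation <- function(frame, ligand_c, water_o, d0 = 2.5,
                             cutoff = 10) {
  s <- 0
  for (i in ligand_c) {
    for (j in water_o) {
      d <- sqrt(sum((frame$xyz[i, ] - frame$xyz[j, ])^2))
      if (d > cutoff) next
      r <- d / d0
      s <- s + if (abs(r - 1) < 1e-9) 0.6 else (1 - r^6) / (1 - r^10)
    }
  }
  s
}

# qhull volume + Delaunay membership + Monte-Carlo rejection volume through
# the pre-installed scipy, as a fully independent geometry reference
scipy_hull_oracle <- function(points, queries = NULL, mc_samples = 0L) {
  inp <- tempfile(fileext = ".json")
  outp <- tempfile(fileext = ".json")
  jsonlite::write_json(list(points = points, queries = queries,
                            mc = mc_samples), inp, digits = NA,
                       auto_unbox = TRUE)
  script <- '
import json, sys
import numpy as np
from scipy.spatial import ConvexHull, Delaunay
with open(sys.argv[1]) as fh:
    d = json.load(fh)
pts = np.asarray(d["points"], float)
out = {"volume": ConvexHull(pts).volume}
tri = Delaunay(pts)
if d.get("queries"):
    q = np.asarray(d["queries"], float)
    out["inside"] = (tri.find_simplex(q) >= 0).tolist()
if d.get("mc"):
    rng = np.random.default_rng(0)
    lo, hi = pts.min(0), pts.max(0)
    s = rng.uniform(lo, hi, size=(int(d["mc"]), 3))
    frac = float(np.mean(tri.find_simplex(s) >= 0))
    out["mc_volume"] = frac * float(np.prod(hi - lo))
with open(sys.argv[2], "w") as fh:
    json.dump(out, fh)
'
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  status <- system2("python", c(sf, inp, outp), stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("scipy oracle call failed")
  jsonlite::read_json(outp, simplifyVector = TRUE)
}

# random role-annotated frame with donors/acceptors/waters for detector
# property tests
random_frame <- function(n_groups = 20, seed = 1, box = 12) {
  set.seed(seed)
  atoms <- list(); xyz <- list(); k <- 0L
  add <- function(elety, resid, resno, chain, role, pos) {
    k <<- k + 1L
    atoms[[k]] <<- data.frame(eleno = k, elety = elety, resid = resid,
                              resno = resno, chain = chain,
                              elem = substr(elety, 1, 1), role = role)
    xyz[[k]] <<- pos
  }
  for (g in seq_len(n_groups)) {
    base <- runif(3, 0, box)
    # donor N-H unit
    dirn <- rnorm(3); dirn <- dirn / sqrt(sum(dirn^2))
    add("N", "RES", g, "A", "protein", base)
    add("H", "RES", g, "A", "protein", base + dirn)
    # acceptor O somewhere nearby
    add("O", "RES", 100 + g, "B", "protein", runif(3, 0, box))
  }
  pp_frame(do.call(rbind, atoms), do.call(rbind, xyz))
}
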