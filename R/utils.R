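#' @keywords internal
"_PACKAGE"

# Standard atomic masses (u) used for mass-weighted centroids.
.atomic_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, NA. = 22.990, CL = 35.45, K = 39.098, MG = 24.305,
  CA = 40.078, ZN = 65.38, FE = 55.845
)

#' Atomic mass lookup by element symbol
#'
#' @param elem character vector of element symbols (e.g. `"C"`, `"O"`).
#' @return numeric vector of masses in unified atomic mass units.
#' @examples
#' atomic_mass(c("C", "O", "H"))
#' @export
atomic_mass <- function(elem) {
  key <- toupper(elem)
  key[key == "NA"] <- "NA."
  m <- .atomic_masses[key]
  if (anyNA(m)) {
    stop("unknown element symbol(s): ",
         paste(unique(elem[is.na(m)]), collapse = ", "))
  }
  unname(m)
}

vec_norm <- function(v) sqrt(sum(v^2))

unit_vec <- function(v) {
  n <- vec_norm(v)
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Angle between three points, in degrees
#'
#' Returns the angle at `vertex` between the rays `vertex -> a` and
#' `vertex -> b`, in degrees in \[0, 180\].
#'
#' @param a,vertex,b numeric length-3 coordinates in angstrom.
#' @return angle in degrees.
#' @examples
#' point_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)) # 90
#' @export
point_angle <- function(a, vertex, b) {
  u <- a - vertex
  v <- b - vertex
  nu <- vec_norm(u)
  nv <- vec_norm(v)
  if (nu < 1e-12 || nv < 1e-12) stop("coincident points: angle undefined")
  cosang <- sum(u * v) / (nu * nv)
  cosang <- min(1, max(-1, cosang))
  acos(cosang) * 180 / pi
}

# Pairwise Euclidean distances between the rows of two coordinate matrices.
cross_dist <- function(a, b) {
  a <- rbind(a)
  b <- rbind(b)
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# Random rotation matrix (uniform over SO(3)) -- used in invariance tests
# and exported for users who want to randomise frames.

#' Random 3x3 rotation matrix
#'
#' Draws a rotation uniformly over SO(3) (QR of a Gaussian matrix with the
#' sign convention fixed, determinant corrected to +1).
#'
#' @return orthogonal 3x3 matrix with determinant +1.
#' @export
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9L), 3L, 3L))
  q <- qr.Q(qr_)
  d <- sign(diag(qr.R(qr_)))
  q <- q %*% diag(d)
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

# Apply a rigid motion (rotation R then translation t) to an n x 3 matrix.
apply_rigid <- function(xyz, rot = diag(3), trans = c(0, 0, 0)) {
  sweep(xyz %*% t(rot), 2L, trans, "+")
}

# Rotation about the z axis by `deg` degrees.
rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3L, 3L)
}

# Derive independent sub-seeds from one master seed without disturbing the
# caller's RNG state more than once. Kept below 2^31.
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- globalenv()$.Random.seed
  set.seed(as.integer(seed %% .Machine$integer.max))
  s <- sample.int(.Machine$integer.max - 1L, n)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  s
}

`%||%` <- function(a, b) if (is.null(a)) b else a
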