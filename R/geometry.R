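# Small 3D vector/geometry helpers shared by the builder, the torsion term
# and the DSSP-equivalent assignment. All coordinates are in Angstrom.

vnorm <- function(v) sqrt(sum(v * v))

# lossless numeric <-> text for JSON containers (C99 hex-float literals;
# round-trips doubles bit-exactly)
.enc_num <- function(x) sprintf("%a", as.numeric(x))
.dec_num <- function(x) as.numeric(unlist(x))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("zero-length vector cannot be normalized")
  v / n
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Dihedral angle of four points
#'
#' @param p1,p2,p3,p4 numeric 3-vectors (Angstrom).
#' @return Angle in degrees in (-180, 180].
#' @keywords internal
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, unitv(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

# NeRF atom placement: position a new atom D given three predecessors A-B-C,
# the C-D bond length, the B-C-D angle and the A-B-C-D dihedral (degrees).
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(dih),
          -bond * sin(ang) * sin(dih))
  bc <- unitv(c - b)
  n <- unitv(vcross(b - a, bc))
  m <- cbind(bc, vcross(n, bc), n)
  as.numeric(m %*% d2 + c)
}

# Angle at vertex b (degrees)
angle_at <- function(a, b, c) {
  u <- unitv(a - b)
  v <- unitv(c - b)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

# Pairwise Euclidean distance matrix between rows of two coordinate matrices.
cross_dist <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * tcrossprod(x, y)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# Random rigid-body motion, used by invariance tests and by the fixture
# generator to decorrelate segment placement.
random_rotation <- function() {
  repeat {
    q <- stats::rnorm(4)
    n <- vnorm(q)
    if (n > 1e-8) break
  }
  q <- q / n
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

apply_rigid <- function(xyz, rot, shift = c(0, 0, 0)) {
  sweep(as.matrix(xyz) %*% t(rot), 2, -shift)
}
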