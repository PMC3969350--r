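# Low-level 3D geometry: internal-coordinate atom placement, rigid
# superposition, deterministic sphere quadrature and frame canonicalization.

vnorm <- function(v) sqrt(sum(v * v))

unit_vec <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) return(c(0, 0, 0))
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Place an atom from internal coordinates
#'
#' Natural extension reference frame (NeRF) construction: the new atom `d` is
#' bonded to `c` with bond length `bond`, bond angle `d-c-b` equal to `angle`
#' and torsion `d-c-b-a` equal to `dihedral`.
#'
#' @param a,b,c numeric length-3 coordinates of the three reference atoms.
#' @param bond bond length in Angstrom.
#' @param angle bond angle in degrees.
#' @param dihedral torsion angle in degrees.
#' @return numeric length-3 coordinates of the placed atom.
#' @keywords internal
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  tor <- dihedral * pi / 180
  bc <- unit_vec(c - b)
  n <- unit_vec(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares rotation (and translation) mapping `mobile` onto `fixed`.
#'
#' @param mobile,fixed n x 3 coordinate matrices with matching rows.
#' @return list with rotated `xyz` (n x 3), rotation matrix `R` and the
#'   centroids used.
#' @keywords internal
kabsch <- function(mobile, fixed) {
  cm <- colMeans(mobile)
  cf <- colMeans(fixed)
  P <- sweep(mobile, 2, cm)
  Q <- sweep(fixed, 2, cf)
  s <- svd(crossprod(P, Q))
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  xyz <- sweep(P %*% t(R), 2, cf, `+`)
  list(xyz = xyz, R = R, center_mobile = cm, center_fixed = cf)
}

#' Deterministic unit-sphere quadrature points
#'
#' Golden-section spiral (Fibonacci) lattice: `n` near-uniform points on the
#' unit sphere, bit-identical across calls.
#'
#' @param n number of points (>= 16).
#' @return n x 3 matrix of unit vectors.
#' @keywords internal
sphere_points <- function(n) {
  if (n < 16) stop("sphere quadrature needs at least 16 points", call. = FALSE)
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Rotation into a canonical principal-axes frame with a deterministic sign
# convention, so surface quadrature (a lab-frame point lattice) yields
# rigid-motion invariant areas. Returns the rotation matrix R (coords %*% R
# gives canonical coordinates); the frame is centered separately by callers.
canonical_rotation <- function(xyz) {
  if (nrow(xyz) < 3) return(diag(3))
  x <- sweep(xyz, 2, colMeans(xyz))
  cv <- crossprod(x) / nrow(x)
  ev <- eigen(cv, symmetric = TRUE)
  V <- ev$vectors
  scale <- sqrt(mean(diag(cv))) + 1e-12
  for (k in 1:2) {
    p <- x %*% V[, k]
    s3 <- sum(p^3)
    if (abs(s3) > 1e-8 * nrow(x) * scale^3) {
      if (s3 < 0) V[, k] <- -V[, k]
    } else {
      # symmetric distribution: orient by the largest-magnitude loading
      j <- which.max(abs(V[, k]))
      if (V[j, k] < 0) V[, k] <- -V[, k]
    }
  }
  V[, 3] <- cross3(V[, 1], V[, 2])
  V
}
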