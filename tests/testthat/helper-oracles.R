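# Independent oracles and small fixture builders shared across the tests.
# Every oracle here is implemented by a different route than the package
# code it checks.

# --- rotation matrices -------------------------------------------------------

rot_zyz <- function(a, b, g) {
  rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1),
                           3, 3, byrow = TRUE)
  ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0, -sin(t), 0, cos(t)),
                           3, 3, byrow = TRUE)
  rz(a) %*% ry(b) %*% rz(g)
}

random_rotation <- function() {
  m <- matrix(rnorm(9), 3, 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# --- brute-force superposed RMSD (coarse Euler grid + simplex polish) --------

oracle_superposed_rmsd <- function(xa, xb) {
  pa <- sweep(xa, 2, colMeans(xa))
  pb <- sweep(xb, 2, colMeans(xb))
  rmsd_at <- function(p) {
    R <- rot_zyz(p[1], p[2], p[3])
    sqrt(mean(rowSums((pa %*% t(R) - pb)^2)))
  }
  full <- seq(0, 2 * pi, length.out = 13)[-13]
  half <- seq(0, pi, length.out = 7)
  best <- c(0, 0, 0); bv <- Inf
  for (a in full) for (b in half) for (g in full) {
    v <- rmsd_at(c(a, b, g))
    if (v < bv) { bv <- v; best <- c(a, b, g) }
  }
  op <- stats::optim(best, rmsd_at, method = "Nelder-Mead",
                     control = list(reltol = 1e-15, maxit = 10000))
  op$value
}

# --- analytic sphere-overlap accessible areas --------------------------------

# Accessible (non-overlapped) areas of two probe-inflated spheres of radii
# r1, r2 at center distance d: the buried part of each sphere is a spherical
# cap cut by the radical plane of the intersection circle.
oracle_two_sphere_area <- function(r1, r2, d, probe) {
  R1 <- r1 + probe; R2 <- r2 + probe
  hidden <- function(RA, RB) {
    if (d >= RA + RB) return(0)            # disjoint
    if (d + RA <= RB) return(4 * pi * RA^2) # A engulfed by B
    if (d + RB <= RA) return(0)            # B inside A, A's surface free
    x <- (d^2 + RA^2 - RB^2) / (2 * d)
    2 * pi * RA * (RA - x)
  }
  c(4 * pi * R1^2 - hidden(R1, R2), 4 * pi * R2^2 - hidden(R2, R1))
}

# --- classical Lance-Williams Ward (squared-distance recurrence) -------------

# Agglomerates by the stored-dissimilarity recurrence
#   d(k, ij)^2 = ((n_i+n_k) d(k,i)^2 + (n_j+n_k) d(k,j)^2 - n_k d(i,j)^2) /
#                (n_i + n_j + n_k)
# and reports the sorted merge heights sqrt(d^2_min). This is a different
# algorithm (no centroids) from the package's reciprocal-nearest-neighbor
# implementation.
oracle_lw_ward_heights <- function(x) {
  n <- nrow(x)
  d2 <- as.matrix(stats::dist(x))^2
  size <- rep(1, n)
  active <- rep(TRUE, n)
  heights <- numeric(n - 1)
  for (s in seq_len(n - 1)) {
    act <- which(active)
    dd <- d2[act, act, drop = FALSE]
    dd[!upper.tri(dd)] <- Inf
    k <- arrayInd(which.min(dd), dim(dd))
    i <- act[k[1]]; j <- act[k[2]]
    heights[s] <- sqrt(d2[i, j])
    ni <- size[i]; nj <- size[j]
    for (o in act) {
      if (o == i || o == j) next
      nk <- size[o]
      d2[i, o] <- d2[o, i] <-
        ((ni + nk) * d2[i, o] + (nj + nk) * d2[j, o] - nk * d2[i, j]) /
        (ni + nj + nk)
    }
    size[i] <- ni + nj
    active[j] <- FALSE
    d2[j, ] <- d2[, j] <- Inf
  }
  sort(heights)
}

# --- fixture builders --------------------------------------------------------

# A ring of pseudo-residues (CA on a circle, CB further out along the same
# radius; GLY gets no CB), useful for loop-annotation and descriptor tests.
toy_sequence_peptide <- function(codes, cyclic = TRUE, radius = 10,
                                 label = "ring") {
  n <- length(codes)
  th <- 2 * pi * (seq_len(n) - 1) / n
  rows <- lapply(seq_len(n), function(i) {
    u <- c(cos(th[i]), sin(th[i]), 0)
    ca <- data.frame(name = "CA", resno = i, code = codes[i],
                     x = radius * u[1], y = radius * u[2], z = 0)
    if (codes[i] == "GLY") return(ca)
    rbind(ca, data.frame(name = "CB", resno = i, code = codes[i],
                         x = (radius + 3) * u[1], y = (radius + 3) * u[2],
                         z = 0))
  })
  new_peptide(do.call(rbind, rows), label = label, cyclic = cyclic)
}

# A bare one-atom-per-residue peptide from an explicit atom table row list.
atoms_peptide <- function(name, resno, code, xyz, ...) {
  new_peptide(data.frame(name = name, resno = resno, code = code,
                         x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]), ...)
}
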