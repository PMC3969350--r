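# Solvent-accessible surface (Shrake-Rupley) with retained surface samples,
# screened-Coulomb electrostatic potential at the samples, and HBD
# classification. Surface sampling is done in a canonical principal-axes
# frame so that areas are invariant under rigid motion of the input.

#' Shrake-Rupley solvent-accessible surface area
#'
#' Rolls a probe sphere over the van der Waals spheres using a deterministic
#' spiral point lattice on each probe-inflated sphere. Each atom's SASA is
#' `(exposed points / n_points) * 4 * pi * (r + probe)^2`; the exposed points
#' are retained as area-weighted surface samples for downstream electrostatic
#' descriptors.
#'
#' @param pep a `peptide`.
#' @param probe probe radius in Angstrom (default 1.4, water).
#' @param n_points quadrature points per atom (>= 16; default 960).
#' @return list with `atom_area` (per-atom SASA, Angstrom^2), `total`
#'   (total SASA) and `samples` (data.frame: `x`, `y`, `z`, `area`, `owner`
#'   atom row index, `residue_index`).
#' @export
shrake_rupley <- function(pep, probe = 1.4, n_points = 960) {
  if (n_points < 16)
    stop("n_points must be at least 16", call. = FALSE)
  a <- pep$atoms
  n <- nrow(a)
  xyz <- coords(pep)
  ctr <- colMeans(xyz)
  V <- canonical_rotation(xyz)
  xc <- sweep(xyz, 2, ctr) %*% V           # canonical frame
  rr <- a$vdw + probe
  pts0 <- sphere_points(n_points)
  out_xyz <- vector("list", n)
  owner <- vector("list", n)
  atom_area <- numeric(n)
  area_w <- numeric(n)
  # neighbor lists from pairwise distances
  d2 <- as.matrix(stats::dist(xc))^2
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (rr[i] + rr)^2 & seq_len(n) != i)
    pts <- pts0 * rr[i]
    pts <- sweep(pts, 2, xc[i, ], `+`)
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      dx <- pts[, 1] - xc[j, 1]
      dy <- pts[, 2] - xc[j, 2]
      dz <- pts[, 3] - xc[j, 3]
      exposed <- exposed & (dx * dx + dy * dy + dz * dz >= rr[j]^2)
      if (!any(exposed)) break
    }
    ne <- sum(exposed)
    atom_area[i] <- ne / n_points * 4 * pi * rr[i]^2
    area_w[i] <- 4 * pi * rr[i]^2 / n_points
    if (ne > 0) {
      out_xyz[[i]] <- pts[exposed, , drop = FALSE]
      owner[[i]] <- rep.int(i, ne)
    }
  }
  own <- unlist(owner)
  sxyz <- do.call(rbind, out_xyz)
  if (is.null(sxyz)) sxyz <- matrix(numeric(0), ncol = 3)
  # map samples back to the input frame
  sxyz <- sweep(sxyz %*% t(V), 2, ctr, `+`)
  samples <- data.frame(x = sxyz[, 1], y = sxyz[, 2], z = sxyz[, 3],
                        area = area_w[own], owner = own,
                        residue_index = a$resno[own])
  list(atom_area = atom_area, total = sum(atom_area), samples = samples)
}

#' Electrostatic potential at surface samples
#'
#' Screened Coulomb potential with a distance-dependent dielectric
#' `epsilon(r) = 4r`: the potential at a sample is `sum_j q_j / (4 r_j^2)`
#' over all formal point charges (arbitrary consistent units). Distances
#' below 0.1 Angstrom are clamped with a warning.
#'
#' @param pep a `peptide` (charge shares assigned by [new_peptide()]).
#' @param samples surface sample data.frame from [shrake_rupley()].
#' @return `samples` with a `potential` column added.
#' @export
electrostatic_potential <- function(pep, samples) {
  q <- pep$atoms$charge_share
  ch <- which(q != 0)
  pot <- numeric(nrow(samples))
  if (length(ch) && nrow(samples)) {
    cx <- pep$atoms$x[ch]; cy <- pep$atoms$y[ch]; cz <- pep$atoms$z[ch]
    clamped <- FALSE
    for (k in seq_along(ch)) {
      r2 <- (samples$x - cx[k])^2 + (samples$y - cy[k])^2 +
        (samples$z - cz[k])^2
      if (any(r2 < 0.01)) { clamped <- TRUE; r2[r2 < 0.01] <- 0.01 }
      pot <- pot + q[ch[k]] / (4 * r2)
    }
    if (clamped)
      warning("surface sample within 0.1 Angstrom of a point charge; ",
              "distance clamped", call. = FALSE)
  }
  samples$potential <- pot
  samples
}

#' Classify hydrogen-bond-donor surface samples
#'
#' A sample is HBD if its owner atom is a donor atom of a positively charged
#' side chain (an atom carrying a positive formal charge share) and the local
#' electrostatic potential is positive.
#'
#' @param pep a `peptide`.
#' @param samples samples with `potential` (see [electrostatic_potential()]).
#' @return `samples` with an `is_hbd` column added.
#' @export
classify_hbd <- function(pep, samples) {
  if (is.null(samples$potential))
    stop("compute electrostatic_potential() before classify_hbd()",
         call. = FALSE)
  samples$is_hbd <- pep$atoms$is_hbd[samples$owner] & samples$potential > 0
  samples
}

#' Full surface computation for a peptide
#'
#' Convenience wrapper: Shrake-Rupley sampling, electrostatic potential and
#' HBD classification in one call.
#'
#' @inheritParams shrake_rupley
#' @return list with `atom_area`, `total` and classified `samples`.
#' @export
peptide_surface <- function(pep, probe = 1.4, n_points = 960) {
  sr <- shrake_rupley(pep, probe = probe, n_points = n_points)
  sr$samples <- classify_hbd(pep, electrostatic_potential(pep, sr$samples))
  sr
}

#' Per-residue side-chain solvent accessibility
#'
#' @param pep a `peptide`.
#' @param atom_area per-atom SASA from [shrake_rupley()].
#' @return named numeric vector, one entry per residue index.
#' @export
sidechain_sasa <- function(pep, atom_area) {
  sel <- pep$atoms$is_sidechain
  out <- numeric(nrow(pep$residues))
  names(out) <- pep$residues$index
  if (any(sel)) {
    agg <- tapply(atom_area[sel], pep$atoms$resno[sel], sum)
    out[names(agg)] <- agg
  }
  out
}
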