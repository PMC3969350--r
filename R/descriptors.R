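# The five physicochemical descriptors: total and exclusive lipophilicity
# (L_S, L_S*), lipophilic moment (L_M), HBD surface area (E_S) and HBD
# amphipathic moment (E_M), plus the per-loop lipophilicity profile.

#' Per-residue lipophilic intensities and direction vectors
#'
#' The lipophilic intensity of residue i is its normalized scale value
#' weighted by its relative side-chain solvent exposure,
#' `intensity = normalized * min(1, SASA_sidechain / sasa_max)`; its
#' direction is the unit vector from the peptide center to the side-chain
#' heavy-atom centroid. Glycine (no side chain) has intensity 0.
#'
#' @param pep a `peptide`.
#' @param scale a `lipo_scale` covering all residue codes.
#' @param sasa per-atom SASA vector from [shrake_rupley()] (or the list it
#'   returns).
#' @return data.frame with one row per residue: `residue_index`, `code`,
#'   `normalized`, `exposure`, `intensity` and direction columns `ux`, `uy`,
#'   `uz`.
#' @export
residue_lipophilicity <- function(pep, scale, sasa) {
  if (is.list(sasa) && !is.null(sasa$atom_area)) sasa <- sasa$atom_area
  res <- pep$residues
  norm <- scale_lookup(scale, res$code, "normalized")
  smax <- scale_lookup(scale, res$code, "sasa_max")
  sc <- sidechain_sasa(pep, sasa)
  exposure <- ifelse(smax > 0, pmin(1, sc / smax), 0)
  intensity <- norm * exposure
  dirs <- matrix(0, nrow(res), 3)
  a <- pep$atoms
  heavy_sc <- a$is_sidechain & a$element != "H"
  for (i in seq_len(nrow(res))) {
    sel <- heavy_sc & a$resno == res$index[i]
    if (any(sel)) {
      centroid <- colMeans(as.matrix(a[sel, c("x", "y", "z")]))
      dirs[i, ] <- unit_vec(centroid - pep$center)
    }
  }
  data.frame(residue_index = res$index, code = res$code, normalized = norm,
             exposure = unname(exposure), intensity = unname(intensity),
             ux = dirs[, 1], uy = dirs[, 2], uz = dirs[, 3],
             stringsAsFactors = FALSE)
}

#' Resultant of the residue lipophilic vectors
#'
#' @param rl residue table from [residue_lipophilicity()].
#' @return length-3 numeric vector (unnormalized resultant).
#' @export
lipophilic_resultant <- function(rl) {
  c(sum(rl$intensity * rl$ux), sum(rl$intensity * rl$uy),
    sum(rl$intensity * rl$uz))
}

#' Lipophilic moment L_M
#'
#' Magnitude of the resultant of the residue lipophilic vectors divided by
#' the number of residues (a length-independent mean resultant). Measures the
#' asymmetry of the lipophilicity distribution over the surface.
#'
#' @param rl residue table from [residue_lipophilicity()].
#' @return L_M (dimensionless, >= 0).
#' @export
lipophilic_moment <- function(rl) {
  if (nrow(rl) == 0) return(0)
  vnorm(lipophilic_resultant(rl)) / nrow(rl)
}

#' Total lipophilicity L_S
#'
#' Signed sum of all residue lipophilic intensities.
#'
#' @param rl residue table from [residue_lipophilicity()].
#' @return L_S (dimensionless).
#' @export
total_lipophilicity <- function(rl) sum(rl$intensity)

#' Exclusive lipophilicity L_S*
#'
#' Sum of the intensities of residues that are lipophilic on the scale
#' (normalized value > 0) and sit in the lipid-attractive region,
#' operationalized as the hemisphere with positive projection on the
#' lipophilic resultant. If the resultant vanishes, the sum over all
#' positive intensities is returned with attribute `degenerate = TRUE`.
#'
#' @param rl residue table from [residue_lipophilicity()].
#' @param resultant optional length-3 resultant vector (computed from `rl`
#'   when missing).
#' @return L_S* (dimensionless, >= 0).
#' @export
exclusive_lipophilicity <- function(rl, resultant = NULL) {
  if (is.null(resultant)) resultant <- lipophilic_resultant(rl)
  pos <- rl$normalized > 0
  if (vnorm(resultant) < 1e-12) {
    out <- sum(rl$intensity[pos & rl$intensity > 0])
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  proj <- rl$ux * resultant[1] + rl$uy * resultant[2] + rl$uz * resultant[3]
  sum(rl$intensity[pos & proj > 0])
}

#' HBD surface area E_S
#'
#' Total area of surface samples classified as hydrogen-bond donating
#' (positively charged side-chain surface with positive local potential).
#'
#' @param samples classified samples (see [classify_hbd()]).
#' @return E_S in Angstrom^2.
#' @export
hbd_surface_area <- function(samples) {
  if (is.null(samples$is_hbd))
    stop("samples must be HBD-classified (see classify_hbd)", call. = FALSE)
  sum(samples$area[samples$is_hbd])
}

#' HBD amphipathic moment E_M
#'
#' Euclidean distance between the area-weighted centroid of the HBD surface
#' and the area-weighted centroid of the hydrophobic surface (samples owned
#' by residues with positive normalized lipophilicity and zero formal
#' charge). Zero if either surface is empty.
#'
#' @param pep a `peptide`.
#' @param samples classified samples.
#' @param scale a `lipo_scale`.
#' @return E_M in Angstrom.
#' @export
hbd_amphipathic_moment <- function(pep, samples, scale) {
  if (is.null(samples$is_hbd))
    stop("samples must be HBD-classified (see classify_hbd)", call. = FALSE)
  if (nrow(samples) == 0) return(0)
  res <- pep$residues
  norm <- scale_lookup(scale, res$code, "normalized")
  lipo_res <- res$index[norm > 0 & res$formal_charge == 0]
  hyd <- samples$residue_index %in% lipo_res
  hbd <- samples$is_hbd
  if (!any(hbd) || !any(hyd)) return(0)
  wcent <- function(sel) {
    w <- samples$area[sel]
    c(sum(w * samples$x[sel]), sum(w * samples$y[sel]),
      sum(w * samples$z[sel])) / sum(w)
  }
  vnorm(wcent(hbd) - wcent(hyd))
}

#' Per-loop lipophilicity profile
#'
#' Signed sum of residue lipophilic intensities within each inter-cysteine
#' loop (see [assign_loops()]); loops with no residues contribute 0.
#'
#' @param pep a `peptide` with loops assigned.
#' @param rl residue table from [residue_lipophilicity()].
#' @return named numeric vector `loop1` .. `loop6`.
#' @export
loop_lipophilicity_profile <- function(pep, rl) {
  lid <- pep$residues$loop_id
  if (all(is.na(lid)) && any(pep$residues$code != "CYS"))
    stop("loops not assigned: call assign_loops() first", call. = FALSE)
  out <- stats::setNames(numeric(6), paste0("loop", 1:6))
  m <- match(rl$residue_index, pep$residues$index)
  for (k in 1:6) {
    sel <- !is.na(lid[m]) & lid[m] == k
    out[k] <- sum(rl$intensity[sel])
  }
  out
}

#' Compute all five descriptors for a peptide
#'
#' Runs the full pipeline: surface sampling, per-residue intensities, the
#' lipophilicity descriptors and the electrostatic descriptors.
#'
#' @param pep a `peptide`.
#' @param scale a `lipo_scale` (default: the packaged scale).
#' @param probe probe radius, Angstrom.
#' @param n_points quadrature points per atom.
#' @param loops also report the per-loop lipophilicity profile (requires 6
#'   cysteines).
#' @return one-row data.frame: `label`, `L_S`, `L_S_star`, `L_M`, `E_S`,
#'   `E_M` (and `loop1`..`loop6` when `loops = TRUE`).
#' @export
peptide_descriptors <- function(pep, scale = default_lipo_scale(),
                                probe = 1.4, n_points = 960, loops = FALSE) {
  surf <- peptide_surface(pep, probe = probe, n_points = n_points)
  rl <- residue_lipophilicity(pep, scale, surf$atom_area)
  resv <- lipophilic_resultant(rl)
  out <- data.frame(label = pep$label,
                    L_S = total_lipophilicity(rl),
                    L_S_star = as.numeric(exclusive_lipophilicity(rl, resv)),
                    L_M = lipophilic_moment(rl),
                    E_S = hbd_surface_area(surf$samples),
                    E_M = hbd_amphipathic_moment(pep, surf$samples, scale),
                    stringsAsFactors = FALSE)
  if (loops) {
    lp <- loop_lipophilicity_profile(pep, rl)
    out <- cbind(out, as.data.frame(as.list(lp)))
  }
  out
}
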