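# Normalized side-chain lipophilicity scale (glycine-anchored) and maximal
# side-chain solvent accessibility, including chemically modified residues.

# Packaged scale. `normalized` is the glycine-anchored normalized logP of the
# side chain; `sasa_max` is the side-chain SASA (Angstrom^2) of X in an
# extended Gly-X-Gly tripeptide. Raw logP values are optional user input (the
# normalized column is what every downstream computation consumes); modified
# residues: ACK = N6-acetyl-lysine, CDR = arginine modified with
# 1,2-cyclohexanedione, KYW = kynurenine, MEE = glutamate delta-methyl ester.
.lipo_scale_data <- data.frame(
  code = c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
           "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
           "TYR", "VAL", "ACK", "CDR", "KYW", "MEE"),
  raw_logp = NA_real_,
  normalized = c(0.015, -0.62, -0.18, -0.51, 0.068, -0.14, -0.47, 0.00,
                 -0.060, 0.38, 0.19, -0.366, 0.096, 0.26, 0.25, -0.083,
                 -0.015, 0.28, 0.19, 0.20, 0.012, -0.49, 0.10, -0.012),
  sasa_max = c(65.85, 200.62, 128.88, 112.53, 99.87, 148.60, 146.78, 0.00,
               157.99, 157.72, 166.64, 195.16, 166.80, 188.38, 105.72,
               82.22, 114.60, 229.66, 214.65, 125.98, 263.09, 336.44,
               236.08, 182.28),
  stringsAsFactors = FALSE
)

# Scaling constants: the raw logP of the protonated-arginine side chain is
# -3.800 and 6.457 is the sum of the magnitudes of the raw logP values of
# Arg+ and Ile, so scaled values run from 0 (Arg+) to 1 (Ile). The packaged
# scaled value of glycine (0.62) anchors the normalized column at
# normalized(Gly) = 0.
.scale_offset <- 3.800
.scale_span <- 6.457
.scaled_gly_default <- 0.62

#' Scale and normalize a raw side-chain logP value
#'
#' Applies the two affine maps of the packaged scale:
#' `scaled = (raw + 3.800) / 6.457` (0 at the protonated-arginine anchor, 1 at
#' isoleucine) and `normalized = scaled - scaled(Gly)` (0 at glycine).
#'
#' @param raw_logp raw side-chain logP.
#' @param scaled_gly scaled value of glycine (default 0.62, the packaged
#'   anchor).
#' @return list with `scaled` and `normalized`.
#' @export
scale_and_normalize <- function(raw_logp, scaled_gly = .scaled_gly_default) {
  scaled <- (raw_logp + .scale_offset) / .scale_span
  list(scaled = scaled, normalized = scaled - scaled_gly)
}

#' Effective histidine logP from its protonation mixture
#'
#' At a given pH, histidine is a mixture of the imidazolium and neutral
#' forms; the effective logP is the mole-fraction-weighted (convex)
#' combination of the two forms' logP values.
#'
#' @param logp_protonated,logp_neutral logP of the two forms.
#' @param ph,pka solution pH and side-chain pKa (defaults 7.4 and 6.50 give
#'   mole fractions 11.2% / 88.8%).
#' @return effective logP.
#' @export
his_effective_logp <- function(logp_protonated, logp_neutral,
                               ph = 7.4, pka = 6.5) {
  f <- his_protonated_fraction(ph, pka)
  f * logp_protonated + (1 - f) * logp_neutral
}

#' Cysteine logP as half of cystine's
#'
#' An oxidized (half-cystine) cysteine carries half the lipophilicity of the
#' cystine dimer.
#'
#' @param logp_cystine raw logP of cystine.
#' @return raw logP assigned to one half-cystine.
#' @export
cys_from_cystine <- function(logp_cystine) logp_cystine / 2

#' The packaged lipophilicity scale
#'
#' @param ph pH recorded for the ionizable-residue entries (default 7.4).
#' @return a `lipo_scale` data.frame with columns `code`, `raw_logp`,
#'   `normalized`, `sasa_max`.
#' @export
default_lipo_scale <- function(ph = 7.4) {
  s <- .lipo_scale_data
  attr(s, "ph") <- ph
  class(s) <- c("lipo_scale", "data.frame")
  s
}

#' Look up normalized lipophilicity values
#'
#' @param scale a `lipo_scale`.
#' @param codes character vector of 3-letter residue codes.
#' @param what column to return (`"normalized"` or `"sasa_max"`).
#' @return numeric vector; errors listing any codes absent from the scale.
#' @export
scale_lookup <- function(scale, codes, what = c("normalized", "sasa_max")) {
  what <- match.arg(what)
  i <- match(toupper(codes), scale$code)
  if (anyNA(i))
    stop("residue code(s) not in lipophilicity scale: ",
         paste(unique(codes[is.na(i)]), collapse = ", "), call. = FALSE)
  scale[[what]][i]
}

#' Maximal side-chain solvent accessibility of a residue type
#'
#' Side-chain SASA of the central residue in an extended Gly-X-Gly
#' tripeptide (see [build_extended_tripeptide()]).
#'
#' @param code 3-letter residue code.
#' @param probe probe radius, Angstrom.
#' @param n_points quadrature points per atom.
#' @param geometry optional z-matrix for non-standard residues.
#' @return SASA in Angstrom^2.
#' @export
max_sidechain_sasa <- function(code, probe = 1.4, n_points = 960,
                               geometry = NULL) {
  tri <- build_extended_tripeptide(code, geometry = geometry)
  sr <- shrake_rupley(tri, probe = probe, n_points = n_points)
  unname(sidechain_sasa(tri, sr$atom_area)[2])
}

#' Read / write a lipophilicity scale as tab-delimited text
#'
#' Columns: `code`, `raw_logp` (may be NA), `normalized`, `sasa_max`. Users
#' can extend the packaged file with modified residues.
#'
#' @param path file path.
#' @return for `read_lipo_scale`, a `lipo_scale`.
#' @export
read_lipo_scale <- function(path) {
  s <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("code", "normalized", "sasa_max")
  if (!all(need %in% names(s)))
    stop("scale file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (is.null(s$raw_logp)) s$raw_logp <- NA_real_
  s$code <- toupper(s$code)
  class(s) <- c("lipo_scale", "data.frame")
  s
}

#' @param scale a `lipo_scale`.
#' @rdname read_lipo_scale
#' @export
write_lipo_scale <- function(scale, path) {
  utils::write.table(as.data.frame(scale)[, c("code", "raw_logp",
                                              "normalized", "sasa_max")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
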