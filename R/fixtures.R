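# Seeded synthetic generators (toy peptides on a sphere, planted-breakpoint
# QSAR datasets) and the packaged compilation of published cyclotide IC50
# values.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

#' Generate a toy peptide on a sphere
#'
#' Pseudo-residues are placed at seeded uniform directions on a sphere of the
#' given radius, each with a backbone pseudo-atom (CA) and a single
#' side-chain sphere (CB) further out, so surface areas have near-analytic
#' values. Residue types: lipophilic (Leu), lipophobic (Asn) and positively
#' charged (Lys). The `segregation` parameter controls hemispheric sorting:
#' at 1, every lipophilic residue points into the +z hemisphere and every
#' charged/lipophobic residue into the -z hemisphere; at 0 directions are
#' left as drawn.
#'
#' @param n_residues number of pseudo-residues (>= 4).
#' @param fraction_lipophilic fraction of residues that are lipophilic.
#' @param segregation hemispheric sorting strength in 0..1.
#' @param n_charged number of positively charged residues.
#' @param radius sphere radius, Angstrom.
#' @param seed integer seed (same seed, bit-identical structure).
#' @param label peptide label.
#' @return a `peptide`.
#' @export
make_toy_peptide <- function(n_residues = 24, fraction_lipophilic = 0.5,
                             segregation = 1, n_charged = 4, radius = 10,
                             seed = 1, label = NULL) {
  stopifnot(n_residues >= 4, fraction_lipophilic >= 0,
            fraction_lipophilic <= 1, segregation >= 0, segregation <= 1,
            n_charged <= n_residues)
  if (is.null(label)) label <- sprintf("toy_s%d_seg%g", seed, segregation)
  with_seed(seed, {
    n_lip <- round(fraction_lipophilic * n_residues)
    n_lip <- min(n_lip, n_residues - n_charged)
    codes <- c(rep("LEU", n_lip), rep("LYS", n_charged),
               rep("ASN", n_residues - n_lip - n_charged))
    # uniform directions on the sphere
    u <- matrix(stats::rnorm(3 * n_residues), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    sortz <- stats::runif(n_residues) < segregation
    lip <- codes == "LEU"
    flip_up <- sortz & lip
    flip_dn <- sortz & !lip
    u[flip_up, 3] <- abs(u[flip_up, 3])
    u[flip_dn, 3] <- -abs(u[flip_dn, 3])
    u <- u / sqrt(rowSums(u^2))
    rows <- vector("list", 2 * n_residues)
    for (i in seq_len(n_residues)) {
      ca <- radius * u[i, ]
      cb <- (radius + 3) * u[i, ]
      rows[[2 * i - 1]] <- data.frame(name = "CA", resno = i, code = codes[i],
                                      x = ca[1], y = ca[2], z = ca[3])
      rows[[2 * i]] <- data.frame(name = "CB", resno = i, code = codes[i],
                                  x = cb[1], y = cb[2], z = cb[3])
    }
    new_peptide(do.call(rbind, rows), label = label, cyclic = FALSE)
  })
}

#' Generate a synthetic QSAR dataset with a planted breakpoint
#'
#' Draws descriptors from uniform ranges spanning the critical-point grid
#' (`L_S* ~ U(0, 5)`, `E_S ~ U(50, 350)`, `L_M ~ U(0, L_M_max)`,
#' `E_M ~ U(0, E_M_max)`) and generates the response from the dummy-variable
#' model `y = k + l * tau * L_S* + m * tau * E_S + noise`, with tau gated by
#' the planted critical point.
#'
#' A breakpoint can only be recovered at grid resolution if the sample
#' actually distinguishes it from the neighboring grid nodes, i.e. if each
#' one-grid-step strip adjacent to the breakpoint contains at least one
#' observation. With `ensure_identifiable = TRUE` (default) the generator
#' redraws (deterministically, continuing the seeded stream) until that holds
#' for an interior breakpoint.
#'
#' @param n number of records (>= 10).
#' @param k,l,m model coefficients.
#' @param critical_point planted `(L_M_c, E_M_c)`.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed integer seed.
#' @param L_M_max,E_M_max moment ranges (the grid bounds).
#' @param grid_n grid nodes per axis used to size the identifiability strips.
#' @param ensure_identifiable redraw until the breakpoint is identifiable.
#' @return data.frame with `label`, `L_S_star`, `E_S`, `L_M`, `E_M`, `tau`,
#'   `y`.
#' @export
make_qsar_dataset <- function(n = 60, k = 0.1, l = 0.05, m = 0.002,
                              critical_point = c(0.03750, 4.5000),
                              noise_sd = 0.02, seed = 1,
                              L_M_max = 0.050, E_M_max = 9.000, grid_n = 17,
                              ensure_identifiable = TRUE) {
  stopifnot(n >= 10)
  cpl <- critical_point[1]; cpe <- critical_point[2]
  dl <- L_M_max / (grid_n - 1)
  de <- E_M_max / (grid_n - 1)
  interior <- cpl > 0 && cpl < L_M_max && cpe > 0 && cpe < E_M_max
  with_seed(seed, {
    for (try in 1:1000) {
      d <- data.frame(label = sprintf("S%02d", seq_len(n)),
                      L_S_star = stats::runif(n, 0, 5),
                      E_S = stats::runif(n, 50, 350),
                      L_M = stats::runif(n, 0, L_M_max),
                      E_M = stats::runif(n, 0, E_M_max))
      if (!ensure_identifiable || !interior) break
      below_e <- d$E_M < cpe
      below_l <- d$L_M < cpl
      ok <- any(d$L_M >= cpl - dl & d$L_M < cpl & below_e) &&
        any(d$L_M >= cpl & d$L_M < cpl + dl & below_e) &&
        any(d$E_M >= cpe - de & d$E_M < cpe & below_l) &&
        any(d$E_M >= cpe & d$E_M < cpe + de & below_l)
      if (ok) break
    }
    d$tau <- tau_diagonal(d[, c("L_M", "E_M")], critical_point)
    d$y <- k + l * d$tau * d$L_S_star + m * d$tau * d$E_S +
      stats::rnorm(n, 0, noise_sd)
    d
  })
}

#' Published cyclotide activity records
#'
#' The packaged compilation of literature IC50 values (micromolar) for the
#' anthelmintic assay against \emph{Haemonchus contortus} larvae and the
#' cytotoxicity assay against the U-937GTB lymphoma line, with censoring
#' ("> limit") preserved as printed. Labels follow the subfamily convention
#' (M = Moebius, B = bracelet, H = hybrid, L = linear); mutant names such as
#' `[G1K]-kB1` are opaque labels.
#'
#' @param assay `"both"` (default), `"anthelmintic"` or `"cytotoxic"`.
#' @return data.frame in long form: `label`, `protein`, `subfamily`,
#'   `assay`, `ic50` (NA when censored or missing), `censored`, `limit`
#'   (censoring limit, NA otherwise).
#' @export
cyclotide_activities <- function(assay = c("both", "anthelmintic",
                                           "cytotoxic")) {
  assay <- match.arg(assay)
  path <- system.file("extdata", "cyclotide_activity.tsv",
                      package = "cyclophys", mustWork = TRUE)
  raw <- utils::read.delim(path, colClasses = "character", fill = TRUE,
                           na.strings = c("", "NA"))
  parse_col <- function(v, which_assay) {
    censored <- !is.na(v) & startsWith(v, ">")
    ic50 <- suppressWarnings(as.numeric(ifelse(censored, NA, v)))
    limit <- suppressWarnings(as.numeric(ifelse(censored, sub(">", "", v),
                                                NA)))
    data.frame(label = raw$label, protein = raw$protein,
               subfamily = raw$subfamily, assay = which_assay,
               ic50 = ic50, censored = censored, limit = limit,
               stringsAsFactors = FALSE)
  }
  out <- rbind(parse_col(raw$anthelmintic, "anthelmintic"),
               parse_col(raw$cytotoxic, "cytotoxic"))
  rownames(out) <- NULL
  if (assay != "both") out <- out[out$assay == assay, , drop = FALSE]
  out
}
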