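# Extended Gly-X-Gly tripeptide builder. Heavy atoms only, ideal internal
# coordinates (Engh-Huber-like values), backbone phi = psi = omega = 180
# degrees, side chains in an extended default rotamer (chi = 180 for chains,
# ring planes at chi2 = 90). Used to define the maximal side-chain solvent
# exposure of each residue type.

# Side-chain z-matrices. Each row places `name` bonded to `r3`, with bond
# length `bond` (Angstrom), angle name-r3-r2 (degrees) and torsion
# name-r3-r2-r1 (degrees). CB rows are shared (placed off the backbone).
.zmat_row <- function(name, r1, r2, r3, bond, angle, dihedral) {
  data.frame(name = name, r1 = r1, r2 = r2, r3 = r3, bond = bond,
             angle = angle, dihedral = dihedral, stringsAsFactors = FALSE)
}

.cb <- .zmat_row("CB", "C", "N", "CA", 1.530, 110.5, -122.5)

.sidechain_zmat <- list(
  GLY = NULL,
  ALA = .cb,
  SER = rbind(.cb, .zmat_row("OG",  "N", "CA", "CB", 1.417, 110.8, 180)),
  CYS = rbind(.cb, .zmat_row("SG",  "N", "CA", "CB", 1.808, 114.4, 180)),
  THR = rbind(.cb,
              .zmat_row("OG1", "N", "CA", "CB", 1.433, 109.6, 180),
              .zmat_row("CG2", "N", "CA", "CB", 1.521, 110.5, -60)),
  VAL = rbind(.cb,
              .zmat_row("CG1", "N", "CA", "CB", 1.521, 110.5, 180),
              .zmat_row("CG2", "N", "CA", "CB", 1.521, 110.5, 60)),
  LEU = rbind(.cb,
              .zmat_row("CG",  "N", "CA", "CB", 1.530, 116.3, 180),
              .zmat_row("CD1", "CA", "CB", "CG", 1.521, 110.7, 180),
              .zmat_row("CD2", "CA", "CB", "CG", 1.521, 110.7, 60)),
  ILE = rbind(.cb,
              .zmat_row("CG1", "N", "CA", "CB", 1.530, 110.4, 180),
              .zmat_row("CG2", "N", "CA", "CB", 1.521, 110.5, -60),
              .zmat_row("CD1", "CA", "CB", "CG1", 1.513, 113.8, 180)),
  MET = rbind(.cb,
              .zmat_row("CG",  "N", "CA", "CB", 1.520, 114.1, 180),
              .zmat_row("SD",  "CA", "CB", "CG", 1.803, 112.7, 180),
              .zmat_row("CE",  "CB", "CG", "SD", 1.791, 100.9, 180)),
  PRO = rbind(.cb,
              .zmat_row("CG",  "N", "CA", "CB", 1.492, 104.5, 30),
              .zmat_row("CD",  "CA", "CB", "CG", 1.503, 106.1, -35)),
  ASP = rbind(.cb,
              .zmat_row("CG",  "N", "CA", "CB", 1.516, 112.6, 180),
              .zmat_row("OD1", "CA", "CB", "CG", 1.249, 118.4, 0),
              .zmat_row("OD2", "CA", "CB", "CG", 1.249, 118.4, 180)),
  ASN = rbind(.cb,
              .zmat_row("CG",  "N", "CA", "CB", 1.516, 112.6, 180),
              .zmat_row("OD1", "CA", "CB", "CG", 1.231, 120.8, 0),
              .zmat_row("ND2", "CA", "CB", "CG", 1.328, 116.4, 180)),
  GLU = rbind(.cb,
              .zmat_row("CG",  "N", "CA", "CB", 1.520, 114.1, 180),
              .zmat_row("CD",  "CA", "CB", "CG", 1.516, 112.6, 180),
              .zmat_row("OE1", "CB", "CG", "CD", 1.249, 118.4, 0),
              .zmat_row("OE2", "CB", "CG", "CD", 1.249, 118.4, 180)),
  GLN = rbind(.cb,
              .zmat_row("CG",  "N", "CA", "CB", 1.520, 114.1, 180),
              .zmat_row("CD",  "CA", "CB", "CG", 1.516, 112.6, 180),
              .zmat_row("OE1", "CB", "CG", "CD", 1.231, 120.8, 0),
              .zmat_row("NE2", "CB", "CG", "CD", 1.328, 116.4, 180)),
  LYS = rbind(.cb,
              .zmat_row("CG",  "N", "CA", "CB", 1.520, 114.1, 180),
              .zmat_row("CD",  "CA", "CB", "CG", 1.520, 111.3, 180),
              .zmat_row("CE",  "CB", "CG", "CD", 1.520, 111.3, 180),
              .zmat_row("NZ",  "CG", "CD", "CE", 1.489, 111.9, 180)),
  ARG = rbind(.cb,
              .zmat_row("CG",  "N", "CA", "CB", 1.520, 114.1, 180),
              .zmat_row("CD",  "CA", "CB", "CG", 1.520, 111.3, 180),
              .zmat_row("NE",  "CB", "CG", "CD", 1.461, 112.0, 180),
              .zmat_row("CZ",  "CG", "CD", "NE", 1.329, 124.2, 180),
              .zmat_row("NH1", "CD", "NE", "CZ", 1.326, 120.0, 0),
              .zmat_row("NH2", "CD", "NE", "CZ", 1.326, 120.0, 180)),
  PHE = rbind(.cb,
              .zmat_row("CG",  "N", "CA", "CB", 1.502, 113.8, 180),
              .zmat_row("CD1", "CA", "CB", "CG", 1.384, 120.8, 90),
              .zmat_row("CD2", "CA", "CB", "CG", 1.384, 120.8, -90),
              .zmat_row("CE1", "CB", "CG", "CD1", 1.384, 120.8, 180),
              .zmat_row("CE2", "CB", "CG", "CD2", 1.384, 120.8, 180),
              .zmat_row("CZ",  "CG", "CD1", "CE1", 1.382, 120.0, 0)),
  TYR = rbind(.cb,
              .zmat_row("CG",  "N", "CA", "CB", 1.502, 113.8, 180),
              .zmat_row("CD1", "CA", "CB", "CG", 1.384, 120.8, 90),
              .zmat_row("CD2", "CA", "CB", "CG", 1.384, 120.8, -90),
              .zmat_row("CE1", "CB", "CG", "CD1", 1.384, 120.8, 180),
              .zmat_row("CE2", "CB", "CG", "CD2", 1.384, 120.8, 180),
              .zmat_row("CZ",  "CG", "CD1", "CE1", 1.382, 120.0, 0),
              .zmat_row("OH",  "CD1", "CE1", "CZ", 1.376, 119.9, 180)),
  TRP = rbind(.cb,
              .zmat_row("CG",  "N", "CA", "CB", 1.498, 113.6, 180),
              .zmat_row("CD1", "CA", "CB", "CG", 1.365, 126.9, 90),
              .zmat_row("CD2", "CA", "CB", "CG", 1.433, 126.6, -90),
              .zmat_row("NE1", "CB", "CG", "CD1", 1.374, 110.2, 180),
              .zmat_row("CE2", "CB", "CG", "CD2", 1.409, 107.2, 180),
              .zmat_row("CE3", "CB", "CG", "CD2", 1.398, 133.9, 0),
              .zmat_row("CZ2", "CG", "CD2", "CE2", 1.394, 122.4, 180),
              .zmat_row("CZ3", "CG", "CD2", "CE3", 1.382, 118.6, 180),
              .zmat_row("CH2", "CD2", "CE2", "CZ2", 1.368, 117.5, 0)),
  HIS = rbind(.cb,
              .zmat_row("CG",  "N", "CA", "CB", 1.497, 113.8, 180),
              .zmat_row("ND1", "CA", "CB", "CG", 1.378, 122.7, 90),
              .zmat_row("CD2", "CA", "CB", "CG", 1.354, 131.1, -90),
              .zmat_row("CE1", "CB", "CG", "ND1", 1.320, 109.2, 180),
              .zmat_row("NE2", "CB", "CG", "CD2", 1.374, 107.2, 180))
)

# Backbone geometry (Angstrom / degrees)
.bb <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
            ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
            ang_ca_c_o = 120.8)

#' Build an extended Gly-X-Gly tripeptide
#'
#' Constructs the tripeptide Gly-X-Gly in a fully extended conformation
#' (phi = psi = omega = 180 degrees) with ideal bond lengths and angles and
#' the side chain of the central residue X in an extended default rotamer.
#' Heavy atoms only. This is the reference conformation for the maximal
#' side-chain solvent accessibility of residue type X.
#'
#' @param code 3-letter residue code of the central residue (one of the 20
#'   standard residues), case-insensitive.
#' @param geometry optional user z-matrix for non-standard residues: a
#'   data.frame with columns `name`, `r1`, `r2`, `r3`, `bond`, `angle`,
#'   `dihedral` (references may be the backbone N, CA, C of the central
#'   residue or previously placed side-chain atoms).
#' @return a `peptide` with 3 residues (Gly, X, Gly).
#' @export
build_extended_tripeptide <- function(code, geometry = NULL) {
  code <- toupper(code)
  if (is.null(geometry)) {
    if (!code %in% names(.sidechain_zmat))
      stop("unsupported residue code '", code,
           "': supply a side-chain geometry table", call. = FALSE)
    geometry <- .sidechain_zmat[[code]]
  }
  bb <- .bb
  # backbone: N, CA, C per residue, extended
  pos <- list()
  pos[["N1"]] <- c(0, 0, 0)
  pos[["CA1"]] <- c(bb$n_ca, 0, 0)
  u <- c(-1, 0, 0)
  ang <- bb$ang_n_ca_c * pi / 180
  pos[["C1"]] <- pos[["CA1"]] +
    bb$ca_c * (cos(ang) * u + sin(ang) * c(0, 1, 0))
  chain <- c("N", "CA", "C")
  for (i in 2:3) {
    p <- function(nm) pos[[nm]]
    pos[[paste0("N", i)]] <- place_atom(p(paste0("N", i - 1)),
                                        p(paste0("CA", i - 1)),
                                        p(paste0("C", i - 1)),
                                        bb$c_n, bb$ang_ca_c_n, 180)   # psi
    pos[[paste0("CA", i)]] <- place_atom(p(paste0("CA", i - 1)),
                                         p(paste0("C", i - 1)),
                                         p(paste0("N", i)),
                                         bb$n_ca, bb$ang_c_n_ca, 180) # omega
    pos[[paste0("C", i)]] <- place_atom(p(paste0("C", i - 1)),
                                        p(paste0("N", i)),
                                        p(paste0("CA", i)),
                                        bb$ca_c, bb$ang_n_ca_c, 180)  # phi
  }
  # carbonyl oxygens: anti to the next N (torsion 0 w.r.t. this N at psi=180)
  for (i in 1:3) {
    pos[[paste0("O", i)]] <- place_atom(pos[[paste0("N", i)]],
                                        pos[[paste0("CA", i)]],
                                        pos[[paste0("C", i)]],
                                        bb$c_o, bb$ang_ca_c_o, 0)
  }
  pos[["OXT3"]] <- place_atom(pos[["N3"]], pos[["CA3"]], pos[["C3"]],
                              bb$c_o, bb$ang_ca_c_o, 180)

  rows <- list()
  add <- function(name, resno, rescode, xyz) {
    rows[[length(rows) + 1]] <<- data.frame(
      name = name, resno = resno, code = rescode,
      x = xyz[1], y = xyz[2], z = xyz[3], stringsAsFactors = FALSE)
  }
  for (i in 1:3) {
    rescode <- if (i == 2) code else "GLY"
    add("N", i, rescode, pos[[paste0("N", i)]])
    add("CA", i, rescode, pos[[paste0("CA", i)]])
    add("C", i, rescode, pos[[paste0("C", i)]])
    add("O", i, rescode, pos[[paste0("O", i)]])
    if (i == 2 && !is.null(geometry)) {
      sc <- list(N = pos[["N2"]], CA = pos[["CA2"]], C = pos[["C2"]])
      for (r in seq_len(nrow(geometry))) {
        g <- geometry[r, ]
        for (ref in c(g$r1, g$r2, g$r3)) {
          if (is.null(sc[[ref]]))
            stop("z-matrix reference atom '", ref, "' not yet placed",
                 call. = FALSE)
        }
        sc[[g$name]] <- place_atom(sc[[g$r1]], sc[[g$r2]], sc[[g$r3]],
                                   g$bond, g$angle, g$dihedral)
        add(g$name, i, rescode, sc[[g$name]])
      }
    }
    if (i == 3) add("OXT", i, rescode, pos[["OXT3"]])
  }
  atoms <- do.call(rbind, rows)
  new_peptide(atoms, label = paste0("GLY-", code, "-GLY"), cyclic = FALSE)
}

#' Measure a torsion angle between four atoms of a peptide
#'
#' @param pep a `peptide`.
#' @param sel 4-row selection: data.frame with `resno` and `name` columns.
#' @return torsion angle in degrees, in (-180, 180].
#' @export
measure_dihedral <- function(pep, sel) {
  stopifnot(nrow(sel) == 4)
  xyz <- t(vapply(seq_len(4), function(i) {
    row <- pep$atoms[pep$atoms$resno == sel$resno[i] &
                       pep$atoms$name == sel$name[i], c("x", "y", "z")]
    if (nrow(row) != 1) stop("atom not found: ", sel$name[i], call. = FALSE)
    as.numeric(row)
  }, numeric(3)))
  b1 <- xyz[2, ] - xyz[1, ]; b2 <- xyz[3, ] - xyz[2, ]; b3 <- xyz[4, ] - xyz[3, ]
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit_vec(b2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}
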