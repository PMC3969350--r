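# Peptide structure model: atom table with radii/charges, PDB I/O via bio3d,
# cysteine-derived loop annotation and C-alpha RMSD.

# United-atom van der Waals radii (Angstrom), after Chothia (1976) as used
# by NACCESS: aliphatic carbons absorb their hydrogens (1.87), trigonal /
# aromatic / carbonyl carbons are 1.76, N 1.65, O 1.40, S 1.85. Explicit
# hydrogens, when present, get 1.00; unlisted elements fall back to 1.80.
.vdw_radii <- c(H = 1.00, C = 1.87, N = 1.65, O = 1.40, S = 1.85, P = 1.80)

# side-chain atoms that are trigonal or aromatic carbons (radius 1.76)
.trigonal_c <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "CD2", "CE1"),
  ARG = "CZ",
  ASP = "CG", ASN = "CG", GLU = "CD", GLN = "CD"
)

assign_vdw <- function(name, code, element) {
  r <- unname(.vdw_radii[element])
  r[is.na(r)] <- 1.80
  is_c <- element == "C"
  # backbone carbonyl carbon and side-chain trigonal carbons
  r[is_c & name == "C"] <- 1.76
  for (res in names(.trigonal_c)) {
    r[is_c & code == res & name %in% .trigonal_c[[res]]] <- 1.76
  }
  r
}

.backbone_names <- c("N", "CA", "C", "O", "OXT",
                     "H", "H1", "H2", "H3", "HA", "HA2", "HA3")

# Side-chain atoms over which a residue's formal charge (pH 7.4) is shared.
.charge_groups <- list(
  ARG = list(q = +1, atoms = c("NH1", "NH2")),
  LYS = list(q = +1, atoms = "NZ"),
  ASP = list(q = -1, atoms = c("OD1", "OD2")),
  GLU = list(q = -1, atoms = c("OE1", "OE2")),
  HIS = list(q = NA, atoms = c("ND1", "NE2")),  # fractional, from pH and pKa
  CDR = list(q = +1, atoms = c("NH1", "NH2"))
)

element_from_name <- function(name) {
  stripped <- gsub("[0-9']", "", toupper(name))
  ifelse(nchar(stripped) > 0, substr(stripped, 1, 1), "C")
}

#' Fraction of histidine protonated at a given pH
#'
#' Henderson-Hasselbalch mole fraction of the imidazolium form,
#' `1 / (1 + 10^(ph - pka))`. With the defaults (pH 7.4, pKa 6.50) this is
#' 0.112, i.e. an 11.2%/88.8% protonated/neutral mixture.
#'
#' @param ph solution pH (default 7.4).
#' @param pka side-chain pKa (default 6.50).
#' @return fraction in (0, 1).
#' @export
his_protonated_fraction <- function(ph = 7.4, pka = 6.5) {
  1 / (1 + 10^(ph - pka))
}

#' Construct a peptide object from an atom table
#'
#' Assigns united-atom van der Waals radii, side-chain membership (backbone N, CA,
#' C, O, OXT and backbone hydrogens excluded), per-atom formal charge shares at
#' pH 7.4 (Arg/Lys/Cdr +1, Asp/Glu -1, His fractional per Henderson-
#' Hasselbalch), and hydrogen-bond-donor flags (side-chain atoms carrying a
#' positive charge share).
#'
#' @param atoms data.frame with columns `name`, `resno` (1-based residue
#'   index), `code` (3-letter residue code), `x`, `y`, `z` and optionally
#'   `element`.
#' @param label peptide label.
#' @param cyclic logical; head-to-tail cyclic backbone.
#' @param ph,his_pka protonation model for histidine.
#' @param termini_charged charge the free termini of linear peptides.
#' @return an object of class `peptide`: list with `label`, `atoms` (with
#'   `vdw`, `is_sidechain`, `charge_share`, `is_hbd` columns), `residues`
#'   (index, code, formal_charge, loop_id), `cyclic`, `disulfides`, `center`.
#' @export
new_peptide <- function(atoms, label = "peptide", cyclic = FALSE,
                        ph = 7.4, his_pka = 6.5, termini_charged = FALSE) {
  stopifnot(is.data.frame(atoms),
            all(c("name", "resno", "code", "x", "y", "z") %in% names(atoms)))
  if (nrow(atoms) == 0L) stop("empty structure: no atoms", call. = FALSE)
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates", call. = FALSE)
  atoms$name <- toupper(trimws(atoms$name))
  atoms$code <- toupper(trimws(atoms$code))
  if (is.null(atoms$element) || all(is.na(atoms$element)) ||
      all(atoms$element == "")) {
    atoms$element <- element_from_name(atoms$name)
  }
  atoms$element <- toupper(trimws(atoms$element))
  atoms$vdw <- assign_vdw(atoms$name, atoms$code, atoms$element)
  atoms$is_sidechain <- !(atoms$name %in% .backbone_names)

  # residue table, in order of first appearance
  uidx <- !duplicated(atoms$resno)
  residues <- data.frame(index = atoms$resno[uidx], code = atoms$code[uidx],
                         stringsAsFactors = FALSE)
  residues <- residues[order(residues$index), , drop = FALSE]
  rownames(residues) <- NULL
  fq <- numeric(nrow(residues))
  for (i in seq_len(nrow(residues))) {
    g <- .charge_groups[[residues$code[i]]]
    if (!is.null(g)) {
      fq[i] <- if (residues$code[i] == "HIS")
        his_protonated_fraction(ph, his_pka) else g$q
    }
  }
  residues$formal_charge <- fq
  residues$loop_id <- NA_integer_

  # distribute each residue's formal charge over its charged-group atoms,
  # falling back to all side-chain heavy atoms, then to CA
  atoms$charge_share <- 0
  for (i in seq_len(nrow(residues))) {
    if (fq[i] == 0) next
    sel <- atoms$resno == residues$index[i]
    grp <- .charge_groups[[residues$code[i]]]$atoms
    tgt <- sel & atoms$name %in% grp
    if (!any(tgt)) tgt <- sel & atoms$is_sidechain & atoms$element != "H"
    if (!any(tgt)) tgt <- sel & atoms$name == "CA"
    if (any(tgt)) atoms$charge_share[tgt] <- fq[i] / sum(tgt)
  }
  if (termini_charged && !cyclic) {
    nt <- which(atoms$resno == residues$index[1] & atoms$name == "N")
    ct <- which(atoms$resno == residues$index[nrow(residues)] &
                  atoms$name %in% c("OXT", "O"))
    if (length(nt)) atoms$charge_share[nt[1]] <- atoms$charge_share[nt[1]] + 1
    if (length(ct)) atoms$charge_share[ct[1]] <- atoms$charge_share[ct[1]] - 1
  }
  atoms$is_hbd <- atoms$is_sidechain & atoms$charge_share > 0

  heavy <- atoms$element != "H"
  center <- colMeans(as.matrix(atoms[heavy, c("x", "y", "z")]))

  pep <- structure(list(label = label, atoms = atoms, residues = residues,
                        cyclic = cyclic, disulfides = find_disulfides(atoms),
                        center = center),
                   class = "peptide")
  pep
}

find_disulfides <- function(atoms, cutoff = 2.5) {
  sg <- atoms[atoms$name == "SG", , drop = FALSE]
  out <- NULL
  if (nrow(sg) >= 2) {
    for (i in seq_len(nrow(sg) - 1)) {
      for (j in (i + 1):nrow(sg)) {
        d <- vnorm(c(sg$x[i] - sg$x[j], sg$y[i] - sg$y[j], sg$z[i] - sg$z[j]))
        if (d < cutoff) out <- rbind(out, c(sg$resno[i], sg$resno[j]))
      }
    }
  }
  if (is.null(out)) out <- matrix(integer(0), ncol = 2)
  colnames(out) <- c("res_i", "res_j")
  out
}

#' @export
print.peptide <- function(x, ...) {
  cat(sprintf("<peptide> %s: %d residues, %d atoms, %s, %d disulfide(s)\n",
              x$label, nrow(x$residues), nrow(x$atoms),
              if (x$cyclic) "cyclic" else "linear", nrow(x$disulfides)))
  invisible(x)
}

coords <- function(pep, sel = TRUE) {
  as.matrix(pep$atoms[sel, c("x", "y", "z"), drop = FALSE])
}

#' Read a peptide from a PDB file
#'
#' Parses a single-model PDB file (ATOM and HETATM records) into a [new_peptide()]
#' object. Residues are renumbered 1..n in file order; cyclicity is
#' auto-detected from the N-terminal N to C-terminal C distance unless given.
#'
#' @param path PDB file path.
#' @param label peptide label (default: file name).
#' @param cyclic logical or NA (auto-detect: backbone closure < 2 Angstrom).
#' @param ... passed to [new_peptide()].
#' @return a `peptide` object.
#' @export
read_pdb <- function(path, label = NULL, cyclic = NA, ...) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path, call. = FALSE)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
                  error = function(e) stop("PDB parse error: ",
                                           conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) stop("empty structure: no atoms",
                                          call. = FALSE)
  # renumber residues 1..n in order of appearance
  key <- paste(at$chain, at$resno, at$insert)
  idx <- cumsum(!duplicated(key))
  atoms <- data.frame(name = at$elety, resno = idx, code = at$resid,
                      x = at$x, y = at$y, z = at$z,
                      element = if (!is.null(at$elesy)) at$elesy else NA,
                      stringsAsFactors = FALSE)
  if (all(is.na(atoms$element)) || all(trimws(atoms$element) == ""))
    atoms$element <- NULL
  if (is.null(label)) label <- sub("\\.pdb$", "", basename(path))
  if (is.na(cyclic)) {
    n1 <- atoms[atoms$resno == 1 & atoms$name == "N", c("x", "y", "z")]
    cl <- atoms[atoms$resno == max(atoms$resno) & atoms$name == "C",
                c("x", "y", "z")]
    cyclic <- nrow(n1) == 1 && nrow(cl) == 1 &&
      vnorm(as.numeric(n1) - as.numeric(cl)) < 2.0
  }
  new_peptide(atoms, label = label, cyclic = cyclic, ...)
}

#' Write a peptide to a PDB file
#'
#' @param pep a `peptide` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(pep, path) {
  a <- pep$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = a$code,
                   eleno = seq_len(nrow(a)), elety = a$name,
                   elesy = a$element, chain = "A")
  invisible(path)
}

#' Annotate inter-cysteine loops
#'
#' Cyclotide loop numbering: loop k comprises the residues strictly between
#' Cys k and Cys k+1; loop 6 wraps across the ligation point for cyclic
#' peptides (or is split over both chain termini for linear ones). Cysteines
#' carry no loop id. For cyclic peptides the sequence has no intrinsic start,
#' so the Cys-anchored rotation with the lexicographically smallest residue
#' code sequence is taken as canonical; the assignment is therefore invariant
#' to cyclic rotation of the input order.
#'
#' @param pep a `peptide` with exactly 6 cysteines.
#' @return `pep` with `residues$loop_id` filled in.
#' @export
assign_loops <- function(pep) {
  codes <- pep$residues$code
  n <- length(codes)
  cys <- which(codes == "CYS")
  if (length(cys) != 6)
    stop(sprintf("loop annotation requires exactly 6 Cys residues (found %d)",
                 length(cys)), call. = FALSE)
  loop_id <- rep(NA_integer_, n)
  if (pep$cyclic) {
    # canonical rotation: start at the Cys giving the smallest code sequence
    keys <- vapply(cys, function(s) {
      paste(codes[((s - 1 + 0:(n - 1)) %% n) + 1], collapse = "|")
    }, character(1))
    anchor <- cys[order(keys, method = "radix")[1]]
    rot <- ((anchor - 1 + 0:(n - 1)) %% n) + 1
    rcodes <- codes[rot]
    rcys <- which(rcodes == "CYS")    # rcys[1] == 1
    for (k in 1:6) {
      from <- rcys[k]
      to <- if (k < 6) rcys[k + 1] else n + 1  # wrap: up to end of rotation
      if (to - from > 1) loop_id[rot[(from + 1):(to - 1)]] <- k
    }
  } else {
    for (k in 1:5) {
      if (cys[k + 1] - cys[k] > 1) loop_id[(cys[k] + 1):(cys[k + 1] - 1)] <- k
    }
    if (cys[6] < n) loop_id[(cys[6] + 1):n] <- 6L   # open loop 6, C-terminal
    if (cys[1] > 1) loop_id[1:(cys[1] - 1)] <- 6L   # and N-terminal part
  }
  pep$residues$loop_id <- loop_id
  pep
}

#' C-alpha root-mean-square deviation
#'
#' @param a,b `peptide` objects with equal residue counts and CA atoms.
#' @param superpose apply optimal least-squares rigid superposition first.
#' @return RMSD in Angstrom.
#' @export
rmsd_ca <- function(a, b, superpose = FALSE) {
  ca_xyz <- function(p) {
    ca <- p$atoms[p$atoms$name == "CA", , drop = FALSE]
    ca <- ca[order(ca$resno), , drop = FALSE]
    if (nrow(ca) != nrow(p$residues))
      stop("CA atom missing in some residue of ", p$label, call. = FALSE)
    as.matrix(ca[, c("x", "y", "z")])
  }
  xa <- ca_xyz(a); xb <- ca_xyz(b)
  if (nrow(xa) != nrow(xb))
    stop("residue count mismatch: ", nrow(xa), " vs ", nrow(xb), call. = FALSE)
  if (superpose) xa <- kabsch(xa, xb)$xyz
  sqrt(mean(rowSums((xa - xb)^2)))
}

#' Translate a peptide rigidly
#' @param pep a `peptide`.
#' @param t length-3 translation (Angstrom).
#' @return the translated `peptide`.
#' @export
translate_peptide <- function(pep, t) {
  pep$atoms$x <- pep$atoms$x + t[1]
  pep$atoms$y <- pep$atoms$y + t[2]
  pep$atoms$z <- pep$atoms$z + t[3]
  pep$center <- pep$center + t
  pep
}

#' Rotate a peptide rigidly about the origin
#' @param pep a `peptide`.
#' @param R 3 x 3 rotation matrix.
#' @return the rotated `peptide`.
#' @export
rotate_peptide <- function(pep, R) {
  xyz <- coords(pep) %*% t(R)
  pep$atoms$x <- xyz[, 1]; pep$atoms$y <- xyz[, 2]; pep$atoms$z <- xyz[, 3]
  pep$center <- as.numeric(pep$center %*% t(R))
  pep
}
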