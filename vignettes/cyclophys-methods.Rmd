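---
title: "Methods and numerical conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and numerical conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(cyclophys)
```

This vignette records the modeling assumptions, parameter choices and
numerical conventions behind the package, plus the design of the synthetic
generators used to validate it. It is the reference for anyone asking "why
this number?" about any constant in the code.

## The lipophilicity scale

The packaged scale stores, per residue type, a raw side-chain logP value,
its affine rescaling, a glycine-anchored `normalized` value, and the
maximal side-chain solvent accessibility `sasa_max`.

- **Affine map.** `scaled = (raw + 3.800) / 6.457`. The offset is the raw
  value of protonated arginine (the most lipophobic side chain, mapped to 0)
  and the divisor is the raw span up to isoleucine (mapped to 1). The map is
  order- and difference-preserving: differences of `normalized` values equal
  raw differences divided by 6.457.
- **Glycine anchor.** `normalized = scaled − scaled(Gly)` with
  `scaled(Gly) = 0.62` by default, so glycine — no side chain — carries
  exactly zero lipophilicity and the sign of `normalized` separates
  lipophilic (positive) from lipophobic (negative) residues.
- **Histidine.** At pH 7.4 with pKa 6.50, the imidazolium fraction is
  `1 / (1 + 10^(pH − pKa)) ≈ 0.112`. `his_effective_logp()` forms the
  convex combination of the charged and neutral raw values with these
  weights before rescaling. The same fraction is used as histidine's formal
  charge in the electrostatics.
- **Half-cystine.** Cyclotide cysteines are in disulfides;
  `cys_from_cystine()` assigns each half-cystine half of cystine's raw
  lipophilicity.
- **Modified residues.** Four non-standard codes are included for modified
  peptides: `ACK` (N6-acetyl-lysine), `CDR` (cyclohexanedione-modified
  arginine, kept at formal charge +1), `KYW` (kynurenine, from tryptophan
  oxidation) and `MEE` (glutamate γ-methyl ester).
- **`sasa_max`.** The reference exposure is the side-chain solvent
  accessibility of residue X in an extended Gly-X-Gly tripeptide
  (φ = ψ = 180°, trans peptide bonds), built from ideal bond lengths,
  angles and standard side-chain rotamers by `build_extended_tripeptide()`
  and measured with the package's own surface engine
  (`max_sidechain_sasa()`). The packaged table stores these values; users
  supplying their own radii should regenerate the column so exposures stay
  in [0, 1].

The scale is a plain data frame and round-trips through
`write_lipo_scale()` / `read_lipo_scale()` (TSV), so user-defined residues
can be added without touching package code.

## Surface model

- **Radii.** United-atom van der Waals radii: aliphatic carbon 1.87 Å;
  trigonal, aromatic and carbonyl carbon 1.76 Å; nitrogen 1.65 Å; oxygen
  1.40 Å; sulfur 1.85 Å; explicit hydrogen 1.00 Å; anything unrecognized
  1.80 Å with no failure. United radii absorb the implicit hydrogens of
  typical experimental structures.
- **Quadrature.** `shrake_rupley()` places a deterministic golden-spiral
  lattice of `n_points` points (default 960, minimum 16) on each expanded
  sphere of radius `vdw + probe` (probe 1.4 Å, a water molecule). A point
  is exposed if it lies outside every other atom's expanded sphere; each
  exposed point carries the weight `4π(vdw + probe)² / n_points`. At 960
  points, single- and two-sphere configurations agree with the analytic
  spherical-cap areas to within 1–2%.
- **Canonical frame.** Before sampling, coordinates are rotated into a
  canonical principal-axes frame (eigenvectors of the coordinate
  covariance, signs fixed by coordinate skewness with a maximum-loading
  fallback, right-handedness enforced). The lattice is deterministic in
  that frame, so every surface quantity — and every descriptor built on it
  — is invariant under rigid motion of the input to ~1e-6 relative or
  better. Samples are mapped back and reported in the input frame, each
  tagged with its owner atom and residue.
- **A consequence worth knowing.** Because adding or moving an atom changes
  the canonical frame, per-atom areas of *other* atoms can shift by a few
  lattice-point weights even when the change can only occlude. This is
  quadrature jitter, bounded by the point weight, not a model effect.

## Electrostatics and charged-donor surface

- **Formal charges.** Arg +1 (shared over NH1/NH2), Lys +1 (NZ), Asp −1
  (OD1/OD2), Glu −1 (OE1/OE2), His +0.112 (see above), CDR +1. Charge is
  shared equally over the named group atoms; if they are absent the charge
  falls back to the side-chain heavy atoms, then to CA, so incomplete
  structures degrade gracefully.
- **Potential.** At each surface sample, `Σ q_i / (4 r_i²)` — a Coulomb
  potential with the distance-dependent dielectric ε(r) = 4r, a standard
  implicit-solvent screening choice. Distances below 0.1 Å are clamped to
  0.1 Å with a warning rather than producing infinities.
- **HBD classification.** A sample is a positively charged hydrogen-bond
  donor sample if its owner atom is a side-chain atom carrying positive
  charge share and the potential at the sample is strictly positive (so a
  lysine ringed by carboxylates loses its donor surface). `E_S` is the sum
  of the areas of these samples. `E_M` is the distance between the
  area-weighted centroid of the HBD samples and the area-weighted centroid
  of the hydrophobic surface — samples owned by residues with positive
  `normalized` lipophilicity and zero formal charge. Under a uniform
  spatial scaling (coordinates, radii and probe together), `E_S` scales as
  length² and `E_M` as length, which the tests verify directly.

## Descriptors

Per residue: `exposure = min(1, sasa_sidechain / sasa_max)`,
`intensity = normalized × exposure`, and a unit direction from the peptide
center to the side-chain heavy-atom centroid (glycine has no direction and
zero intensity).

- `L_S` = Σ intensity (signed).
- `L_M` = ‖Σ intensity · u‖ / n_residues, the mean lipophilic resultant.
- `L_S*` = Σ of intensities over residues with positive intensity *and*
  positive projection on the resultant direction. If the resultant vanishes
  (a perfectly balanced structure) there is no preferred side; the sum over
  all positive intensities is returned with a `degenerate` attribute set,
  so callers can detect the fallback.
- The loop profile distributes `L_S` over the six inter-cysteine loops of
  the cyclotide framework; cysteines themselves belong to no loop. For
  cyclic sequences the loop labeling is made rotation-invariant by
  canonicalizing to the cysteine-anchored rotation with the
  lexicographically smallest code sequence (byte-order comparison, locale
  independent).

## QSAR

Activities enter as relative potencies `x = IC50_ref / IC50` against the
reference peptide; a censored measurement (`IC50 > limit`, no activity
observed) gets `x = 0` exactly. Two monotone response transforms are
available: `y = log10(x + 1)` (λ = 1) and `y = (x + 1)^(−1/2)` (λ = −1/2);
both are finite at `x = 0`, which is why censored records can stay in the
fit. Activity classes from the ratio `IC50 / IC50_ref`: `< 0.2` → A2
(more potent than reference), `≤ 1.0` → A1, `> 1.0` → A0, missing → An.

The model is `y = k + l·τ·L_S* + m·τ·E_S` with the 0/1 gate
`τ = 0` iff `L_M < L_M_c` **and** `E_M < E_M_c` (both strictly below;
equality on either coordinate keeps the record active). Fitting is
ordinary least squares via the QR decomposition; leverages come from the
thin Q factor, giving the exact leave-one-out `q² = 1 − PRESS/TSS` without
refitting; `F = (SSR/2) / (SSE/(n−3))` is compared against
`qf(0.95, 2, n−3)`. The critical point is found on a fixed 17 × 17 grid
from (0, 0) to (0.050, 9.000) — steps 0.003125 in `L_M_c`, 0.5625 in
`E_M_c` — maximizing q², breaking ties by r² and then by lowest node
index, so the search is fully deterministic. Grid nodes where the gated
design matrix is singular are skipped with a warning rather than aborting
the search. `refit_excluding()` supports leave-out refits for outlier
diagnosis and flags excluded records in the returned model.

## Clustering and template selection

Descriptors are min-max normalized per column (constant columns map to 0
with a warning; missing values are an error naming the offending rows).
`ward_cluster()` is a reciprocal-nearest-neighbor implementation of Ward
linkage with cluster-size/centroid state and merge cost
`sqrt(2 n_a n_b / (n_a + n_b)) · ‖c_a − c_b‖` — numerically identical to
`hclust(..., "ward.D2")` heights and, independently, to the classical
Lance–Williams recurrence on squared distances, which the tests use as an
oracle. Trees export to Newick (round-tripping through `ape`), and
`leaf_labels()` composes the `G<group>-<class>-<label>` display names.

Template selection walks a bootstrap-annotated Newick tree: if the
target's sister is a single known leaf, take it alone when its split
support exceeds 50, otherwise pair it with the nearest other known leaf
(path length; alphabetical tie-break; support exactly 50 counts as "not
above"). A two-leaf sister clade of known structures is taken whole. A
larger sister clade with several known leaves yields a seeded random pair,
drawn with the caller's RNG state saved and restored so library calls
never perturb user reproducibility. With no usable sister information the
nearest known leaf overall is the fallback. The applied rule is attached
to the result as an attribute.

## Synthetic generators

**Toy peptides** (`make_toy_peptide`) place pseudo-residues (LEU
lipophilic, LYS charged, ASN neutral filler) on a sphere: CA at radius
`r`, a single side-chain pseudo-atom at `r + 3` along the same radial
direction, so directions and exposures are controlled exactly. With
`segregation = 1` lipophilic residues are reflected into the +z hemisphere
and charged ones into −z, producing large `L_M` and `E_M`; with
`segregation = 0` positions are left where sampled, so moments stay near
the √n noise floor. This two-population contrast is what the clustering
validation exploits: segregated and scrambled populations differ in
exactly the two moment descriptors and should split cleanly under a
two-group cut.

**QSAR datasets** (`make_qsar_dataset`) draw `L_M ~ U(0.001, 0.05)` and
`E_M ~ U(0.1, 9.0)` (spanning the search grid), plant a breakpoint at a
specified interior grid node (default (0.0375, 4.5)), compute τ from it,
draw `L_S*` and `E_S`, and emit `y = k + l·τ·L_S* + m·τ·E_S + ε` with
Gaussian noise. The planted node is only identifiable if the sample
constrains it on all four sides: `ensure_identifiable = TRUE` (default)
rejection-samples until each of the four one-grid-step strips adjacent to
the breakpoint — just below/above in each coordinate, on the gating side
of the other — contains at least one record. Without this, neighboring
nodes gate identical record subsets and the argmax is a coin flip; with
it, recovery is reliable at n = 60 and noise σ = 0.02 while leaving the
generator's distribution otherwise untouched.

**Packaged activities.** `inst/extdata/cyclotide_activity.tsv` compiles 75
published IC50 records (anthelmintic and cytotoxic assays; labels `M*`,
`B*`, `H*`, `L*` by subfamily) in long form, including the censoring
limits (> 11.5 and > 30 µM), read by `cyclotide_activities()`.

## Problem sizes and cost

Designed scales: peptides of tens of residues (hundreds of atoms), datasets
of tens to low hundreds of records, trees of up to a few hundred leaves.
On one CPU core, a full descriptor evaluation of a 24-residue toy peptide
takes ~0.1 s at 960 points/atom; the 17 × 17 grid search on 60 records
runs in about a second; Ward clustering is O(n²) in memory and fine to a
few thousand rows. Surface cost is O(n_atoms² · n_points) — for much
larger proteins a neighbor grid would be the first optimization, but at
cyclotide scale it is unnecessary.

## Limitations

- The surface engine has no cavity detection: interior voids count as
  exposed if lattice points fall in them (not an issue at cyclotide size).
- Electrostatics are screened-Coulomb point charges, not Poisson–Boltzmann;
  the pH enters only through histidine's protonation fraction.
- The extended tripeptide uses idealized internal coordinates and a single
  standard rotamer per residue, which is a convention for the *reference*
  exposure, not a claim about conformational preference.
- The QSAR is deliberately small (two gated regressors); it is a
  structure–activity screen, not a potency predictor, and `q²` is
  leave-one-out, not external validation.
- Template selection trusts the input tree and its support values; it does
  not re-estimate either.
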