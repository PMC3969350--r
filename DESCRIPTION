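Package: cyclophys
Title: Physicochemical Surface Descriptors and QSAR for Cyclic Knotted Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes surface-exposure-weighted lipophilic and electrostatic
    descriptors for cyclic cystine-knot peptides (cyclotides) from 3D structures:
    total and exclusive lipophilicity (L_S, L_S*), the lipophilic moment (L_M),
    the hydrogen-bond-donor surface area (E_S) and the HBD amphipathic moment
    (E_M). Ships a normalized side-chain lipophilicity scale anchored on glycine,
    a Shrake-Rupley solvent-accessible surface engine with per-point samples, an
    extended Gly-X-Gly tripeptide builder for maximal side-chain exposure,
    cysteine-derived loop annotation, a dummy-variable QSAR with critical-point
    grid search and leave-one-out validation, Ward reciprocal-nearest-neighbor
    clustering of descriptor space, activity classification relative to kalata B1,
    and bootstrap-tree template selection for homology modeling. Includes seeded
    synthetic generators (toy peptides on a sphere, planted-breakpoint QSAR
    datasets) and a packaged compilation of published cyclotide IC50 values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
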