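Package: igproto
Title: Pseudosymmetry Analysis of Immunoglobulin Folds and Protodomains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to analyze the internal (tertiary) C2 pseudosymmetry of
    immunoglobulin (Ig) and Ig-like beta-sandwich domains. The package
    annotates beta-strands and sheets from coordinates, assigns the canonical
    Ig strand labels (A/A', B, C, C', C'', D, E, F, G), decomposes a domain
    into its two protodomains (AB-CC' and DE-FG), superposes them by a
    least-squares rigid fit and extracts the C2 symmetry axis, classifies the
    domain topology (V-set, C1-set, C2-set, I-set, FN3, cadherin), detects the
    interdigitated double Ig fold of CD19-like chains including its inverse Ig
    composite domain, analyzes quaternary Ig-Ig dimer interfaces (sheet
    attribution, parallel/inverted/tilted orientation, quasi-D2 geometry,
    protodomain swaps), and computes typed residue-interaction networks at
    protodomain cores and dimer interfaces. A synthetic generator of idealized
    beta-sandwich coordinates with ground-truth labels makes the whole
    pipeline testable without structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    seqinr,
    yaml
Config/testthat/edition: 3
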