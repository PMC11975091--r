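Package: ringmorph
Title: Layer-Specific Residual Deformation Morphometry of Arterial Rings
Version: 0.1.0
Authors@R: person("ringmorph", "developers", role = c("aut", "cre"),
    email = "ringmorph@example.org")
Description: Quantifies residual deformations of radially cut arterial ring
    specimens and their separated layers (media-intima and adventitia) from
    traced boundary point sets. Fits parametric B-splines to inner and outer
    boundaries, resamples them at equidistant arc-length positions, and
    derives local curvature, boundary length and the signed opening angle.
    Specimen-level morphometry (layer thickness, adventitia percentage,
    circumferential boundary strains and their membrane/bending
    decomposition) feeds a normality-gated statistical pipeline
    (Anderson-Darling gate, t / Mann-Whitney / Wilcoxon paths, Spearman
    correlation, protocol merging). A synthetic annular-sector generator with
    closed-form ground truth makes every stage verifiable without raw
    photographs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    splines,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
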