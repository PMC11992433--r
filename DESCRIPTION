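Package: triplehelix
Title: Collagen Triple-Helix Variant Annotation and Trajectory Geometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the structural-computational analysis of in-frame
    duplications in fibrillar collagen chains such as the collagen
    alpha-1(III) chain. Parses HGVS-style cDNA duplication descriptors,
    projects them onto protein coordinates, checks conservation of the
    Gly-Xaa-Yaa triple-helix registry, scans for the collagenase (MMP-1)
    cleavage-site motif and measures variant-to-cleavage-site distances.
    Builds idealized collagen triple-helix models for wild-type and mutant
    chain windows, enumerates all eight trimer register combinations, and
    computes trajectory-geometry statistics on coordinate ensembles:
    end-to-end distance, curvature via SVD plane projection and
    least-squares circle fitting, flexibility, RMSD/RMSF, hydrogen-bond
    and contact counts, Daura conformational clustering, and block-shifted
    standard errors. A synthetic-ensemble generator with analytic ground
    truth makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    minpack.lm,
    seqinr,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    Biostrings
Config/testthat/edition: 3
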