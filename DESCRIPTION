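Package: mtocscreen
Title: Candidate-Gene Screening and Image Quantification for Nuclear-Envelope
    MTOC Formation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to prioritize transcription-factor target genes that mediate
    nuclear-envelope microtubule-organizing center (NE-MTOC) formation in
    differentiating muscle cells, and to quantify NE-MTOC phenotypes in
    fluorescence micrographs. The screening arm assigns significant ChIP-seq
    peaks (narrowPeak) to gene promoters, intersects genes persistently bound
    across differentiation time points with genes upregulated in RNA-seq and in
    a developmental expression time course (area-under-profile permutation
    test), and applies a Gene Ontology cellular-component filter. The imaging
    arm segments nuclei, measures marker coverage inside a 1-micrometre band
    around each nuclear outline, quantifies centrosomal focus intensities in
    circular ROIs at local maxima, extracts radial intensity profiles
    perpendicular to nuclear outlines, and calls marker-positive nuclei against
    control-derived thresholds. Synthetic fixture generators with planted
    ground truth make every stage testable without external downloads, and a
    statistics layer reproduces the group comparisons used for such data
    (t with F-test gate, Kolmogorov-Smirnov, ANOVA with Bonferroni pairs,
    confidence intervals of group differences).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    jsonlite,
    yaml,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
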