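Package: carbodot
Title: Carbon-Dot Nucleic-Acid Structure Building and Trajectory Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds atomistic models of layered graphitic carbon dots
    (coronene/circumcoronene flakes, stacking, charged edge
    functionalization), generates idealized nucleic-acid structures
    (B-DNA and A-RNA duplexes, nucleosomal superhelix DNA, mock
    G-quadruplex tetrads) and synthetic trajectories with planted
    carbon-dot binding poses, and analyzes carbon-dot/nucleic-acid
    complexes: base-pair and base-pair-step helical parameters, backbone
    dihedrals and sugar pucker, groove widths, Shrake-Rupley solvent
    accessible surface area and SASA-difference contact area, hydrogen
    bonds, radial distribution functions, pi-stacking detection,
    per-frame binding-mode classification, carbon-dot layer shape
    descriptors, nucleosome gyre distances, per-residue RMSF and
    event-aligned RMSD.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
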