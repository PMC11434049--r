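Package: alveodyn
Title: Alveolar Micro-Dynamics Morphometry from Paired Respiratory-State Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Three-dimensional morphometry of pulmonary gas-exchange units
    (alveoli and alveolar ducts) imaged at paired respiratory states.
    Generates synthetic two-state alveolar phantoms with closed-form ground
    truth, segments grayscale volumes into instance-labeled lumina, extracts
    closed triangle meshes and per-structure measures (volume, surface area,
    equivalent diameter, thinnest septal wall, entrance-ring perimeter,
    inter-alveolar angle), derives tidal-cycle dynamics (the dimensionless
    shape factor k = S/V^(2/3), the shape-change statistic q = k_insp/k_exp,
    area and linear strains, angle changes), and reproduces the associated
    one-sample, Welch and one-way ANOVA inference with five-number and
    mean +/- SEM summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tiff,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
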