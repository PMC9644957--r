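Package: craniofea
Title: Comparative Cranial Finite-Element Feeding Biomechanics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative feeding biomechanics of longirostrine marine-reptile
    crania: dry-skull estimation of jaw adductor muscle forces from
    reconstructed muscle dimensions, construction of finite-element load cases
    for bilateral biting at several tooth-row positions, a linear-elastic
    tetrahedral finite-element solver producing von Mises stress fields,
    two-dimensional jaw lever mechanics (mechanical advantage and bite force
    along the tooth row), and robust-versus-gracile morphotype stress
    contrasts. Skull geometry is generated parametrically as tetrahedral
    solids with named attachment, constraint and bite-point node sets, so the
    full pipeline runs without CT-derived meshes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
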