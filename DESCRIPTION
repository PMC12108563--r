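Package: tmjfem
Title: Patient-Specific Finite-Element Workflow for Temporomandibular Joint Prostheses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An image-based finite-element pipeline for custom
    temporomandibular-joint (TMJ) prostheses: CT calibration against water and
    air references, mask segmentation with morphological cleanup,
    Hounsfield-unit to density to Young's-modulus power-law material mapping,
    quadratic ten-node tetrahedral (C3D10) mesh generation from label volumes,
    linear-elastic solves under muscle and bite loading with bonded multi-point
    constraints and Coulomb penalty contact, normalized von Mises stress
    comparison across model variants, surface-deviation mapping between CAD and
    segmented implant surfaces, and ISO-14243-style gravimetric wear-rate
    regression. A seeded synthetic CT phantom generator makes every stage
    testable without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
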