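Package: willisflow
Title: Lumped-Parameter Hemodynamics of the Circle of Willis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reduced-order (lumped-parameter) simulator of steady blood
    flow in the circle of Willis. Arterial segments are cylindrical
    Poiseuille resistors with Carreau shear-thinning viscosity; inlet and
    outlet pressures follow the cerebral-perfusion-pressure derivation from
    vital signs, intracranial pressure and lumped cerebrovascular
    resistance. The package applies NASCET-graded stenosis to the internal
    carotid artery, removes communicating or proximal segments to emulate
    common anatomical variants, calibrates distal resistances to a target
    cerebral blood flow and efferent split, and sweeps variant-by-stenosis
    grids to report total flows, percentage changes, communicating-artery
    cross-flows and flow-reversal turning points.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    igraph,
    generics,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
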