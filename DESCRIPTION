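Package: gmphoto
Title: Mesophyll Conductance in Leaf and Canopy Gas Exchange Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Explicit mesophyll conductance (gm) for C3 and C4 photosynthesis
    modeling. Implements a multiplicative empirical gm model (canopy depth,
    temperature, soil moisture, intercellular CO2 and light responses), couples
    it to Farquhar C3 and von Caemmerer-Furbank C4 biochemistry and Medlyn
    stomatal conductance, and provides the apparent-to-true (Ci-based to
    Cc-based) adjustment of Vcmax25, Jmax25 and Vpmax25 required when gm is
    made explicit. Includes sun/shade canopy scaling, a synthetic diurnal
    forcing generator, paired ambient/elevated-CO2 sensitivity experiments,
    and tools to standardize and aggregate literature gm measurements to
    plant-functional-type parameters.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    stats,
    utils
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
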