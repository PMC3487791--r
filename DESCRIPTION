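Package: volresp
Title: Volumetric Tumor Response Criteria for Imatinib-Treated GIST Liver Metastases
Version: 0.1.0
Authors@R:
    person("volresp", "maintainers", email = "volresp@example.org", role = c("aut", "cre"))
Description: Tools to classify tumor response of GIST liver metastases under
    four criteria (RECIST 1.1, 3D-sphere, 3D-ellipsoid, Choi), compare 1D and
    3D detection of size changes, test paired cross-classifications for table
    symmetry with an exact conditional-binomial test, and run landmark
    Kaplan-Meier survival analyses with Mantel-Haenszel hazard ratios. Includes
    a synthetic-cohort generator with prolate-spheroid lesion geometry,
    anisotropic treatment response, density decline and response-linked
    survival, plus packaged published cross-classification counts for
    end-to-end reproduction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
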