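Package: resinate
Title: Solid-State NMR and Electronic-Tongue Analytics for Drug-Resin Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to characterize drug/ion-exchange-resin complexes
    (resinates) from 13C CPMAS solid-state NMR and impedimetric
    electronic-tongue data. Implements the variable-contact-time
    cross-polarization dynamics model S(tc) = S0 (1 - exp(-tc/TCH))
    exp(-tc/T1rhoH), nonlinear least-squares extraction of TCH and T1rhoH
    per carbon with uncertainties, chemical-shift change and splitting
    analysis, and a proton spin-diffusion criterion that distinguishes a
    true complex from a physical mixture. Also provides impedance
    feature extraction, 2-D projection (force scheme and classical MDS),
    hierarchical clustering, silhouette scoring, and single-exponential
    dissolution-release fitting, together with seedable synthetic-data
    generators for spectral series, sensor arrays and release curves.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
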