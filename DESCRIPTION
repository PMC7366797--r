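Package: doseresp
Title: Personal Dosemeter Response and Reading-to-Air-Kerma Conversion Factors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computation chain for personal-dosemeter response experiments on
    an anthropomorphic phantom: reference air kerma and calibration factors
    from slab-phantom exposures, per-condition dosemeter response (mSv per mGy
    air kerma) with lognormal uncertainty factors, synthesis of the
    isotropic-geometry response from rotational exposures by solid-angle band
    weighting, working-environment conversion factors by nuclear-facility type
    (photon-energy-band and geometry mixing), conversion of legacy responses
    expressed per Hp(10), and a synthetic-data generator emulating the
    irradiation experiment for validation and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
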