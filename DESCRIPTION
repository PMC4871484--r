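Package: photocyclr
Title: Flash-Photolysis Global Analysis and Photocycle Kinetics for Microbial Rhodopsins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the kinetic and spectroscopic characterization of microbial
    rhodopsin photocycles from laser flash-photolysis data: simulation of transient
    absorbance trace sets from first-order kinetic schemes, logarithmic block
    reduction and merging of dual-oscilloscope time bases, global multi-exponential
    fitting by variable projection yielding lifetimes and decay-associated spectra,
    analytic population dynamics and photostationary proton-current models (including
    the kinetic invisibility of the M intermediate and its blue-light shunt),
    double Henderson-Hasselbalch pH-titration fitting, oxime-referenced extinction
    coefficients, and sequence-level spectral-tuning classification of
    proteorhodopsins.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
RoxygenNote: 7.3.3
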