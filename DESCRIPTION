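Package: aprepair
Title: Repairing Mutant Cardiac Action Potentials with Optimal Drug Combinations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for computing optimal combinations of existing ion-channel
    drugs that restore the action potential and calcium transient of mutant
    cardiomyocytes towards their wild-type waveforms. Implements a Hill-type
    (EC50/IC50) single-drug effect model and a multiplicative combination
    factor applied per ion current, a surrogate ventricular action-potential
    model with a channel-density/flux (rho*J) current split that separates
    maturation and species translation from mutation effects, the N588K
    (short QT syndrome type 1) gain-of-function modification of the rapid
    delayed rectifier potassium current, extraction of action-potential and
    calcium-transient biomarkers, a weighted biomarker cost function, and a
    deterministic incremental multi-drug dose optimizer with dose-cap modes.
    Ships a literature-derived drug library and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
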