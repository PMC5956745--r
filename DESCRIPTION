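Package: synaptiq
Title: Quantal Analysis of Synaptic Currents and Presynaptic Vesicle Morphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A measurement chain for cerebellar mossy fiber-granule cell
    synaptic transmission: threshold-crossing detection and screening of
    miniature and quantal excitatory postsynaptic currents (mEPSCs/qEPSCs),
    rise-time and biexponential decay kinetics with the amplitude-weighted
    time constant, peak-scaled non-stationary fluctuation analysis (ps-NSFA)
    of unitary current and channel count, slope and count-matched
    rectification indices of AMPA receptor currents, strontium-evoked
    asynchronous quantal counting with failure rates, short-term plasticity
    train analysis with paired-pulse ratios, and grid-based vesicle
    morphometry of electron-microscopy terminal annotations. Every analysis
    stage is paired with a synthetic-data generator with known ground truth
    (stochastic channel gating, rectifying current-voltage ramps,
    desynchronized quantal release, vesicle-depletion trains, and planar
    vesicle point patterns) for parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
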