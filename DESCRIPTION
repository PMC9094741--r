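Package: pwvagree
Title: Agreement Between Estimated and Transit-Time Measured Pulse Wave Velocity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for comparing device-estimated
    pulse wave velocity (an almost deterministic function of entered age and
    mean arterial pressure) with aortic pulse wave velocity measured from
    corrected pulse arrival times. Provides a calibrated synthetic cohort
    generator, a multichannel hemodynamic waveform synthesizer (ECG, Doppler
    envelope, thigh-cuff pulse), fiducial detectors (R-peak, aortic valve
    opening, intersecting-tangents pulse foot), the corrected pulse-arrival-time
    PWV computation, a triplicate estimation protocol with an entered-age
    experiment, and the agreement statistics: quadratic regression with
    standardized coefficients, Bland-Altman analysis, age-adjusted partial
    correlation, Lilliefors normality testing, and a closed-form
    variance-decomposition oracle for validating the simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nortest,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
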