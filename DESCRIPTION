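Package: cochleate
Title: Extremal-Function Wavelet Model of Cochlear Signal Processing
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A level-dependent analytic wavelet filterbank for the auditory
    periphery. The basilar-membrane transfer function is modelled by the
    extremal (coherent-state) functions of the uncertainty principle for the
    affine-times-circle group, translated along a tonotopic position-frequency
    map. The package computes the analytic wavelet transform of sound, checks
    the first-order structure equations that link temporal and place
    derivatives of log-amplitude and phase, represents solutions as a
    time-independent particular factor times a holomorphic function of
    z = t - a*beta + i*a*gamma, and generalises the whole construction to
    one-parameter invariance groups given by a vector field on the frequency
    axis. Includes synthetic signal generators (tones, amplitude modulation,
    harmonic complexes, clicks, band-limited noise), RIFF WAVE input/output
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
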