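Package: ciliabeat
Title: Waveform Analysis and Mechanochemical Modelling of Ciliary Beating
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the beating of isolated cilia and flagella from tracked
    filament coordinates. Tangent-angle time series are reduced to the complex
    fundamental Fourier mode (beat frequency, amplitude and phase profiles,
    Q-factor), projected onto a low-dimensional shape space of shifted-Legendre
    coefficients (mean amplitude, asymmetry, parabolicity, wavelength), and
    mapped onto a three-parameter mechanochemical model of dynein curvature
    control by solving the Machin boundary-value problem, including its
    analytic low-friction (dry) limit. A synthetic-data generator emulates
    hierarchically variable beating axonemes so the full pipeline is testable
    without microscopy recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
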