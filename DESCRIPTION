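Package: skullray
Title: Deterministic Ray-Tracing Simulation of Transcranial Photoacoustic Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation of photoacoustic signals recorded through the
    skull using deterministic acoustic ray tracing. Models power-law
    absorption with Kramers-Kronig dispersion, reflection, refraction and
    longitudinal-to-shear mode conversion at flat fluid-solid interfaces,
    N-shaped photoacoustic source pulses from spherical absorbers, a
    per-frequency impulse-response engine with short-time Fourier transform
    convolution, and metrics quantifying skull-induced signal distortion
    (attenuation, broadening, time shift, bandwidth narrowing).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
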