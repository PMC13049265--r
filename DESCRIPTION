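Package: spenr
Title: Spatiotemporal-Encoded MRI: Pulse Design, Bloch Simulation, and
    Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale toolkit for spatiotemporal-encoded (SPEN) magnetic
    resonance imaging. Designs frequency-swept (WURST) chirped-RF and sinc
    excitation pulses and compares their energy, peak power and RMS amplitude;
    verifies the encoded quadratic phase with a hard-pulse Bloch simulator;
    builds the SPEN forward operator and its k-space convolution (Fresnel)
    description; synthesizes signals from digital phantoms including
    off-resonance and echo-planar gradient-delay effects; reconstructs images
    by sample reordering, matched-filter (Fresnel) deconvolution or Tikhonov
    inversion; and assembles SPEN and Fourier spin-echo EPI event timelines
    with export to a text subset of the Pulseq sequence format.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    graphics,
    grDevices
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
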