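Package: helixpsd
Title: Surface-Periodicity Analysis of Helical Virions in Scanning-Probe Height Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects and interprets the helical surface lattice of rod-shaped
    virus particles (such as tobacco mosaic virus) in atomic force microscopy
    height maps. Provides a helical-lattice geometry model that predicts axial
    and near-axial repeat distances and their off-axis angles, a synthetic
    height-map generator (lying cylinder, per-subunit corrugation, substrate
    roughness, disk aggregates, scan-line noise and phase jitter) with probe
    broadening by greyscale dilation against a parametric tip, the
    line-averaged power spectral density of boxed scan lines with background
    comparison and signal-to-noise box optimization, spectral peak detection
    with harmonic assignment against the lattice building block, and
    correlation-length extraction from two-slope log-log spectral fits.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tiff,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
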