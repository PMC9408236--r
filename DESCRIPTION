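Package: pamendo
Title: Simulation and Analysis Toolkit for Multimode-Fibre Photoacoustic
    Endomicroscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale digital twin of a multimode-fibre optical-resolution
    photoacoustic endomicroscope. Simulates complex fibre transmission
    matrices and digital-micromirror-device (DMD) binary patterns, estimates
    the real-valued intensity transmission matrix (RVITM) from intensity-only
    Hadamard calibration measurements, selects binary focusing patterns,
    synthesises band-limited photoacoustic A-lines from digital absorption
    phantoms, assembles raster-scanned images and volumes with acoustic or
    optical sectioning, quantifies focusing and resolution (enhancement
    factor, power ratio, FWHM, ESF/LSF lateral resolution, axial resolution,
    fluence), and stitches translated frames into mosaics by subpixel
    upsampled-DFT registration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    pracma,
    minpack.lm,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
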