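Package: comsli
Title: Fiber Orientation Mapping from Computational Scattered Light Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis chain for computational scattered light imaging (ComSLI)
    of fibrous tissue: per-pixel azimuthal intensity profiles are searched for
    prominent antipodal peak pairs whose midpoints give in-plane fiber
    orientations, rendered as hue-coded fiber orientation maps. Companion
    polarized light imaging (PLI) fits recover retardance and fast-axis
    azimuth from four-polarizer-angle stacks. Landmark-based similarity
    registration and picrosirius-red collagen masking align histology stains,
    and peritumoral relative-orientation statistics contrast tangential versus
    radial collagen arrangements around a tumor boundary. A synthetic phantom
    generator renders scattering stacks, polarization stacks and stained-slide
    imagery from known-truth orientation fields so every stage is verifiable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    tiff,
    png,
    jsonlite,
    EBImage,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
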