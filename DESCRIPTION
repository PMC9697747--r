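Package: toothshade
Title: Hyperspectral Colorimetry of Dental Structures
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for tooth color measurement with line-scan
    hyperspectral cameras. Reads ENVI-format reflectance cubes, performs
    dark/gray flat-field correction to spectral reflectance, converts
    reflectance to CIELAB under the CIE 1931 2-degree observer and D65
    illuminant, segments the tooth crown into cervical, middle and incisal
    thirds, and computes CIELAB (Delta E*ab) and CIEDE2000 (Delta E00) color
    differences between contralateral teeth, adjacent teeth and thirds of a
    single tooth, judged against the dental perceptibility and acceptability
    thresholds. Includes a synthetic hyperspectral scene generator with known
    ground truth for end-to-end validation without camera hardware.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    tiff,
    png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
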