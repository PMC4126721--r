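Package: gjquant
Title: Automated Quantification of Gap-Junction Remodeling and
    Interstitial Collagen in Cardiac Histology Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for automated, operator-independent quantification of
    connexin-43 (Cx43) gap-junction abundance and distribution from
    Cx43/N-Cadherin double-immunostained confocal images, and of
    interstitial collagen from Masson's Trichrome stained bright-field
    images.  Implements per-image staining-threshold calibration by
    Otsu-style between-class scoring, classification of Cx43 signal into
    end-to-end (intercalated-disc associated) and side-by-side
    (lateralized) pools by disk dilation of N-Cadherin positive pixels
    with plateau analysis of the dilation-radius curve, N-Cadherin
    internal-reference normalization, layer-by-layer Z-stack
    quantification, and RGB channel-statistics thresholding of trichrome
    images.  Includes a synthetic image generator with exact ground truth
    for validation, batch processing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
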