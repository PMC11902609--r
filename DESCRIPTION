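Package: busseg
Title: Automated Detection and Segmentation of Breast Lesions in Ultrasound Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Two-stage automated segmentation of hypoechoic focal lesions in
    B-mode breast ultrasound frames. Stage one classifies normal tissues
    (skin, fat, glandular, fibrous, artifacts) with a random forest over
    multi-scale Hessian-eigenvalue and local-binary-pattern pixel features;
    pixels the classifier cannot explain with confidence localize a
    suspicious lesion and yield a region of interest and seed point. Stage
    two extracts the lesion contour by casting radial rays from the seed,
    locating brightness-gradient extrema, smoothing the polar boundary with
    sliding cubic regression and correcting outliers with a Niblack
    threshold. Includes a synthetic speckle-phantom generator with known
    tissue labels and lesion masks, contour and overlap evaluation metrics,
    frame-by-frame video processing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    ranger,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
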