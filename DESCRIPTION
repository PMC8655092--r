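Package: fundusWSSH
Title: Weakly Supervised Lesion Localization in Fundus Photographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Diabetic-retinopathy image analysis around a weakly supervised
    sensitive heat map (a class-activation-map variant with region-pooled
    weights): fundus preprocessing (median denoising, CLAHE on the LAB
    lightness channel, gamma correction, Kirsch compass edge maps),
    optic-disc detection and excision (Sobel gradient field, automatic
    global thresholding, binary morphology, circular Hough accumulator),
    a small trainable convolutional classifier with global and region
    average pooling trained by momentum with a stepwise learning-rate
    schedule, heat-map thresholding into lesion bounding boxes with
    optic-disc false-positive suppression, and a deterministic synthetic
    fundus generator with exact ground-truth masks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    tiff,
    yaml,
    jsonlite,
    grDevices,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    EBImage,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
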