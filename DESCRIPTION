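Package: dedscreen
Title: Retinal Fundus Image Preprocessing, Segmentation and CNN Screening
    for Diabetic Eye Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for early diabetic eye disease (DED) screening from color
    fundus photographs: classical image enhancement (green-channel extraction,
    contrast-limited adaptive histogram equalization, illumination correction,
    min-max contrast stretching, median filtering), binary morphology, region
    of interest segmentation (blood vessels via ISODATA thresholding, optic
    disc via the circular Hough transform, exudates via Otsu thresholding
    after disc and vessel removal), seeded geometric augmentation, a compact
    five-convolution-layer CNN classifier trained with RMSprop or Adam, and
    declarative builders with exact parameter accounting for the VGG16,
    Xception and DenseNet-121 transfer-learning bases. A bundled synthetic
    fundus generator with pixel-level ground truth makes the whole pipeline
    testable without any dataset download.
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
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
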