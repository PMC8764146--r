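Package: fluoroseg
Title: Semi-Supervised Adversarial Segmentation of Corneal Ulcers in
    Fluorescein-Stained Slit-Lamp Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Segmentation of corneal ulcer lesions in fluorescein-stained
    slit-lamp photographs with a conditional adversarial network. The
    segmentor is a five-stage residual encoder-decoder whose bottleneck fuses
    multi-scale encoder features through a cross-scale query/key/value
    spatial self-attention block; a 70-pixel-receptive-field patch
    discriminator scores image/mask pairs, enabling a semi-supervised
    protocol that trains on labeled pairs with pixel losses and on unlabeled
    images with an adversarial loss alone. Includes composite Dice/BCE/GAN
    objectives, evaluation metrics (Dice, Jaccard, sensitivity, Pearson
    correlation), a deterministic synthetic slit-lamp image generator for
    download-free testing, cross-validation utilities and a command-line
    interface. Networks and backpropagation are implemented in pure R.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
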