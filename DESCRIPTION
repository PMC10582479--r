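Package: mggan
Title: Multi-Generator Adversarial Stain Translation for Histopathology Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains and evaluates a multi-generator conditional generative
    adversarial network that translates hematoxylin-and-eosin (HE) stained
    tissue images into immunohistochemistry-like (IHC) images. The generator
    combines two U-shaped encoder-decoder networks operating at different
    spatial scales; the discriminator partitions images into a grid of
    independent patches scored by a shared encoder. The objective combines a
    conditional adversarial term, an L1 reconstruction term and a pixel-wise
    cross-entropy consistency term. Includes a reverse-mode automatic
    differentiation engine for the network computations, a procedural
    generator of paired stain-like images stratified by HER2-style expression
    grade, full-reference image quality metrics (MSE, PSNR, SSIM), ablation
    and hyperparameter-sweep harnesses, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    png,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
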