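Package: rfcottnet
Title: Lightweight Multi-Exit Hybrid Attention Classifier for Cotton Leaf Disease Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds, trains and compresses a lightweight hybrid
    convolution/attention image classifier for cotton disease and pest
    diagnosis. The backbone combines MobileNetV2-style inverted-residual
    blocks with MobileViT blocks whose attention is the linear-complexity
    separable self-attention; three auxiliary classification heads provide
    early-exit inference gated by confidence or entropy thresholds, and a
    quantization-aware-training path exports an INT8 model. Includes a
    synthetic leaf-image corpus generator emulating an 11-class imbalanced
    dataset, the dataset-construction pipeline (augmentation, stratified
    8:2 split, CSV manifests), evaluation metrics, and an analytic model
    profiler (parameters, multiply-accumulates, storage).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
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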