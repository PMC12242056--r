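Package: eegdecode
Title: Contrastive EEG-to-Image Decoding with an Embedding-Space Diffusion Prior
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-stage framework for decoding visual semantics from
    electroencephalography (EEG). Stage one aligns a convolution-plus-attention
    EEG encoder with target image embeddings using a symmetric InfoNCE
    contrastive objective; stage two refines the resulting EEG embeddings into
    image-embedding space with a classifier-free-guided denoising diffusion
    prior on a cosine noise schedule. The package ships a synthetic generator
    for rapid-serial-visual-presentation-style EEG/image-embedding datasets
    with controllable posterior-channel signal concentration, an n-way
    zero-shot retrieval evaluator, category-tag (CAT) and Frechet-distance
    metrics, and a visual-cortex channel-perturbation experiment. Networks are
    trained with AdamW on a compact reverse-mode automatic-differentiation
    engine included in the package, so everything runs on a single CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
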