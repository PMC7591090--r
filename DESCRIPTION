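Package: semcomp
Title: Semantic Compression Models of Memory Distortions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Beta variational autoencoders with explicit rate-distortion
    bookkeeping, used to model systematic distortions of human memory as
    lossy semantic compression. Includes a domain-agnostic beta-VAE with
    diagonal-Gaussian posteriors and pluggable likelihoods, a chess-board
    memory domain reproducing expertise effects (Chase-Simon style board
    reconstruction), a bag-of-words text domain reproducing gist-based
    false memories in the Deese-Roediger-McDermott (DRM) paradigm, and a
    forgetting analysis sweeping the rate-distortion trade-off parameter.
    Synthetic data generators (a Latent Dirichlet Allocation corpus and a
    random-legal-move chess game generator) make every analysis runnable
    without external corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
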