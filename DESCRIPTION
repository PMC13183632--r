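Package: pharl
Title: Physics-Aware Alignment Representation Learning for Fall-Motion
    Windows
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns window-level fall-motion representations that are aligned
    with physics-derived contact outcomes instead of visual similarity alone.
    Provides a synthetic multi-phase fall simulator with contact-descriptor
    streams, window-level label denoising by temporal alignment and hierarchical
    dominance, contrastive relation graphs with denominator masking and
    cross-trajectory physics positives, a composite contrastive objective with a
    variance regularizer, a deterministic training loop with checkpoint
    selection, and a rank-prioritized diagnostic suite (Spearman, Kendall,
    pairwise ordering accuracy, linear probes, physics consistency ratio,
    cross-video neighborhood consistency).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    arrow,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
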