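Package: kernbiome
Title: Kernel Methods for Compositional and Spatio-Temporal Microbiome Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A kernel framework for microbiome abundance tables. Provides
    compositional kernels built on the centered log-ratio transform
    (Aitchison-RBF and compositional linear), beta-diversity-derived kernels
    (Jensen-Shannon, quantitative Jaccard/Ruzicka), functional kernels for
    longitudinal series (discrete and continuous), multiple kernel learning
    for spatially structured samples, support vector machines and kernel PCA
    operating on precomputed kernel matrices, microbial-signature retrieval
    from linear-kernel hyperplanes, an evaluation harness with grouped
    train/test replication and nested tuning, and seed-deterministic
    synthetic-data generators for compositional, multi-site and longitudinal
    designs.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    kernlab,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
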