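Package: rootarch
Title: Root System Architecture Phenotyping, Ideotype Scoring, and
    Multi-Modal Clustering for Seedling Diversity Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for seedling root system architecture
    (RSA) studies on germination-paper imaging platforms. Segments root
    foreground from blue-paper scans by hue thresholding, skeletonizes the
    root network, and extracts the standard RSA trait set (lengths, angles,
    areas, branching, and depth-distribution ratios). Fits random-effects
    models to replicated trait tables to obtain BLUPs, variance components,
    and entry-mean broad-sense heritability; scores genotypes against
    literature-derived informative-root (iRoot) ideotypes by direction-aware
    rank sums; and builds genotype-, phenotype-, and shape-based clusters
    from SNP allele sharing, z-scored trait profiles, and elliptic Fourier /
    convolutional-autoencoder shape descriptors respectively, with Hudson
    FST contrasts between genotype clusters. Includes generators for
    synthetic root images, phenotype panels, structured SNP matrices, and
    shape families with known ground truth, so the whole pipeline is
    testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    EBImage,
    lme4,
    igraph,
    ape,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    mclust,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
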