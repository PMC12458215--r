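Package: drscan
Title: Deep Receptor Scanning: Pooled GPCR Expression Profiling and Sequence Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for pooled "deep receptor scanning" (Sort-Seq)
    experiments on G protein-coupled receptor (GPCR) libraries. Covers
    barcoded expression-cassette design with Hamming-constrained UMI sets,
    quantification of plasma-membrane expression from bin-resolved barcode
    sequencing (expected-error read filtering, exact-match UMI counting,
    rarefaction, low-GFP enrichment with Fisher tests, intensity-weighted
    averaging and replicate normalization), %MinMax codon-usage profiling
    with random-reverse-translation null models, ribosome-profiling
    metagene analysis (monosome/disome classification, 100-bin profiles,
    coverage Z-scores), receptor feature extraction (translocon
    insertion-energy scanning of transmembrane segments, physicochemical
    descriptors, Shrake-Rupley solvent-accessible surface areas,
    secondary-structure fractions), a random-forest expression
    classification harness with TreeSHAP attributions and UMAP embeddings,
    and seeded synthetic-data generators that emulate every assay stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    Biostrings,
    bio3d,
    randomForest,
    uwot
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pROC
Config/testthat/edition: 3
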