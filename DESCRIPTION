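Package: cavityseg
Title: Automated Resection-Cavity Segmentation from Multimodal Brain MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automated delineation of the post-operative resection
    cavity in glioblastoma patients from four co-registered, skull-stripped
    MR sequences (T1w, T1w-gadolinium, T2w, FLAIR). Implements a densely
    connected fully-convolutional 2D encoder-decoder applied slice-wise in
    the three orthogonal planes with probability averaging (2.5D inference),
    together with z-score intensity preprocessing, majority-vote fusion of
    multiple expert label maps into a reference segmentation, slice-sampling
    training with cross-entropy and Adam, k-fold cross-validation, and a
    Dice / volume-error evaluation suite with the accompanying
    Kruskal-Wallis / Wilcoxon statistical workflow. A synthetic brain
    phantom generator (cavity, air pockets, blood products, ventricles,
    bias field, noise, simulated raters) provides reproducible test data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp,
    RcppArmadillo
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
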