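Package: pegl
Title: Phylogenetically Effective Gene Length via Sparse Learning on Site Likelihoods
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the phylogenetic informativeness of alignment sites with
    an L1-penalized (Lasso) regression of per-tree total log-likelihoods on
    site-wise log-likelihoods computed over an ensemble of random phylogenetic
    trees. The number of sites receiving non-zero coefficients at the
    cross-validated penalty defines the phylogenetically effective gene length
    (PEGL). Includes a Felsenstein pruning likelihood engine for JC69, HKY85
    and GTR models with discrete-gamma rate heterogeneity, BIC model choice,
    neighbor-joining plus NNI hill-climbing maximum-likelihood tree search,
    parametric aLRT branch support, panel-level statistics
    (length-informativeness regression, codon-position breakdown, positional
    profiles, percentile-bootstrap group comparison), and simulators for
    within-species and among-species nucleotide alignments with planted
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
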