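Package: sfmeb
Title: Scaling-Free Minimum Enclosing Ball Detection of Differentially
    Expressed Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects differentially expressed (DE) genes from RNA-seq count
    matrices without any normalization step.  A soft-margin minimum enclosing
    ball (the one-class kernel method also known as support vector data
    description) is trained in an RBF feature space on a small set of known
    non-DE genes -- housekeeping genes within a species, or conserved
    orthologs across species -- and genes falling outside the fitted ball are
    called DE.  Includes a synthetic RNA-seq count generator (Poisson and
    negative binomial, with library-size heterogeneity, uniquely expressed
    genes and two-species designs), reject-rate based tuning of the kernel
    scale, and ROC/AUC evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
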