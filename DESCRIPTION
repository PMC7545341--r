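Package: cernaxis
Title: Discovery of Drug-Response-Predictive ceRNA Axes from Small-Cohort
    Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Screens competing endogenous RNA (ceRNA) axes -- a lncRNA, a
    miRNA, and an mRNA linked by shared miRNA recognition elements -- that
    discriminate treatment responders from nonresponders.  Differential
    expression is tested with a random-variance-model moderated t-test suited
    to very small cohorts; group-specific lncRNA-mRNA coexpression networks
    are summarised by relative-degree centrality to nominate core nodes;
    miRNA binding is scored in-package by canonical seed-class matching,
    position-weighted complementarity alignment, and nearest-neighbour duplex
    free energy; candidate axes must satisfy shared targeting,
    anticorrelation with the miRNA, and a sponge-competition criterion.
    Response is predicted from the axis RNAs with a partial-least-squares
    classifier evaluated by ROC analysis, including DeLong comparison against
    single markers.  A synthetic-cohort generator with planted axes provides
    ground truth for every stage, and qPCR comparative-Ct quantification is
    supported.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    igraph,
    jsonlite,
    pROC
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
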