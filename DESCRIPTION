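Package: gaileaf
Title: Candidate-Gene Association Analysis of Leaf Growth in a Perennial
    Ryegrass Synthetic Variety
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Re-implements, as a tested pipeline, a candidate-gene
    association analysis between polymorphism in the gibberellic acid
    insensitive (GAI) gene and leaf growth in 'Herbie', a panmictic
    synthetic variety of perennial ryegrass (Lolium perenne L.).
    Provides beta-function growth-curve fitting of leaf elongation
    kinetics (final length, maximum elongation rate, elongation
    duration), broad-sense heritability from REML variance components,
    EM haplotype phasing of unphased amplicon genotypes, Hill-Robertson
    gametic r2 and LD-decay summaries, and three association methods:
    blockwise stepwise SNP regression, Scheffe presence/absence
    haplotype contrasts, and permutation tree-scanning on a
    maximum-parsimony haplotype tree. A synthetic-data module generates
    Hardy-Weinberg populations from a haplotype pool with known ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    lme4,
    car,
    emmeans,
    ape,
    phangorn,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
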