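#!/usr/bin/env Rscript
# Stage 3 -- variance components, heritability, adjusted means and trait
# correlations. Per period: genotypic + residual components by REML and
# h2 = s2_G / (s2_G + s2_E). Across periods the genotype-by-period
# interaction joins the denominator. Adjusted (least-squares) genotype
# means feed the association stages.

library(gaileaf)

out <- "results/demo"
pheno <- read_phenotype_table(file.path(out, "phenotypes.csv"))
periods <- unique(pheno$period)

rows <- list()
for (tr in c("Llength", "LERmax", "LED")) {
  for (per in periods) {
    vc <- reml_components(pheno, tr, "per-period", period = per)
    rows[[length(rows) + 1L]] <- data.frame(
      trait = tr, period = per, sigma2_GE = vc$sigma2_GE,
      sigma2_E = vc$sigma2_E, sigma2_GExPeriod = NA, h2 = heritability(vc))
  }
  vc <- reml_components(pheno, tr, "cross-period")
  rows[[length(rows) + 1L]] <- data.frame(
    trait = tr, period = "both", sigma2_GE = vc$sigma2_GE,
    sigma2_E = vc$sigma2_E, sigma2_GExPeriod = vc$sigma2_GExPeriod,
    h2 = heritability(vc))
}
herit <- do.call(rbind, rows)
utils::write.csv(herit, file.path(out, "heritability.csv"),
                 row.names = FALSE, quote = FALSE)

means <- adjusted_means(pheno)
write_phenotype_table(means, file.path(out, "adjusted_means.csv"))
cors <- trait_correlations(means)
utils::write.csv(cors, file.path(out, "trait_correlations.csv"),
                 row.names = FALSE, quote = FALSE)

cat("Heritability (REML):\n")
print(herit, row.names = FALSE, digits = 3)
strong <- cors[cors$var1 != cors$var2 & abs(cors$r) > 0.5, ]
cat("Correlations with |r| > 0.5:\n")
print(strong, row.names = FALSE, digits = 2)
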