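balanced_pheno <- function(n_geno = 20, n_blocks = 3, sigma_E = 10,
                           sigma_G = 30, seed = 1) {
  simulate_trait_table(n_geno = n_geno, n_blocks = n_blocks, sigma_G = sigma_G,
                       sigma_E = sigma_E, seed = seed)
}

test_that("noiseless genotype effects give a (near) exact two-way fit", {
  ph <- simulate_trait_table(n_geno = 12, n_blocks = 3, sigma_G = 40,
                             sigma_E = 0, block_sd = 5, seed = 2)
  a <- suppressWarnings(anova_per_period(ph, "Llength", "spring"))
  res <- a$table[a$table$effect == "Residuals", ]
  expect_lt(res$sum_sq, 1e-16 * sum(a$table$sum_sq))
  expect_lt(a$table$p[a$table$effect == "G"], 1e-12)
  # adjusted means recover genotype means up to the block structure
  d <- as.data.frame(ph)
  raw <- tapply(d$value, d$plant, mean)
  expect_equal(a$adjusted_means$mean[match(names(raw), a$adjusted_means$plant)],
               as.numeric(raw), tolerance = 1e-8)
})

test_that("type-3 and sequential sums of squares coincide on balanced data", {
  ph <- balanced_pheno(seed = 5)
  a3 <- anova_per_period(ph, "Llength", "spring")
  d <- as.data.frame(ph)
  d$G <- factor(d$plant); d$B <- factor(d$block)
  seq_ss <- stats::anova(stats::lm(value ~ G + B, data = d))
  expect_equal(a3$table$sum_sq[a3$table$effect == "G"],
               seq_ss["G", "Sum Sq"], tolerance = 1e-8)
  expect_equal(a3$table$sum_sq[a3$table$effect == "B"],
               seq_ss["B", "Sum Sq"], tolerance = 1e-8)
})

test_that("REML components match the closed-form EMS solution on balanced data", {
  for (seed in c(3, 4)) {
    ph <- balanced_pheno(seed = seed)
    vc <- reml_components(ph, "Llength", "per-period", period = "spring")
    ems <- ems_components(ph, "Llength", "spring")
    expect_equal(vc$sigma2_GE, ems$sigma2_GE, tolerance = 1e-6)
    expect_equal(vc$sigma2_E, ems$sigma2_E, tolerance = 1e-6)
  }
})

test_that("zero-residual data give a zero residual component", {
  ph <- simulate_trait_table(n_geno = 10, n_blocks = 3, sigma_G = 40,
                             sigma_E = 0, block_sd = 0, seed = 6)
  vc <- suppressWarnings(suppressMessages(
    reml_components(ph, "Llength", "per-period", period = "spring")))
  expect_lt(vc$sigma2_E, 1e-8 * vc$sigma2_GE)
})

test_that("cross-period REML recovers known variance components", {
  # sigma2: G = 4, GxP = 1, E = 1 (sd 2, 1, 1), 200 genotypes x 2 periods
  ests <- t(vapply(1:10, function(r) {
    ph <- simulate_trait_table(n_geno = 200, n_blocks = 3,
                               periods = c("spring", "autumn"),
                               mu = 100, sigma_G = 2, sigma_GxP = 1,
                               sigma_E = 1,
                               period_effects = c(spring = 2, autumn = -2),
                               seed = 100 + r)
    vc <- reml_components(ph, "Llength", "cross-period")
    c(vc$sigma2_GE, vc$sigma2_GExPeriod, vc$sigma2_E)
  }, numeric(3)))
  med <- apply(ests, 2, median)
  expect_lt(abs(med[1] - 4) / 4, 0.25)
  expect_lt(abs(med[2] - 1) / 1, 0.25)
  expect_lt(abs(med[3] - 1) / 1, 0.25)
})

test_that("heritability follows the variance-component ratio exactly", {
  expect_equal(round(heritability(list(sigma2_GE = 4524, sigma2_E = 1176)), 2),
               0.79)
  expect_equal(heritability(list(sigma2_GE = 0, sigma2_E = 10)), 0)
  expect_equal(heritability(list(sigma2_GE = 7, sigma2_E = 7)), 0.5)
  # cross-period variant includes the interaction in the denominator
  expect_equal(heritability(list(sigma2_GE = 2, sigma2_E = 1,
                                 sigma2_GExPeriod = 1), "cross-period"), 0.5)
  expect_error(heritability(list(sigma2_GE = 0, sigma2_E = 0)), "undefined")
  # scale invariance: trait rescaling multiplies all components by k^2
  k <- 3.7
  expect_equal(heritability(list(sigma2_GE = 4524 * k^2, sigma2_E = 1176 * k^2)),
               heritability(list(sigma2_GE = 4524, sigma2_E = 1176)))
})

test_that("printed residual CVs are reproduced from components and means", {
  vc <- herbie_variance_components()
  ts <- herbie_trait_summary()
  per <- vc[vc$period != "both", ]
  for (i in seq_len(nrow(per))) {
    m <- ts$mean[ts$population == per$population[i] &
                   ts$period == per$period[i] & ts$trait == per$trait[i]]
    expect_lt(abs(residual_cv(per$sigma2_E[i], m) - per$cv_pct[i]), 1)
  }
})

test_that("trait correlations recover known correlation structure", {
  # self-correlation is exactly 1
  ph <- balanced_pheno(seed = 8)
  m <- adjusted_means(ph)
  tc <- trait_correlations(m)
  expect_equal(tc$r[tc$var1 == tc$var2], 1)
  # rho = 0.9 bivariate normal, n = 200: mean r within 0.02 over 100 reps
  set.seed(13)
  rs <- vapply(1:100, function(r) {
    x <- rnorm(200); y <- 0.9 * x + sqrt(1 - 0.81) * rnorm(200)
    mm <- phenotype_table(data.frame(
      plant = rep(sprintf("G%03d", 1:200), 2), block = "adj",
      period = "spring", trait = rep(c("Llength", "LERmax"), each = 200),
      value = c(x + 10, y + 10)))
    tcc <- trait_correlations(mm)
    tcc$r[tcc$var1 != tcc$var2]
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.9), 0.02)
  # independent traits: |r| < 0.2 in at least 95% of reps
  set.seed(14)
  rs0 <- vapply(1:100, function(r) {
    mm <- phenotype_table(data.frame(
      plant = rep(sprintf("G%03d", 1:200), 2), block = "adj",
      period = "spring", trait = rep(c("Llength", "LERmax"), each = 200),
      value = rnorm(400) + 10))
    tcc <- trait_correlations(mm)
    tcc$r[tcc$var1 != tcc$var2]
  }, numeric(1))
  expect_gte(mean(abs(rs0) < 0.2), 0.95)
  # significance stars follow the p-value
  expect_true(all(tc$stars %in% c("", "*", "**", "***", "NS", "undefined")))
})

test_that("degenerate correlation input is flagged, not propagated", {
  mm <- phenotype_table(data.frame(
    plant = rep(c("G1", "G2", "G3", "G4"), 2), block = "adj",
    period = "spring", trait = rep(c("Llength", "LERmax"), each = 4),
    value = c(1, 2, 3, 4, 5, 5, 5, 5)))
  tcc <- trait_correlations(mm)
  expect_true(any(tcc$stars == "undefined"))
})

test_that("genotype F-test holds its nominal size under the null", {
  rej <- vapply(1:2000, function(r) {
    ph <- simulate_trait_table(n_geno = 25, n_blocks = 3, sigma_G = 0,
                               sigma_E = 30, block_sd = 5,
                               seed = 60000 + r)
    a <- anova_per_period(ph, "Llength", "spring", compute_means = FALSE)
    a$table$p[a$table$effect == "G"] < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})
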