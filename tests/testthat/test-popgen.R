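test_that("SNP summary reports spacing and rare-allele counts", {
  sites <- gai_snp_sites()
  s <- snp_summary(sites)
  expect_equal(s$mean_spacing, mean(diff(sites$position)))
  expect_equal(s$mean_spacing_rounded, 12)
  expect_equal(s$n_rare, 6L)
  # same flags from the count-weighted haplotype pool
  sh <- snp_summary(gai_haplotype_pool())
  expect_equal(sh$n_rare, 6L)
  # trivial spacing case
  two <- snp_sites(data.frame(snp_no = 1:2, position = c(10L, 20L),
                              alleles = c("A/C", "G/T"),
                              reported_freq = c("0.5", "0.5")),
                   amplicon_length = 30L)
  expect_equal(snp_summary(two, rare_threshold = 0.1)$mean_spacing, 10)
})

test_that("EM phasing resolves trivially phaseable plants with posterior 1", {
  gm <- two_site_gm(c("A/A", "A/C", "A/A"), c("G/G", "T/T", "G/T"))
  ph <- em_phase(gm)
  expect_s3_class(ph, "phased_sample")
  expect_equal(sum(ph$frequencies), 1, tolerance = 1e-9)
  a <- ph$assignments
  # fully homozygous plant: single consistent pair
  expect_equal(a$posterior[a$plant == "P01"], 1, tolerance = 1e-9)
  expect_equal(pair_key(a$hap1[1], a$hap2[1]), pair_key("AG", "AG"))
  # exactly one heterozygous site: both orderings give the same pair
  expect_equal(a$posterior[a$plant == "P02"], 1, tolerance = 1e-9)
  expect_equal(pair_key(a$hap1[2], a$hap2[2]), pair_key("AT", "CT"))
  expect_equal(a$posterior[a$plant == "P03"], 1, tolerance = 1e-9)
})

test_that("EM phasing is equivariant under plant relabelling", {
  cfg <- sim_config(seed = 21, n_plants = 60)
  pop <- simulate_population(cfg)
  ph1 <- em_phase(pop$genotypes)
  perm <- sample(seq_along(pop$genotypes$plants))
  gm2 <- genotype_matrix(pop$genotypes$plants[perm], pop$genotypes$sites,
                         pop$genotypes$calls[perm, ])
  ph2 <- em_phase(gm2)
  expect_equal(ph1$frequencies, ph2$frequencies, tolerance = 1e-9)
  a1 <- ph1$assignments; a2 <- ph2$assignments
  a2 <- a2[match(a1$plant, a2$plant), ]
  expect_equal(pair_key(a1$hap1, a1$hap2), pair_key(a2$hap1, a2$hap2))
})

test_that("EM phasing recovers simulated phase and pool frequencies", {
  cfg <- sim_config(seed = 42, n_plants = 400)
  pop <- simulate_population(cfg)
  ph <- em_phase(pop$genotypes)
  expect_true(ph$converged)
  a <- ph$assignments
  tr <- pop$truth[match(a$plant, pop$truth$plant), ]
  match_rate <- mean(pair_key(a$hap1, a$hap2) == pair_key(tr$hap1, tr$hap2))
  expect_gte(match_rate, 0.90)
  pf <- haplotype_freqs(cfg$pool)
  est <- ph$frequencies[names(pf)]
  est[is.na(est)] <- 0
  expect_lt(max(abs(est - pf)), 0.03)
})

test_that("phasing errors on corrupt input name the plant", {
  gm <- two_site_gm(c("A/A", "A/C"), c("G/G", "G/T"))
  gm$calls[2, 1] <- "Z/Q"   # corrupt after construction
  expect_error(em_phase(gm), "P02|subscript")
})

test_that("gametic r2 matches coupling, equilibrium and hand-computed cases", {
  # perfect coupling: only AB and ab
  f <- c("AG" = 0.3, "CT" = 0.7)
  expect_equal(gametic_r2(f, 1, 2), 1)
  # linkage equilibrium: p_AB = p_A p_B
  f <- c("AG" = 0.12, "AT" = 0.28, "CG" = 0.18, "CT" = 0.42)
  expect_equal(gametic_r2(f, 1, 2), 0, tolerance = 1e-12)
  # hand-arithmetic oracle: pA=0.6, pB=0.065, pAB=0.0648 -> D=0.0258
  f <- c("AG" = 0.0648, "AT" = 0.5352, "CG" = 0.0002, "CT" = 0.3998)
  expect_equal(gametic_r2(f, 1, 2),
               0.0258^2 / (0.6 * 0.4 * 0.065 * 0.935), tolerance = 1e-9)
})

test_that("gametic r2 agrees with a brute-force 2x2 count oracle", {
  set.seed(31)
  for (k in 1:25) {
    counts <- c(AB = sample(1:50, 1), Ab = sample(1:50, 1),
                aB = sample(1:50, 1), ab = sample(1:50, 1))
    f <- counts / sum(counts)
    names(f) <- c("AG", "AT", "CG", "CT")
    expect_equal(gametic_r2(f, 1, 2), unname(r2_bruteforce(counts)),
                 tolerance = 1e-12)
  }
})

test_that("LD matrix excludes multi-allelic sites and is distance-consistent", {
  pool <- gai_haplotype_pool()
  ldm <- ld_matrix(pool)
  expect_equal(attr(ldm, "n_excluded"), 1L)   # the triallelic site
  expect_false(any(ldm$site_i == 3 | ldm$site_j == 3))
  expect_equal(nrow(ldm), choose(19, 2))
  expect_true(all(ldm$r2 >= 0 & ldm$r2 <= 1))
  expect_equal(ldm$distance, abs(ldm$pos_j - ldm$pos_i))
})

test_that("LD decays with distance in the published haplotypes", {
  ldm <- ld_matrix(gai_haplotype_pool())
  dec <- ld_decay(ldm, threshold_bp = 150)
  expect_lte(dec$max_r2_beyond, 0.1)
  expect_lt(dec$slope, 0)
  # brute-force check of the beyond-threshold maximum
  expect_equal(dec$max_r2_beyond, max(ldm$r2[ldm$distance > 150]))
})

test_that("LD decay slope is zero for constant r2 and negative for built-in decay", {
  flat <- data.frame(site_i = 1, site_j = 2, pos_i = 1, pos_j = 2,
                     distance = c(10, 50, 200, 400), r2 = 0.3)
  dec <- ld_decay(flat)
  expect_equal(dec$slope, 0, tolerance = 1e-12)
  synth <- data.frame(site_i = 1, site_j = 2, pos_i = 0, pos_j = 0,
                      distance = c(5, 10, 20, 80, 160, 320),
                      r2 = c(0.9, 0.7, 0.5, 0.2, 0.1, 0.05))
  expect_lt(ld_decay(synth)$slope, 0)
})

test_that("genotypic LD permutation test hits its analytic extremes", {
  # perfectly coupled duplicate columns: maximal association
  n <- 100
  set.seed(8)
  g1 <- sample(c("A/A", "A/C", "C/C"), n, replace = TRUE, prob = c(.25, .5, .25))
  g2 <- chartr("AC", "GT", g1)
  gm <- two_site_gm(g1, g2)
  out <- genotypic_ld_test(gm, 1, 2, n_perm = 500, seed = 2)
  expect_equal(out$p, 1 / (1 + 500))
  # identical duplicate columns behave the same
  gm2 <- two_site_gm(g1, chartr("AC", "GT", g1))
  out2 <- genotypic_ld_test(gm2, 1, 2, n_perm = 500, seed = 2)
  expect_equal(out2$G, out$G)
  expect_equal(out2$p, out$p)
  expect_error(genotypic_ld_test(gm, 1, 2, n_perm = 50), ">= 100")
})

test_that("monomorphic sites are rejected by the LD tests", {
  gm <- two_site_gm(c("A/A", "A/A", "A/A"), c("G/T", "G/G", "T/T"))
  expect_error(genotypic_ld_test(gm, 1, 2, n_perm = 200), "polymorphic")
  f <- c("AG" = 0.5, "AT" = 0.5)
  expect_error(gametic_r2(f, 1, 2), "biallelic")
})
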