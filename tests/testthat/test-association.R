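# shared simulated population for the association tests
assoc_pop <- local({
  cfg <- sim_config(seed = 101, n_plants = 200)
  pop <- simulate_population(cfg)
  list(cfg = cfg, pop = pop,
       design = snp_design(pop$genotypes),
       cls10 = genotype_class(pop$truth, cfg$pool$sites, 10))
})

mk_means <- function(values, plants, trait = "Llength", period = "spring") {
  phenotype_table(data.frame(plant = plants, block = "adj", period = period,
                             trait = trait, value = values))
}

test_that("genotype-class design encodes homozygotes and heterozygotes", {
  gm <- two_site_gm(c("A/A", "A/C", "C/C", "./."), c("G/T", "T/T", "G/G", "G/T"))
  d <- snp_design(gm)
  expect_equal(unname(d[, 1]), c("11", "12", "22", NA))
  expect_equal(unname(d[, 2]), c("12", "22", "11", "12"))
})

test_that("a fully explanatory SNP is selected first with R2 = 1", {
  pop <- assoc_pop$pop
  cls <- assoc_pop$cls10
  class_means <- c("11" = 290, "12" = 330, "22" = 310)
  y <- class_means[cls]
  means <- mk_means(unname(y), pop$truth$plant)
  sw <- suppressWarnings(
    stepwise_snp_regression(means, assoc_pop$design, "Llength", "spring"))
  expect_equal(sw$selected$site[1], 10)
  expect_equal(sw$selected$partial_R2[1], 1, tolerance = 1e-9)
  expect_equal(sw$global_R2, 1, tolerance = 1e-9)
})

test_that("stepwise global R2 equals a direct refit and effects are centred", {
  set.seed(55)
  pop <- assoc_pop$pop
  cls <- assoc_pop$cls10
  y <- 312 + 25 * (cls == "12") + rnorm(200, 0, 30)
  means <- mk_means(y, pop$truth$plant)
  sw <- suppressWarnings(
    stepwise_snp_regression(means, assoc_pop$design, "Llength", "spring"))
  expect_gt(nrow(sw$selected), 0)
  # refit the final model from scratch
  dat <- data.frame(y = y)
  for (s in sw$selected$site)
    dat[[paste0("s", s)]] <- factor(assoc_pop$design[pop$truth$plant, s])
  refit <- lm(y ~ ., data = dat)
  expect_equal(sw$global_R2, summary(refit)$r.squared, tolerance = 1e-10)
  # partial R2 never exceed the global R2 and sum to it for sequential entry
  expect_lte(max(sw$selected$partial_R2), sw$global_R2 + 1e-12)
  expect_equal(sum(sw$selected$partial_R2), sw$global_R2, tolerance = 1e-8)
  # class-frequency-weighted effects sum to zero per selected SNP
  for (s in unique(sw$effects$site)) {
    e <- sw$effects[sw$effects$site == s, ]
    expect_equal(sum(e$effect * e$n) / sum(e$n), 0, tolerance = 1e-8)
  }
})

test_that("monomorphic SNPs are skipped with a warning", {
  pop <- assoc_pop$pop
  design <- assoc_pop$design
  design[, 1] <- "11"   # force monomorphic
  y <- rnorm(200, 300, 20)
  means <- mk_means(y, pop$truth$plant)
  expect_warning(
    stepwise_snp_regression(means, design, "Llength", "spring"),
    "monomorphic")
})

test_that("null stepwise screening selects few SNPs and honest R2", {
  # no genetic effect: selection count stays modest at the 0.15 screen
  pop <- assoc_pop$pop
  n_sel <- vapply(1:20, function(r) {
    set.seed(300 + r)
    y <- rnorm(200, 300, 25)
    means <- mk_means(y, pop$truth$plant)
    sw <- suppressWarnings(
      stepwise_snp_regression(means, assoc_pop$design, "Llength", "spring"))
    nrow(sw$selected)
  }, numeric(1))
  expect_gt(mean(n_sel), 0)        # a liberal screen admits some noise terms
  expect_lt(mean(n_sel), 8)        # but not wholesale inflation
})

test_that("presence/absence contrasts detect a planted carrier effect", {
  cfg <- sim_config(seed = 61, n_plants = 300)
  pop <- simulate_population(cfg)
  tr <- pop$truth
  target <- "CCGCCGAAGGCCCACGGCAG"   # a common pool haplotype
  hits <- 0
  for (r in 1:20) {
    set.seed(700 + r)
    carrier <- tr$hap1 == target | tr$hap2 == target
    y <- 300 + 20 * carrier + rnorm(300, 0, 10)
    means <- mk_means(y, tr$plant)
    hc <- haplotype_presence_contrasts(means, tr, "Llength", "spring")
    row <- hc[hc$haplotype == target, ]
    hits <- hits + (row$p_scheffe < 0.05)
  }
  expect_gte(hits / 20, 0.9)
})

test_that("contrast familywise error under the null respects the Scheffe bound", {
  cfg <- sim_config(seed = 62, n_plants = 200)
  pop <- simulate_population(cfg)
  tr <- pop$truth
  n_rep <- 200
  fw <- vapply(1:n_rep, function(r) {
    set.seed(900 + r)
    y <- rnorm(200, 300, 15)
    means <- mk_means(y, tr$plant)
    hc <- haplotype_presence_contrasts(means, tr, "Llength", "spring")
    any(hc$p_scheffe < 0.05, na.rm = TRUE)
  }, logical(1))
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lte(mean(fw), 0.05 + 2 * se)
})

test_that("degenerate contrasts (all plants carriers) are flagged inestimable", {
  plants <- sprintf("P%02d", 1:30)
  asg <- data.frame(plant = plants, hap1 = "AAAA", hap2 = "AAAA")
  means <- mk_means(rnorm(30, 300, 5), plants)
  hc <- haplotype_presence_contrasts(means, asg, "Llength", "spring")
  expect_false(hc$estimable[hc$haplotype == "AAAA"])
  # nothing above threshold -> empty result with a message
  asg2 <- data.frame(plant = plants[1:5], hap1 = "AAAA", hap2 = "CCCC")
  means2 <- mk_means(rnorm(5, 300, 5), plants[1:5])
  expect_message(
    hc2 <- haplotype_presence_contrasts(means2, asg2, "Llength", "spring"),
    "threshold")
  expect_equal(nrow(hc2), 0)
})

test_that("parsimony tree is minimal and contains the expected clade split", {
  # additive case: four haplotypes differing at disjoint single sites
  sites4 <- snp_sites(data.frame(snp_no = 1:4, position = c(5L, 10L, 15L, 20L),
                                 alleles = rep("A/C", 4),
                                 reported_freq = rep("0.5", 4)),
                      amplicon_length = 25L)
  haps <- c(h1 = "AAAA", h2 = "CAAA", h3 = "ACAA", h4 = "AACA")
  tr <- build_parsimony_tree(haps)
  expect_equal(attr(tr, "parsimony_score"), 3L)  # = number of variable sites
  expect_equal(ape::Ntip(tr), 4L)

  # the nine common published haplotypes split at the site-10 SNP
  pool <- gai_haplotype_pool()
  common <- pool$haplotypes[pool$haplotypes$count > 10, ]
  haps9 <- setNames(common$haplotype, paste0("h", common$haplotype_no))
  tr9 <- build_parsimony_tree(haps9)
  spl <- as.matrix(phangorn::as.splits(ape::unroot(tr9)))
  sides <- lapply(seq_len(nrow(spl)), function(k)
    sort(tr9$tip.label[spl[k, ] == 1]))
  sides <- c(sides, lapply(sides, function(s) sort(setdiff(tr9$tip.label, s))))
  target <- sort(c("h24", "h25", "h27", "h30", "h37"))
  expect_true(any(vapply(sides, identical, logical(1), target)))

  # tie-break determinism
  tr9b <- build_parsimony_tree(haps9)
  expect_equal(ape::write.tree(tr9), ape::write.tree(tr9b))

  # Fitch score of the returned tree beats random topologies (own scorer)
  seqs <- as.list(haps9)
  own <- fitch_score(tr9, seqs)
  expect_equal(own, attr(tr9, "parsimony_score"))
  set.seed(77)
  rand <- vapply(1:100, function(i)
    fitch_score(random_topology(names(haps9)), seqs), numeric(1))
  expect_true(all(own <= rand))

  expect_error(build_parsimony_tree(haps[1:3]), "4-12")
  expect_error(build_parsimony_tree(setNames(rep("A", 13), paste0("x", 1:13))),
               "4-12")
})

test_that("tree scan: two-class branch F equals the squared t statistic", {
  # homozygous-only plants make every branch a clean two-class comparison;
  # two mutations on the internal branch give a resolved ((h1,h2),(h3,h4))
  haps <- c(h1 = "AAAA", h2 = "AAAC", h3 = "CCAA", h4 = "CCAC")
  tree <- build_parsimony_tree(haps)
  plants <- sprintf("P%03d", 1:60)
  tip_of <- rep(unname(haps), each = 15)
  asg <- data.frame(plant = plants, hap1 = tip_of, hap2 = tip_of)
  set.seed(5)
  y <- rnorm(60, 300, 20)
  means <- mk_means(y, plants)
  ts <- tree_scan(tree, asg, means, "Llength", "spring",
                  hap_labels = haps, n_perm = 100, min_class = 5, seed = 9)
  two_class <- ts[ts$df1 == 1, ]
  expect_gt(nrow(two_class), 0)
  for (k in seq_len(nrow(two_class))) {
    b <- two_class[k, ]
    side_tips <- strsplit(b$side, ",")[[1]]
    side_haps <- unname(haps[side_tips])
    grp <- tip_of %in% side_haps
    tt <- t.test(y[grp], y[!grp], var.equal = TRUE)
    expect_equal(b$F, unname(tt$statistic)^2, tolerance = 1e-9)
  }
})

test_that("tree scan flags a constant phenotype as null everywhere", {
  cfg <- sim_config(seed = 64, n_plants = 120)
  pop <- simulate_population(cfg)
  pool <- gai_haplotype_pool()
  common <- pool$haplotypes[pool$haplotypes$count > 10, ]
  haps9 <- setNames(common$haplotype, paste0("h", common$haplotype_no))
  tree <- build_parsimony_tree(haps9)
  means <- mk_means(rep(300, 120), pop$truth$plant)
  ts <- tree_scan(tree, pop$truth, means, "Llength", "spring",
                  hap_labels = haps9, n_perm = 100, seed = 3)
  expect_true(all(ts$F == 0))
  expect_true(all(ts$Psim > 0.95))
})

test_that("tree scan localises a planted clade effect at the causal branch", {
  pool <- gai_haplotype_pool()
  common <- pool$haplotypes[pool$haplotypes$count > 10, ]
  haps9 <- setNames(common$haplotype, paste0("h", common$haplotype_no))
  tree <- build_parsimony_tree(haps9)
  g_side <- names(haps9)[substr(haps9, 10, 10) == "G"]   # site-10 clade
  hit <- 0
  n_rep <- 25
  for (r in 1:n_rep) {
    cfg <- sim_config(seed = 1200 + r, n_plants = 200)
    pop <- simulate_population(cfg)
    tr <- pop$truth
    cls <- genotype_class(tr, cfg$pool$sites, 10)
    set.seed(4000 + r)
    y <- 300 + 30 * (cls == "12") + rnorm(200, 0, 18)
    means <- mk_means(y, tr$plant)
    ts <- tree_scan(tree, tr, means, "Llength", "spring",
                    hap_labels = haps9, n_perm = 200, seed = 10 + r)
    is_target <- vapply(ts$side, function(sd) {
      bs <- sort(strsplit(sd, ",")[[1]])
      comp <- sort(setdiff(tree$tip.label, bs))
      identical(bs, sort(g_side)) || identical(comp, sort(g_side))
    }, logical(1))
    # the causal branch attains the smallest Psim (permutation-floor ties count)
    hit <- hit + (min(ts$Psim[is_target]) <= min(ts$Psim) + 1e-12)
  }
  expect_gte(hit / n_rep, 0.8)
})

test_that("tree-scan permutation p-values are uniform under the null", {
  pool <- gai_haplotype_pool()
  common <- pool$haplotypes[pool$haplotypes$count > 10, ]
  haps9 <- setNames(common$haplotype, paste0("h", common$haplotype_no))
  tree <- build_parsimony_tree(haps9)
  cfg <- sim_config(seed = 65, n_plants = 150)
  pop <- simulate_population(cfg)
  ps <- vapply(1:60, function(r) {
    set.seed(5000 + r)
    y <- rnorm(150, 300, 15)
    means <- mk_means(y, pop$truth$plant)
    ts <- tree_scan(tree, pop$truth, means, "Llength", "spring",
                    hap_labels = haps9, n_perm = 199, seed = 20 + r)
    ts$Psim[1]
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})
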