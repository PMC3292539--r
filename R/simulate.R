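## Synthetic "Herbie-like" populations with known ground truth.
## Genotypes: each plant's two gametes are i.i.d. draws from a haplotype
## pool (count-weighted), i.e. Hardy-Weinberg union of gametes in a
## panmictic synthetic variety. Phenotypes: a genotype-class effect at
## one causal SNP plus genotypic, genotype-by-period, block and residual
## deviates act on one beta-growth parameter (default the final length
## Ym); leaves 3 and 4 of each plant are measured three times a week
## along a thermal-time axis and carry independent measurement noise.

#' Simulation configuration
#'
#' Defaults emulate the 'Herbie' study conditions: ~200 plants cloned
#' into 3 blocks in two periods (spring at 16 degrees C, autumn at 13),
#' measurements three times a week (every 7/3 days), baseline growth
#' parameters giving a ~316 mm leaf with peak elongation rate
#' ~1.7 mm/Cd, genotypic / genotype-by-period / residual trait standard
#' deviations matching the printed per-period variance components
#' (sd_G ~ 67 mm, residual ~ 34 mm on final length), and a 3 mm
#' measurement error on individual length readings.
#'
#' @param seed integer seed; every stochastic stage derives its stream
#'   from it.
#' @param n_plants number of plants (genotypes).
#' @param n_blocks number of clonal blocks per period.
#' @param periods character vector of period labels.
#' @param pool haplotype pool ([haplotype_table]) gametes are drawn from.
#' @param causal_site index (in site order) of the causal SNP.
#' @param effects named numeric `c(e11, e12, e22)`: genotype-class
#'   effects (trait units) added to the target parameter for homozygous
#'   first-allele, heterozygous, homozygous second-allele plants.
#'   `e12 > e11 = e22` encodes superdominance.
#' @param effect_param which growth parameter carries the genetic and
#'   random effects (default `"Ym"`).
#' @param sigma_G genotypic sd (shared by a plant across periods).
#' @param sigma_GxP genotype-by-period interaction sd.
#' @param sigma_B sd of the additive block effects.
#' @param sigma_PB residual plant-within-block trait sd (the
#'   within-period ANOVA residual on the target parameter).
#' @param sigma_meas measurement noise sd on each length reading (mm).
#' @param baseline named list/vector of baseline `(Ym, tc, tm, te)`.
#' @param temperatures named numeric, mean daily air temperature
#'   (degrees C) per period; thermal time accrues at this daily rate.
#' @param cadence_days days between measurements (default 7/3: three
#'   times a week).
#' @param max_days length of the observation campaign.
#' @param mature_mm,mature_runs maturity stopping rule: truncate a series
#'   once `mature_runs` consecutive readings change by less than
#'   `mature_mm` mm.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_plants = 200L,
                       n_blocks = 3L,
                       periods = c("spring", "autumn"),
                       pool = gai_haplotype_pool(),
                       causal_site = 10L,
                       effects = c(e11 = 0, e12 = 0, e22 = 0),
                       effect_param = "Ym",
                       sigma_G = 67,
                       sigma_GxP = 30,
                       sigma_B = 10,
                       sigma_PB = 34,
                       sigma_meas = 3,
                       baseline = c(Ym = 316, tc = 8, tm = 160, te = 300),
                       temperatures = c(spring = 16, autumn = 13),
                       cadence_days = 7 / 3,
                       max_days = 60,
                       mature_mm = 1,
                       mature_runs = 3) {
  stopifnot(inherits(pool, "haplotype_table"),
            nrow(pool$haplotypes) >= 1L,
            all(c(sigma_G, sigma_GxP, sigma_B, sigma_PB, sigma_meas) >= 0),
            cadence_days >= 1 / 7,
            baseline["tc"] <= baseline["tm"], baseline["tm"] < baseline["te"],
            all(periods %in% names(temperatures)))
  if (sum(pool$haplotypes$count) == 0L)
    stop("sim_config: haplotype pool has zero total count")
  structure(list(seed = as.integer(seed), n_plants = as.integer(n_plants),
                 n_blocks = as.integer(n_blocks), periods = periods,
                 pool = pool, causal_site = as.integer(causal_site),
                 effects = effects, effect_param = effect_param,
                 sigma_G = sigma_G, sigma_GxP = sigma_GxP, sigma_B = sigma_B,
                 sigma_PB = sigma_PB, sigma_meas = sigma_meas,
                 baseline = baseline, temperatures = temperatures,
                 cadence_days = cadence_days, max_days = max_days,
                 mature_mm = mature_mm, mature_runs = mature_runs),
            class = "sim_config")
}

#' Draw a Hardy-Weinberg population from the haplotype pool
#'
#' Each plant receives two i.i.d. gametes from the pool's count-weighted
#' haplotype frequencies; the unphased genotype matrix is obtained by
#' dropping phase at every site.
#'
#' @param config a [sim_config].
#' @return list: `genotypes` ([genotype_matrix]) and `truth` (data.frame
#'   `plant`, `hap1`, `hap2` of the true phased pair).
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  f <- haplotype_freqs(config$pool)
  n <- config$n_plants
  h1 <- sample(names(f), n, replace = TRUE, prob = f)
  h2 <- sample(names(f), n, replace = TRUE, prob = f)
  plants <- sprintf("P%03d", seq_len(n))
  M1 <- hap_char_matrix(h1)
  M2 <- hap_char_matrix(h2)
  calls <- matrix(paste(pmin(M1, M2), pmax(M1, M2), sep = "/"),
                  nrow = n)
  gm <- genotype_matrix(plants, config$pool$sites, calls)
  truth <- data.frame(plant = plants, hap1 = h1, hap2 = h2,
                      stringsAsFactors = FALSE)
  list(genotypes = gm, truth = truth)
}

#' Genotype class at one site from a phased pair
#'
#' Classes are `"11"` (homozygous first listed allele), `"22"`
#' (homozygous second), `"12"` (heterozygous); pairs involving a third
#' allele are labelled by their allele indices (e.g. `"13"`, `"33"`).
#'
#' @param truth data.frame with `hap1`, `hap2` (as from
#'   [simulate_population]).
#' @param sites the [snp_sites] table.
#' @param site site index.
#' @return character vector of class labels.
#' @export
genotype_class <- function(truth, sites, site) {
  al <- site_alleles(sites)[[site]]
  a1 <- substr(truth$hap1, site, site)
  a2 <- substr(truth$hap2, site, site)
  i1 <- match(a1, al); i2 <- match(a2, al)
  paste0(pmin(i1, i2), pmax(i1, i2))
}

maturity_cut <- function(y, mature_mm, mature_runs, min_points = 6L) {
  d <- abs(diff(y)) < mature_mm
  if (length(d) >= mature_runs) {
    runs <- which(vapply(seq_len(length(d) - mature_runs + 1L),
                         function(i) all(d[i:(i + mature_runs - 1L)]),
                         logical(1)))
    if (length(runs))
      return(max(min_points, runs[1] + mature_runs))
  }
  length(y)
}

#' Simulate leaf-length measurement series for a population
#'
#' Per plant x period the target growth parameter equals
#' baseline + genotype-class effect at the causal site + a genotypic
#' deviate (shared across periods) + a genotype-by-period deviate; per
#' block an additive block effect and a residual plant-within-block
#' deviate are added. Both leaves (ranks 3 and 4) share the plant-level
#' parameters and get independent N(0, sigma_meas) noise on each
#' reading (lengths truncated at 0). Series stop at maturity (see
#' [sim_config]). Deviates that would break `tc <= tm < te` are resampled
#' (a warning counter is attached).
#'
#' @param pop output of [simulate_population].
#' @param config the same [sim_config].
#' @return list: `series` (long data.frame `plant`, `block`, `period`,
#'   `leaf`, `t`, `y`), `truth` (per plant x period true parameters and
#'   class), `block_effects`, `residuals` (per plant x block x period
#'   trait deviate); attribute `n_resampled`.
#' @export
simulate_phenotypes <- function(pop, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  truth <- pop$truth
  n <- nrow(truth)
  cls <- genotype_class(truth, config$pool$sites, config$causal_site)
  eff <- c("11" = unname(config$effects["e11"]),
           "12" = unname(config$effects["e12"]),
           "22" = unname(config$effects["e22"]))[cls]
  eff[is.na(eff)] <- 0
  g_dev <- stats::rnorm(n, 0, config$sigma_G)
  base <- config$baseline
  n_resampled <- 0L

  blocks <- sprintf("B%d", seq_len(config$n_blocks))
  block_effects <- expand.grid(period = config$periods, block = blocks,
                               stringsAsFactors = FALSE)
  block_effects$effect <- stats::rnorm(nrow(block_effects), 0, config$sigma_B)

  par_rows <- list(); res_rows <- list(); ser_rows <- list()
  for (per in config$periods) {
    gp_dev <- stats::rnorm(n, 0, config$sigma_GxP)
    temp <- config$temperatures[[per]]
    days <- seq(config$cadence_days, config$max_days, by = config$cadence_days)
    t_full <- temp * days
    for (i in seq_len(n)) {
      p <- base
      repeat {
        p <- base
        p[config$effect_param] <- p[config$effect_param] +
          eff[i] + g_dev[i] + gp_dev[i]
        if (p["tc"] <= p["tm"] && p["tm"] < p["te"] && p["Ym"] > 0) break
        n_resampled <- n_resampled + 1L
        gp_dev[i] <- stats::rnorm(1, 0, config$sigma_GxP)
      }
      par_rows[[length(par_rows) + 1L]] <-
        data.frame(plant = truth$plant[i], period = per, class = cls[i],
                   Ym = p[["Ym"]], tc = p[["tc"]], tm = p[["tm"]],
                   te = p[["te"]], stringsAsFactors = FALSE)
      for (b in blocks) {
        be <- block_effects$effect[block_effects$period == per &
                                     block_effects$block == b]
        pb <- stats::rnorm(1, 0, config$sigma_PB)
        pbk <- p
        pbk[config$effect_param] <- pbk[config$effect_param] + be + pb
        if (!(pbk["tc"] <= pbk["tm"] && pbk["tm"] < pbk["te"]))
          pbk <- p   # block shift would break the domain; drop it
        res_rows[[length(res_rows) + 1L]] <-
          data.frame(plant = truth$plant[i], block = b, period = per,
                     deviate = pb, stringsAsFactors = FALSE)
        mu <- beta_growth(t_full, pbk[["Ym"]], pbk[["tc"]], pbk[["tm"]],
                          pbk[["te"]])
        for (leaf in c(3L, 4L)) {
          y <- pmax(0, mu + stats::rnorm(length(mu), 0, config$sigma_meas))
          keep <- maturity_cut(y, config$mature_mm, config$mature_runs)
          ser_rows[[length(ser_rows) + 1L]] <-
            data.frame(plant = truth$plant[i], block = b, period = per,
                       leaf = leaf, t = t_full[seq_len(keep)],
                       y = y[seq_len(keep)], stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- list(series = do.call(rbind, c(ser_rows, list(make.row.names = FALSE))),
              truth = do.call(rbind, c(par_rows, list(make.row.names = FALSE))),
              block_effects = block_effects,
              residuals = do.call(rbind, c(res_rows, list(make.row.names = FALSE))))
  attr(out, "n_resampled") <- n_resampled
  if (n_resampled > 0)
    message("simulate_phenotypes: resampled ", n_resampled,
            " deviate(s) violating tc <= tm < te")
  out
}

#' Simulate a trait-level phenotype table with known variance components
#'
#' Direct simulation at the adjusted-trait level (no growth curves):
#' `Y_ijk = mu + G_i + P_k + GxP_ik + B_j(k) + e_ijk` with independent
#' normal components. Used for variance-component and heritability
#' recovery experiments where the variance ratio must be exact.
#'
#' @param n_geno,n_blocks design size.
#' @param periods period labels (length 1 gives the per-period model).
#' @param mu grand mean (keep large enough that values stay positive).
#' @param sigma_G,sigma_GxP,sigma_E component standard deviations.
#' @param period_effects optional named fixed period effects.
#' @param block_sd sd of fixed block effects (drawn once).
#' @param trait trait label.
#' @param seed integer seed.
#' @return a [phenotype_table].
#' @export
simulate_trait_table <- function(n_geno, n_blocks = 3L, periods = "spring",
                                 mu = 300, sigma_G = 50, sigma_GxP = 0,
                                 sigma_E = 30, period_effects = NULL,
                                 block_sd = 5, trait = "Llength",
                                 seed = 1L) {
  set.seed(seed)
  genos <- sprintf("G%03d", seq_len(n_geno))
  blocks <- sprintf("B%d", seq_len(n_blocks))
  g <- stats::rnorm(n_geno, 0, sigma_G)
  rows <- list()
  for (per in periods) {
    pe <- if (!is.null(period_effects)) period_effects[[per]] else 0
    gp <- if (length(periods) > 1L) stats::rnorm(n_geno, 0, sigma_GxP) else 0
    be <- stats::rnorm(n_blocks, 0, block_sd)
    for (j in seq_len(n_blocks)) {
      rows[[length(rows) + 1L]] <- data.frame(
        plant = genos, block = blocks[j], period = per, trait = trait,
        value = mu + pe + g + gp + be[j] + stats::rnorm(n_geno, 0, sigma_E),
        stringsAsFactors = FALSE)
    }
  }
  phenotype_table(do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

#' Write / read a simulation configuration
#'
#' Flat YAML serialisation; the haplotype pool itself is stored as its
#' CSV fixture reference (counts + strings) so the file round-trips.
#'
#' @param config a [sim_config].
#' @param path file path.
#' @export
write_sim_config <- function(config, path) {
  x <- unclass(config)
  # yaml drops names on atomic vectors; store named vectors as maps
  for (v in c("effects", "baseline", "temperatures")) x[[v]] <- as.list(x[[v]])
  x$pool <- list(haplotype = x$pool$haplotypes$haplotype,
                 count = x$pool$haplotypes$count,
                 position = x$pool$sites$position,
                 alleles = x$pool$sites$alleles,
                 reported_freq = x$pool$sites$reported_freq,
                 snp_no = x$pool$sites$snp_no)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  sites <- snp_sites(data.frame(snp_no = x$pool$snp_no,
                                position = x$pool$position,
                                alleles = x$pool$alleles,
                                reported_freq = x$pool$reported_freq))
  pool <- haplotype_table(data.frame(haplotype_no = seq_along(x$pool$haplotype),
                                     haplotype = x$pool$haplotype,
                                     count = x$pool$count), sites)
  sim_config(seed = x$seed, n_plants = x$n_plants, n_blocks = x$n_blocks,
             periods = unlist(x$periods), pool = pool,
             causal_site = x$causal_site,
             effects = unlist(x$effects), effect_param = x$effect_param,
             sigma_G = x$sigma_G, sigma_GxP = x$sigma_GxP,
             sigma_B = x$sigma_B, sigma_PB = x$sigma_PB,
             sigma_meas = x$sigma_meas, baseline = unlist(x$baseline),
             temperatures = unlist(x$temperatures),
             cadence_days = x$cadence_days, max_days = x$max_days,
             mature_mm = x$mature_mm, mature_runs = x$mature_runs)
}
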