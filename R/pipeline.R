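## End-to-end orchestration: simulate -> fit kinetics -> heritability ->
## phase -> LD -> associate. Single-process and fully deterministic for
## a fixed configuration; each stage writes plain CSV/YAML under the run
## directory and a manifest records seeds and input hashes.

#' Pipeline configuration
#'
#' @param sim a [sim_config] (simulation stage; its seed drives every
#'   stochastic stage downstream).
#' @param grid_coarse use the thinned growth-fit seed grid (fast runs).
#' @param traits traits carried through the analysis stages.
#' @param n_perm permutations for the tree scan.
#' @param min_class minimum tree-scan class size.
#' @param alpha_entry,alpha_stay stepwise thresholds.
#' @param common_threshold carrier threshold for common haplotypes.
#' @param ld_threshold_bp LD-decay distance threshold (bp).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), grid_coarse = FALSE,
                            traits = c("Llength", "LERmax", "LED"),
                            n_perm = 1000L, min_class = 5L,
                            alpha_entry = 0.15, alpha_stay = 0.15,
                            common_threshold = 10L, ld_threshold_bp = 150) {
  stopifnot(inherits(sim, "sim_config"))
  structure(list(sim = sim, grid_coarse = grid_coarse, traits = traits,
                 n_perm = as.integer(n_perm), min_class = as.integer(min_class),
                 alpha_entry = alpha_entry, alpha_stay = alpha_stay,
                 common_threshold = as.integer(common_threshold),
                 ld_threshold_bp = ld_threshold_bp),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration (YAML)
#' @param config a [pipeline_config].
#' @param path file path.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  simpath <- paste0(path, ".sim")
  write_sim_config(x$sim, simpath)
  x$sim <- basename(simpath)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  sim <- read_sim_config(file.path(dirname(path), x$sim))
  pipeline_config(sim = sim, grid_coarse = x$grid_coarse,
                  traits = unlist(x$traits), n_perm = x$n_perm,
                  min_class = x$min_class, alpha_entry = x$alpha_entry,
                  alpha_stay = x$alpha_stay,
                  common_threshold = x$common_threshold,
                  ld_threshold_bp = x$ld_threshold_bp)
}

write_df <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8",
                   quote = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order, writing each stage's outputs
#' under `out_dir`: simulated genotypes and measurement series, fitted
#' growth parameters and per-plant traits, variance components and
#' heritabilities, adjusted means, phased haplotypes, LD matrix and
#' decay summary, the three association analyses, a YAML manifest (seed,
#' file hashes, package version) and a plain-text summary report. Reruns
#' with the same configuration produce byte-identical outputs.
#'
#' @param config a [pipeline_config].
#' @param out_dir run directory (created if missing).
#' @return invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(out_dir, f)

  ## stage 1: simulate
  pop <- simulate_population(config$sim)
  phen <- simulate_phenotypes(pop, config$sim)
  write_genotype_matrix(pop$genotypes, pth("genotypes.csv"))
  write_df(phen$series, pth("series.csv"))
  write_df(phen$truth, pth("truth_params.csv"))

  ## stage 2: fit kinetics
  fits <- fit_leaf_curves(phen$series, grid = seed_grid(config$grid_coarse))
  pheno <- traits_per_plant(fits)
  write_df(fits, pth("leaf_fits.csv"))
  write_phenotype_table(pheno, pth("phenotypes.csv"))

  ## stage 3: heritability
  comp_rows <- list()
  for (tr in config$traits) {
    for (per in config$sim$periods) {
      vc <- reml_components(pheno, tr, "per-period", period = per)
      comp_rows[[length(comp_rows) + 1L]] <- data.frame(
        trait = tr, period = per, sigma2_GE = vc$sigma2_GE,
        sigma2_E = vc$sigma2_E, sigma2_GExPeriod = NA_real_,
        h2 = heritability(vc))
    }
    if (length(config$sim$periods) > 1L) {
      vc <- reml_components(pheno, tr, "cross-period")
      comp_rows[[length(comp_rows) + 1L]] <- data.frame(
        trait = tr, period = "both", sigma2_GE = vc$sigma2_GE,
        sigma2_E = vc$sigma2_E, sigma2_GExPeriod = vc$sigma2_GExPeriod,
        h2 = heritability(vc))
    }
  }
  herit <- do.call(rbind, c(comp_rows, list(make.row.names = FALSE)))
  write_df(herit, pth("heritability.csv"))

  ## stage 4: adjusted means
  means <- adjusted_means(pheno, traits = config$traits,
                          periods = config$sim$periods)
  write_phenotype_table(means, pth("adjusted_means.csv"))

  ## stage 5: phase + LD
  phased <- em_phase(pop$genotypes)
  write_df(phased$assignments, pth("phased.csv"))
  ldm <- ld_matrix(phased, sites = config$sim$pool$sites)
  write_df(ldm, pth("ld_matrix.csv"))
  decay <- ld_decay(ldm, threshold_bp = config$ld_threshold_bp)
  yaml::write_yaml(decay[c("intercept", "slope", "fit_R2", "max_r2_beyond",
                           "threshold_bp")], pth("ld_decay.yaml"))

  ## stage 6: association
  design <- snp_design(pop$genotypes)
  step_rows <- list(); scheffe_rows <- list(); scan_rows <- list()
  freqs <- phased$frequencies
  common <- names(freqs)[vapply(names(freqs), function(h) {
    sum(phased$assignments$hap1 == h | phased$assignments$hap2 == h)
  }, numeric(1)) > config$common_threshold]
  tree <- NULL
  if (length(common) >= 4L && length(common) <= 12L) {
    labs <- stats::setNames(common, paste0("h", seq_along(common)))
    tree <- build_parsimony_tree(stats::setNames(unname(labs), names(labs)))
    ape::write.tree(tree, pth("haplotype_tree.nwk"))
  }
  for (tr in config$traits) for (per in config$sim$periods) {
    sw <- stepwise_snp_regression(means, design, tr, per,
                                  alpha_entry = config$alpha_entry,
                                  alpha_stay = config$alpha_stay)
    if (nrow(sw$selected)) {
      s <- sw$selected
      s$trait <- tr; s$period <- per; s$global_R2 <- sw$global_R2
      s$position <- config$sim$pool$sites$position[s$site]
      step_rows[[length(step_rows) + 1L]] <- s
    }
    sc <- haplotype_presence_contrasts(means, phased, tr, per,
                                       common_threshold = config$common_threshold)
    if (nrow(sc)) {
      sc$trait <- tr; sc$period <- per
      scheffe_rows[[length(scheffe_rows) + 1L]] <- sc
    }
    if (!is.null(tree)) {
      ts <- tree_scan(tree, phased, means, tr, per,
                      hap_labels = stats::setNames(common,
                                                   paste0("h", seq_along(common))),
                      n_perm = config$n_perm, min_class = config$min_class,
                      seed = config$sim$seed + 97L)
      ts$trait <- tr; ts$period <- per
      scan_rows[[length(scan_rows) + 1L]] <- ts
    }
  }
  rbind_rows <- function(rows) if (length(rows))
    do.call(rbind, c(rows, list(make.row.names = FALSE))) else NULL
  stepwise <- rbind_rows(step_rows)
  scheffe <- rbind_rows(scheffe_rows)
  scan <- rbind_rows(scan_rows)
  if (!is.null(stepwise)) write_df(stepwise, pth("stepwise.csv"))
  if (!is.null(scheffe)) write_df(scheffe, pth("scheffe_contrasts.csv"))
  if (!is.null(scan)) write_df(scan, pth("tree_scan.csv"))

  ## manifest + report
  files <- sort(list.files(out_dir, pattern = "\\.(csv|yaml|nwk)$"))
  manifest <- list(
    seed = config$sim$seed,
    package_version = as.character(utils::packageVersion("gaileaf")),
    n_plants = config$sim$n_plants,
    files = as.list(tools::md5sum(file.path(out_dir, files))))
  names(manifest$files) <- files
  yaml::write_yaml(manifest, pth("manifest.yaml"))

  report <- c(
    "Pipeline summary",
    "================",
    sprintf("Plants: %d; blocks: %d; periods: %s", config$sim$n_plants,
            config$sim$n_blocks, paste(config$sim$periods, collapse = ", ")),
    "",
    "Heritability (REML components):",
    utils::capture.output(print(herit, row.names = FALSE)),
    "",
    sprintf("LD decay: slope %.4f, max r2 beyond %g bp = %.4f",
            decay$slope, decay$threshold_bp, decay$max_r2_beyond),
    "",
    "Stepwise-selected SNPs (position, trait, period, partial R2):",
    if (!is.null(stepwise))
      sprintf("  pos%d %s %s partialR2=%.3f entry_p=%.4f",
              stepwise$position, stepwise$trait, stepwise$period,
              stepwise$partial_R2, stepwise$entry_p)
    else "  none",
    "",
    "Significant Scheffe contrasts (p_scheffe < 0.05):",
    if (!is.null(scheffe) && any(scheffe$p_scheffe < 0.05, na.rm = TRUE)) {
      sg <- scheffe[!is.na(scheffe$p_scheffe) & scheffe$p_scheffe < 0.05, ]
      sprintf("  %s %s %s p=%.4f", substr(sg$haplotype, 1, 8), sg$trait,
              sg$period, sg$p_scheffe)
    } else "  none",
    "",
    "Tree-scan branches with smallest Psim per trait/period:",
    if (!is.null(scan)) {
      best <- do.call(rbind, lapply(split(scan, paste(scan$trait, scan$period)),
                                    function(d) d[which.min(d$Psim), ]))
      sprintf("  %s %s branch{%s} F=%.2f Psim=%.4f PMon=%.4f",
              best$trait, best$period, best$side, best$F, best$Psim, best$PMon)
    } else "  no tree")
  writeLines(report, pth("report.txt"))

  invisible(list(pop = pop, phen = phen, fits = fits, pheno = pheno,
                 heritability = herit, means = means, phased = phased,
                 ld = ldm, decay = decay, stepwise = stepwise,
                 scheffe = scheffe, tree = tree, scan = scan,
                 out_dir = out_dir))
}
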