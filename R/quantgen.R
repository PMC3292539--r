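## ANOVA, REML variance components, broad-sense heritability and
## adjusted (least-squares) genotype means. Genotype is treated as fixed
## for F-tests and LS means and as random for variance components,
## mirroring the study's dual GLM / VARCOMP use.

pheno_subset <- function(pheno, trait, period = NULL) {
  d <- as.data.frame(pheno)
  d <- d[d$trait == trait, ]
  if (!is.null(period)) d <- d[d$period == period, ]
  if (nrow(d) == 0L) stop("no phenotype rows for trait ", trait,
                          if (!is.null(period)) paste0(" in period ", period))
  d$G <- factor(d$plant)
  d$B <- factor(d$block)
  d$P <- factor(d$period)
  d
}

#' Per-period two-way ANOVA with adjusted genotype means
#'
#' Fixed-effects model `Y_ij = mu + G_i + B_j + e_ij` fitted per period;
#' type-3 sums of squares (sum-to-zero contrasts) so unbalanced data
#' (dropped plants) are handled; genotype F-test against the residual;
#' adjusted genotype means are least-squares means.
#'
#' @param pheno a [phenotype_table].
#' @param trait trait name.
#' @param period period label.
#' @param compute_means also compute least-squares genotype means (set
#'   `FALSE` to skip the emmeans step in tight simulation loops).
#' @return list of class `anova_result`: `table` (per-effect df, SS, MS,
#'   F, p), `adjusted_means` (data.frame `plant`, `mean`; `NULL` when
#'   `compute_means = FALSE`), `cv_pct` (residual CV, percent of the
#'   trait mean), `sigma2_E` (residual mean square), `fit` (the `lm`).
#' @export
anova_per_period <- function(pheno, trait, period, compute_means = TRUE) {
  d <- pheno_subset(pheno, trait, period)
  if (nlevels(d$G) < 2L || nlevels(d$B) < 2L)
    stop("anova_per_period: need >= 2 genotypes and >= 2 blocks")
  tab <- table(d$G, d$B)
  if (any(rowSums(tab > 0) < 2L))
    warning("anova_per_period: some genotype(s) observed in a single block; ",
            "type-3 tests computed where estimable")
  fit <- stats::lm(value ~ G + B, data = d,
                   contrasts = list(G = "contr.sum", B = "contr.sum"))
  a3 <- tryCatch(car::Anova(fit, type = 3),
                 error = function(e) {
                   if (!grepl("residual sum of squares is 0",
                              conditionMessage(e))) stop(e)
                   # exact fit: sequential SS are the type-3 SS here and the
                   # genotype test is degenerate (p -> 0)
                   a <- stats::anova(fit)
                   a$`F value`[is.nan(a$`F value`)] <- Inf
                   a$`Pr(>F)`[seq_len(nrow(a) - 1L)] <- 0
                   a
                 })
  a3 <- a3[rownames(a3) %in% c("G", "B", "Residuals"), ]
  out_tab <- data.frame(effect = rownames(a3), df = a3$Df,
                        sum_sq = a3$`Sum Sq`,
                        mean_sq = a3$`Sum Sq` / a3$Df,
                        F = a3$`F value`, p = a3$`Pr(>F)`,
                        row.names = NULL)
  adj <- NULL
  if (compute_means) {
    em <- emmeans::emmeans(fit, "G")
    emdf <- as.data.frame(em)
    adj <- data.frame(plant = as.character(emdf$G), mean = emdf$emmean,
                      stringsAsFactors = FALSE)
  }
  s2e <- out_tab$mean_sq[out_tab$effect == "Residuals"]
  structure(list(table = out_tab, adjusted_means = adj,
                 cv_pct = 100 * sqrt(s2e) / mean(d$value),
                 sigma2_E = s2e, fit = fit),
            class = "anova_result")
}

#' Adjusted genotype means for every trait (and optionally per period)
#'
#' Convenience wrapper running [anova_per_period] per trait x period and
#' returning the LS means as a genotype-level [phenotype_table]
#' (`block = "adj"`).
#'
#' @param pheno a [phenotype_table].
#' @param traits traits to process (default: all present).
#' @param periods periods to process (default: all present).
#' @return a [phenotype_table] of adjusted means.
#' @export
adjusted_means <- function(pheno, traits = NULL, periods = NULL) {
  d <- as.data.frame(pheno)
  if (is.null(traits)) traits <- unique(d$trait)
  if (is.null(periods)) periods <- unique(d$period)
  rows <- list()
  for (tr in traits) for (per in periods) {
    a <- anova_per_period(pheno, tr, per)
    rows[[length(rows) + 1L]] <- data.frame(
      plant = a$adjusted_means$plant, block = "adj", period = per,
      trait = tr, value = a$adjusted_means$mean, stringsAsFactors = FALSE)
  }
  phenotype_table(do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

#' REML variance components
#'
#' Per-period model: `value ~ B (fixed) + (1 | G)` giving genotypic and
#' residual components. Cross-period model: period and block-within-
#' period fixed, genotype and genotype-by-period random:
#' `value ~ P + P:B + (1 | G) + (1 | G:P)`. Estimates are restricted
#' maximum likelihood with lme4's non-negativity constraint.
#'
#' @param pheno a [phenotype_table].
#' @param trait trait name.
#' @param model `"per-period"` or `"cross-period"`.
#' @param period period label (required for the per-period model).
#' @return list of class `variance_components` with `sigma2_GE`,
#'   `sigma2_E` and, for the cross-period model, `sigma2_GExPeriod`;
#'   plus `model` and the underlying `fit`.
#' @export
reml_components <- function(pheno, trait,
                            model = c("per-period", "cross-period"),
                            period = NULL) {
  model <- match.arg(model)
  if (model == "per-period") {
    if (is.null(period)) stop("reml_components: per-period model needs `period`")
    d <- pheno_subset(pheno, trait, period)
    fit <- lme4::lmer(value ~ B + (1 | G), data = d, REML = TRUE)
    vc <- as.data.frame(lme4::VarCorr(fit))
    out <- list(sigma2_GE = vc$vcov[vc$grp == "G"],
                sigma2_E = vc$vcov[vc$grp == "Residual"],
                sigma2_GExPeriod = NULL)
  } else {
    d <- pheno_subset(pheno, trait)
    if (nlevels(d$P) < 2L)
      stop("reml_components: cross-period model needs >= 2 periods")
    fit <- lme4::lmer(value ~ P + P:B + (1 | G) + (1 | G:P), data = d,
                      REML = TRUE)
    vc <- as.data.frame(lme4::VarCorr(fit))
    out <- list(sigma2_GE = vc$vcov[vc$grp == "G"],
                sigma2_E = vc$vcov[vc$grp == "Residual"],
                sigma2_GExPeriod = vc$vcov[vc$grp == "G:P"])
  }
  if (!isTRUE(fit@optinfo$conv$opt == 0))
    stop("reml_components: REML did not converge")
  structure(c(out, list(model = model, fit = fit)),
            class = "variance_components")
}

#' Broad-sense heritability from variance components
#'
#' Per-period: `h2 = s2_G / (s2_G + s2_E)`. Cross-period: the
#' genotype-by-period component joins the denominator,
#' `h2 = s2_G / (s2_G + s2_GxP + s2_E)`.
#'
#' @param vc a `variance_components` object, or a list/row with fields
#'   `sigma2_GE`, `sigma2_E` and (cross-period) `sigma2_GExPeriod`.
#' @param model `"per-period"` or `"cross-period"`; defaults to the
#'   model recorded in `vc`, else per-period.
#' @return h2 in `[0, 1]`.
#' @export
heritability <- function(vc, model = NULL) {
  if (is.null(model)) model <- if (!is.null(vc$model)) vc$model else "per-period"
  model <- match.arg(model, c("per-period", "cross-period"))
  s2g <- as.numeric(vc$sigma2_GE)
  s2e <- as.numeric(vc$sigma2_E)
  den <- s2g + s2e
  if (model == "cross-period") {
    s2gp <- as.numeric(vc$sigma2_GExPeriod)
    if (is.na(s2gp)) stop("heritability: cross-period model needs sigma2_GExPeriod")
    den <- den + s2gp
  }
  if (!is.finite(den) || den <= 0)
    stop("heritability: undefined, all variance components are zero")
  s2g / den
}

#' Closed-form expected-mean-squares variance components (balanced data)
#'
#' Method-of-moments solution for the balanced randomized-block design:
#' `s2_E = MS_resid`, `s2_G = (MS_G - MS_resid) / b` with `b` blocks
#' (per period), truncated at zero. Serves as the independent oracle for
#' the REML estimates on balanced designs.
#'
#' @inheritParams anova_per_period
#' @return list with `sigma2_GE`, `sigma2_E`.
#' @export
ems_components <- function(pheno, trait, period) {
  d <- pheno_subset(pheno, trait, period)
  tab <- table(d$G, d$B)
  if (!all(tab == 1L)) stop("ems_components: design must be balanced (one obs per cell)")
  fit <- stats::aov(value ~ G + B, data = d)
  ms <- summary(fit)[[1]][, "Mean Sq"]
  names(ms) <- trimws(rownames(summary(fit)[[1]]))
  b <- nlevels(d$B)
  list(sigma2_GE = max(0, (ms[["G"]] - ms[["Residuals"]]) / b),
       sigma2_E = ms[["Residuals"]])
}

#' Pearson correlations between traits on adjusted genotype means
#'
#' Correlates every pair of (trait, period) columns of a genotype-level
#' adjusted-means table; two-sided p-values with the usual significance
#' stars (`*` 0.05, `**` 0.01, `***` 0.001, `NS` otherwise).
#'
#' @param means a genotype-level [phenotype_table] (e.g. from
#'   [adjusted_means]).
#' @return data.frame: `var1`, `var2` (trait_period labels), `r`, `p`,
#'   `stars`, `n`.
#' @export
trait_correlations <- function(means) {
  d <- as.data.frame(means)
  d$var <- paste(d$trait, d$period, sep = "_")
  wide <- stats::reshape(d[, c("plant", "var", "value")],
                         idvar = "plant", timevar = "var",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  vars <- setdiff(names(wide), "plant")
  out <- list()
  for (i in seq_along(vars)) for (j in seq_len(i)) {
    x <- wide[[vars[i]]]; y <- wide[[vars[j]]]
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 3L) next
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      out[[length(out) + 1L]] <- data.frame(var1 = vars[j], var2 = vars[i],
                                            r = NA_real_, p = NA_real_,
                                            stars = "undefined", n = sum(ok))
      next
    }
    ct <- stats::cor.test(x[ok], y[ok])
    stars <- if (i == j) "" else if (ct$p.value < 0.001) "***"
      else if (ct$p.value < 0.01) "**"
      else if (ct$p.value < 0.05) "*" else "NS"
    out[[length(out) + 1L]] <- data.frame(var1 = vars[j], var2 = vars[i],
                                          r = unname(ct$estimate),
                                          p = ct$p.value, stars = stars,
                                          n = sum(ok))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Residual coefficient of variation from printed components
#'
#' `CV% = 100 * sqrt(sigma2_E) / mean`, recomputable from the packaged
#' variance-component and trait-summary fixtures.
#'
#' @param sigma2_E residual variance (squared trait units).
#' @param trait_mean trait mean (same units as the trait).
#' @return CV in percent.
#' @export
residual_cv <- function(sigma2_E, trait_mean) 100 * sqrt(sigma2_E) / trait_mean
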