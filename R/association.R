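## Three association methods between amplicon polymorphism and
## adjusted genotype means: (1) blockwise forward-backward stepwise
## regression on per-SNP genotype-class indicators, (2) Scheffe
## presence/absence contrasts for common haplotypes, (3) permutation
## tree-scanning on a maximum-parsimony haplotype tree.

#' Genotype-class design from an unphased genotype matrix
#'
#' Per plant x site a genotype class: `"11"` homozygous first listed
#' allele, `"22"` homozygous second, `"12"` heterozygous; triallelic
#' sites yield classes `"13"`, `"23"`, `"33"` etc. Classes are the
#' factor levels whose indicator dummies enter the stepwise regression
#' as a block.
#'
#' @param gm a [genotype_matrix].
#' @return character matrix (plants x sites) with class
#'   `snp_design`; missing calls are `NA`.
#' @export
snp_design <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  al <- site_alleles(gm$sites)
  out <- matrix(NA_character_, length(gm$plants), nrow(gm$sites),
                dimnames = dimnames(gm$calls))
  for (j in seq_len(nrow(gm$sites))) {
    cl <- gm$calls[, j]
    ok <- cl != "./."
    parts <- strsplit(cl[ok], "/", fixed = TRUE)
    idx <- vapply(parts, function(p) {
      k <- sort(match(p, al[[j]]))
      paste0(k[1], k[2])
    }, character(1))
    out[ok, j] <- idx
  }
  class(out) <- c("snp_design", class(out))
  out
}

means_vector <- function(means, trait, period) {
  d <- as.data.frame(means)
  d <- d[d$trait == trait & d$period == period, ]
  if (nrow(d) == 0L) stop("no adjusted means for ", trait, " / ", period)
  stats::setNames(d$value, d$plant)
}

#' Blockwise stepwise SNP regression on adjusted means
#'
#' Forward-backward stepwise selection where each SNP enters or leaves
#' as the block of its genotype-class dummies (joint partial F test).
#' A SNP enters when its block's F-test p-value is below `alpha_entry`
#' (smallest p first) and terms whose F-to-stay p exceeds `alpha_stay`
#' are removed. Partial R2 is the sequential (type-1) SS of the block at
#' entry divided by the total SS. Per-genotype-class effects are
#' reported as deviations from the population average: the class means
#' of the SNP's centred model-term contribution plus residual, so the
#' class-frequency-weighted effects sum to zero.
#'
#' @param means genotype-level [phenotype_table] of adjusted means.
#' @param design a [snp_design] matrix.
#' @param trait,period which adjusted means to model.
#' @param alpha_entry,alpha_stay entry / stay thresholds (defaults 0.15,
#'   the classical stepwise screening defaults).
#' @return list of class `stepwise_result`: `selected` (data.frame
#'   `site`, `snp_no`, `position`, `entry_p`, `partial_R2`),
#'   `effects` (data.frame `site`, `class`, `n`, `effect`),
#'   `global_R2`, `average`, `n`, `fit`.
#' @export
stepwise_snp_regression <- function(means, design, trait, period,
                                    alpha_entry = 0.15, alpha_stay = 0.15) {
  y <- means_vector(means, trait, period)
  plants <- intersect(names(y), rownames(design))
  if (length(plants) == 0L) stop("stepwise_snp_regression: no shared plant ids")
  y <- y[plants]
  X <- design[plants, , drop = FALSE]
  n_site <- ncol(X)
  if (length(y) <= 3L) stop("stepwise_snp_regression: too few genotypes")

  fac <- lapply(seq_len(n_site), function(j) factor(X[, j]))
  usable <- vapply(fac, function(f) nlevels(droplevels(f[!is.na(f)])) >= 2L,
                   logical(1))
  if (any(!usable))
    warning("stepwise_snp_regression: skipping ", sum(!usable),
            " monomorphic/constant site(s)")

  dat <- data.frame(y = y)
  for (j in seq_len(n_site)) dat[[paste0("s", j)]] <- fac[[j]]
  # listwise-complete across usable candidate sites so every partial-F
  # comparison sees the same observations
  cc <- stats::complete.cases(dat[, c(TRUE, usable), drop = FALSE])
  dat <- droplevels(dat[cc, , drop = FALSE])
  y <- dat$y
  usable <- usable & vapply(seq_len(n_site), function(j)
    nlevels(dat[[paste0("s", j)]]) >= 2L, logical(1))
  tss <- sum((y - mean(y))^2)

  selected <- integer(0)
  entry_p <- numeric(0)
  partial_r2 <- numeric(0)
  fit_formula <- function(sel) {
    rhs <- if (length(sel)) paste(paste0("s", sel), collapse = " + ") else "1"
    stats::as.formula(paste("y ~", rhs))
  }
  current_rss <- function(sel) {
    f <- stats::lm(fit_formula(sel), data = dat, na.action = stats::na.exclude)
    sum(stats::resid(f)^2, na.rm = TRUE)
  }

  repeat {
    changed <- FALSE
    # forward
    cand <- setdiff(which(usable), selected)
    if (length(cand)) {
      base_fit <- stats::lm(fit_formula(selected), data = dat)
      ps <- rep(NA_real_, length(cand)); rssd <- rep(NA_real_, length(cand))
      for (k in seq_along(cand)) {
        f1 <- tryCatch(stats::lm(fit_formula(c(selected, cand[k])), data = dat),
                       error = function(e) NULL)
        if (is.null(f1)) next
        an <- stats::anova(base_fit, f1)
        ps[k] <- an$`Pr(>F)`[2]
        rssd[k] <- an$`Sum of Sq`[2]
      }
      if (any(!is.na(ps)) && min(ps, na.rm = TRUE) < alpha_entry) {
        k <- which.min(ps)
        selected <- c(selected, cand[k])
        entry_p <- c(entry_p, ps[k])
        partial_r2 <- c(partial_r2, rssd[k] / tss)
        changed <- TRUE
      }
    }
    # backward
    if (length(selected) > 0L) {
      full <- stats::lm(fit_formula(selected), data = dat)
      pstay <- vapply(seq_along(selected), function(k) {
        red <- stats::lm(fit_formula(selected[-k]), data = dat)
        stats::anova(red, full)$`Pr(>F)`[2]
      }, numeric(1))
      if (max(pstay) > alpha_stay) {
        k <- which.max(pstay)
        selected <- selected[-k]
        entry_p <- entry_p[-k]
        partial_r2 <- partial_r2[-k]
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  fit <- stats::lm(fit_formula(selected), data = dat)
  global_r2 <- if (length(selected)) summary(fit)$r.squared else 0
  eff_rows <- list()
  if (length(selected)) {
    tt <- stats::predict(fit, type = "terms")
    res <- stats::resid(fit)
    for (k in seq_along(selected)) {
      j <- selected[k]
      contrib <- tt[, paste0("s", j)] + res
      cl <- as.character(dat[[paste0("s", j)]])
      eff <- tapply(contrib, cl, mean)
      eff_rows[[k]] <- data.frame(site = j,
                                  class = names(eff),
                                  n = as.integer(table(cl)[names(eff)]),
                                  effect = as.numeric(eff),
                                  row.names = NULL)
    }
  }
  structure(list(
    selected = data.frame(site = selected,
                          entry_p = entry_p, partial_R2 = partial_r2),
    effects = do.call(rbind, c(eff_rows, list(make.row.names = FALSE))),
    global_R2 = global_r2, average = mean(y), n = length(y), fit = fit),
    class = "stepwise_result")
}

#' @export
print.stepwise_result <- function(x, ...) {
  cat("stepwise_result:", nrow(x$selected), "SNP(s) selected; global R2 =",
      round(x$global_R2, 4), "; average =", signif(x$average, 4), "\n")
  if (nrow(x$selected)) print(x$selected)
  invisible(x)
}

#' Presence/absence haplotype contrasts with Scheffe's criterion
#'
#' For every haplotype carried by more than `common_threshold` plants
#' (carriers = plants holding at least one copy in their assigned phased
#' pair), tests presence versus absence on the adjusted means with a
#' one-way F test. Scheffe's simultaneous criterion over the family of
#' all `m` tested contrasts gives the adjusted p-value
#' `P(F_{m, n-2} >= F/m)`; the raw per-contrast p is also reported.
#'
#' @param means genotype-level [phenotype_table] of adjusted means.
#' @param phased a `phased_sample` (from [em_phase]) or a data.frame
#'   with `plant`, `hap1`, `hap2`.
#' @param trait,period which adjusted means to test.
#' @param common_threshold minimum number of carrier plants (strict:
#'   carriers must exceed it).
#' @return data.frame per tested haplotype: `haplotype`, `n_plus`,
#'   `n_minus`, `F`, `p_raw`, `p_scheffe`, `mean_plus`, `mean_minus`,
#'   `estimable`. Empty (with a message) if nothing passes the
#'   threshold.
#' @export
haplotype_presence_contrasts <- function(means, phased, trait, period,
                                         common_threshold = 10L) {
  asg <- if (inherits(phased, "phased_sample")) phased$assignments else phased
  y <- means_vector(means, trait, period)
  asg <- asg[asg$plant %in% names(y), ]
  y <- y[asg$plant]
  haps <- sort(unique(c(asg$hap1, asg$hap2)))
  carrier <- vapply(haps, function(h) asg$hap1 == h | asg$hap2 == h,
                    logical(nrow(asg)))
  n_carrier <- colSums(carrier)
  test_haps <- haps[n_carrier > common_threshold]
  if (length(test_haps) == 0L) {
    message("haplotype_presence_contrasts: no haplotype exceeds the carrier threshold")
    return(data.frame(haplotype = character(0), n_plus = integer(0),
                      n_minus = integer(0), F = numeric(0),
                      p_raw = numeric(0), p_scheffe = numeric(0),
                      mean_plus = numeric(0), mean_minus = numeric(0),
                      estimable = logical(0)))
  }
  m <- length(test_haps)
  n <- length(y)
  rows <- lapply(test_haps, function(h) {
    plus <- carrier[, h]
    if (all(plus) || !any(plus))
      return(data.frame(haplotype = h, n_plus = sum(plus),
                        n_minus = sum(!plus), F = NA_real_, p_raw = NA_real_,
                        p_scheffe = NA_real_, mean_plus = mean(y[plus]),
                        mean_minus = NA_real_, estimable = FALSE))
    fit <- stats::lm(y ~ plus)
    an <- stats::anova(fit)
    Fv <- an$`F value`[1]
    df2 <- an$Df[2]
    data.frame(haplotype = h, n_plus = sum(plus), n_minus = sum(!plus),
               F = Fv, p_raw = an$`Pr(>F)`[1],
               p_scheffe = stats::pf(Fv / m, m, df2, lower.tail = FALSE),
               mean_plus = mean(y[plus]), mean_minus = mean(y[!plus]),
               estimable = TRUE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "family_size") <- m
  out
}

#' Maximum-parsimony tree over common haplotypes
#'
#' Branch-and-bound maximum-parsimony search (Fitch length) over the
#' haplotype strings; ties between equally parsimonious topologies are
#' broken deterministically by the lexicographic order of their Newick
#' strings. Feasible for 4-12 haplotypes.
#'
#' @param haps named character vector: haplotype strings, names used as
#'   tip labels.
#' @return an unrooted `phylo` tree with attribute `parsimony_score`.
#' @export
build_parsimony_tree <- function(haps) {
  n <- length(haps)
  if (n < 4L || n > 12L)
    stop("build_parsimony_tree: need 4-12 haplotypes (got ", n,
         "); larger sets require a heuristic search, out of scope")
  if (is.null(names(haps))) names(haps) <- paste0("h", seq_along(haps))
  M <- hap_char_matrix(unname(haps))
  rownames(M) <- names(haps)
  pd <- phangorn::phyDat(M, type = "USER", levels = c("A", "C", "G", "T"))
  trees <- phangorn::bab(pd, trace = 0)
  if (!inherits(trees, "multiPhylo")) trees <- c(trees)
  nwk <- vapply(trees, function(tr)
    ape::write.tree(ape::ladderize(tr)), character(1))
  tree <- ape::unroot(trees[[order(nwk)[1]]])
  attr(tree, "parsimony_score") <-
    as.integer(phangorn::parsimony(tree, pd))
  tree
}

## classes 0/1/2 copies of one side of a branch, with small classes
## merged into the heterozygote class
branch_classes <- function(copies, min_class) {
  cl <- as.character(copies)
  repeat {
    tab <- table(cl)
    small <- names(tab)[tab < min_class]
    small <- setdiff(small, "1")
    if (length(small) == 0L) break
    cl[cl == small[1]] <- "1"
  }
  tab <- table(cl)
  if ("1" %in% names(tab) && tab[["1"]] < min_class && length(tab) > 1L) {
    other <- setdiff(names(tab), "1")
    target <- other[which.min(tab[other])]
    cl[cl == "1"] <- target
  }
  cl
}

#' Tree-scanning association on a haplotype tree
#'
#' Each interior branch of the unrooted haplotype tree bipartitions the
#' haplotypes; every plant is classed by how many of its two assigned
#' haplotypes (0/1/2) fall on one side. Classes smaller than `min_class`
#' are merged into the heterozygote class. Per branch, a one-way F test
#' of the adjusted means across classes; `Psim` is the per-branch
#' permutation p-value from `n_perm` phenotype permutations and `PMon`
#' a familywise step-down max-F permutation correction across branches.
#'
#' @param tree unrooted `phylo` over haplotype tip labels (see
#'   [build_parsimony_tree]).
#' @param phased a `phased_sample` or data.frame `plant`, `hap1`, `hap2`;
#'   plants carrying non-tree haplotypes are excluded (counted).
#' @param means genotype-level [phenotype_table] of adjusted means.
#' @param trait,period which adjusted means to test.
#' @param hap_labels named character vector mapping tip labels to
#'   haplotype strings (names = tip labels). If `NULL`, tip labels are
#'   taken to be the haplotype strings themselves.
#' @param n_perm number of phenotype permutations.
#' @param min_class minimum genotype-class size before merging.
#' @param seed integer seed for the permutation stream.
#' @return data.frame per testable branch: `branch`, `side` (tip labels
#'   on the clade side), `classes`, `F`, `df1`, `df2`, `Psim`, `PMon`;
#'   attributes `n_excluded_plants`, `n_skipped_branches`, `seed`.
#' @export
tree_scan <- function(tree, phased, means, trait, period, hap_labels = NULL,
                      n_perm = 5000L, min_class = 5L, seed = 1L) {
  asg <- if (inherits(phased, "phased_sample")) phased$assignments else phased
  y_all <- means_vector(means, trait, period)
  asg <- asg[asg$plant %in% names(y_all), ]
  tips <- tree$tip.label
  tipstr <- if (is.null(hap_labels)) stats::setNames(tips, tips) else hap_labels
  str2tip <- stats::setNames(names(tipstr), unname(tipstr))
  h1 <- str2tip[asg$hap1]
  h2 <- str2tip[asg$hap2]
  keep <- !is.na(h1) & !is.na(h2)
  n_excluded <- sum(!keep)
  asg <- asg[keep, ]; h1 <- h1[keep]; h2 <- h2[keep]
  y <- y_all[asg$plant]
  n <- length(y)
  if (n < 2L * min_class) stop("tree_scan: too few plants on the tree")

  spl <- as.matrix(phangorn::as.splits(ape::unroot(tree)))
  sides <- lapply(seq_len(nrow(spl)), function(k) sort(tips[spl[k, ] == 1]))
  # canonicalise each bipartition and keep interior branches only
  # (both sides >= 2 tips)
  sides <- unique(lapply(sides, function(s) {
    comp <- sort(setdiff(tips, s))
    if (paste(s, collapse = ",") < paste(comp, collapse = ",")) s else comp
  }))
  sides <- Filter(function(s)
    length(s) >= 2L && length(s) <= length(tips) - 2L, sides)

  branch_info <- list()
  skipped <- 0L
  for (s in sides) {
    copies <- (h1 %in% s) + (h2 %in% s)
    cl <- branch_classes(copies, min_class)
    if (length(unique(cl)) < 2L) { skipped <- skipped + 1L; next }
    branch_info[[length(branch_info) + 1L]] <-
      list(side = s, cl = factor(cl))
  }
  if (length(branch_info) == 0L)
    stop("tree_scan: no testable branch after class merging")

  f_stat <- function(yv, cl) {
    g <- nlevels(cl)
    m <- tapply(yv, cl, mean)
    nn <- tabulate(cl)
    ssb <- sum(nn * (m - mean(yv))^2)
    ssw <- sum((yv - m[cl])^2)
    if (ssb == 0) return(0)          # constant phenotype / no class signal
    if (ssw == 0) return(Inf)
    (ssb / (g - 1)) / (ssw / (length(yv) - g))
  }
  F_obs <- vapply(branch_info, function(b) f_stat(y, b$cl), numeric(1))
  set.seed(seed)
  F_perm <- matrix(NA_real_, n_perm, length(branch_info))
  for (p in seq_len(n_perm)) {
    yp <- sample(y)
    F_perm[p, ] <- vapply(branch_info, function(b) f_stat(yp, b$cl),
                          numeric(1))
  }
  psim <- vapply(seq_along(branch_info), function(k)
    (1 + sum(F_perm[, k] >= F_obs[k])) / (1 + n_perm), numeric(1))
  # step-down max-F familywise correction
  ord <- order(F_obs, decreasing = TRUE)
  pmon <- numeric(length(ord))
  for (r in seq_along(ord)) {
    set_k <- ord[r:length(ord)]
    mx <- apply(F_perm[, set_k, drop = FALSE], 1, max)
    pmon[ord[r]] <- (1 + sum(mx >= F_obs[ord[r]])) / (1 + n_perm)
    if (r > 1L) pmon[ord[r]] <- max(pmon[ord[r]], pmon[ord[r - 1L]])
  }
  out <- data.frame(
    branch = seq_along(branch_info),
    side = vapply(branch_info, function(b) paste(b$side, collapse = ","),
                  character(1)),
    classes = vapply(branch_info, function(b)
      paste(names(table(b$cl)), table(b$cl), sep = ":", collapse = " "),
      character(1)),
    F = F_obs,
    df1 = vapply(branch_info, function(b) nlevels(b$cl) - 1L, integer(1)),
    df2 = vapply(branch_info, function(b) n - nlevels(b$cl), integer(1)),
    Psim = psim, PMon = pmon)
  attr(out, "n_excluded_plants") <- n_excluded
  attr(out, "n_skipped_branches") <- skipped
  attr(out, "seed") <- seed
  out
}
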