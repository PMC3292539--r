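## Allele summaries, EM haplotype phasing (a maximum-likelihood stand-in
## for coalescent-based phasing of short amplicons), Hill-Robertson
## gametic r2 and LD-decay summaries, and a permutation G-test of
## genotypic LD.

#' Per-site allele summary
#'
#' Allele frequencies per site, rare-allele flags (minimum allele
#' frequency below 0.10) and the mean spacing between consecutive SNPs.
#'
#' @param x a [genotype_matrix] (frequencies from the diploid calls,
#'   missing excluded), a [haplotype_table] (count-weighted haplotype
#'   frequencies) or a [snp_sites] table (reported frequencies).
#' @param rare_threshold minor-allele frequency below which a site is
#'   flagged rare.
#' @return list: `sites` (data.frame `snp_no`, `position`, `freq_first`
#'   = frequency of the first listed allele, `min_freq`, `rare`),
#'   `mean_spacing` (bp, raw), `mean_spacing_rounded`, `n_rare`.
#' @export
snp_summary <- function(x, rare_threshold = 0.10) {
  if (inherits(x, "haplotype_table")) {
    sites <- x$sites
    M <- hap_char_matrix(x$haplotypes$haplotype)
    w <- x$haplotypes$count / sum(x$haplotypes$count)
    freq_of <- function(j, allele) sum(w[M[, j] == allele])
  } else if (inherits(x, "snp_sites")) {
    sites <- x
    fr <- site_freqs(sites)
    freq_of <- function(j, allele) unname(fr[[j]][allele])
  } else if (inherits(x, "genotype_matrix")) {
    sites <- x$sites
    freq_of <- function(j, allele) {
      cl <- x$calls[, j]
      cl <- cl[cl != "./."]
      a <- unlist(strsplit(cl, "/", fixed = TRUE))
      mean(a == allele)
    }
  } else stop("snp_summary: unsupported input")
  if (nrow(sites) < 2L) stop("snp_summary: need >= 2 sites")
  al <- site_alleles(sites)
  freq_first <- vapply(seq_len(nrow(sites)), function(j) freq_of(j, al[[j]][1]),
                       numeric(1))
  min_freq <- vapply(seq_len(nrow(sites)), function(j) {
    f <- vapply(al[[j]], function(a) freq_of(j, a), numeric(1))
    min(f[f > 0])
  }, numeric(1))
  df <- data.frame(snp_no = sites$snp_no, position = sites$position,
                   freq_first = freq_first, min_freq = min_freq,
                   rare = min_freq < rare_threshold)
  sp <- mean(diff(sites$position))
  list(sites = df, mean_spacing = sp, mean_spacing_rounded = round(sp),
       n_rare = sum(df$rare))
}

## ---- EM phasing ------------------------------------------------------

# All unordered haplotype pairs consistent with one plant's calls.
# Heterozygous sites contribute a phase choice; missing sites are free on
# both chromosomes.
consistent_pairs <- function(calls, alleles, max_expansions = 2^16) {
  n_site <- length(calls)
  opts <- vector("list", n_site)   # list of 2-row matrices (h1 allele, h2 allele)
  for (j in seq_len(n_site)) {
    cl <- calls[j]
    if (cl == "./.") {
      a <- alleles[[j]]
      g <- expand.grid(a, a, stringsAsFactors = FALSE)
      opts[[j]] <- t(as.matrix(g))
    } else {
      p <- strsplit(cl, "/", fixed = TRUE)[[1]]
      if (p[1] == p[2]) opts[[j]] <- matrix(p, nrow = 2)
      else opts[[j]] <- matrix(c(p[1], p[2], p[2], p[1]), nrow = 2)
    }
  }
  n_opt <- vapply(opts, ncol, integer(1))
  if (prod(n_opt) > max_expansions)
    stop("consistent_pairs: too many phase expansions (", prod(n_opt), ")")
  idx <- expand.grid(lapply(n_opt, seq_len))
  h1 <- h2 <- matrix("", nrow(idx), n_site)
  for (j in seq_len(n_site)) {
    h1[, j] <- opts[[j]][1, idx[[j]]]
    h2[, j] <- opts[[j]][2, idx[[j]]]
  }
  s1 <- apply(h1, 1, paste, collapse = "")
  s2 <- apply(h2, 1, paste, collapse = "")
  key <- paste(pmin(s1, s2), pmax(s1, s2))
  keep <- !duplicated(key)
  cbind(pmin(s1, s2)[keep], pmax(s1, s2)[keep])
}

#' EM haplotype phasing of unphased diploid genotypes
#'
#' Multinomial haplotype-frequency EM over all haplotype pairs consistent
#' with each plant's genotype (missing sites marginalised). Converges
#' when the largest frequency change is below `tol` (restricted log-
#' likelihood is checked to be non-decreasing each iteration). After
#' convergence, haplotypes below `prune` frequency are pruned and
#' frequencies renormalised; each plant is assigned its maximum-posterior
#' pair.
#'
#' @param gm a [genotype_matrix] with at most `max_sites` sites.
#' @param tol convergence tolerance on frequencies.
#' @param max_iter maximum EM iterations.
#' @param prune frequency below which haplotypes are pruned.
#' @param max_sites enumeration feasibility guard.
#' @return list of class `phased_sample`: `frequencies` (named, sums to
#'   1), `assignments` (data.frame `plant`, `hap1`, `hap2`, `posterior`),
#'   `loglik`, `n_iter`, `converged`.
#' @export
em_phase <- function(gm, tol = 1e-8, max_iter = 500L, prune = 1e-4,
                     max_sites = 30L) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (nrow(gm$sites) > max_sites)
    stop("em_phase: more than ", max_sites, " sites; enumeration infeasible")
  al <- site_alleles(gm$sites)
  n <- length(gm$plants)
  pairs <- vector("list", n)
  for (i in seq_len(n)) {
    for (j in seq_len(ncol(gm$calls))) {
      cl <- gm$calls[i, j]
      if (cl != "./." &&
          !all(strsplit(cl, "/", fixed = TRUE)[[1]] %in% al[[j]]))
        stop("em_phase: no consistent haplotype pair for plant ",
             gm$plants[i], " (illegal call ", cl, " at site ", j, ")")
    }
    pr <- consistent_pairs(gm$calls[i, ], al)
    if (nrow(pr) == 0L)
      stop("em_phase: no consistent haplotype pair for plant ", gm$plants[i])
    pairs[[i]] <- pr
  }
  haps <- sort(unique(unlist(pairs)))
  f <- stats::setNames(rep(1 / length(haps), length(haps)), haps)
  i1 <- lapply(pairs, function(p) match(p[, 1], haps))
  i2 <- lapply(pairs, function(p) match(p[, 2], haps))
  het <- lapply(pairs, function(p) ifelse(p[, 1] == p[, 2], 1, 2))

  loglik <- -Inf
  n_iter <- 0L
  converged <- FALSE
  repeat {
    n_iter <- n_iter + 1L
    cnt <- stats::setNames(numeric(length(haps)), haps)
    ll <- 0
    for (i in seq_len(n)) {
      w <- het[[i]] * f[i1[[i]]] * f[i2[[i]]]
      s <- sum(w)
      ll <- ll + log(s)
      w <- w / s
      for (k in seq_along(w)) {
        cnt[i1[[i]][k]] <- cnt[i1[[i]][k]] + w[k]
        cnt[i2[[i]][k]] <- cnt[i2[[i]][k]] + w[k]
      }
    }
    if (ll < loglik - 1e-9)
      stop("em_phase: log-likelihood decreased (", loglik, " -> ", ll, ")")
    loglik <- ll
    f_new <- cnt / (2 * n)
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) { converged <- TRUE; break }
    if (n_iter >= max_iter) break
  }

  f_kept <- f[f >= prune]
  f_kept <- f_kept / sum(f_kept)
  assign_one <- function(i, fr) {
    p1 <- fr[pairs[[i]][, 1]]; p2 <- fr[pairs[[i]][, 2]]
    p1[is.na(p1)] <- 0; p2[is.na(p2)] <- 0
    w <- het[[i]] * p1 * p2
    if (sum(w) == 0) return(NULL)
    w <- w / sum(w)
    k <- which.max(w)
    data.frame(plant = gm$plants[i], hap1 = pairs[[i]][k, 1],
               hap2 = pairs[[i]][k, 2], posterior = w[k],
               stringsAsFactors = FALSE)
  }
  rows <- lapply(seq_len(n), function(i) {
    r <- assign_one(i, f_kept)
    if (is.null(r)) r <- assign_one(i, f)   # all pairs pruned: fall back
    r
  })
  structure(list(frequencies = f_kept,
                 assignments = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 loglik = loglik, n_iter = n_iter, converged = converged),
            class = "phased_sample")
}

#' @export
print.phased_sample <- function(x, ...) {
  cat("phased_sample:", nrow(x$assignments), "plants,",
      length(x$frequencies), "haplotypes; EM",
      if (x$converged) "converged" else "NOT converged",
      "after", x$n_iter, "iterations\n")
  invisible(x)
}

## ---- gametic LD ------------------------------------------------------

#' Hill-Robertson gametic r2 between two sites
#'
#' From a haplotype frequency table: with A the first observed allele at
#' site i and B at site j, `D = p_AB - p_A p_B` and
#' `r2 = D^2 / (p_A (1 - p_A) p_B (1 - p_B))`.
#'
#' @param freqs named numeric vector of haplotype frequencies (names are
#'   haplotype strings, positions indexed by site order).
#' @param i,j site indices (1-based columns of the haplotype strings).
#' @return r2 in `[0, 1]`.
#' @export
gametic_r2 <- function(freqs, i, j) {
  a_i <- substr(names(freqs), i, i)
  a_j <- substr(names(freqs), j, j)
  ui <- unique(a_i[freqs > 0]); uj <- unique(a_j[freqs > 0])
  if (length(ui) != 2L || length(uj) != 2L)
    stop("gametic_r2: sites must be biallelic in the frequency table")
  pA <- sum(freqs[a_i == ui[1]])
  pB <- sum(freqs[a_j == uj[1]])
  pAB <- sum(freqs[a_i == ui[1] & a_j == uj[1]])
  D <- pAB - pA * pB
  # clamp float overshoot at the perfect-coupling boundary
  min(1, max(0, D^2 / (pA * (1 - pA) * pB * (1 - pB))))
}

#' Pairwise gametic LD matrix
#'
#' Computes [gametic_r2] for every pair of biallelic sites. Sites listed
#' with more than two alleles, or monomorphic in the frequency table,
#' are excluded (their count is reported as attribute `n_excluded`).
#'
#' @param x a [haplotype_table], or a `phased_sample` together with
#'   `sites`.
#' @param sites [snp_sites] (required when `x` is a `phased_sample`).
#' @return data.frame `site_i`, `site_j`, `pos_i`, `pos_j`, `distance`,
#'   `r2`, with attribute `n_excluded`.
#' @export
ld_matrix <- function(x, sites = NULL) {
  if (inherits(x, "haplotype_table")) {
    freqs <- haplotype_freqs(x)
    sites <- x$sites
  } else if (inherits(x, "phased_sample")) {
    if (is.null(sites)) stop("ld_matrix: sites required for a phased_sample")
    freqs <- x$frequencies
  } else stop("ld_matrix: unsupported input")
  n_site <- nrow(sites)
  n_all <- lengths(site_alleles(sites))
  obs_all <- vapply(seq_len(n_site), function(j)
    length(unique(substr(names(freqs)[freqs > 0], j, j))), integer(1))
  usable <- which(n_all == 2L & obs_all == 2L)
  n_excluded <- n_site - length(usable)
  rows <- list()
  for (ii in seq_along(usable)) for (jj in seq_len(ii - 1L)) {
    i <- usable[jj]; j <- usable[ii]
    rows[[length(rows) + 1L]] <- data.frame(
      site_i = i, site_j = j, pos_i = sites$position[i],
      pos_j = sites$position[j],
      distance = abs(sites$position[j] - sites$position[i]),
      r2 = gametic_r2(freqs, i, j))
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "n_excluded") <- n_excluded
  out
}

#' LD-decay summary
#'
#' Ordinary least squares of r2 on log distance
#' (`r2 = a + b log(distance)`), per-distance-bin mean r2, and the
#' maximum r2 among pairs separated by more than `threshold_bp`.
#'
#' @param ldm output of [ld_matrix] (>= 3 pairs).
#' @param threshold_bp distance beyond which the maximum r2 is reported.
#' @param bin_width width (bp) of the distance bins.
#' @return list: `intercept`, `slope`, `fit_R2`, `max_r2_beyond`,
#'   `threshold_bp`, `bins` (data.frame `mid`, `mean_r2`, `n`).
#' @export
ld_decay <- function(ldm, threshold_bp = 150, bin_width = 25) {
  if (nrow(ldm) < 3L) stop("ld_decay: need >= 3 site pairs")
  fit <- stats::lm(r2 ~ log(distance), data = ldm)
  beyond <- ldm$r2[ldm$distance > threshold_bp]
  br <- seq(0, max(ldm$distance) + bin_width, by = bin_width)
  bin <- cut(ldm$distance, br)
  bins <- data.frame(mid = (br[-length(br)] + br[-1]) / 2,
                     mean_r2 = as.numeric(tapply(ldm$r2, bin, mean))[
                       match(levels(bin), names(tapply(ldm$r2, bin, mean)))],
                     n = as.integer(table(bin)))
  bins <- bins[!is.na(bins$mean_r2), ]
  list(intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]),
       fit_R2 = suppressWarnings(summary(fit)$r.squared),
       max_r2_beyond = if (length(beyond)) max(beyond) else NA_real_,
       threshold_bp = threshold_bp, bins = bins)
}

#' Permutation G-test of genotypic LD between two sites
#'
#' Log-likelihood-ratio G statistic on the two-site genotype contingency
#' table (missing calls dropped); the null distribution is obtained by
#' permuting one site's genotype column; `p = (1 + #{G* >= G}) /
#' (1 + n_perm)`.
#'
#' @param gm a [genotype_matrix].
#' @param i,j site indices.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed for the permutation stream.
#' @return list: `G`, `p`, `n_perm`, `seed`, `table`.
#' @export
genotypic_ld_test <- function(gm, i, j, n_perm = 2000L, seed = 1L) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (n_perm < 100L) stop("genotypic_ld_test: n_perm must be >= 100")
  gi <- gm$calls[, i]; gj <- gm$calls[, j]
  ok <- gi != "./." & gj != "./."
  gi <- gi[ok]; gj <- gj[ok]
  if (length(unique(gi)) < 2L || length(unique(gj)) < 2L)
    stop("genotypic_ld_test: both sites must be polymorphic")
  g_stat <- function(a, b) {
    O <- table(a, b)
    E <- outer(rowSums(O), colSums(O)) / sum(O)
    nz <- O > 0
    2 * sum(O[nz] * log(O[nz] / E[nz]))
  }
  g_obs <- g_stat(gi, gj)
  set.seed(seed)
  g_perm <- vapply(seq_len(n_perm),
                   function(k) g_stat(gi, sample(gj)), numeric(1))
  list(G = g_obs, p = (1 + sum(g_perm >= g_obs)) / (1 + n_perm),
       n_perm = n_perm, seed = seed, table = table(gi, gj))
}

#' Bonferroni-summarised genotypic LD across all site pairs
#'
#' Computes the G statistic for every polymorphic pair and reports which
#' pairs remain significant at a familywise threshold after Bonferroni
#' correction across the tested pairs. The per-pair p-value here is the
#' asymptotic chi-square tail of G: a permutation p-value's resolution
#' floor of `1/(n_perm + 1)` cannot fall below a Bonferroni cut of
#' `alpha / n_pairs` at any affordable `n_perm`, so the permutation test
#' ([genotypic_ld_test]) is kept for single-pair inference while the
#' familywise scan relies on the asymptotic tail.
#'
#' @param gm a [genotype_matrix].
#' @param alpha familywise significance level (default 0.01).
#' @return data.frame `site_i`, `site_j`, `distance`, `G`, `df`, `p`,
#'   `significant` (Bonferroni at `alpha`).
#' @export
genotypic_ld_scan <- function(gm, alpha = 0.01) {
  n_site <- nrow(gm$sites)
  poly <- which(vapply(seq_len(n_site), function(j) {
    cl <- gm$calls[, j]; length(unique(cl[cl != "./."])) >= 2L
  }, logical(1)))
  rows <- list()
  for (a in seq_along(poly)) for (b in seq_len(a - 1L)) {
    i <- poly[b]; j <- poly[a]
    gi <- gm$calls[, i]; gj <- gm$calls[, j]
    ok <- gi != "./." & gj != "./."
    O <- table(gi[ok], gj[ok])
    E <- outer(rowSums(O), colSums(O)) / sum(O)
    nz <- O > 0
    G <- 2 * sum(O[nz] * log(O[nz] / E[nz]))
    df <- (nrow(O) - 1L) * (ncol(O) - 1L)
    rows[[length(rows) + 1L]] <- data.frame(
      site_i = i, site_j = j,
      distance = abs(gm$sites$position[j] - gm$sites$position[i]),
      G = G, df = df, p = stats::pchisq(G, df, lower.tail = FALSE))
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$significant <- out$p < alpha / nrow(out)
  out
}
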