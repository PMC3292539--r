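## Leaf growth kinetics: a beta growth function Y(t) describes leaf
## length (mm) against thermal time t (degree-days, Cd) with four
## parameters: Ym final length, tc start of elongation, tm time of
## maximum elongation rate, te end of elongation (tc <= tm < te).
## Fitting mimics a grid-seeded nonlinear least-squares protocol: Ym is
## pinned to the maximum observed length, (tc, tm, te) are grid-searched
## then refined by Levenberg-Marquardt.

check_beta_domain <- function(tc, tm, te) {
  if (any(!(tc <= tm & tm < te)))
    stop("beta growth parameters must satisfy tc <= tm < te")
}

#' Beta growth function for leaf elongation
#'
#' \deqn{Y(t) = Y_m (1 + \frac{t_e - t}{t_e - t_m})
#'   (\frac{t - t_c}{t_e - t_c})^{(t_e - t_c)/(t_e - t_m)}}
#' on \eqn{[t_c, t_e]}; \eqn{Y = Y_m} for \eqn{t > t_e} and \eqn{Y = 0}
#' for \eqn{t < t_c} (pre-emergence convention: the leaf has no length
#' before elongation starts).
#'
#' @param t thermal time in degree-days (vectorised).
#' @param Ym final leaf length (mm).
#' @param tc,tm,te start, inflection and end of elongation (degree-days);
#'   must satisfy `tc <= tm < te`.
#' @return leaf length (mm), same length as `t`.
#' @export
beta_growth <- function(t, Ym, tc, tm, te) {
  check_beta_domain(tc, tm, te)
  cc <- (te - tc) / (te - tm)
  u <- (t - tc) / (te - tc)
  y <- Ym * (1 + cc * (1 - u)) * u^cc
  y[t < tc] <- 0
  y[t > te] <- Ym
  y
}

#' Leaf elongation rate (first derivative of the growth function)
#'
#' Analytic derivative of [beta_growth] with respect to thermal time:
#' with \eqn{u = (t - t_c)/(t_e - t_c)} and
#' \eqn{c = (t_e - t_c)/(t_e - t_m)}, the rate is
#' \eqn{Y_m c (1 + c) u^{c-1} (1 - u) / (t_e - t_c)}. Outside
#' \eqn{[t_c, t_e]} the rate is 0 (no elongation). The maximum is
#' attained at \eqn{t_m}.
#'
#' @inheritParams beta_growth
#' @return elongation rate (mm per degree-day), same length as `t`.
#' @export
leaf_elongation_rate <- function(t, Ym, tc, tm, te) {
  check_beta_domain(tc, tm, te)
  cc <- (te - tc) / (te - tm)
  u <- (t - tc) / (te - tc)
  r <- Ym * cc * (1 + cc) / (te - tc) * u^(cc - 1) * (1 - u)
  r[t < tc | t > te] <- 0
  r
}

#' Seed grid for the growth-curve fit
#'
#' The full grid evaluates tc in 0..10 by 1, tm in 10.001..1000.001 by 10
#' and te in 150..1200 by 10 (triples with `tm >= te` are infeasible and
#' skipped). `coarse = TRUE` thins each axis for fast test runs.
#'
#' @param coarse logical; use a thinned grid.
#' @return data.frame of feasible `(tc, tm, te)` triples.
#' @export
seed_grid <- function(coarse = FALSE) {
  if (coarse) {
    g <- expand.grid(tc = seq(0, 10, by = 5),
                     tm = seq(10.001, 1000.001, by = 40),
                     te = seq(150, 1200, by = 40))
  } else {
    g <- expand.grid(tc = 0:10,
                     tm = 10.001 + 10 * (0:99),
                     te = seq(150, 1200, by = 10))
  }
  g[g$tm < g$te, , drop = FALSE]
}

## Precompute, for a fixed time vector, the normalised growth surface
## G[triple, time] = Y(t)/Ym for every feasible grid triple, so that the
## SSE over the grid for a series with the same t is a single mat-vec:
## SSE = Ym^2 * rowSums(G^2) - 2 Ym (G y) + sum(y^2).
grid_surface <- function(t, grid) {
  U <- outer(-grid$tc, t, "+") / (grid$te - grid$tc)
  C <- (grid$te - grid$tc) / (grid$te - grid$tm)
  G <- (1 + C * (1 - U)) * U^C
  G[U < 0] <- 0
  G[U > 1] <- 1
  list(G = G, g2 = rowSums(G * G))
}

grid_best_triple <- function(surf, grid, Ym, y) {
  sse <- Ym^2 * surf$g2 - 2 * Ym * drop(surf$G %*% y) + sum(y * y)
  grid[which.min(sse), ]
}

lm_refine <- function(t, y, Ym, start, tol = 1e-8) {
  # transformed variables enforce tc <= tm < te: theta = (tc, log(tm-tc), log(te-tm))
  th0 <- c(start$tc, log(max(start$tm - start$tc, 1e-3)), log(start$te - start$tm))
  resid_fn <- function(th) {
    tc <- th[1]; tm <- tc + exp(th[2]); te <- tm + exp(th[3])
    y - beta_growth(t, Ym, tc, tm, te)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = th0, fn = resid_fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 200, ftol = tol, ptol = tol)),
    error = function(e) NULL)
  if (is.null(fit) || !(fit$info %in% 1:4))
    return(list(ok = FALSE))
  th <- fit$par
  tc <- th[1]; tm <- tc + exp(th[2]); te <- tm + exp(th[3])
  list(ok = TRUE, tc = tc, tm = tm, te = te, rss = sum(resid_fn(th)^2))
}

#' Fit the beta growth curve to one leaf's measurement series
#'
#' `Ym` is fixed to the maximum observed length; `(tc, tm, te)` are
#' chosen by exhaustive residual-sum-of-squares evaluation over the
#' [seed_grid] and refined by Levenberg-Marquardt under the constraint
#' `tc <= tm < te` (enforced by a log-gap reparameterisation). Series
#' with no observable elongation (constant length) are flagged
#' non-converged.
#'
#' @param t thermal time (degree-days), strictly increasing, length >= 6.
#' @param y leaf length (mm), non-negative.
#' @param grid seed grid (see [seed_grid]).
#' @param tol Levenberg-Marquardt convergence tolerance.
#' @param surface optional precomputed `grid_surface` for this `t`
#'   (internal batch use).
#' @return one-row data.frame: `Ym`, `tc`, `tm`, `te`, `rss`,
#'   `converged`.
#' @export
fit_leaf_curve <- function(t, y, grid = seed_grid(), tol = 1e-8,
                           surface = NULL) {
  if (length(t) < 6L) stop("fit_leaf_curve: need at least 6 points")
  if (is.unsorted(t, strictly = TRUE)) stop("fit_leaf_curve: t must be strictly increasing")
  if (any(y < 0)) stop("fit_leaf_curve: lengths must be >= 0")
  Ym <- max(y)
  if (Ym <= 0 || diff(range(y)) < 1e-9)
    return(data.frame(Ym = Ym, tc = NA_real_, tm = NA_real_, te = NA_real_,
                      rss = NA_real_, converged = FALSE))
  if (nrow(grid) == 0L)
    return(data.frame(Ym = Ym, tc = NA_real_, tm = NA_real_, te = NA_real_,
                      rss = NA_real_, converged = FALSE))
  if (is.null(surface)) surface <- grid_surface(t, grid)
  best <- grid_best_triple(surface, grid, Ym, y)
  ref <- lm_refine(t, y, Ym, best, tol = tol)
  if (!ref$ok)
    return(data.frame(Ym = Ym, tc = NA_real_, tm = NA_real_, te = NA_real_,
                      rss = NA_real_, converged = FALSE))
  data.frame(Ym = Ym, tc = ref$tc, tm = ref$tm, te = ref$te, rss = ref$rss,
             converged = TRUE)
}

#' Derive leaf traits from fitted growth parameters
#'
#' Final length `Llength = Ym`; `tc5` is the thermal time at which the
#' leaf is 5 mm long (bracketed root of the growth curve, found to
#' 1e-3 degree-days); elongation duration `LED = te - tc5`; maximum
#' elongation rate `LERmax` is the analytic rate at `tm`.
#'
#' @param params one-row data.frame from [fit_leaf_curve] (converged).
#' @return the row augmented with `tc5`, `LED`, `LERmax`, `Llength`.
#' @export
derive_traits <- function(params) {
  stopifnot(nrow(params) == 1L)
  if (!isTRUE(params$converged)) stop("derive_traits: fit did not converge")
  if (params$Ym <= 5) stop("derive_traits: traits underivable, Ym <= 5 mm")
  Ym <- params$Ym; tc <- params$tc; tm <- params$tm; te <- params$te
  f <- function(t) beta_growth(t, Ym, tc, tm, te) - 5
  upper <- if (f(tm) >= 0) tm else te   # Y monotone: unique root below te
  tc5 <- stats::uniroot(f, lower = tc, upper = upper, tol = 1e-6,
                        extendInt = "no")$root
  params$tc5 <- tc5
  params$LED <- te - tc5
  params$LERmax <- leaf_elongation_rate(tm, Ym, tc, tm, te)
  params$Llength <- Ym
  params
}

#' Fit growth curves for a collection of measurement series
#'
#' Fits every (plant, block, period, leaf) series in a long-format
#' measurement table. The grid surface is cached per distinct
#' thermal-time vector, which makes fitting whole simulated experiments
#' (many leaves sharing a measurement calendar) fast.
#'
#' @param series data.frame with columns `plant`, `block`, `period`,
#'   `leaf`, `t`, `y`.
#' @param grid,tol see [fit_leaf_curve].
#' @param derive also derive `tc5`/`LED`/`LERmax` (rows that fail trait
#'   derivation are flagged non-converged).
#' @return data.frame: ids, fitted parameters, derived traits,
#'   `converged`.
#' @export
fit_leaf_curves <- function(series, grid = seed_grid(), tol = 1e-8,
                            derive = TRUE) {
  need <- c("plant", "block", "period", "leaf", "t", "y")
  stopifnot(all(need %in% names(series)))
  key <- interaction(series$plant, series$block, series$period, series$leaf,
                     drop = TRUE)
  cache <- new.env(parent = emptyenv())
  out <- lapply(split(series, key), function(d) {
    d <- d[order(d$t), ]
    tk <- paste(signif(d$t, 12), collapse = ",")
    surf <- cache[[tk]]
    if (is.null(surf)) {
      surf <- grid_surface(d$t, grid)
      assign(tk, surf, envir = cache)
    }
    fit <- fit_leaf_curve(d$t, d$y, grid = grid, tol = tol, surface = surf)
    if (derive && isTRUE(fit$converged) && fit$Ym > 5) {
      fit <- derive_traits(fit)
    } else if (derive) {
      fit$tc5 <- NA_real_; fit$LED <- NA_real_
      fit$LERmax <- NA_real_; fit$Llength <- fit$Ym
      fit$converged <- FALSE
    }
    cbind(d[1, c("plant", "block", "period", "leaf")], fit,
          row.names = NULL)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Per-plant leaf traits from fitted leaves
#'
#' Keeps only plant x block x period groups with converged fits for both
#' leaf ranks 3 and 4 (plants missing either leaf are dropped and
#' counted), then averages the two leaves' derived trait values.
#'
#' @param fits output of [fit_leaf_curves] with derived traits.
#' @param leaves the two leaf ranks that must both be present.
#' @return a [phenotype_table] (long format, traits `Llength`, `LERmax`,
#'   `LED`) with attribute `n_dropped` = number of plant x block x period
#'   groups discarded.
#' @export
traits_per_plant <- function(fits, leaves = c(3, 4)) {
  f <- fits[fits$converged %in% TRUE & fits$leaf %in% leaves, ]
  key <- interaction(f$plant, f$block, f$period, drop = TRUE)
  groups <- split(f, key)
  ok <- vapply(groups, function(g) all(leaves %in% g$leaf), logical(1))
  n_dropped <- length(unique(interaction(fits$plant, fits$block,
                                         fits$period, drop = TRUE))) - sum(ok)
  if (n_dropped > 0)
    message("traits_per_plant: dropped ", n_dropped,
            " plant x block x period group(s) lacking both leaves")
  rows <- lapply(groups[ok], function(g) {
    data.frame(plant = g$plant[1], block = g$block[1], period = g$period[1],
               trait = c("Llength", "LERmax", "LED"),
               value = c(mean(g$Llength), mean(g$LERmax), mean(g$LED)),
               stringsAsFactors = FALSE)
  })
  out <- phenotype_table(do.call(rbind, c(rows, list(make.row.names = FALSE))))
  attr(out, "n_dropped") <- n_dropped
  out
}
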