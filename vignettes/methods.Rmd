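---
title: "Models and methods: leaf growth kinetics and candidate-gene association in a synthetic ryegrass variety"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the growth model, the quantitative-genetic machinery, the haplotype and
LD analyses, the three association methods, and the synthetic-data
generator that ties them together. It also records the numerical choices
and the design decisions that were genuinely open.

## The study system

`gaileaf` re-implements a candidate-gene association analysis between
polymorphism in a 370 bp coding fragment of the gibberellic acid
insensitive gene (*GAI*) and leaf growth in 'Herbie', a synthetic
variety of perennial ryegrass (*Lolium perenne* L.). A synthetic variety
is produced by intercrossing many parents (here 336) and multiplying the
progeny panmictically; after several generations it carries wide allelic
diversity but no population substructure, and linkage disequilibrium
decays within a gene. Both properties make a candidate-gene association
scan valid without structure covariates: the package therefore fits no
kinship or structure terms, by design.

The package ships transcriptions of the published amplicon tables as
plain-CSV fixtures: `gai_snp_sites()` (20 SNPs, positions 6–228 bp, one
triallelic site at position 39) and `gai_haplotype_pool()` (39 phased
haplotypes whose inferred counts sum to 380 gametes = 2 × 190 sequenced
plants; 9 haplotypes exceed 10 copies). The phenotype data of the study
were never deposited, so every data-dependent stage is exercised on
synthetic populations with known ground truth instead; the
desk-checkable published quantities (SNP density, rare-allele counts,
heritabilities from printed variance components, the LD bound beyond
150 bp) are recomputed from the fixtures.

## Leaf growth kinetics

Leaf length $Y$ (mm) against thermal time $t$ (°Cd, the running sum of
daily mean air temperature above 0 °C since cutting) follows a beta
growth function with parameters $Y_m$ (final length), $t_c$ (start of
elongation), $t_m$ (time of maximum elongation rate) and $t_e$ (end of
elongation), $t_c \le t_m < t_e$:

$$Y(t) = Y_m\left(1 + \frac{t_e - t}{t_e - t_m}\right)
 \left(\frac{t - t_c}{t_e - t_c}\right)^{\frac{t_e - t_c}{t_e - t_m}},
 \qquad t_c \le t \le t_e,$$

with $Y = Y_m$ for $t > t_e$. For $t < t_c$ the function is undefined in
the source formulation; the package defines $Y = 0$ there (a leaf has no
length before initiation), which keeps residuals defined for early
readings. The analytic derivative gives the elongation rate; its
maximum, `LERmax` (mm °Cd⁻¹), is attained exactly at $t_m$. Because
fitted $t_c$ can be slightly negative without physiological meaning,
elongation duration is measured from $t_{c5}$, the time at which the
leaf is 5 mm long: `LED` $= t_e - t_{c5}$. $t_{c5}$ is found by a
bracketed root search on $[t_c, t_m]$ (extended to $t_e$ if needed — the
curve is monotone, so the root is unique whenever $Y_m > 5$) to
$10^{-3}$ °Cd.

**Fitting.** `fit_leaf_curve()` mimics a grid-seeded nonlinear
least-squares protocol: $Y_m$ is pinned to the maximum observed length
and never refined; $(t_c, t_m, t_e)$ are screened on the full seed grid
($t_c$ 0–10 by 1, $t_m$ 10.001–1000.001 by 10, $t_e$ 150–1200 by 10;
infeasible triples $t_m \ge t_e$ skipped — 75 449 feasible triples,
evaluated in one vectorised pass), then refined by Levenberg–Marquardt
(`minpack.lm::nls.lm`). The constraint $t_c \le t_m < t_e$ is enforced
without penalties by refining on $(t_c, \log(t_m - t_c),
\log(t_e - t_m))$. Constant series (no observable elongation) and
diverging refinements are flagged non-converged rather than guessed.
`fit_leaf_curves()` caches the grid surface per distinct thermal-time
vector, so fitting a whole simulated experiment (thousands of leaves on
a shared measurement calendar) costs one grid evaluation per calendar
plus one matrix–vector product per leaf. Only plants with converged
fits for **both** leaf ranks 3 and 4 are kept; the two leaves are
averaged. Whether the source protocol averaged or treated leaves as
repeated measures is not stated; averaging is the default and the leaf
ranks are an argument of `traits_per_plant()`.

## Quantitative genetics

Per period, a fixed-effects two-way model $Y_{ij} = \mu + G_i + B_j +
e_{ij}$ is fitted with type-3 sums of squares (sum-to-zero contrasts)
so that unbalanced data — plants dropped by the both-leaves rule — are
handled; adjusted genotype means are least-squares means
(`emmeans`). Variance components use REML (`lme4`), with genotype
random and block fixed; across periods the model adds fixed period and
block-within-period effects and a random genotype-by-period
interaction. Broad-sense heritability is
$h^2 = \sigma^2_G / (\sigma^2_G + \sigma^2_E)$ per period and
$h^2 = \sigma^2_G / (\sigma^2_G + \sigma^2_{G\times P} + \sigma^2_E)$
across periods. Genotype is deliberately treated as fixed for the
F-test/LS-means and random for components, mirroring the study's dual
GLM/VARCOMP usage. On balanced designs REML coincides with the
closed-form expected-mean-squares solution; `ems_components()` provides
that closed form and the tests assert agreement to $10^{-6}$ relative.

Applying the cross-period ratio to the *printed* cross-period
components does not reproduce the printed cross-period $H^2$ column
(e.g. LED: $4635/(4635+1680+928) \approx 0.64$ versus a printed 0.32);
the printed basis is unstated. The package reports the literal ratio
and prints both side by side in `analysis/06_published_tables.R` rather
than emulating an unknown rescaling.

## Phasing and linkage disequilibrium

Direct amplicon sequencing yields unphased diploid genotypes. The
original study phased them with a coalescent-informed Bayesian tool;
the package substitutes a multinomial **EM** algorithm
(`em_phase()`): all haplotype pairs consistent with each plant's calls
are enumerated (heterozygous sites contribute a phase choice, missing
sites are free on both chromosomes), haplotype frequencies are
maximum-likelihood estimates under random pairing, and each plant is
assigned its maximum-posterior pair. The restricted log-likelihood is
asserted non-decreasing every iteration; convergence is a maximum
frequency change below $10^{-8}$ (at most 500 iterations); haplotypes
below $10^{-4}$ frequency are pruned and frequencies renormalised. This
is a documented methodological substitution, not assumed equivalent:
its recovery is *measured* — on populations drawn from the published
pool (n = 400), ≥ 90% of plants get their true pair back and estimated
frequencies sit within 0.03 of the pool's.

Gametic LD between biallelic sites is the classical squared correlation
of gamete indicators, $r^2 = D^2 / (p_A(1-p_A)\,p_B(1-p_B))$ with
$D = p_{AB} - p_A p_B$, computed from count-weighted haplotype
frequencies. The triallelic site is excluded from the pairwise matrix
(the count of excluded sites is reported). `ld_decay()` summarises the
matrix by an OLS fit of $r^2$ on $\log(\text{distance})$, per-bin
means, and the maximum $r^2$ beyond a threshold distance (default
150 bp). Genotypic LD uses a log-likelihood-ratio G statistic on the
two-site genotype table with a seeded permutation null for single-pair
inference; the Bonferroni familywise scan uses the asymptotic
chi-square tail instead, because a permutation p-value's resolution
floor $1/(n_\mathrm{perm}+1)$ can never fall below
$\alpha/n_\mathrm{pairs}$ at an affordable $n_\mathrm{perm}$.

## The three association methods

All three operate on adjusted genotype means, separately per period.

**1. Blockwise stepwise SNP regression.** Each SNP enters or leaves the
multiple regression as the block of its genotype-class indicator
dummies (two dummies for a biallelic SNP), tested jointly by a partial
F. The published class effects include superdominant patterns, which a
single additive code cannot express — hence the class-indicator block.
Entry and stay thresholds default to 0.15, the classical stepwise
screening defaults, consistent with retained terms showing entry
p-values up to ≈ 0.145. Partial $R^2$ is the sequential
sum-of-squares of the block at entry over the total SS. Class effects
are reported as deviations from the population average, computed as
class means of the SNP's centred model-term contribution plus residual,
so the class-frequency-weighted effects sum to zero exactly.

**2. Scheffé presence/absence contrasts.** Every haplotype carried by
more than 10 plants (carriers = at least one copy in the assigned
maximum-posterior pair) is tested presence-versus-absence by a one-way
F on the adjusted means. Simultaneous control over the family of all
$m$ tested contrasts uses Scheffé's criterion; since the family
dimension of the original analysis is unstated, the package takes $m$ =
number of tested haplotypes and reports
$P(F_{m,\,n-2} \ge F/m)$ alongside the raw per-contrast p. This is
conservative; the null familywise error is verified below the nominal
level by simulation.

**3. Tree-scanning.** The common haplotypes are placed on an unrooted
maximum-parsimony tree (branch-and-bound, `phangorn::bab`; ties between
equally parsimonious topologies broken deterministically by Newick
lexicographic order). Each interior branch bipartitions the haplotypes;
plants are classed by carrying 0/1/2 copies of one side, classes below
the minimum size (default 5) are merged into the heterozygote class,
and a one-way F on the adjusted means is referenced to a seeded
permutation null (default 5000 phenotype permutations). The original
tool's "monotonicity" familywise correction is not algorithmically
specified anywhere; the package implements a step-down max-F
permutation correction across branches and labels it an analogue
(`PMon`). The published table's `Pvk` column is undefined in the source
text and is not reproduced.

## The synthetic-data generator

`simulate_population()` draws each plant's two gametes i.i.d. from the
count-weighted haplotype pool — the Hardy–Weinberg union of gametes of
a panmictic synthetic variety — and drops phase to produce the genotype
matrix. `simulate_phenotypes()` places all genetic and random effects
on **one** growth parameter (default $Y_m$): target = baseline +
genotype-class effect at one causal SNP + a genotypic deviate shared
across periods ($\sigma_G$) + a genotype-by-period deviate
($\sigma_{G\times P}$); per block an additive block effect
($\sigma_B$) and a residual plant-within-block deviate ($\sigma_{PB}$)
are added, and both leaves (ranks 3 and 4) share the plant parameters
while receiving independent N(0, $\sigma_\mathrm{meas}$) noise on each
reading, truncated at zero. Deviates that would break
$t_c \le t_m < t_e$ are resampled and counted.

Defaults are the study conditions: 200 plants × 3 blocks × 2 periods;
constant 16 °C (spring) and 13 °C (autumn) daily temperatures driving
the thermal-time axis; measurements every 7/3 days (three times a
week) for 60 days; baseline $(Y_m, t_c, t_m, t_e) = (316, 8, 160,
300)$, giving a ≈ 316 mm leaf with peak rate ≈ 1.7 mm °Cd⁻¹ and LED
≈ 270 °Cd, matching the published spring trait means; $\sigma_G = 67$
mm and $\sigma_{PB} = 34$ mm so the per-period variance components
match the printed spring leaf-length components (4524 and 1176 mm²);
$\sigma_{G\times P} = 30$ mm gives a clear genotype-by-period
interaction. The measurement-error magnitude is not reported anywhere;
$\sigma_\mathrm{meas} = 3$ mm is the package's one free choice (a
realistic ruler error for glasshouse length readings) and is exposed in
the configuration. A series is truncated once three consecutive
readings change by less than 1 mm, emulating the observers stopping at
maturity; with 3 mm noise this rule rarely engages before the campaign
ends, which is faithful to how noisy plateaus behave.

What the generator does **not** emulate: the four-generation polycross
pedigree (gametes are drawn directly from the pool), recombination
within the amplicon, selection, weather fluctuations (temperatures are
constant within period), and — because effects ride on a single
parameter — the joint variation of all four curve parameters. The last
point matters for interpretation: with default settings `Llength` and
`LERmax` are almost perfectly collinear across simulated plants,
whereas real leaves vary $t_c, t_m, t_e$ too. Passing tests therefore
demonstrate correctness of the machinery under a known single-parameter
genetic architecture, not realism of multi-parameter trait covariance.

## Numerical choices and degenerate inputs

* Grid-then-refine keeps the fitter deterministic; the LM refinement
  tolerance is $10^{-8}$ on both `ftol` and `ptol`, 200 iterations.
* $t_{c5}$ root search tolerance $10^{-6}$ °Cd (tighter than the
  $10^{-3}$ °Cd reporting requirement).
* EM tolerance $10^{-8}$ on frequencies; pruning threshold $10^{-4}$;
  plants whose every consistent pair was pruned fall back to the
  unpruned frequencies for assignment.
* $r^2$ is clamped to $[0, 1]$ against floating-point overshoot at
  perfect coupling.
* Permutation p-values use the add-one estimator
  $(1 + \#\{T^* \ge T\})/(1 + n_\mathrm{perm})$ and every permutation
  stream is seeded; reruns are byte-identical.
* Exact fits (zero residual) short-circuit the type-3 ANOVA: sequential
  SS are reported and the genotype p-value is 0 by convention.
* Degenerate inputs error loudly rather than silently: all-carrier
  contrasts are flagged inestimable, monomorphic SNPs are skipped with
  a warning, constant phenotypes give F = 0 and null p-values in the
  tree scan, and an all-zero variance decomposition makes `h2`
  undefined.

## Problem sizes used by the tests

The shipped tests run the full machinery at reduced but honest sizes
chosen to exercise every code path: 200-series fitter-recovery batches
on a shared calendar (the surface cache makes these cheap), 50
replicate heritability recoveries per target ratio at 100 genotypes ×
3 blocks, 500 null datasets for the permutation-test size check at 199
permutations each, 100 stepwise power replicates at n = 200, and one
full demo pipeline on 200 plants with the complete seed grid. The
acceptance script itself only performs the desk recomputations from
the packaged published tables and runs in seconds.

## Known limitations

* The EM phasing ignores the coalescent prior of the original tool; on
  short amplicons with strong LD its accuracy is high (measured, not
  assumed), but haplotypes absent from every plant's likely pairs
  cannot be recovered.
* The Scheffé family dimension and the tree-scan familywise correction
  are analogues of underspecified originals; both are conservative by
  construction.
* The stepwise procedure inherits the classical caveats of stepwise
  model selection: liberal screening admits noise terms under the null
  (verified ≈ 3 on average at n = 200 with 20 candidate SNPs), and a
  neighbouring SNP in LD with a causal site can enter first.
* Cross-period printed heritabilities cannot be reconciled with the
  printed components under the literal ratio (see above); the package
  refuses to guess the unstated basis.
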