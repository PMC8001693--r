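---
title: "Random regression evaluation of longevity under censored and penalized records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random regression evaluation of longevity under censored and penalized records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Cow longevity is scored late in life, and at any evaluation date many cows
are still alive or have an unreported culling date. A genetic evaluation
must either carry those animals as *censored* (their record simply stops
after the last reported calving) or *augment* their records by imputing a
plausible culling date — the penalty method. `longrrm` provides a complete,
simulation-backed workbench for studying how those two choices affect a
random regression genetic evaluation of two binary longevity indicators:

* **Traditional longevity (TL)** — coded 1 at every age (2–15 years) at
  which the cow is alive and 0 from the culling age onward.
* **Functional longevity (FL)** — coded 1 at ages with a recorded calving,
  0 from the culling age onward, and missing at alive ages without a
  calving.

The culling year itself is coded 0 for both indicators. That boundary is
genuinely ambiguous in the verbal definition ("0 after the cow was
culled"); coding the culling year 0 is symmetric across the two indicators
and keeps the invariant that every calving age strictly precedes the
culling age.

## The model

Both indicators are analyzed with the linear random regression animal model

$$
\mathbf{y} = \mathbf{X}\mathbf{b} + \mathbf{H}\mathbf{q} +
\mathbf{Z}\mathbf{a} + \mathbf{W}\mathbf{p} + \mathbf{e},
$$

where every random effect is a curve over age parameterized by $k$
coefficients on normalized Legendre polynomials (degree 4, i.e. $k = 5$, by
default; "order" is read as polynomial degree, and $k$ is configurable
because the animal-breeding literature uses the word for both
conventions). Age $t \in [2, 15]$ is standardized to
$t^\* = 2(t-2)/13 - 1$ and column $m$ of the covariate matrix
$\mathbf{T}$ holds $\phi_m(t^\*) = \sqrt{(2m+1)/2}\, P_m(t^\*)$.

* $\mathbf{b}$: systematic effects — an embryo-transfer covariate plus
  fixed Legendre regressions per year–season of birth, with a vague
  $N(0, 10^{10})$ prior per coefficient;
* $\mathbf{q}$: herd–year–season (HYS) random regressions,
  $\mathbf{q} \sim N(0, \mathbf{R}_q \otimes \mathbf{I})$;
* $\mathbf{a}$: additive genetic random regressions,
  $\mathbf{a} \sim N(0, \mathbf{G}_0 \otimes \mathbf{A})$ with
  $\mathbf{A}$ the pedigree relationship matrix ($\mathbf{A}^{-1}$ is
  assembled sparsely by Henderson's rules, with inbreeding via recursive
  kinship);
* $\mathbf{p}$: permanent-environment random regressions,
  $\mathbf{p} \sim N(0, \mathbf{R}_p \otimes \mathbf{I})$;
* $\mathbf{e} \sim N(0, \mathbf{I}\sigma^2_e)$, homogeneous across ages.

$\mathbf{G}_0$, $\mathbf{R}_q$, $\mathbf{R}_p$ carry inverted Wishart
priors ($\mathrm{IW}(3, 0.01\,\mathbf{I})$ by default — with $k = 5$ this
is improper, which the prior constructor flags; the posterior is proper
once data enter) and $\sigma^2_e$ a scaled inverted chi-squared prior.
Missing codes are simply absent rows: nothing is imputed by the model
itself, which is precisely why random regression handles censored
longevity records gracefully.

Age-scale parameters follow from the coefficient-scale posterior means:
$\Sigma = \mathbf{T}\mathbf{G}_0\mathbf{T}'$,
$\varphi = \mathbf{T}\mathbf{R}_q\mathbf{T}'$,
$\theta = \mathbf{T}\mathbf{R}_p\mathbf{T}'$,

$$
h^2_j = \frac{\sigma^2_{a_j}}{\sigma^2_{a_j} + \sigma^2_{q_j} +
\sigma^2_{p_j} + \sigma^2_e},
\qquad
\mathrm{EBV}_i = \mathbf{T}\hat{\mathbf{a}}_i .
$$

Heritabilities are computed from the posterior-mean covariance matrices
(a per-draw option would supply credible intervals; the posterior-mean
route is the standard reporting convention for this model class).

## Estimation: two routes, one model

1. **Direct BLUP** (`assemble_mme()`, `solve_blup()`): Henderson's mixed
   model equations with fixed variance components, assembled with sparse
   `Matrix` algebra and solved by sparse Cholesky. This route exists both
   as a production solver and as the oracle against which the sampler is
   tested.
2. **Gibbs sampling** (`gibbs_rrm()`): C++ sampler drawing every effect
   level's coefficient vector from its conditional normal, the covariance
   matrices from inverted Wishart full conditionals, and $\sigma^2_e$ from
   its scaled inverse chi-squared full conditional. All draws use the R
   RNG, so `set.seed()` governs the entire chain.

### Mixing, and two structural remedies

The additive and permanent-environment effects are both per-cow curves on
the same covariates; only the pedigree separates them. Plain single-site
scans therefore walk the $(\mathbf{G}_0, \mathbf{R}_p)$ ridge extremely
slowly — a property of the alternation itself, which we confirmed by
comparing chains against exact quadrature of the marginal posterior
(locations integrated analytically) on a small single-coefficient model.
Two exact remedies are built in:

* each recorded cow's additive and permanent-environment vectors are
  sampled **jointly** as one $2k$-dimensional conditional block;
* a **scale-swap Metropolis move** proposes, one coefficient at a time,
  $(\,a_{\cdot m},\, G_{0,mm}\,) \to (\sqrt{c}\,a_{\cdot m},\, c\,G_{0,mm})$
  together with the inverse rescaling of the PE side. The acceptance ratio
  is exact (likelihood × inverted Wishart prior × Jacobian; the Gaussian
  effect prior cancels against its own rescaled covariance), and the
  anti-correlated proposal travels along the confounded direction where
  the likelihood penalty is smallest. Acceptance rates near 20% at
  `swap_tau = 0.1` were observed across problem sizes.

Chain presets: `"full"` (150,000 / 50,000 / 10) is the production run
length customary for this model family; `"desk"` (5,000 / 1,000 / 5) is the default
used by the package's own validation studies. Even with the remedies
above, variance-component chains at desk length retain visible Monte Carlo
noise; `geweke_diagnostic()` and `heidelberger_welch()` (cross-checked
against the `coda` reference implementations) should be consulted on
`fit$draws` for any run that matters.

## The synthetic population

Because the motivating cattle records are proprietary, the package ships a
generator (`simulate_population()`) that emulates their statistical
structure: a multi-herd, multi-generation pedigree with random mating
within herd; additive effects following the pedigree with Mendelian
sampling variance $(0.5 - 0.25(F_s + F_d))\mathbf{G}_0$; iid HYS and PE
curves; and a discrete-time culling process. At each age $j$ a latent
production score

$$
\eta_{ij} = \mu_j + \phi(t_j)'(\mathbf{a}_i + \mathbf{p}_i +
\mathbf{q}_{\mathrm{hys}(i,j)}) + \beta_{ET}\,\mathrm{ET}_i + e_{ij}
$$

is evaluated and the cow is culled at the first age with
$\eta_{ij} < 0.5$ — the midpoint of the 0/1 coding scale, so that the
fitted linear model is approximately well specified. Default parameters
describe a low-heritability longevity trait (latent-scale age
heritabilities of roughly 0.08–0.14, annual culling probabilities of
12–20%, mean culling age near nine years, 15% calving skips with
reappearance, 5% embryo-transfer cows, first calvings at 22–29 months).
Cows never culled through age 15 receive a culling age drawn uniformly
from 16–20, emulating the natural-death inclusion rule. All noise is drawn
up-front with fixed dimensions, so configurations that share a seed share
their randomness (common random numbers): raising every survival intercept
can only delay culling.

Quality control removes cows born before 1990, cows without a first
calving before 30 months, and culling ages above 20. A cow culled at age 2
never calved and is therefore removed by the first-calving rule — which
means that after quality control the TL code at age 2 is structurally
constant. Age-2 estimates are consequently basis extrapolations, and the
generator's implied truth (below) is computed on the full pre-QC
population.

### What the generator does *not* emulate

No allele-level genetics, no culling-reason taxonomy, no heterogeneous
residual variances, no seasonal calving-interval structure, and no
relationship between herd size and recording quality. Passing recovery
tests on this generator demonstrates that the estimation machinery is
correct under its own assumptions — not that real beef-cattle data meet
those assumptions.

### The observed-scale generating truth

Thresholding a Gaussian latent score attenuates variance ratios: the
heritability of the recorded 0/1 codes is smaller than the latent-scale
ratio of the configured covariance matrices. Validation therefore compares
fits to `implied_heritability()`: the pedigree and additive effects are
simulated once, the environmental parts are redrawn `reps` times, and per
age the between-animal variance of the conditional code expectation
(bias-corrected one-way ANOVA estimator) is divided by the total code
variance. This is the generating value *on the scale the model actually
sees*. The embryo-transfer shift is switched off inside this computation
because the evaluation model absorbs it as a systematic effect.

## Censoring, penalties, and designs

`assign_censoring()` draws strictly nested censored sets (20% ⊂ 40% ⊂ 60%
⊂ 80%, sizes rounded to the nearest integer, no contemporary-group
balancing). Censoring erases the culling age and keeps calvings; trait
coding then truncates information after the last reported calving. The
three penalty criteria impute a culling age from the last reported calving
(`lc`):

| criterion | cow older than 9 years | cow 9 years or younger |
|---|---|---|
| m1 | `lc + 1` | `lc + 1` |
| m2 | `lc + 1` | stays censored |
| m3 | `lc + 1` | `lc + 2` |

The reference point for "older than nine years" is not pinned down by the
verbal description; the package defaults to the cow's age at the dataset
reference date (latest calving date in the population minus her birth
year) and exposes age-at-last-calving as an alternative
(`reference_age_source`), so the sensitivity of m2/m3 to this choice is
testable. Imputed ages are capped at the 20-year quality-control bound
with a warning. Penalized culling ages can reach the coding scale's upper
ages; for cows whose last calving fell just before their true culling age
the imputation is exact, which is why penalty methods preserve functional
longevity evaluations so well.

Two experimental designs disentangle information loss from dataset size:
design 1 keeps a fixed pool of uncensored cows and *adds* level% of that
pool as censored/penalized cows (55,000 → 99,000 at reference scale);
design 2 keeps the total fixed and converts level% of it (100,000 cows,
100,000 → 20,000 uncensored). `design_counts()` is the pure arithmetic;
`build_design()` realizes either design at any scale. The design-1 pool
shuffle is deliberately seeded independently of the replicate seed so the
pool is identical across replicates and only the censoring assignment
varies, mirroring how replicates are defined. Three replicates are the
reporting default.

## Scenario comparison

Each scenario is contrasted against the complete-data reference (COM),
fitted once per design and trait: proportions of commonly selected animals
(top 1% and 10% per age; reference-set denominator; ties broken by EBV
descending then animal id), Pearson EBV correlations over all animals and
ages together, age-four correlations split by censoring status (age four
is the conventional selection age for this trait family and is a
parameter), paired t-tests between scenario series (no multiplicity
correction by default, with `p.adjust` available), and replicate
mean/SD/SE aggregation.

## Numerical choices and degenerate inputs

* Fixed-effect block ridge-stabilized at $1/\sigma_b = 10^{-10}$; the BLUP
  solver reports its relative residual norm and errors above $10^{-6}$.
* Covariance draws and posterior means are checked for positive
  semi-definiteness; age-scale negative diagonals (possible only through
  rounding) are clipped at zero with a counted warning.
* Zero-variance chains, empty top sets, constant-difference t-tests, and
  censored cows without a calving anchor raise explicit errors rather
  than propagating `NaN`.
* All-zero covariance matrices are legal generator inputs (eigenvalue
  square roots, not Cholesky), giving exactly zero effects.

## Validation studies and their sizes

The shipped test-suite studies are sized for a single CPU: heritability
recovery uses three simulated populations of ≈1,700–1,800 cows (≈4,400
pedigree animals, k = 5) with the desk chain preset, compared to the
implied truth from 30 environmental redraws; the directional
censoring/penalty study uses one population of ≈800 cows with a 2,500
iteration chain over 14 scenario fits. At those sizes the directional
findings — commonly selected proportions falling monotonically with
censoring level, additive variance shrinking with censoring, penalty
criterion m1 preserving FL evaluations almost perfectly — reproduce with
wide margins, while per-age heritability recovery within ±0.05 holds in
the majority of replicates (chain noise at desk length remains the
binding constraint, which is why the recovery acceptance is defined over
two of three replicates).

## Known limitations

* The linear model on 0/1 codes is the evaluated design, not a
  proportional-hazards analysis; no threshold-model link is provided.
* Residual variance is homogeneous across ages.
* Variance-component mixing at desk chain lengths is adequate for
  directional contrasts but leaves per-age heritability estimates with
  Monte Carlo noise of a few hundredths; full-length chains reduce it.
* The scenario machinery treats censoring as non-informative (uniform
  random), as in the study design it implements; informative censoring is
  out of scope.
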