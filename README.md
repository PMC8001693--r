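# longrrm

Random regression genetic evaluation of beef-cattle longevity under
censored and penalty-augmented culling records.

## The problem

Longevity is scored late in life: at evaluation time many cows are still
alive or their culling was never reported. A breeding program must decide
whether to carry such cows as **censored** (their record simply stops
after the last reported calving) or to **augment** their records with the
penalty method (impute a culling date one or two years after the last
reported calving, possibly only for older cows). `longrrm` implements the
full study workbench for that question:

* simulation of a multi-generation pedigree and discrete-time cow
  culling/calving histories with known variance components;
* binary trait coding of **traditional longevity** (TL: 1 alive, 0 from
  culling) and **functional longevity** (FL: 1 at calving ages, 0 from
  culling, missing otherwise) over ages 2–15;
* nested random censoring (20% ⊂ 40% ⊂ 60% ⊂ 80%), three penalty
  criteria (m1/m2/m3, switching on a nine-year age threshold), and two
  experimental designs (fixed uncensored pool vs. fixed total);
* the random regression animal model
  `y = Xb + Hq + Za + Wp + e` on degree-4 normalized Legendre
  polynomials, with herd–year–season, additive genetic
  (`a ~ N(0, G0 ⊗ A)`) and permanent-environment random regressions —
  fitted either by sparse mixed-model equations (BLUP) or by a C++ Gibbs
  sampler with inverted Wishart variance updates;
* age-specific heritabilities `h2_j = s2_aj / (s2_aj + s2_qj + s2_pj +
  s2_e)` from `Sigma = T G0 T'` (and analogues), EBV trajectories
  `EBV_i = T a_i`;
* scenario comparison: proportions of commonly selected animals (top 1% /
  10% per age), EBV correlations (all animals and ages; age four split by
  censoring status), paired t-tests, replicate aggregation;
* Geweke and Heidelberger–Welch convergence diagnostics.

## Worked example

```r
library(longrrm)

set.seed(1)
cfg <- sim_config(n_base_animals = 240, n_generations = 3,
                  n_cows_target = 900, n_herds = 8, seed = 11)
pop <- simulate_population(cfg)       # pedigree + QC'd cow histories
nrow(pop$histories)
#> [1] 786

## complete-data reference vs 60% censoring, traditional longevity
com <- build_design(pop$histories,
                    spec = scenario_spec("D2_fixed_total", 0, "COM", 1, seed = 11))
cen <- build_design(pop$histories,
                    spec = scenario_spec("D2_fixed_total", 60, "CEN", 1, seed = 11))
ch  <- chain_config(2500, 600, 4, seed = 17)   # desk-scale chain
f_com <- fit_scenario(com, pop$pedigree, "TL", chain = ch)
f_cen <- fit_scenario(cen, pop$pedigree, "TL", chain = ch)

attr(cen, "manifest")$n_censored       # cows whose culling age was erased
#> [1] 472
round(top_overlap(f_com$ebv, f_cen$ebv, age = 4, fraction = 0.10), 3)
#> [1] 0.549
round(ebv_correlation(f_com$ebv, f_cen$ebv), 3)
#> [1] 0.711
```

The overlap says that with 60% of culling records censored, only ~55% of
the cows a breeder would keep (top 10% on age-4 EBV) coincide with the
complete-data choice, and EBVs across all animals and ages correlate at
only 0.71 with the complete-data evaluation. Single-fit variance
components carry visible Monte Carlo noise at this chain length; the
systematic effects of censoring on heritability and additive variance
emerge from the replicated factorial:
`run_study()` executes the whole design × level × treatment × replicate
factorial from one configuration and returns tidy contrast tables
(`summarize_study()` aggregates over replicates). A command-line wrapper
lives at `inst/cli/longrrm_run.R`.

The methods vignette (`vignettes/longrrm-methods.Rmd`) documents the
model, the generator, the penalty machinery, and every numerical choice.

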