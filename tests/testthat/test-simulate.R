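test_that("founder coefficient covariance recovers G0 (Monte Carlo)", {
  k <- 3
  cfg <- sim_config(n_base_animals = 10000, n_generations = 1,
                    n_cows_target = 10, n_herds = 5, k_coefficients = k,
                    G0_true = diag(c(0.03, 0.005, 0.002)),
                    Rq_true = diag(0.01, k), Rp_true = diag(0.01, k),
                    seed = 12)
  ped <- simulate_pedigree(cfg)
  eff <- simulate_genetic_effects(ped, cfg)
  f <- ped$sire == 0 & ped$dam == 0
  emp <- cov(eff$a[f, ])
  n <- sum(f)
  for (i in 1:k) for (j in 1:k) {
    # Monte-Carlo SE of a covariance entry of a Gaussian sample
    se <- sqrt((cfg$G0_true[i, i] * cfg$G0_true[j, j] +
                  cfg$G0_true[i, j]^2) / n)
    expect_lt(abs(emp[i, j] - cfg$G0_true[i, j]), 3 * se)
  }
})

test_that("zero additive covariance gives exactly zero effects", {
  cfg <- small_config()
  cfg$G0_true <- matrix(0, 3, 3)
  ped <- simulate_pedigree(cfg)
  eff <- simulate_genetic_effects(ped, cfg)
  expect_true(all(eff$a == 0))
  expect_false(all(eff$p == 0))
})

test_that("offspring effects center on the parent average", {
  # one sire, one dam, many full sibs: mean of a_offspring ~ (a_s + a_d)/2
  n_off <- 4000
  ped <- data.frame(id = 1:(n_off + 2),
                    sire = c(0, 0, rep(1, n_off)),
                    dam = c(0, 0, rep(2, n_off)),
                    sex = c("M", "F", rep("F", n_off)),
                    generation = c(0, 0, rep(1, n_off)),
                    birth_year = 2000, birth_season = 1, herd = 1,
                    et_flag = 0)
  class(ped) <- c("pedigree", "data.frame")
  cfg <- small_config(k = 3)
  eff <- simulate_genetic_effects(ped, cfg)
  pa <- (eff$a[1, ] + eff$a[2, ]) / 2
  off_mean <- colMeans(eff$a[-(1:2), ])
  se <- sqrt(0.5 * diag(cfg$G0_true) / n_off)
  expect_true(all(abs(off_mean - pa) < 4 * se))
})

test_that("degenerate survival intercepts behave as designed", {
  cfg <- small_config()
  cfg$sigma_e2_true <- 1e-12
  cfg$G0_true[] <- 0; cfg$Rq_true[] <- 0; cfg$Rp_true[] <- 0
  cfg$et_effect <- 0
  ped <- simulate_pedigree(cfg)
  eff <- simulate_genetic_effects(ped, cfg)
  cfg$baseline_survival <- rep(1, 14)   # eta = 1 >= 0.5: never culled by 15
  his <- simulate_cow_histories(ped, eff, cfg)
  expect_true(all(his$culling_age > 15))
  cfg$baseline_survival <- rep(0, 14)   # eta = 0 < 0.5: culled at age 2
  his0 <- simulate_cow_histories(ped, eff, cfg)
  expect_true(all(his0$culling_age == 2))
})

test_that("no calving skips means calving at every survived age", {
  cfg <- small_config()
  cfg$calving_skip_prob <- 0
  pop <- simulate_population(cfg)
  ok <- mapply(function(cv, ca) identical(cv, seq.int(2L, ca - 1L)),
               pop$histories$calving_ages,
               pmin(pop$histories$culling_age, 16L))
  expect_true(all(ok))
})

test_that("calving ages stay strictly below the culling age", {
  his <- small_population()$histories
  expect_true(all(mapply(function(cv, ca) !length(cv) || max(cv) < ca,
                         his$calving_ages, his$culling_age)))
})

test_that("raising survival intercepts never lowers a culling age (CRN)", {
  cfg <- small_config(seed = 31)
  pop1 <- simulate_population(cfg)
  cfg2 <- cfg
  cfg2$baseline_survival <- cfg$baseline_survival + 0.3
  ped <- simulate_pedigree(cfg2)
  eff <- simulate_genetic_effects(ped, cfg2)
  his2 <- simulate_cow_histories(ped, eff, cfg2)
  his1 <- simulate_cow_histories(ped, simulate_genetic_effects(ped, cfg), cfg)
  expect_true(all(his2$culling_age >= his1$culling_age))
})

test_that("quality control applies the three filters exactly", {
  h <- rbind(make_history(1, 8, 2:7),
             make_history(2, 8, 2:7, birth_year = 1989L),
             make_history(3, 20, 2:7),
             make_history(4, 21, 2:7),
             make_history(5, 8, 2:7))
  h$first_calving_age_months[5] <- 30L   # "before 30 months" is strict
  class(h) <- c("cow_histories", "data.frame")
  out <- apply_quality_control(h)
  expect_identical(out$cow, c(1L, 3L))
  counts <- attr(out, "qc_counts")
  expect_identical(unname(counts[c("born_before_cutoff",
                                   "no_early_first_calving",
                                   "culling_age_over_20")]),
                   c(1L, 1L, 1L))
  # all-compliant input passes through untouched
  ok <- rbind(make_history(1, 8, 2:7), make_history(2, 20, 2:7))
  class(ok) <- c("cow_histories", "data.frame")
  expect_equal(apply_quality_control(ok)$cow, ok$cow)
})

test_that("cow histories survive a text round-trip", {
  his <- small_population()$histories
  f <- tempfile(fileext = ".tsv")
  write_cow_histories(his, f)
  back <- read_cow_histories(f)
  expect_equal(back$cow, his$cow)
  expect_equal(back$culling_age, his$culling_age)
  expect_equal(back$calving_ages, unname(his$calving_ages))
  unlink(f)
})

test_that("identical configurations reproduce identical populations", {
  p1 <- simulate_population(small_config(seed = 19))
  p2 <- simulate_population(small_config(seed = 19))
  expect_identical(p1$pedigree, p2$pedigree)
  expect_identical(p1$effects, p2$effects)
  expect_equal(as.data.frame(p1$histories), as.data.frame(p2$histories))
})
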