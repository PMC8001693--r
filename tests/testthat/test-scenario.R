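test_that("nested censoring assignment has exact sizes and nesting", {
  ids <- sprintf("c%03d", 1:100)
  asg <- assign_censoring(ids, seed = 4)
  expect_equal(lengths(asg), c(S20 = 20L, S40 = 40L, S60 = 60L, S80 = 80L))
  expect_true(all(asg$S20 %in% asg$S40))
  expect_true(all(asg$S40 %in% asg$S60))
  expect_true(all(asg$S60 %in% asg$S80))
  expect_identical(assign_censoring(ids, seed = 4), asg)   # seed-stable
  expect_false(identical(assign_censoring(ids, seed = 5)$S20, asg$S20))
  expect_error(assign_censoring(ids[1:4], seed = 1), "at least 5")
  expect_error(assign_censoring(ids[1:10], seed = 1, base_n = 100),
               "rounding policy")
})

test_that("censoring removes the culling age and cannot be repeated", {
  h <- make_history(1, culling_age = 8, calvings = 2:7)
  cen <- censor_history(h)
  expect_true(is.na(cen$culling_age))
  expect_identical(cen$censoring_state, "censored")
  expect_identical(cen$calving_ages[[1]], 2:7)
  expect_error(censor_history(cen), "already censored")
})

test_that("the three penalty criteria impute as specified", {
  cen <- censor_history(make_history(1, 9, calvings = 2:6))  # last calving 6
  m1 <- penalize_history(cen, "m1")
  expect_equal(m1$culling_age, 7L)                      # one year after
  expect_identical(m1$censoring_state, "penalized-m1")
  m2y <- penalize_history(cen, "m2", reference_age = 8)
  expect_true(is.na(m2y$culling_age))                   # young cows stay censored
  expect_identical(m2y$censoring_state, "censored")
  m3y <- penalize_history(cen, "m3", reference_age = 8)
  expect_equal(m3y$culling_age, 8L)                     # two years after
  m2o <- penalize_history(cen, "m2", reference_age = 10)
  m3o <- penalize_history(cen, "m3", reference_age = 10)
  expect_equal(m2o$culling_age, 7L)
  expect_equal(m3o$culling_age, 7L)
  expect_error(penalize_history(cen, "m2"), "reference age")
  expect_error(penalize_history(make_history(1, 8, 2:7), "m1"),
               "censored records only")
  nocalv <- censor_history(make_history(2, 3, integer(0)))
  expect_error(penalize_history(nocalv, "m1"), "no calving")
  late <- censor_history(make_history(3, NA_integer_, calvings = c(2, 19),
                                      state = "uncensored"))
  expect_warning(p <- penalize_history(late, "m3", reference_age = 5),
                 "capped")
  expect_equal(p$culling_age, 20L)
})

test_that("censor-then-penalize composition restores last calving + 1", {
  h <- make_history(1, culling_age = 11, calvings = c(2:5, 7))
  out <- penalize_history(censor_history(h), "m1")
  expect_equal(out$culling_age, 8L)
})

test_that("design arithmetic yields the reference cow counts", {
  d1 <- t(vapply(c(0, 20, 40, 60, 80),
                 function(l) design_counts("D1_fixed_uncensored", l, 55000),
                 numeric(3)))
  expect_equal(d1[, "total"], c(55000, 66000, 77000, 88000, 99000))
  d2 <- t(vapply(c(0, 20, 40, 60, 80),
                 function(l) design_counts("D2_fixed_total", l, 100000),
                 numeric(3)))
  expect_equal(d2[, "uncensored"], c(100000, 80000, 60000, 40000, 20000))
  expect_equal(d2[, "total"], rep(100000, 5))
})

test_that("scenario specs validate the COM/level-0 equivalence", {
  expect_error(scenario_spec(level = 0, treatment = "CEN"), "level 0")
  expect_error(scenario_spec(level = 20, treatment = "COM"), "level 0")
  expect_error(scenario_spec(level = 30, treatment = "CEN"), "level must")
  s <- scenario_spec("D2_fixed_total", 40, "PENm2", 2, seed = 9)
  expect_s3_class(s, "scenario_spec")
})

test_that("build_design realizes both designs at scaled counts", {
  cows <- small_population()$histories
  n <- nrow(cows)
  s2 <- scenario_spec("D2_fixed_total", 40, "CEN", 1, seed = 3)
  ds2 <- build_design(cows, spec = s2)
  m2 <- attr(ds2, "manifest")
  expect_equal(m2$n_total, n)
  expect_equal(m2$n_censored, round(0.4 * n))
  expect_equal(sum(is.na(ds2$culling_age)), round(0.4 * n))

  s1 <- scenario_spec("D1_fixed_uncensored", 40, "CEN", 1, seed = 3)
  u <- floor(0.55 * n)
  ds1 <- build_design(cows, spec = s1)
  m1 <- attr(ds1, "manifest")
  expect_equal(m1$n_censored, round(0.4 * u))
  expect_equal(m1$n_total, u + round(0.4 * u))
  expect_equal(sum(ds1$censoring_state == "uncensored"), u)

  s0 <- scenario_spec("D2_fixed_total", 0, "COM", 1, seed = 3)
  ds0 <- build_design(cows, spec = s0)
  expect_true(all(ds0$censoring_state == "uncensored"))
  expect_equal(nrow(ds0), n)
})

test_that("design-1 keeps its uncensored pool fixed across replicates", {
  cows <- small_population()$histories
  d_r1 <- build_design(cows, spec = scenario_spec("D1_fixed_uncensored", 20,
                                                  "CEN", 1, seed = 11))
  d_r2 <- build_design(cows, spec = scenario_spec("D1_fixed_uncensored", 20,
                                                  "CEN", 2, seed = 12))
  pool1 <- d_r1$cow[d_r1$censoring_state == "uncensored"]
  pool2 <- d_r2$cow[d_r2$censoring_state == "uncensored"]
  expect_identical(sort(pool1), sort(pool2))
  expect_false(identical(sort(attr(d_r1, "censored_ids")),
                         sort(attr(d_r2, "censored_ids"))))
})

test_that("penalty criteria agree on cows older than nine years", {
  cows <- small_population()$histories
  base <- scenario_spec("D2_fixed_total", 60, "CEN", 1, seed = 21)
  ra <- longrrm:::reference_ages(cows, "reference_year")
  out <- lapply(c("PENm1", "PENm2", "PENm3"), function(tr) {
    sp <- scenario_spec("D2_fixed_total", 60, tr, 1, seed = 21)
    build_design(cows, spec = sp)
  })
  ids_old <- cows$cow[ra > 9]
  for (id in intersect(attr(out[[1]], "censored_ids"), ids_old)) {
    r <- match(id, cows$cow)
    expect_equal(out[[1]]$culling_age[r], out[[2]]$culling_age[r])
    expect_equal(out[[1]]$culling_age[r], out[[3]]$culling_age[r])
  }
  # m2's missing set contains m3's (young cows stay censored under m2 only)
  expect_true(all(out[[3]]$cow[is.na(out[[3]]$culling_age)] %in%
                    out[[2]]$cow[is.na(out[[2]]$culling_age)]))
  # m1 and m3 leave no unknown culling ages
  expect_false(anyNA(out[[1]]$culling_age))
  expect_false(anyNA(out[[3]]$culling_age))
})
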