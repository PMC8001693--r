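fake_ebv <- function(values, ids = NULL) {
  m <- matrix(rep(values, 14), ncol = 14,
              dimnames = list(ids %||% seq_along(values),
                              paste0("age", 2:15)))
  class(m) <- c("ebv_matrix", class(m))
  m
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("top-set overlap handles identity, reversal and swaps", {
  set.seed(4)
  v <- rnorm(100)
  e <- fake_ebv(v)
  expect_equal(top_overlap(e, e, age = 4, fraction = 0.10), 1)
  expect_equal(top_overlap(e, fake_ebv(-v), age = 4, fraction = 0.10), 0)
  # n = 10, top-2: swapping ranks 2 and 3 keeps one of the two selected
  r <- fake_ebv(10:1)
  alt <- fake_ebv(c(10, 8, 9, 7:1))
  expect_equal(top_overlap(r, alt, age = 7, fraction = 0.2), 0.5)
  expect_error(top_overlap(r, alt, age = 7, fraction = 0.01), "empty top set")
  expect_error(top_overlap(r, fake_ebv(1:5), age = 4), "different animal")
})

test_that("EBV correlations cover all scopes with exact oracles", {
  ids <- sprintf("a%02d", 1:20)
  set.seed(5)
  v <- rnorm(20)
  ref <- fake_ebv(v, ids)
  expect_equal(ebv_correlation(ref, ref), 1)
  expect_equal(ebv_correlation(ref, fake_ebv(-v + 7, ids)), -1)
  # textbook Pearson on 4 points
  r4 <- fake_ebv(c(1, 2, 3, 4), ids[1:4])
  a4 <- fake_ebv(c(1, 2, 3, 10), ids[1:4])
  num <- sum((c(1, 2, 3, 4) - 2.5) * (c(1, 2, 3, 10) - 4))
  den <- sqrt(sum((c(1, 2, 3, 4) - 2.5)^2) * sum((c(1, 2, 3, 10) - 4)^2))
  expect_equal(ebv_correlation(r4, a4), num / den)
  # age-4 scopes split by censoring status
  alt <- fake_ebv(v + rnorm(20, 0, 0.1), ids)
  cens <- ids[1:8]
  rc <- ebv_correlation(ref, alt, "age_censored", censored_ids = cens)
  ru <- ebv_correlation(ref, alt, "age_uncensored", censored_ids = cens)
  expect_equal(rc, cor(ref[1:8, "age4"], alt[1:8, "age4"]))
  expect_equal(ru, cor(ref[9:20, "age4"], alt[9:20, "age4"]))
  expect_error(ebv_correlation(ref, alt, "age_censored"), "censored_ids")
  expect_error(ebv_correlation(ref, fake_ebv(rep(1, 20), ids)),
               "zero variance")
  # affine invariance (sign-aware)
  expect_equal(ebv_correlation(ref, alt),
               ebv_correlation(fake_ebv(3 * v - 2, ids), alt))
})

test_that("paired t-tests match hand-computed values and handle edge cases", {
  eq <- paired_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)
  z <- paired_ttest(c(5, 3), c(4, 4))   # differences (1, -1): zero mean
  expect_equal(z$t, 0)
  expect_equal(z$p, 1)
  h <- paired_ttest(c(2, 3, 4), c(1, 1, 1))  # differences (1, 2, 3)
  expect_equal(h$t, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(h$p, 2 * pt(-h$t, df = 2), tolerance = 1e-12)
  expect_error(paired_ttest(c(2, 3, 4), c(1, 2, 3)), "degenerate")
  expect_error(paired_ttest(1, 1), "at least 2")
})

test_that("replicate aggregation reports mean, SD and SE conventions", {
  agg <- replicate_aggregate(c(0.7, 0.8, 0.9))
  expect_equal(agg$mean, 0.8)
  expect_equal(agg$sd, 0.1)
  expect_equal(agg$se, 0.1 / sqrt(3))
  one <- replicate_aggregate(0.5)
  expect_equal(one$sd, 0)
  expect_true(one$single_replicate)
  expect_equal(replicate_aggregate(rep(0.3, 4))$sd, 0)
})

test_that("pairwise scenario tests flag differences at alpha = 0.05", {
  set.seed(6)
  base <- rnorm(10)
  series <- list(A = base, B = base + 2 + rnorm(10, 0, 0.1),
                 C = base + rnorm(10, 0, 0.1))
  out <- pairwise_scenario_tests(series)
  expect_true(out$significant[out$a == "A" & out$b == "B"])
  expect_false(out$significant[out$a == "A" & out$b == "C"])
  adj <- pairwise_scenario_tests(series, p_adjust = "bonferroni")
  expect_true(all(adj$p >= out$p - 1e-12))
})
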