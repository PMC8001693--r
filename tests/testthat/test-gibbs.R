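# Sampler correctness on small models: BLUP equivalence under fixed
# variances, conjugate closed forms, prior reproduction, determinism.

test_that("chain configuration presets and validation", {
  desk <- chain_config()
  expect_equal(c(desk$length, desk$burn_in, desk$thin), c(5000L, 1000L, 5L))
  full <- chain_config(preset = "full")
  expect_equal(c(full$length, full$burn_in, full$thin),
               c(150000L, 50000L, 10L))
  expect_error(chain_config(1000, 2000), "burn_in")
  expect_error(chain_config(1000, 100, 0), "thin")
})

test_that("fixed-variance Gibbs means reproduce BLUP within Monte-Carlo error", {
  pop <- small_population(seed = 9, k = 2)
  basis <- legendre_basis(k = 2)
  his <- pop$histories[1:60, ]
  class(his) <- c("cow_histories", "data.frame")
  rec <- code_trajectories(his, "TL")
  dat <- rrm_data(rec, his, pop$pedigree, basis)
  ainv <- build_ainverse(pop$pedigree)
  vc <- variance_components(diag(0.05, 2), diag(0.03, 2), diag(0.04, 2), 0.2)
  bl <- solve_blup(assemble_mme(dat, vc, ainv = ainv))
  fit <- gibbs_rrm(dat, ainv, chain = chain_config(6000, 1000, 1, seed = 2),
                   start = vc, fix_variances = TRUE, store_locations = TRUE)
  draws <- fit$location_draws
  est <- colMeans(draws)
  se <- apply(draws, 2, mcmc_se)
  z <- abs(est - bl$solution) / pmax(se, 1e-12)
  expect_lt(stats::quantile(z, 0.99), 5)
  expect_lt(mean(z > 3), 0.02)
})

test_that("variance full conditional matches the closed conjugate form", {
  # near-noiseless records pin the HYS effects to their class means, so the
  # sampled Rq draws follow a known scaled inverse chi-squared distribution
  k <- 1
  nq <- 40; per <- 6
  ped <- data.frame(id = 1:3, sire = c(0, 0, 1), dam = c(0, 0, 2),
                    sex = c("M", "F", "F"), generation = c(0, 0, 1),
                    birth_year = rep(1995L, 3), birth_season = 1L,
                    herd = 1L, et_flag = 0L)
  class(ped) <- c("pedigree", "data.frame")
  set.seed(3)
  qtrue <- rnorm(nq, 0, 0.5)
  dat <- list(
    y = rep(qtrue, each = per) + rnorm(nq * per, 0, 1e-4),
    age_idx = rep(1L, nq * per),
    Phi = matrix(1, 14, 1),
    ys = rep(1L, nq * per), ys_levels = "1995-1",
    et = rep(0, nq * per),
    hys = rep(seq_len(nq), each = per), hys_levels = as.character(1:nq),
    anim = rep(3L, nq * per), animal_ids = ped$id,
    pe = rep(1L, nq * per), pe_levels = "3",
    basis = legendre_basis(k = 1, normalized = FALSE),
    cow = rep(3L, nq * per), age = rep(2L, nq * per), trait = "TL")
  class(dat) <- "rrm_data"
  ainv <- build_ainverse(ped)
  pr <- prior_spec(k = 1, V_q = matrix(0.04), iw_df = 4)
  st <- variance_components(matrix(1e-10), matrix(0.25), matrix(1e-10), 1e-8)
  fit <- gibbs_rrm(dat, ainv, priors = pr,
                   chain = chain_config(6000, 500, 1, seed = 5),
                   start = st, update_g = FALSE, update_p = FALSE,
                   update_e = FALSE)
  draws <- as.numeric(fit$draws$Rq)
  # q is pinned near the class means (fixed effect absorbs the global mean)
  qhat <- tapply(dat$y, dat$hys, mean)
  S <- sum((qhat - mean(qhat))^2)
  # the flat fixed regression absorbs the overall level: one df is lost and
  # the scale is the centered sum of squares (exact for k = 1)
  df <- pr$iw_df + nq - 1
  scale <- pr$V_q[1, 1] + S
  m_theory <- scale / (df - 2)
  v_theory <- 2 * scale^2 / ((df - 2)^2 * (df - 4))
  expect_lt(abs(mean(draws) - m_theory),
            3 * sqrt(v_theory / 200) + 0.02 * m_theory)
  expect_lt(abs(var(draws) - v_theory), 0.35 * v_theory)
})

test_that("with no records the residual variance reproduces its prior", {
  ped <- data.frame(id = 1:2, sire = 0L, dam = 0L, sex = c("M", "F"),
                    generation = 0L, birth_year = 1995L, birth_season = 1L,
                    herd = 1L, et_flag = 0L)
  class(ped) <- c("pedigree", "data.frame")
  dat <- list(y = numeric(0), age_idx = integer(0),
              Phi = matrix(1, 14, 1),
              ys = integer(0), ys_levels = character(0),
              et = numeric(0),
              hys = integer(0), hys_levels = as.character(1:5),
              anim = integer(0), animal_ids = ped$id,
              pe = integer(0), pe_levels = character(0),
              basis = legendre_basis(k = 1, normalized = FALSE),
              cow = integer(0), age = integer(0), trait = "TL")
  class(dat) <- "rrm_data"
  pr <- prior_spec(k = 1, resid_df = 5, resid_scale = 0.4)
  fit <- gibbs_rrm(dat, build_ainverse(ped), priors = pr,
                   chain = chain_config(5200, 200, 1, seed = 8),
                   update_locations = FALSE)
  # draws are iid from the scaled inverse chi-squared prior:
  # nu * s2 / sigma2 ~ chisq(nu)
  transformed <- pr$resid_df * pr$resid_scale / fit$sigma_e2
  ks <- suppressWarnings(stats::ks.test(transformed, stats::pchisq,
                                        df = pr$resid_df))
  expect_gt(ks$p.value, 0.01)
})

test_that("chains are reproducible under a fixed seed", {
  pop <- small_population(seed = 9, k = 2)
  basis <- legendre_basis(k = 2)
  rec <- code_trajectories(pop$histories, "TL")
  dat <- rrm_data(rec, pop$histories, pop$pedigree, basis)
  ainv <- build_ainverse(pop$pedigree)
  f1 <- gibbs_rrm(dat, ainv, chain = chain_config(400, 100, 2, seed = 42))
  f2 <- gibbs_rrm(dat, ainv, chain = chain_config(400, 100, 2, seed = 42))
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$location_mean, f2$location_mean)
  f3 <- gibbs_rrm(dat, ainv, chain = chain_config(400, 100, 2, seed = 43))
  expect_false(identical(f1$draws$G0, f3$draws$G0))
})

test_that("posterior summaries are means/SDs with PSD verification", {
  pop <- small_population(seed = 9, k = 2)
  basis <- legendre_basis(k = 2)
  rec <- code_trajectories(pop$histories, "TL")
  dat <- rrm_data(rec, pop$histories, pop$pedigree, basis)
  ainv <- build_ainverse(pop$pedigree)
  fit <- gibbs_rrm(dat, ainv, chain = chain_config(600, 100, 2, seed = 1))
  ps <- posterior_summarize(fit)
  expect_true(all(ps$psd))
  expect_equal(ps$mean$G0[1, 1], mean(fit$draws$G0[, "G0[1,1]"]))
  expect_equal(ps$sd$sigma_e2, sd(fit$sigma_e2))
  expect_true(isSymmetric(ps$mean$Rq))
  # two-draw chain: mean is the simple average
  fit2 <- fit
  fit2$draws <- lapply(fit$draws, function(m) m[1:2, , drop = FALSE])
  fit2$sigma_e2 <- fit$sigma_e2[1:2]
  fit2$n_saved <- 2L
  ps2 <- posterior_summarize(fit2)
  expect_equal(ps2$mean$G0[1, 1], mean(fit$draws$G0[1:2, "G0[1,1]"]))
  fit2$n_saved <- 1L
  expect_error(posterior_summarize(fit2), "two retained")
})
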