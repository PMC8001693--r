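make_small_system <- function(seed = 7, trait = "TL", k = 3) {
  pop <- small_population(seed = seed, k = k)
  basis <- legendre_basis(k = k)
  rec <- code_trajectories(pop$histories, trait)
  dat <- rrm_data(rec, pop$histories, pop$pedigree, basis)
  ainv <- build_ainverse(pop$pedigree)
  list(pop = pop, dat = dat, ainv = ainv, basis = basis)
}

test_that("model frame drops missing records and aligns maps", {
  s <- make_small_system(trait = "FL")
  expect_false(anyNA(s$dat$y))
  expect_true(all(s$dat$y %in% c(0, 1)))
  expect_equal(length(s$dat$y), length(s$dat$anim))
  expect_equal(length(s$dat$y), length(s$dat$hys))
  expect_true(all(s$dat$anim >= 1 & s$dat$anim <= nrow(s$pop$pedigree)))
})

test_that("BLUP solution matches a dense generalized least squares oracle", {
  s <- make_small_system()
  vc <- variance_components(diag(0.05, 3), diag(0.03, 3), diag(0.04, 3), 0.2)
  sys <- assemble_mme(s$dat, vc, ainv = s$ainv)
  bl <- solve_blup(sys)
  expect_lt(bl$residual_norm, 1e-8)
  # dense oracle: build the same normal equations with base R matrices
  des <- longrrm:::rrm_design(s$dat)
  M <- as.matrix(des$M)
  k <- 3
  D <- as.matrix(Matrix::bdiag(
    Matrix::Diagonal(des$blocks$ys + 1, 1e-10),
    diag(des$blocks$hys / k) %x% solve(vc$Rq),
    as.matrix(s$ainv) %x% solve(vc$G0),
    diag(des$blocks$pe / k) %x% solve(vc$Rp)))
  C <- crossprod(M) / vc$sigma_e2 + D
  sol <- solve(C, crossprod(M, s$dat$y) / vc$sigma_e2)
  expect_equal(bl$solution, as.numeric(sol), tolerance = 1e-8)
})

test_that("duplicating every record leaves the solution unchanged", {
  s <- make_small_system()
  pop <- s$pop
  rec <- code_trajectories(pop$histories, "TL")
  rec2 <- rbind(rec, rec)
  attr(rec2, "trait") <- "TL"
  class(rec2) <- class(rec)
  dat2 <- rrm_data(rec2, pop$histories, pop$pedigree, s$basis)
  vc <- variance_components(diag(0.05, 3), diag(0.03, 3), diag(0.04, 3), 0.2)
  b1 <- solve_blup(assemble_mme(s$dat, vc, ainv = s$ainv))
  # doubled records at the same residual variance = halved variance once:
  # scale invariance of the normal equations requires scaling R too
  vc2 <- variance_components(vc$G0, vc$Rq, vc$Rp, vc$sigma_e2 * 2)
  b2 <- solve_blup(assemble_mme(dat2, vc2, ainv = s$ainv))
  expect_equal(b2$solution, b1$solution, tolerance = 1e-8)
})

test_that("record order does not change the solution", {
  s <- make_small_system()
  pop <- s$pop
  rec <- code_trajectories(pop$histories, "TL")
  set.seed(1)
  perm <- rec[sample(nrow(rec)), ]
  attr(perm, "trait") <- "TL"
  class(perm) <- class(rec)
  datp <- rrm_data(perm, pop$histories, pop$pedigree, s$basis)
  vc <- variance_components(diag(0.05, 3), diag(0.03, 3), diag(0.04, 3), 0.2)
  b1 <- solve_blup(assemble_mme(s$dat, vc, ainv = s$ainv))
  b2 <- solve_blup(assemble_mme(datp, vc, ainv = s$ainv))
  expect_equal(b2$anim, b1$anim, tolerance = 1e-8)
  expect_equal(b2$hys, b1$hys, tolerance = 1e-8)
})

test_that("vanishing random-effect variances collapse BLUP to fixed OLS", {
  s <- make_small_system()
  tiny <- 1e-10
  vc <- variance_components(diag(tiny, 3), diag(tiny, 3), diag(tiny, 3), 0.3)
  bl <- solve_blup(assemble_mme(s$dat, vc, ainv = s$ainv))
  # oracle: plain linear model on the fixed part only
  phi <- s$dat$Phi[s$dat$age_idx, ]
  Xf <- model.matrix(~ 0 + factor(s$dat$ys))[, , drop = FALSE]
  X <- cbind(Xf[, rep(seq_len(ncol(Xf)), each = 3)] *
               phi[, rep(1:3, ncol(Xf))], s$dat$et)
  ols <- lm.fit(X, s$dat$y)
  fitted_blup <- rowSums(phi * bl$ys[s$dat$ys, , drop = FALSE]) +
    bl$et * s$dat$et
  expect_equal(unname(fitted_blup), unname(ols$fitted.values),
               tolerance = 1e-5)
  # random-effect solutions are shrunk to zero
  expect_lt(max(abs(bl$anim)), 1e-6)
})

test_that("animals without records get nonzero solutions via the pedigree", {
  s <- make_small_system()
  vc <- variance_components(diag(0.05, 3), diag(0.03, 3), diag(0.04, 3), 0.2)
  bl <- solve_blup(assemble_mme(s$dat, vc, ainv = s$ainv))
  ped <- s$pop$pedigree
  recorded <- unique(s$dat$cow)
  sires <- unique(ped$sire[ped$id %in% recorded & ped$sire != 0])
  unrecorded_sires <- setdiff(sires, recorded)
  expect_gt(length(unrecorded_sires), 0)
  expect_gt(max(abs(bl$anim[as.character(unrecorded_sires), ])), 1e-6)
})
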