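# Simulation configuration for the synthetic longevity population.

default_G0 <- function() diag(c(0.030, 0.005, 0.002, 0.001, 0.0005))
default_Rq <- function() diag(c(0.016, 0.003, 0.001, 0.0005, 0.00025))
default_Rp <- function() diag(c(0.024, 0.004, 0.0015, 0.0008, 0.0004))

is_psd <- function(M, tol = 1e-8) {
  is.matrix(M) && nrow(M) == ncol(M) &&
    max(abs(M - t(M))) < 1e-8 &&
    min(eigen(M, symmetric = TRUE, only.values = TRUE)$values) > -tol
}

#' Configuration of the synthetic cow population
#'
#' Bundles every parameter of the data-generating process: pedigree structure,
#' herd-year-season layout, the true random regression covariance matrices on
#' the Legendre coefficient scale, and the discrete-time culling/calving
#' process over ages 2-15.
#'
#' The default covariance matrices and baseline survival intercepts describe a
#' beef-cow population with low longevity heritability (latent-scale
#' age-specific heritabilities of roughly 0.08-0.14), an annual culling
#' probability near 12-20% (mean culling age around nine years), occasional
#' skipped calvings with later reappearance, and a small proportion of
#' embryo-transfer calves.
#'
#' @param n_base_animals number of founder animals (>= 2, and at least two per
#'   herd so every herd has both sexes).
#' @param n_generations number of non-founder generations (>= 1).
#' @param n_cows_target approximate number of cows (non-founder females) to
#'   produce across all generations.
#' @param n_herds number of herds.
#' @param seasons_per_year number of calving seasons per year (default 2).
#' @param year_range inclusive integer span of birth years, length-2 vector.
#' @param k_coefficients Legendre coefficients per random effect (default 5,
#'   i.e. polynomial degrees 0-4).
#' @param G0_true,Rq_true,Rp_true true additive-genetic, herd-year-season and
#'   permanent-environment covariance matrices (k x k, coefficient scale).
#' @param sigma_e2_true true residual variance of the latent culling score.
#' @param baseline_survival length-14 vector of per-age survival intercepts
#'   for ages 2-15; a cow is culled at the first age where her latent score
#'   falls below 0.5.
#' @param calving_skip_prob probability that a surviving cow skips calving in
#'   a given year (she may reappear later).
#' @param et_proportion proportion of embryo-transfer cows.
#' @param et_effect fixed latent-scale shift applied to embryo-transfer cows
#'   (systematic effect of the evaluation model).
#' @param first_calving_months_range integer range (months) of first-calving
#'   age; must stay below 30 months to pass quality control.
#' @param use_inbreeding logical; account for parental inbreeding in the
#'   Mendelian sampling variance (can be switched off for speed).
#' @param seed integer seed driving the whole simulation.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_base_animals = 400,
                       n_generations = 3,
                       n_cows_target = 2000,
                       n_herds = 10,
                       seasons_per_year = 2,
                       year_range = c(1990, 2015),
                       k_coefficients = 5,
                       G0_true = default_G0(),
                       Rq_true = default_Rq(),
                       Rp_true = default_Rp(),
                       sigma_e2_true = 0.16,
                       baseline_survival = seq(1.05, 0.85, length.out = 14),
                       calving_skip_prob = 0.15,
                       et_proportion = 0.05,
                       et_effect = 0.10,
                       first_calving_months_range = c(22, 29),
                       use_inbreeding = TRUE,
                       seed = 1L) {
  k <- as.integer(k_coefficients)
  cfg <- list(
    n_base_animals = as.integer(n_base_animals),
    n_generations = as.integer(n_generations),
    n_cows_target = as.integer(n_cows_target),
    n_herds = as.integer(n_herds),
    seasons_per_year = as.integer(seasons_per_year),
    year_range = as.integer(year_range),
    k_coefficients = k,
    G0_true = G0_true, Rq_true = Rq_true, Rp_true = Rp_true,
    sigma_e2_true = sigma_e2_true,
    baseline_survival = baseline_survival,
    calving_skip_prob = calving_skip_prob,
    et_proportion = et_proportion,
    et_effect = et_effect,
    first_calving_months_range = as.integer(first_calving_months_range),
    use_inbreeding = isTRUE(use_inbreeding),
    seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_base_animals < 2L) stop("n_base_animals must be >= 2")
    if (n_base_animals < 2L * n_herds)
      stop("need at least two founders per herd (both sexes): ",
           "n_base_animals >= 2 * n_herds")
    if (n_generations < 1L) stop("n_generations must be >= 1")
    if (n_cows_target < 1L) stop("n_cows_target must be >= 1")
    if (length(year_range) != 2L || diff(year_range) < 0)
      stop("year_range must be an inclusive integer span c(min, max)")
    if (k_coefficients < 1L) stop("k_coefficients must be >= 1")
    for (nm in c("G0_true", "Rq_true", "Rp_true")) {
      M <- get(nm)
      if (!is_psd(M)) stop(nm, " must be a symmetric PSD matrix")
      if (nrow(M) != k_coefficients)
        stop(nm, " must be k_coefficients x k_coefficients")
    }
    if (sigma_e2_true <= 0) stop("sigma_e2_true must be > 0")
    if (length(baseline_survival) != 14L)
      stop("baseline_survival must have one intercept per age 2-15 (14 values)")
    for (p in c(calving_skip_prob, et_proportion))
      if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
    if (first_calving_months_range[2L] >= 30L)
      stop("first calvings must occur before 30 months to pass quality control")
    if (first_calving_months_range[1L] > first_calving_months_range[2L])
      stop("invalid first_calving_months_range")
  })
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic longevity population configuration\n")
  cat("  founders:", x$n_base_animals, " generations:", x$n_generations,
      " target cows:", x$n_cows_target, "\n")
  cat("  herds:", x$n_herds, " seasons/year:", x$seasons_per_year,
      " birth years:", paste(x$year_range, collapse = "-"), "\n")
  cat("  k =", x$k_coefficients, "Legendre coefficients; sigma_e2 =",
      x$sigma_e2_true, "\n")
  invisible(x)
}
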