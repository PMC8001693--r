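# Gibbs sampling front end: chain configuration, the sampler wrapper and
# posterior summaries.

#' MCMC chain configuration
#'
#' Two presets are provided: `"full"` (150,000 iterations, 50,000 burn-in,
#' thinning 10 - the production run length customary for this class of evaluation) and
#' `"desk"` (5,000 / 1,000 / 5), sized for workstation-scale validation runs.
#' Explicit values override the preset.
#'
#' @param length,burn_in,thin chain length, burn-in and thinning stride.
#' @param seed integer seed for the whole chain.
#' @param preset `"desk"` or `"full"`.
#' @return object of class `chain_config`.
#' @export
chain_config <- function(length = NULL, burn_in = NULL, thin = NULL,
                         seed = 1L, preset = c("desk", "full")) {
  preset <- match.arg(preset)
  def <- if (preset == "full") c(150000L, 50000L, 10L) else c(5000L, 1000L, 5L)
  cfg <- list(length = as.integer(length %||% def[1L]),
              burn_in = as.integer(burn_in %||% def[2L]),
              thin = as.integer(thin %||% def[3L]),
              seed = as.integer(seed), preset = preset)
  if (cfg$burn_in >= cfg$length) stop("burn_in must be smaller than length")
  if (cfg$thin < 1L) stop("thin must be >= 1")
  structure(cfg, class = "chain_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the random regression model by Gibbs sampling
#'
#' Runs the blocked single-site Gibbs sampler: every effect level's
#' coefficient vector is drawn from its conditional normal (with the
#' pedigree links of `A^-1` entering the additive-genetic conditionals), the
#' coefficient covariance matrices from their inverted Wishart full
#' conditionals, and the residual variance from its scaled inverted
#' chi-squared full conditional. Retained draws are
#' `floor((length - burn_in) / thin)`.
#'
#' @param data an [rrm_data()] model frame.
#' @param ainv sparse `A^-1` over `data$animal_ids` (see [build_ainverse()]).
#' @param priors a [prior_spec()].
#' @param chain a [chain_config()].
#' @param start optional [variance_components()] starting (or fixed) values.
#' @param fix_variances logical; keep all variance components at `start`
#'   (turns the sampler into a location-only sampler whose posterior mean is
#'   the BLUP solution).
#' @param update_locations logical; with `FALSE` the location effects stay at
#'   zero and only variance components are sampled.
#' @param store_locations logical; store every retained location draw
#'   (memory-heavy, meant for small models and Monte-Carlo error checks).
#' @param swap_tau,swap_moves proposal scale (log domain) and number of
#'   proposals per iteration for the additive/permanent-environment
#'   scale-swap Metropolis move (see Details).
#' @return object of class `rrm_fit` with elements `draws` (matrices of
#'   retained variance-component draws), `location_mean` (posterior means
#'   split by effect, as in [solve_blup()]), `n_saved`, `chain`, `priors`,
#'   `trait`, `basis`, and optionally `location_draws`.
#' @export
gibbs_rrm <- function(data, ainv, priors = prior_spec(k = data$basis$k),
                      chain = chain_config(), start = NULL,
                      fix_variances = FALSE, update_locations = TRUE,
                      store_locations = FALSE,
                      update_g = !fix_variances, update_q = !fix_variances,
                      update_p = !fix_variances, update_e = !fix_variances,
                      swap_tau = 0.1, swap_moves = 10L) {
  stopifnot(inherits(data, "rrm_data"), inherits(chain, "chain_config"))
  k <- data$basis$k
  if (is.null(start)) {
    s2y <- if (length(data$y) > 1L) stats::var(data$y) else 1
    start <- variance_components(diag(0.05, k), diag(0.05, k), diag(0.05, k),
                                 max(0.05, s2y))
  }
  ainv <- methods::as(methods::as(ainv, "generalMatrix"), "CsparseMatrix")
  if (nrow(ainv) != length(data$animal_ids))
    stop("A-inverse dimension does not match the pedigree")

  n <- length(data$y)
  phi <- data$Phi[data$age_idx, , drop = FALSE]
  if (n == 0L) phi <- matrix(0, 0L, k)

  set.seed(chain$seed)
  res <- .gibbs_rrm_cpp(
    y = data$y, phi = phi,
    ys = data$ys, n_ys = length(data$ys_levels),
    et = data$et,
    hys = data$hys, n_hys = length(data$hys_levels),
    anim = data$anim, n_anim = length(data$animal_ids),
    pe = data$pe, n_pe = length(data$pe_levels),
    pe_anim = match(data$pe_levels, as.character(data$animal_ids)),
    Ai = ainv@i, Ap = ainv@p, Ax = ainv@x,
    priors = list(sigma_b = priors$sigma_b,
                  nu_g = priors$iw_df, nu_q = priors$iw_df,
                  nu_p = priors$iw_df,
                  V_g = priors$V_g, V_q = priors$V_q, V_p = priors$V_p,
                  nu_e = priors$resid_df, s2_e = priors$resid_scale),
    init = list(G0 = start$G0, Rq = start$Rq, Rp = start$Rp,
                sigma_e2 = start$sigma_e2),
    chain = list(length = chain$length, burn_in = chain$burn_in,
                 thin = chain$thin),
    control = list(update_locations = update_locations,
                   update_g = update_g, update_q = update_q,
                   update_p = update_p, update_e = update_e,
                   store_locations = store_locations,
                   swap_tau = swap_tau, swap_moves = as.integer(swap_moves)))

  vn <- character(0)  # row-major upper triangle, matching the C++ storage
  for (i in seq_len(k)) for (j in i:k) vn <- c(vn, paste0("[", i, ",", j, "]"))
  for (nm in c("G0", "Rq", "Rp")) colnames(res[[nm]]) <- paste0(nm, vn)

  blocks <- list(ys = length(data$ys_levels) * k, et = 1L,
                 hys = length(data$hys_levels) * k,
                 anim = length(data$animal_ids) * k,
                 pe = length(data$pe_levels) * k)
  fit <- list(draws = res[c("G0", "Rq", "Rp")],
              sigma_e2 = as.numeric(res$sigma_e2),
              location_mean = split_solution(as.numeric(res$location_mean),
                                             blocks, k, data),
              n_saved = res$n_saved, chain = chain, priors = priors,
              basis = data$basis, trait = data$trait, blocks = blocks,
              k = k, swap_acceptance = res$swap_acceptance)
  if (!is.null(res$location_draws)) fit$location_draws <- res$location_draws
  class(fit) <- "rrm_fit"
  fit
}

#' @export
print.rrm_fit <- function(x, ...) {
  cat("RRM Gibbs fit", if (!is.null(x$trait)) paste0("(", x$trait, ")"),
      ":", x$n_saved, "retained draws, k =", x$k, "\n")
  ps <- posterior_summarize(x)
  cat("  posterior mean sigma_e2:", format(ps$mean$sigma_e2, digits = 4), "\n")
  invisible(x)
}

vech_to_sym <- function(v, k) {
  M <- matrix(0, k, k)
  c <- 0L
  for (i in seq_len(k)) for (j in i:k) {
    c <- c + 1L
    M[i, j] <- M[j, i] <- v[c]
  }
  M
}

#' Posterior summaries of the variance components
#'
#' Elementwise posterior means and standard deviations of `G0`, `Rq`, `Rp`
#' and the residual variance; the positive semi-definiteness of each mean
#' covariance matrix is verified and reported.
#'
#' @param fit an `rrm_fit`.
#' @return list with `mean` (list `G0`, `Rq`, `Rp`, `sigma_e2`), `sd` (same
#'   shape), `psd` (named logicals), `n_saved`.
#' @export
posterior_summarize <- function(fit) {
  if (fit$n_saved < 2L) stop("need at least two retained draws to summarize")
  k <- fit$k
  mean_l <- sd_l <- list()
  psd <- logical(0)
  for (nm in c("G0", "Rq", "Rp")) {
    d <- fit$draws[[nm]]
    mean_l[[nm]] <- vech_to_sym(colMeans(d), k)
    sd_l[[nm]] <- vech_to_sym(apply(d, 2L, stats::sd), k)
    psd[nm] <- is_psd(mean_l[[nm]], tol = 1e-8)
  }
  mean_l$sigma_e2 <- mean(fit$sigma_e2)
  sd_l$sigma_e2 <- stats::sd(fit$sigma_e2)
  list(mean = mean_l, sd = sd_l, psd = psd, n_saved = fit$n_saved)
}
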