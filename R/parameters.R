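# Age-scale genetic parameters: covariance functions, heritability
# trajectories and breeding-value trajectories.

#' Age-scale covariance function from coefficient-scale covariances
#'
#' Computes `T M T'` for a Legendre covariate matrix `T` over the evaluated
#' ages, mapping a k x k coefficient covariance matrix to the 14 x 14
#' covariance among ages; symmetry is enforced to numerical tolerance.
#'
#' @param T ages x k covariate matrix (e.g. `legendre_basis()$T`).
#' @param M k x k symmetric PSD coefficient covariance.
#' @return ages x ages covariance matrix.
#' @export
covariance_function <- function(T, M) {
  if (ncol(T) != nrow(M)) stop("dimension mismatch between T and M")
  if (!is_psd(M)) stop("M must be symmetric PSD")
  S <- T %*% M %*% t(T)
  (S + t(S)) / 2
}

#' Covariance functions for all three random effects
#'
#' @param basis a [legendre_basis()].
#' @param vc variance components (posterior means), e.g.
#'   `posterior_summarize(fit)$mean` or a [variance_components()].
#' @return list of class `covariance_functions`: `Sigma` (additive), `phi`
#'   (herd-year-season), `theta` (permanent environment), `ages`.
#' @export
covariance_functions <- function(basis, vc) {
  structure(list(Sigma = covariance_function(basis$T, vc$G0),
                 phi = covariance_function(basis$T, vc$Rq),
                 theta = covariance_function(basis$T, vc$Rp),
                 ages = basis$ages),
            class = "covariance_functions")
}

#' Heritability trajectory over ages
#'
#' Per age j, `h2_j = s2_aj / (s2_aj + s2_qj + s2_pj + s2_e)` with the
#' age-specific variances taken from the diagonals of the age-scale
#' covariance functions. Numerically negative diagonals are clipped at zero
#' with a warning; clip events are counted in attribute `n_clipped`.
#'
#' @param cf a `covariance_functions` object.
#' @param sigma_e2 residual variance (> 0).
#' @return data.frame (`age`, `h2`, `var_a`, `var_q`, `var_p`, `var_e`) of
#'   class `heritability_trajectory`.
#' @export
heritability_by_age <- function(cf, sigma_e2) {
  if (sigma_e2 <= 0) stop("sigma_e2 must be > 0")
  comp <- cbind(var_a = diag(cf$Sigma), var_q = diag(cf$phi),
                var_p = diag(cf$theta))
  n_clip <- sum(comp < 0)
  if (n_clip > 0) {
    warning(n_clip, " negative age-scale variance(s) clipped at 0")
    comp[comp < 0] <- 0
  }
  h2 <- comp[, "var_a"] / (rowSums(comp) + sigma_e2)
  out <- data.frame(age = cf$ages, h2 = h2, comp, var_e = sigma_e2)
  attr(out, "n_clipped") <- n_clip
  class(out) <- c("heritability_trajectory", "data.frame")
  out
}

#' Breeding-value trajectories over ages
#'
#' `EBV_i = T a_i` for every animal: each row of the result is the animal's
#' predicted additive-genetic trajectory over the evaluated ages.
#'
#' @param T ages x k covariate matrix.
#' @param a_hat animals x k matrix of (posterior mean) additive regression
#'   coefficient solutions.
#' @return animals x ages `ebv_matrix` (rownames preserved from `a_hat`).
#' @export
ebv_trajectories <- function(T, a_hat) {
  a_hat <- as.matrix(a_hat)
  if (ncol(a_hat) != ncol(T)) stop("a_hat must have k columns")
  ebv <- a_hat %*% t(T)
  colnames(ebv) <- paste0("age", seq_len(ncol(ebv)) + 1L)
  class(ebv) <- c("ebv_matrix", class(ebv))
  ebv
}

#' Genetic parameters of a Gibbs fit
#'
#' Convenience wrapper: posterior-mean variance components to covariance
#' functions, heritability trajectory and EBV matrix.
#'
#' @param fit an `rrm_fit`.
#' @return list with `cf`, `h2` (heritability trajectory), `ebv`, `vc_mean`.
#' @export
genetic_parameters <- function(fit) {
  ps <- posterior_summarize(fit)
  cf <- covariance_functions(fit$basis, ps$mean)
  h2 <- heritability_by_age(cf, ps$mean$sigma_e2)
  ebv <- ebv_trajectories(fit$basis$T, fit$location_mean$anim)
  list(cf = cf, h2 = h2, ebv = ebv, vc_mean = ps$mean)
}
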