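# Legendre polynomial age covariates for random regression models.

#' Legendre polynomial covariates for a set of ages
#'
#' Builds the matrix of Legendre polynomial covariates used by the random
#' regression model. Integer ages on `[age_min, age_max]` are standardized to
#' `t* = 2 (t - age_min) / (age_max - age_min) - 1` in `[-1, 1]`, and column
#' `m` (for `m = 0, ..., k - 1`) holds the degree-`m` Legendre polynomial
#' evaluated at `t*`. With `normalized = TRUE` (the default, standard in
#' covariance-function models) each polynomial is scaled by
#' `sqrt((2 m + 1) / 2)` so the basis is orthonormal on `[-1, 1]`.
#'
#' @param ages numeric vector of ages; must lie within `[age_min, age_max]`.
#' @param k number of coefficients (polynomial degrees `0` to `k - 1`).
#'   A degree-4 fit therefore uses `k = 5`.
#' @param normalized logical; use the orthonormal scaling (default `TRUE`).
#' @param age_min,age_max bounds of the modelled age range (defaults 2 and 15).
#' @return numeric matrix with `length(ages)` rows and `k` columns.
#' @examples
#' legendre_covariates(2:15, k = 5)
#' @export
legendre_covariates <- function(ages, k, normalized = TRUE,
                                age_min = 2, age_max = 15) {
  stopifnot(is.numeric(ages), length(ages) >= 1L, k >= 1L)
  if (any(ages < age_min | ages > age_max)) {
    stop("ages must lie within [", age_min, ", ", age_max, "]")
  }
  tstar <- 2 * (ages - age_min) / (age_max - age_min) - 1
  P <- matrix(0, length(ages), k)
  P[, 1L] <- 1
  if (k >= 2L) P[, 2L] <- tstar
  if (k >= 3L) {
    # Bonnet recurrence: (m+1) P_{m+1} = (2m+1) x P_m - m P_{m-1}
    for (m in 1:(k - 2L)) {
      P[, m + 2L] <- ((2 * m + 1) * tstar * P[, m + 1L] - m * P[, m]) / (m + 1)
    }
  }
  if (normalized) {
    P <- sweep(P, 2L, sqrt((2 * seq_len(k) - 1) / 2), `*`)
  }
  dimnames(P) <- list(NULL, paste0("leg", 0:(k - 1L)))
  P
}

#' Legendre basis over the evaluated age range
#'
#' Convenience container bundling the covariate matrix over all integer ages
#' with its metadata; this is the `T` matrix mapping random regression
#' coefficients to age-scale values.
#'
#' @inheritParams legendre_covariates
#' @return object of class `legendre_basis` with elements `T` (ages x k
#'   covariate matrix), `ages`, `k`, `normalized`, `age_min`, `age_max`.
#' @export
legendre_basis <- function(k = 5, age_min = 2, age_max = 15, normalized = TRUE) {
  ages <- seq.int(age_min, age_max)
  structure(
    list(T = legendre_covariates(ages, k, normalized, age_min, age_max),
         ages = ages, k = as.integer(k), normalized = normalized,
         age_min = age_min, age_max = age_max),
    class = "legendre_basis")
}

#' @export
print.legendre_basis <- function(x, ...) {
  cat("Legendre basis: k =", x$k, "coefficients (degrees 0-", x$k - 1L,
      "), ages ", x$age_min, "-", x$age_max,
      if (x$normalized) ", orthonormal scaling" else ", raw polynomials",
      "\n", sep = "")
  invisible(x)
}
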