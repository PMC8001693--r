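# Simulation of random regression effects and discrete-time cow histories.

AGES <- 2:15

# matrix square root that tolerates singular (e.g. all-zero) covariances
mat_sqrt <- function(M) {
  if (!is_psd(M)) stop("covariance matrix is not symmetric PSD")
  e <- eigen(M, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

hys_key <- function(herd, year, season) paste(herd, year, season, sep = "-")

# all herd-year-season classes reachable by records at ages 2-15
hys_classes <- function(ped, config) {
  years <- seq.int(min(ped$birth_year) + min(AGES),
                   max(ped$birth_year) + max(AGES))
  grid <- expand.grid(herd = seq_len(config$n_herds), year = years,
                      season = seq_len(config$seasons_per_year))
  hys_key(grid$herd, grid$year, grid$season)
}

#' Simulate random regression effects for a pedigree
#'
#' Additive-genetic coefficient vectors follow the pedigree: founders are
#' drawn with covariance `G0_true`; an offspring receives the parent average
#' plus a Mendelian sampling deviation with covariance
#' `(0.5 - 0.25 (F_s + F_d)) G0_true` (an unknown parent contributes as a
#' non-inbred base animal). Permanent-environment vectors are iid with
#' covariance `Rp_true` and herd-year-season class vectors iid with
#' covariance `Rq_true`.
#'
#' @param ped a `pedigree` data.frame from [simulate_pedigree()].
#' @param config a [sim_config()].
#' @return object of class `genetic_effects`: list with `a` (animals x k,
#'   rownames = animal id), `p` (animals x k), `q` (HYS classes x k, rownames
#'   = "herd-year-season" keys), and `k`.
#' @export
simulate_genetic_effects <- function(ped, config) {
  stopifnot(inherits(config, "sim_config"))
  k <- config$k_coefficients
  for (nm in c("G0_true", "Rq_true", "Rp_true"))
    if (!is_psd(config[[nm]])) stop(nm, " is not symmetric PSD")
  set.seed(config$seed + 1L)
  n <- nrow(ped)
  Lg <- mat_sqrt(config$G0_true)
  pp <- parent_positions(ped)
  Fcoef <- if (config$use_inbreeding) inbreeding_coefficients(ped) else numeric(n)

  z <- matrix(stats::rnorm(n * k), n, k)
  a <- matrix(0, n, k)
  for (i in seq_len(n)) {
    s <- pp$s[i]; d <- pp$d[i]
    if (s == 0L && d == 0L) {
      a[i, ] <- Lg %*% z[i, ]
    } else {
      pa <- ((if (s > 0L) a[s, ] else 0) + (if (d > 0L) a[d, ] else 0)) / 2
      Fs <- if (s > 0L) Fcoef[s] else 0
      Fd <- if (d > 0L) Fcoef[d] else 0
      vd <- if (s > 0L && d > 0L) 0.5 - 0.25 * (Fs + Fd)
            else 0.75 - 0.25 * (Fs + Fd)
      a[i, ] <- pa + sqrt(vd) * (Lg %*% z[i, ])
    }
  }
  rownames(a) <- ped$id

  p <- matrix(stats::rnorm(n * k), n, k) %*% t(mat_sqrt(config$Rp_true))
  rownames(p) <- ped$id
  classes <- hys_classes(ped, config)
  q <- matrix(stats::rnorm(length(classes) * k), length(classes), k) %*%
    t(mat_sqrt(config$Rq_true))
  rownames(q) <- classes

  structure(list(a = a, p = p, q = q, k = k), class = "genetic_effects")
}

#' Simulate cow culling and calving histories
#'
#' For every cow (non-founder female) a latent production score
#' `eta_ij = mu_j + phi(t_j)' (a_i + p_i + q_HYS(i,j)) + et_effect x ET_i + e_ij`
#' is evaluated at each age j = 2..15; the cow is culled at the first age
#' where the score falls below 0.5 (the scale of the 0/1 trait codes). Cows
#' never culled by 15 receive a culling age drawn uniformly from 16-20,
#' emulating natural death after the evaluated window. A cow culled at age 2
#' never calved and therefore cannot pass quality control; all other cows
#' calve at age 2 and in each later survived year with probability
#' `1 - calving_skip_prob` (skips may be followed by reappearance).
#'
#' All random draws are made up-front with fixed dimensions, so two runs of
#' the same configuration share their noise ("common random numbers"): e.g.
#' raising every survival intercept can only delay culling.
#'
#' @param ped pedigree from [simulate_pedigree()].
#' @param effects effects from [simulate_genetic_effects()].
#' @param config a [sim_config()].
#' @return data.frame of class `cow_histories`: columns `cow`, `herd`,
#'   `birth_year`, `birth_season`, `et_flag`, `first_calving_age_months`,
#'   `calving_ages` (list column of integer ages), `culling_age`,
#'   `natural_death`, `censoring_state`.
#' @export
simulate_cow_histories <- function(ped, effects, config) {
  stopifnot(inherits(config, "sim_config"), inherits(effects, "genetic_effects"))
  set.seed(config$seed + 2L)
  is_cow <- ped$sex == "F" & (if ("generation" %in% names(ped))
                                ped$generation > 0L else TRUE)
  cows <- ped[is_cow, ]
  n <- nrow(cows)
  if (n == 0L) stop("pedigree contains no cows")
  miss <- setdiff(as.character(cows$id), rownames(effects$a))
  if (length(miss))
    stop("no genetic effects for cow(s): ", paste(utils::head(miss, 5L), collapse = ", "))

  basis <- legendre_basis(k = effects$k)
  Tm <- basis$T                                   # 14 x k
  rows <- match(as.character(cows$id), rownames(effects$a))
  genet <- (effects$a[rows, , drop = FALSE] +
            effects$p[rows, , drop = FALSE]) %*% t(Tm)   # n x 14

  years <- outer(cows$birth_year, AGES, `+`)
  keys <- hys_key(rep(cows$herd, times = 14L), as.vector(years),
                  rep(cows$birth_season, times = 14L))
  cls <- match(keys, rownames(effects$q))
  if (anyNA(cls)) stop("cow record maps to an unknown herd-year-season class")
  Qage <- effects$q %*% t(Tm)                      # classes x 14
  qmat <- matrix(Qage[cbind(cls, rep(seq_along(AGES), each = n))], n, 14L)

  # fixed-dimension draws (common random numbers across configurations)
  e <- matrix(stats::rnorm(n * 14L, sd = sqrt(config$sigma_e2_true)), n, 14L)
  late_cull <- sample(16:20, n, replace = TRUE)
  skip <- matrix(stats::runif(n * 14L) < config$calving_skip_prob, n, 14L)
  fc_months <- sample(seq(config$first_calving_months_range[1L],
                          config$first_calving_months_range[2L]),
                      n, replace = TRUE)

  eta <- matrix(config$baseline_survival, n, 14L, byrow = TRUE) +
    genet + qmat + config$et_effect * cows$et_flag + e
  culled <- eta < 0.5
  first_cull <- max.col(cbind(culled, TRUE), ties.method = "first")
  culling_age <- ifelse(first_cull <= 14L, AGES[pmin(first_cull, 14L)], late_cull)

  calving_ages <- lapply(seq_len(n), function(i) {
    ca <- culling_age[i]
    if (ca <= 2L) return(integer(0))              # culled before first calving
    later <- AGES[AGES > 2L & AGES < ca & !skip[i, ]]
    as.integer(c(2L, later))
  })
  fc_months[culling_age <= 2L] <- NA_integer_

  out <- data.frame(
    cow = cows$id, herd = cows$herd, birth_year = cows$birth_year,
    birth_season = cows$birth_season, et_flag = cows$et_flag,
    first_calving_age_months = fc_months, culling_age = as.integer(culling_age),
    natural_death = 1L, censoring_state = "uncensored",
    stringsAsFactors = FALSE)
  out$calving_ages <- calving_ages
  class(out) <- c("cow_histories", "data.frame")
  out
}

#' Phenotypic quality control
#'
#' Removes cows born before the cutoff year, cows without a first calving
#' before 30 months of age, and cows with a culling age greater than 20
#' years. Per-rule removal counts are attached as attribute `qc_counts`.
#'
#' @param histories a `cow_histories` data.frame.
#' @param min_birth_year birth-year cutoff (default 1990).
#' @return filtered `cow_histories` with attribute `qc_counts`.
#' @export
apply_quality_control <- function(histories, min_birth_year = 1990L) {
  h <- histories
  r1 <- h$birth_year < min_birth_year
  r2 <- is.na(h$first_calving_age_months) | h$first_calving_age_months >= 30L
  r3 <- !is.na(h$culling_age) & h$culling_age > 20L
  keep <- !(r1 | r2 | r3)
  out <- h[keep, , drop = FALSE]
  attr(out, "qc_counts") <- c(born_before_cutoff = sum(r1),
                              no_early_first_calving = sum(r2),
                              culling_age_over_20 = sum(r3),
                              kept = sum(keep))
  if (nrow(out) == 0L) warning("quality control removed every cow")
  class(out) <- c("cow_histories", "data.frame")
  out
}

#' Write / read cow histories as delimited text
#'
#' Tab-separated, one row per cow; `calving_ages` serialized as a
#' comma-joined list field (empty when the cow never calved), unknown
#' culling age as an empty field.
#' @param histories `cow_histories` data.frame.
#' @param file path.
#' @export
write_cow_histories <- function(histories, file) {
  h <- as.data.frame(histories)
  h$calving_ages <- vapply(histories$calving_ages, paste, "", collapse = ",")
  utils::write.table(h, file, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
}

#' @rdname write_cow_histories
#' @export
read_cow_histories <- function(file) {
  h <- utils::read.table(file, header = TRUE, sep = "\t", na.strings = "",
                         stringsAsFactors = FALSE)
  h$calving_ages <- lapply(strsplit(ifelse(is.na(h$calving_ages), "",
                                           h$calving_ages), ","),
                           function(x) as.integer(x[nzchar(x)]))
  class(h) <- c("cow_histories", "data.frame")
  h
}

#' Full synthetic population: pedigree, effects, quality-controlled cows
#'
#' Convenience wrapper chaining [simulate_pedigree()],
#' [simulate_genetic_effects()], [simulate_cow_histories()] and
#' [apply_quality_control()].
#'
#' @param config a [sim_config()].
#' @return list with `pedigree`, `effects`, `histories` (post-QC).
#' @export
simulate_population <- function(config) {
  ped <- simulate_pedigree(config)
  eff <- simulate_genetic_effects(ped, config)
  his <- simulate_cow_histories(ped, eff, config)
  list(pedigree = ped, effects = eff, histories = apply_quality_control(his))
}
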