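# Scenario-contrast statistics: commonly selected proportions, EBV
# correlations, paired t-tests, and replicate aggregation.

top_set <- function(ebv, age, fraction) {
  col <- paste0("age", age)
  if (!col %in% colnames(ebv)) stop("age ", age, " not present in EBV matrix")
  n <- nrow(ebv)
  size <- round(fraction * n)
  if (size < 1L) stop("fraction ", fraction, " yields an empty top set")
  # stable tie-break: EBV descending, then animal id (row order) ascending
  ord <- order(-ebv[, col], seq_len(n))
  rownames(ebv)[ord[seq_len(size)]] %||% ord[seq_len(size)]
}

#' Proportion of commonly selected animals
#'
#' Overlap between the top `fraction` of animals ranked on EBV at one age
#' under a reference scenario and under an alternative scenario, relative to
#' the size of the reference top set. Ties are broken by stable animal
#' order (EBV descending, then id).
#'
#' @param ref,alt EBV matrices over the same animals (see
#'   [ebv_trajectories()]).
#' @param age age (years) at which animals are ranked.
#' @param fraction selected fraction, e.g. 0.01 or 0.10.
#' @return proportion in `[0, 1]`.
#' @export
top_overlap <- function(ref, alt, age, fraction = 0.10) {
  if (nrow(ref) != nrow(alt)) stop("EBV matrices cover different animal sets")
  ts_ref <- top_set(ref, age, fraction)
  ts_alt <- top_set(alt, age, fraction)
  length(intersect(ts_ref, ts_alt)) / length(ts_ref)
}

#' Pearson correlation between EBVs of two scenarios
#'
#' With `scope = "all"` the correlation is computed over all animals and all
#' ages flattened together. The age-specific scopes restrict to one age
#' column (default age four) and to the animals with, respectively without,
#' censored/penalized records.
#'
#' @param ref,alt EBV matrices over the same animals.
#' @param scope `"all"`, `"age_censored"` or `"age_uncensored"`.
#' @param censored_ids animal ids whose records were censored/penalized in
#'   the alternative scenario (needed for the age-specific scopes).
#' @param age age for the age-specific scopes (default 4).
#' @return Pearson correlation coefficient.
#' @export
ebv_correlation <- function(ref, alt,
                            scope = c("all", "age_censored", "age_uncensored"),
                            censored_ids = NULL, age = 4L) {
  scope <- match.arg(scope)
  if (nrow(ref) != nrow(alt)) stop("EBV matrices cover different animal sets")
  if (scope == "all") {
    x <- as.numeric(ref); y <- as.numeric(alt)
  } else {
    if (is.null(censored_ids)) stop("censored_ids required for scope ", scope)
    col <- paste0("age", age)
    sel <- rownames(ref) %in% as.character(censored_ids)
    if (scope == "age_uncensored") sel <- !sel
    x <- ref[sel, col]; y <- alt[sel, col]
  }
  if (length(x) < 3L) stop("need at least 3 paired values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in EBVs; correlation undefined")
  stats::cor(x, y)
}

#' Paired t-test between two scenario value series
#'
#' Thin wrapper around [stats::t.test()] (two-sided, paired). Identical
#' series (all differences exactly zero) are reported as `t = 0, p = 1`;
#' constant non-zero differences are a degenerate case and raise an error.
#'
#' @param a,b equal-length numeric series (e.g. per-age or per-replicate
#'   values under two scenarios).
#' @return list with `t`, `p`, `df`, `mean_difference`.
#' @export
paired_ttest <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2L)
    stop("need equal-length series of at least 2 values")
  d <- a - b
  if (stats::sd(d) == 0) {
    if (all(d == 0))
      return(list(t = 0, p = 1, df = length(d) - 1L, mean_difference = 0))
    stop("constant non-zero differences; paired t-test is degenerate")
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean_difference = unname(tt$estimate))
}

#' Aggregate a metric over replicates
#'
#' Arithmetic mean, sample standard deviation (n - 1) and standard error.
#' With a single replicate the SD is reported as 0 and flagged.
#'
#' @param values numeric vector of per-replicate values.
#' @return list with `mean`, `sd`, `se`, `n`, `single_replicate`.
#' @export
replicate_aggregate <- function(values) {
  n <- length(values)
  if (n < 1L) stop("need at least one replicate")
  single <- n == 1L
  s <- if (single) 0 else stats::sd(values)
  list(mean = mean(values), sd = s, se = s / sqrt(n), n = n,
       single_replicate = single)
}

#' Pairwise scenario significance at alpha = 0.05
#'
#' Pairwise paired t-tests between scenario value series (no multiplicity
#' correction by default, mirroring how such comparisons are usually
#' tabulated; `p_adjust` switches on a correction).
#'
#' @param series named list of equal-length numeric vectors, one per
#'   scenario.
#' @param alpha significance level.
#' @param p_adjust `p.adjust` method, `"none"` by default.
#' @return data.frame with columns `a`, `b`, `t`, `p`, `significant`.
#' @export
pairwise_scenario_tests <- function(series, alpha = 0.05, p_adjust = "none") {
  nm <- names(series)
  pairs <- utils::combn(nm, 2L)
  out <- data.frame(a = pairs[1L, ], b = pairs[2L, ], t = NA_real_,
                    p = NA_real_)
  for (i in seq_len(ncol(pairs))) {
    tt <- paired_ttest(series[[pairs[1L, i]]], series[[pairs[2L, i]]])
    out$t[i] <- tt$t; out$p[i] <- tt$p
  }
  out$p <- stats::p.adjust(out$p, method = p_adjust)
  out$significant <- out$p < alpha
  out
}
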