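# Nested record censoring, penalty-method data augmentation, and the two
# experimental designs contrasting censored vs. penalized culling records.

TREATMENTS <- c("COM", "CEN", "PENm1", "PENm2", "PENm3")
LEVELS <- c(0L, 20L, 40L, 60L, 80L)

#' Scenario specification
#'
#' Identifies one cell of the study: design, censoring level, treatment of
#' the censored records, and replicate. Level 0 is the complete-data scenario
#' (`COM`) and vice versa.
#'
#' @param design `"D1_fixed_uncensored"` (fixed pool of uncensored cows plus
#'   level% extra censored/penalized cows) or `"D2_fixed_total"` (fixed total
#'   with level% of it censored/penalized).
#' @param level percentage of censored/penalized records: 0, 20, 40, 60, 80.
#' @param treatment `"COM"`, `"CEN"` (keep censored), or `"PENm1"` /
#'   `"PENm2"` / `"PENm3"` (penalty criteria 1-3).
#' @param replicate replicate index (censoring assignment seed varies by
#'   replicate; the base population stays fixed).
#' @param seed integer seed for the censoring assignment.
#' @param reference_age_source how a cow's age is measured against the
#'   nine-year threshold of criteria m2/m3: `"reference_year"` (age at the
#'   dataset reference date) or `"last_calving"` (age at last calving).
#' @return object of class `scenario_spec`.
#' @export
scenario_spec <- function(design = c("D2_fixed_total", "D1_fixed_uncensored"),
                          level = 0L,
                          treatment = "COM",
                          replicate = 1L,
                          seed = 1L,
                          reference_age_source = c("reference_year",
                                                   "last_calving")) {
  design <- match.arg(design)
  treatment <- match.arg(treatment, TREATMENTS)
  level <- as.integer(level)
  if (!level %in% LEVELS) stop("level must be one of 0, 20, 40, 60, 80")
  if ((level == 0L) != (treatment == "COM"))
    stop("level 0 corresponds exactly to treatment COM")
  structure(list(design = design, level = level, treatment = treatment,
                 replicate = as.integer(replicate), seed = as.integer(seed),
                 reference_age_source = match.arg(reference_age_source)),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  lab <- if (x$treatment == "COM") "COM"
         else if (x$treatment == "CEN") paste0("CEN", x$level)
         else paste0("PEN", x$level, sub("PEN", "", x$treatment))
  cat("Scenario ", lab, " [", x$design, ", replicate ", x$replicate, "]\n",
      sep = "")
  invisible(x)
}

#' Nested censoring assignment
#'
#' Randomly samples 20% of the cows to censor, then repeatedly adds a further
#' random sample from the still-uncensored cows, so that the censored sets at
#' 20/40/60/80% are strictly nested. Sample sizes are rounded to the nearest
#' integer. No balance constraint per contemporary group is imposed.
#'
#' @param cow_ids vector of cow identifiers (the censoring base).
#' @param seed integer seed; the same seed reproduces the same assignment.
#' @param levels percentages (default `c(20, 40, 60, 80)`).
#' @param base_n optional base count the percentages refer to (defaults to
#'   `length(cow_ids)`; the first design censors a percentage of the
#'   uncensored pool, drawn from a separate reserve of cows).
#' @return object of class `censor_assignment`: named list of nested id sets
#'   (`S20`, `S40`, ...).
#' @export
assign_censoring <- function(cow_ids, seed, levels = c(20L, 40L, 60L, 80L),
                             base_n = length(cow_ids)) {
  if (length(cow_ids) < 5L) stop("need at least 5 cows to assign censoring")
  sizes <- round(levels / 100 * base_n)
  if (max(sizes) > length(cow_ids))
    stop("rounding policy conflict: largest censored set (", max(sizes),
         ") exceeds the ", length(cow_ids), " available cows")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  shuffled <- sample(cow_ids)
  out <- lapply(sizes, function(s) shuffled[seq_len(s)])
  names(out) <- paste0("S", levels)
  structure(out, class = "censor_assignment", seed = seed, base_n = base_n)
}

#' Censor one cow's culling information
#'
#' The culling age becomes unknown while the calving records are retained;
#' downstream trait coding then truncates the cow's information after her
#' last reported calving.
#'
#' @param history one-row cow history.
#' @return the history with `culling_age = NA` and state `"censored"`.
#' @export
censor_history <- function(history) {
  if (history$censoring_state != "uncensored")
    stop("cow ", history$cow, " is already censored")
  history$culling_age <- NA_integer_
  history$censoring_state <- "censored"
  history
}

#' Apply a penalty criterion to one censored cow
#'
#' Criterion `m1` imputes culling one year after the last reported calving
#' for every censored cow. Criterion `m2` imputes one year after the last
#' calving only for cows older than nine years and keeps younger cows
#' censored. Criterion `m3` imputes one year after the last calving for cows
#' older than nine years and two years after for younger cows. Imputed
#' culling ages are capped at the 20-year quality-control bound (with a
#' warning).
#'
#' @param history one-row censored cow history.
#' @param criterion `"m1"`, `"m2"` or `"m3"`.
#' @param reference_age the cow's age (years) used against the nine-year
#'   threshold; see [scenario_spec()] for the rule options.
#' @return the penalized (or still censored, under m2) history.
#' @export
penalize_history <- function(history, criterion = c("m1", "m2", "m3"),
                             reference_age = NULL) {
  criterion <- match.arg(criterion)
  if (history$censoring_state != "censored")
    stop("penalty criteria apply to censored records only")
  calv <- history$calving_ages[[1L]]
  if (!length(calv))
    stop("censored cow ", history$cow,
         " has no calving record to anchor the penalty")
  if (criterion != "m1" && is.null(reference_age))
    stop("criteria m2/m3 require the cow's reference age")
  last <- max(calv)
  add <- switch(criterion,
    m1 = 1L,
    m2 = if (reference_age > 9) 1L else NA_integer_,
    m3 = if (reference_age > 9) 1L else 2L)
  if (is.na(add)) return(history)        # m2 keeps young cows censored
  imputed <- last + add
  if (imputed > 20L) {
    warning("imputed culling age ", imputed, " for cow ", history$cow,
            " capped at the 20-year quality-control bound")
    imputed <- 20L
  }
  history$culling_age <- as.integer(imputed)
  history$censoring_state <- paste0("penalized-", criterion)
  history
}

# Reference ages for the nine-year threshold; eval_year defaults to the
# latest calving date observed anywhere in the population.
reference_ages <- function(histories, source = "reference_year",
                           eval_year = NULL) {
  last_calv <- vapply(histories$calving_ages,
                      function(x) if (length(x)) max(x) else NA_integer_, 0L)
  if (source == "last_calving") return(last_calv)
  if (is.null(eval_year))
    eval_year <- max(histories$birth_year + last_calv, na.rm = TRUE)
  eval_year - histories$birth_year
}

# Vectorized treatment application over a set of censored cow ids.
apply_treatment <- function(histories, ids, treatment, ref_ages = NULL) {
  rows <- match(ids, histories$cow)
  if (anyNA(rows)) stop("censored ids not found in histories")
  h <- histories
  h$culling_age[rows] <- NA_integer_
  h$censoring_state[rows] <- "censored"
  if (treatment == "CEN") return(h)
  crit <- sub("PEN", "", treatment)
  for (r in rows) {
    ph <- penalize_history(h[r, , drop = FALSE], crit,
                           if (crit == "m1") NULL else ref_ages[r])
    h$culling_age[r] <- ph$culling_age
    h$censoring_state[r] <- ph$censoring_state
  }
  h
}

#' Cow counts implied by a design
#'
#' Pure arithmetic of the two designs: with an uncensored pool of `U` cows,
#' design 1 totals `U + level% x U` cows; with a fixed total of `N` cows,
#' design 2 keeps `N - level% x N` uncensored.
#'
#' @param design design name (see [scenario_spec()]).
#' @param level censoring percentage.
#' @param pool_size `U` for design 1, `N` for design 2.
#' @return named vector: `total`, `uncensored`, `censored`.
#' @export
design_counts <- function(design, level, pool_size) {
  c_n <- round(level / 100 * pool_size)
  if (design == "D1_fixed_uncensored") {
    c(total = pool_size + c_n, uncensored = pool_size, censored = c_n)
  } else {
    c(total = pool_size, uncensored = pool_size - c_n, censored = c_n)
  }
}

#' Build one scenario's analysis dataset
#'
#' Applies a scenario specification to the base population: selects the cows
#' the design calls for, censors the assigned set, and applies the penalty
#' criterion when the treatment requires it. A manifest (design, level,
#' treatment, replicate, seed, counts) is attached as an attribute.
#'
#' @param cows quality-controlled `cow_histories` (the fixed base population;
#'   for design 1 the first `u_pool` cows after a seeded shuffle form the
#'   uncensored pool and censored cows are drawn from the remainder).
#' @param assignment a `censor_assignment` over the appropriate base set, or
#'   `NULL` to build it internally from `spec$seed`.
#' @param spec a [scenario_spec()].
#' @param u_pool size of the design-1 uncensored pool (defaults to
#'   `floor(55/100 * nrow(cows))`, a 55,000:100,000 uncensored-to-total ratio at reference scale).
#' @param pool_seed seed of the design-1 pool shuffle; deliberately separate
#'   from `spec$seed` so the uncensored pool is identical across replicates
#'   (only the censoring assignment varies between replicates).
#' @return `cow_histories` dataset with attribute `manifest`.
#' @export
build_design <- function(cows, assignment = NULL, spec, u_pool = NULL,
                         pool_seed = 101L) {
  n <- nrow(cows)
  if (spec$design == "D1_fixed_uncensored") {
    if (is.null(u_pool)) u_pool <- floor(0.55 * n)
    old <- get0(".Random.seed", envir = globalenv())
    set.seed(pool_seed)
    ord <- sample.int(n)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    pool_ids <- cows$cow[ord[seq_len(u_pool)]]
    reserve_ids <- cows$cow[ord[-seq_len(u_pool)]]
    if (is.null(assignment))
      assignment <- assign_censoring(reserve_ids, spec$seed + 1000L,
                                     base_n = u_pool)
    cens_ids <- if (spec$level == 0L) character(0)
                else assignment[[paste0("S", spec$level)]]
    keep <- cows$cow %in% c(pool_ids, cens_ids)
    ds <- cows[keep, , drop = FALSE]
  } else {
    if (is.null(assignment))
      assignment <- assign_censoring(cows$cow, spec$seed + 1000L)
    cens_ids <- if (spec$level == 0L) cows$cow[0] else
      assignment[[paste0("S", spec$level)]]
    ds <- cows
  }
  if (spec$level > 0L) {
    ra <- reference_ages(ds, spec$reference_age_source)
    ds <- apply_treatment(ds, cens_ids, spec$treatment, ra)
  }
  class(ds) <- c("cow_histories", "data.frame")
  attr(ds, "manifest") <- list(
    design = spec$design, level = spec$level, treatment = spec$treatment,
    replicate = spec$replicate, seed = spec$seed,
    n_total = nrow(ds), n_censored = length(cens_ids),
    n_uncensored = nrow(ds) - length(cens_ids))
  attr(ds, "censored_ids") <- cens_ids
  ds
}
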