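# Study orchestration: fit one scenario, compute the generator-implied
# observed-scale heritability, and run the full design x level x treatment x
# replicate factorial.

#' Fit the random regression model to one scenario dataset
#'
#' Codes the requested longevity indicator, assembles the model frame over
#' the full pedigree, runs the Gibbs sampler and extracts genetic
#' parameters.
#'
#' @param histories scenario `cow_histories` (e.g. from [build_design()]).
#' @param pedigree the full pedigree.
#' @param trait `"TL"` or `"FL"`.
#' @param chain a [chain_config()].
#' @param priors a [prior_spec()]; defaults to the basis dimension.
#' @param basis a [legendre_basis()].
#' @param ainv optional precomputed `A^-1` (recomputed when `NULL`).
#' @return list of class `scenario_result`: `fit` (`rrm_fit`), `h2`
#'   (heritability trajectory), `ebv` (animals x ages), `vc_mean`,
#'   `censored_ids`, `manifest`, `trait`.
#' @export
fit_scenario <- function(histories, pedigree, trait = c("TL", "FL"),
                         chain = chain_config(), priors = NULL,
                         basis = legendre_basis(), ainv = NULL) {
  trait <- match.arg(trait)
  records <- code_trajectories(histories, trait)
  data <- rrm_data(records, histories, pedigree, basis)
  if (is.null(ainv)) ainv <- build_ainverse(pedigree)
  if (is.null(priors)) priors <- prior_spec(k = basis$k)
  fit <- gibbs_rrm(data, ainv, priors = priors, chain = chain)
  gp <- genetic_parameters(fit)
  structure(list(fit = fit, h2 = gp$h2, ebv = gp$ebv, vc_mean = gp$vc_mean,
                 censored_ids = attr(histories, "censored_ids"),
                 manifest = attr(histories, "manifest"), trait = trait),
            class = "scenario_result")
}

#' Generator-implied heritability on the observed 0/1 scale
#'
#' The culling process thresholds a Gaussian latent score, so the
#' heritability of the recorded 0/1 codes is smaller than the latent-scale
#' ratio of the configured variance components. This function computes the
#' generating truth on the scale the evaluation model actually sees: the
#' pedigree and additive effects are simulated once, the environmental parts
#' (permanent environment, herd-year-season, residual, calving skips) are
#' redrawn `reps` times, and per age the between-animal variance of the
#' conditional code expectation (bias-corrected one-way ANOVA estimator) is
#' related to the total code variance. The embryo-transfer shift is switched
#' off here because the evaluation model absorbs it as a systematic effect.
#'
#' @param config a [sim_config()].
#' @param trait `"TL"` or `"FL"`.
#' @param reps number of environmental redraws (default 40).
#' @return data.frame (`age`, `h2`) of the implied observed-scale
#'   heritability per age.
#' @export
implied_heritability <- function(config, trait = c("TL", "FL"), reps = 40L) {
  trait <- match.arg(trait)
  cfg <- config
  cfg$et_effect <- 0
  ped <- simulate_pedigree(cfg)
  eff <- simulate_genetic_effects(ped, cfg)
  n_classes <- nrow(eff$q)
  k <- cfg$k_coefficients
  Y <- NULL
  for (r in seq_len(reps)) {
    eff_r <- eff
    set.seed(cfg$seed + 50000L + r)
    eff_r$p <- matrix(stats::rnorm(nrow(eff$p) * k), ncol = k) %*%
      t(mat_sqrt(cfg$Rp_true))
    rownames(eff_r$p) <- rownames(eff$p)
    eff_r$q <- matrix(stats::rnorm(n_classes * k), ncol = k) %*%
      t(mat_sqrt(cfg$Rq_true))
    rownames(eff_r$q) <- rownames(eff$q)
    cfg_r <- cfg
    cfg_r$seed <- cfg$seed + 60000L + r
    his <- simulate_cow_histories(ped, eff_r, cfg_r)
    codes <- code_trajectories(his, trait)
    ym <- matrix(codes$code, nrow = nrow(his), ncol = 14L, byrow = TRUE)
    if (is.null(Y)) Y <- array(NA_real_, c(nrow(his), 14L, reps))
    Y[, , r] <- ym
  }
  h2 <- numeric(14L)
  for (j in seq_len(14L)) {
    yj <- Y[, j, ]
    ybar <- rowMeans(yj, na.rm = TRUE)
    wvar <- apply(yj, 1L, stats::var, na.rm = TRUE)
    wvar[is.na(wvar)] <- 0
    between <- max(0, stats::var(ybar, na.rm = TRUE) - mean(wvar) / reps)
    total <- stats::var(as.numeric(yj), na.rm = TRUE)
    h2[j] <- if (isTRUE(total > 0)) between / total else 0
  }
  data.frame(age = AGES, h2 = h2)
}

#' Study run configuration
#'
#' The factorial grid of the evaluation: designs x censoring levels x
#' treatments x longevity indicators x replicates, on a population shrunk by
#' `scale_factor` relative to the reference study sizes (100,000 total /
#' 55,000 uncensored).
#'
#' @param sim a [sim_config()] for the base population.
#' @param designs character vector of designs (see [scenario_spec()]).
#' @param levels censoring percentages to evaluate (excluding 0; the
#'   complete-data reference COM is always fitted).
#' @param treatments subset of `"CEN"`, `"PENm1"`, `"PENm2"`, `"PENm3"`.
#' @param traits subset of `"TL"`, `"FL"`.
#' @param n_replicates number of censoring replicates (default 3).
#' @param chain a [chain_config()].
#' @param u_pool_frac design-1 uncensored pool as a fraction of the base
#'   population (default 0.55, i.e. 55,000 of 100,000 at reference scale).
#' @param seed master seed for censoring assignments.
#' @param out_dir optional directory for per-cell result files (enables
#'   resuming an interrupted run).
#' @return object of class `run_config`.
#' @export
run_config <- function(sim = sim_config(),
                       designs = "D2_fixed_total",
                       levels = c(20L, 40L, 60L, 80L),
                       treatments = c("CEN", "PENm1", "PENm2", "PENm3"),
                       traits = c("TL", "FL"),
                       n_replicates = 3L,
                       chain = chain_config(),
                       u_pool_frac = 0.55,
                       seed = 1L,
                       out_dir = NULL) {
  stopifnot(all(levels %in% c(20L, 40L, 60L, 80L)),
            all(treatments %in% c("CEN", "PENm1", "PENm2", "PENm3")),
            all(traits %in% c("TL", "FL")),
            u_pool_frac > 0, u_pool_frac <= 1)
  structure(list(sim = sim, designs = designs, levels = as.integer(levels),
                 treatments = treatments, traits = traits,
                 n_replicates = as.integer(n_replicates), chain = chain,
                 u_pool_frac = u_pool_frac, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

scenario_label <- function(treatment, level) {
  if (treatment == "COM") "COM"
  else if (treatment == "CEN") paste0("CEN", level)
  else paste0("PEN", level, sub("PEN", "", treatment))
}

#' Run the full censoring/penalty evaluation study
#'
#' Simulates (or reuses) the base population, fits the complete-data
#' reference COM once per design and trait, fits every grid cell, and
#' contrasts each cell against COM: top 1% / 10% commonly selected
#' proportions per age, EBV correlations over all animals and ages, and
#' age-four EBV correlations split by censoring status. Heritability
#' trajectories are collected for every fit.
#'
#' @param config a [run_config()].
#' @param population optional precomputed [simulate_population()] output.
#' @param progress print per-cell progress lines (default TRUE).
#' @return list of class `study_result`: `contrasts` (tidy data.frame:
#'   design, trait, level, treatment, replicate, metric, age, value), `h2`
#'   (tidy heritability table), `results` (named list of
#'   `scenario_result`s), `population`, `config`.
#' @export
run_study <- function(config, population = NULL, progress = TRUE) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(population)) population <- simulate_population(config$sim)
  cows <- population$histories
  ped <- population$pedigree
  basis <- legendre_basis(k = config$sim$k_coefficients)
  ainv <- build_ainverse(ped, use_inbreeding = config$sim$use_inbreeding)

  say <- function(...) if (progress) message(...)
  results <- list()
  contrasts <- list()
  h2_rows <- list()

  cell_fit <- function(histories, trait, key) {
    if (!is.null(config$out_dir)) {
      path <- file.path(config$out_dir, paste0(key, ".rds"))
      if (file.exists(path)) return(readRDS(path))
    }
    res <- fit_scenario(histories, ped, trait, chain = config$chain,
                        basis = basis, ainv = ainv)
    if (!is.null(config$out_dir)) {
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      saveRDS(res, file.path(config$out_dir, paste0(key, ".rds")))
    }
    res
  }

  for (design in config$designs) {
    u_pool <- if (design == "D1_fixed_uncensored")
      floor(config$u_pool_frac * nrow(cows)) else NULL
    for (trait in config$traits) {
      spec0 <- scenario_spec(design, 0L, "COM", 1L, seed = config$seed)
      ds0 <- build_design(cows, spec = spec0, u_pool = u_pool)
      key0 <- paste(design, trait, "COM", sep = "_")
      say("fitting ", key0, " (", nrow(ds0), " cows)")
      com <- cell_fit(ds0, trait, key0)
      results[[key0]] <- com
      h2_rows[[key0]] <- data.frame(design = design, trait = trait,
                                    scenario = "COM", replicate = 1L,
                                    com$h2[, c("age", "h2")])
      for (rep_i in seq_len(config$n_replicates)) {
        rep_seed <- config$seed + 97L * rep_i
        for (level in config$levels) {
          for (treatment in config$treatments) {
            spec <- scenario_spec(design, level, treatment, rep_i,
                                  seed = rep_seed)
            ds <- build_design(cows, spec = spec, u_pool = u_pool)
            lab <- scenario_label(treatment, level)
            key <- paste(design, trait, lab, "r", rep_i, sep = "_")
            say("fitting ", key, " (", nrow(ds), " cows, ",
                attr(ds, "manifest")$n_censored, " censored)")
            res <- cell_fit(ds, trait, key)
            results[[key]] <- res
            h2_rows[[key]] <- data.frame(design = design, trait = trait,
                                         scenario = lab, replicate = rep_i,
                                         res$h2[, c("age", "h2")])
            contrasts[[key]] <- contrast_vs_com(com, res, design, trait,
                                                lab, level, treatment, rep_i)
          }
        }
      }
    }
  }
  structure(list(contrasts = do.call(rbind, c(contrasts,
                                              make.row.names = FALSE)),
                 h2 = do.call(rbind, c(h2_rows, make.row.names = FALSE)),
                 results = results, population = population,
                 config = config),
            class = "study_result")
}

# all contrast metrics of one cell against its COM reference
contrast_vs_com <- function(com, res, design, trait, lab, level, treatment,
                            rep_i) {
  row <- function(metric, age, value)
    data.frame(design = design, trait = trait, level = level,
               treatment = treatment, scenario = lab, replicate = rep_i,
               metric = metric, age = age, value = value)
  out <- list()
  keep <- intersect(rownames(com$ebv), rownames(res$ebv))
  er <- com$ebv[keep, , drop = FALSE]
  ea <- res$ebv[keep, , drop = FALSE]
  for (age in AGES) {
    out[[length(out) + 1L]] <-
      row("top10_overlap", age, top_overlap(er, ea, age, 0.10))
    out[[length(out) + 1L]] <-
      row("top1_overlap", age, top_overlap(er, ea, age, 0.01))
  }
  out[[length(out) + 1L]] <-
    row("ebv_cor_all", NA, ebv_correlation(er, ea, "all"))
  cens <- intersect(as.character(res$censored_ids), keep)
  if (length(cens) >= 3L && length(cens) <= length(keep) - 3L) {
    out[[length(out) + 1L]] <-
      row("ebv_cor_age4_censored", 4L,
          ebv_correlation(er, ea, "age_censored", censored_ids = cens))
    out[[length(out) + 1L]] <-
      row("ebv_cor_age4_uncensored", 4L,
          ebv_correlation(er, ea, "age_uncensored", censored_ids = cens))
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Aggregate study contrasts over replicates
#'
#' Mean, SD and SE per (design, trait, scenario, metric, age) across
#' replicates, the layout in which the contrasts are usually reported.
#'
#' @param study a `study_result` from [run_study()].
#' @return tidy data.frame.
#' @export
summarize_study <- function(study) {
  cs <- study$contrasts
  keys <- interaction(cs$design, cs$trait, cs$scenario, cs$metric, cs$age,
                      drop = TRUE)
  parts <- split(cs, keys)
  do.call(rbind, c(lapply(parts, function(p) {
    agg <- replicate_aggregate(p$value)
    data.frame(design = p$design[1L], trait = p$trait[1L],
               scenario = p$scenario[1L], metric = p$metric[1L],
               age = p$age[1L], mean = agg$mean, sd = agg$sd, se = agg$se,
               n = agg$n)
  }), make.row.names = FALSE))
}

#' Export a scenario dataset in a BLUPF90-style dialect
#'
#' Writes three files: a data file (cow, year-season class, embryo-transfer
#' flag, herd-year-season class, and one column per age with a numeric
#' missing code), a pedigree file (animal, sire, dam) and a parameter-like
#' header describing the columns. Intended for cross-validation against the
#' reference software family, not used by the internal fitters.
#'
#' @param histories scenario `cow_histories`.
#' @param pedigree pedigree data.frame.
#' @param trait `"TL"` or `"FL"`.
#' @param dir output directory.
#' @param miss numeric missing-value code (default -999).
#' @return invisibly, the paths written.
#' @export
export_blupf90 <- function(histories, pedigree, trait = "TL", dir,
                           miss = -999L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rec <- code_trajectories(histories, trait)
  datf <- file.path(dir, "data.txt")
  pedf <- file.path(dir, "pedigree.txt")
  hdrf <- file.path(dir, "columns.txt")
  write_codes_wide(rec, datf, miss = miss)
  utils::write.table(pedigree[, c("id", "sire", "dam")], pedf,
                     sep = " ", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  writeLines(c("# data.txt: cow id, then one 0/1 column per age 2-15",
               paste0("# missing record code: ", miss),
               "# pedigree.txt: animal sire dam (0 = unknown)"), hdrf)
  invisible(c(datf, pedf, hdrf))
}
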