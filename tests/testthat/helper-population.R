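# Shared small synthetic populations, built once per test run.

small_config <- function(seed = 7, k = 3, ...) {
  sim_config(n_base_animals = 60, n_generations = 2, n_cows_target = 160,
             n_herds = 4, k_coefficients = k,
             G0_true = diag(c(0.03, 0.005, 0.002))[1:k, 1:k, drop = FALSE],
             Rq_true = diag(c(0.016, 0.003, 0.001))[1:k, 1:k, drop = FALSE],
             Rp_true = diag(c(0.024, 0.004, 0.0015))[1:k, 1:k, drop = FALSE],
             seed = seed, ...)
}

.pop_cache <- new.env(parent = emptyenv())

small_population <- function(seed = 7, k = 3) {
  key <- paste0("pop", seed, "_", k)
  if (is.null(.pop_cache[[key]]))
    .pop_cache[[key]] <- simulate_population(small_config(seed = seed, k = k))
  .pop_cache[[key]]
}

# one-row cow history for coding/penalty unit tests
make_history <- function(cow = 1L, culling_age = NA, calvings = integer(0),
                         state = "uncensored", birth_year = 2000L) {
  h <- data.frame(cow = as.integer(cow), herd = 1L, birth_year = birth_year,
                  birth_season = 1L, et_flag = 0L,
                  first_calving_age_months = 26L,
                  culling_age = as.integer(culling_age), natural_death = 1L,
                  censoring_state = state, stringsAsFactors = FALSE)
  h$calving_ages <- list(as.integer(calvings))
  class(h) <- c("cow_histories", "data.frame")
  h
}
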