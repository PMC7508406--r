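# Fixtures are built in code; nothing is read from disk.

# Minimal valid record table; override any column via ...
toy_records <- function(n = 6, ...) {
  out <- tibble::tibble(
    context = "captivity",
    study_id = "s1",
    species_id = "sp1",
    trait_id = "t1",
    trait_class = "behavioral",
    generation = seq_len(n) - 1,
    raw_mean = seq_len(n) / 2,
    raw_sd = 1,
    sample_size = 10L,
    direction = 1,
    selected_for_high_fear = FALSE
  )
  dots <- list(...)
  for (nm in names(dots)) out[[nm]] <- dots[[nm]]
  out
}

# Records shaped for direct Gibbs tests: y/weight supplied, grouping columns
# chosen by the caller.
gibbs_records <- function(y, x, weight = 1, study = "s1", species = "sp1",
                          trait_class = "behavioral") {
  tibble::tibble(
    context = "captivity", study_id = study, species_id = species,
    trait_id = "t1", trait_class = trait_class, generation = x,
    raw_mean = y, raw_sd = 1, sample_size = 5L, direction = 1,
    selected_for_high_fear = FALSE, standardized_mean = y, weight = weight
  )
}

quick_mcmc <- function(n_iter = 4000, burn_in = 1000, thin = 3, n_chains = 1,
                       seed = 1) {
  mcmc_config(n_iter = n_iter, burn_in = burn_in, thin = thin,
              n_chains = n_chains, seed = seed)
}

ess_total <- function(fit, term) {
  s <- summarize_posterior(fit)
  s$ess[s$term == term]
}

# Hand-built posterior container for summary-level tests.
fake_mcmc <- function(draws, chain = NULL) {
  structure(list(draws = draws,
                 chain = chain %||% rep(1L, nrow(draws))),
            class = "relax_mcmc")
}
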