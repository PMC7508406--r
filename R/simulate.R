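#' Configuration for the synthetic meta-analytic data generator
#'
#' Defines the ground truth of a simulated relaxed-selection meta-analysis:
#' species-level trait trajectories with phylogenetic signal, study and
#' trait-type random effects, and sampling noise that shrinks with sample
#' size. Defaults emulate the domestication context of the study design:
#' 30 species on a pure-birth tree, 20 studies of 2 traits each observed on
#' a generation grid spanning 0-100 (440 records), an inverse-decay mean
#' trajectory, a Weibull CV trajectory, and moderate random-effect and
#' residual noise.
#'
#' @param context Context label for the generated records.
#' @param n_species Number of species on the simulated tree.
#' @param n_studies Number of studies; each study follows one species.
#' @param traits_per_study Distinct traits measured per study.
#' @param generations Generation grid at which each (study, trait) is
#'   observed.
#' @param mean_curve True [inverse_params()] for the standardized-mean
#'   trajectory.
#' @param cv_curve True [weibull_params()] for the absolute-CV trajectory.
#' @param sd_species,sd_phylo,sd_study,sd_trait_type Random-effect SDs
#'   (trait z-score units).
#' @param sd_residual Residual SD; a record with sample size n has residual
#'   SD `sd_residual / sqrt(n)`.
#' @param cv_noise_sd SD of the lognormal (multiplicative) noise on the CV
#'   trajectory.
#' @param sample_sizes Integer pool from which per-record sample sizes are
#'   drawn.
#' @param birth_rate Pure-birth speciation rate for the simulated tree.
#' @param guild_probs Named probabilities of the five foraging guilds.
#' @param p_gregarious Probability a species is gregarious.
#' @param longevity_meanlog,longevity_sdlog Lognormal parameters of maximum
#'   longevity (years).
#' @param prop_inverted Fraction of traits measured on an inverted scale
#'   (stored with `direction = -1`).
#' @param slope_by_guild,slope_by_sociality Optional named multipliers on
#'   the mean-curve scaling coefficient `k` per life-history level
#'   (amplitude differences; note that within-study standardization removes
#'   pure amplitude differences when studies share a generation grid).
#' @param rate_by_guild,rate_by_sociality Optional named exponents on the
#'   decay factor per life-history level (`a_effective = a^m`); `m > 1`
#'   means faster trait loss. Rate differences survive standardization and
#'   are the way to plant detectable group x generation interactions.
#' @param seed Integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(context = "domestication",
                       n_species = 30, n_studies = 20, traits_per_study = 2,
                       generations = seq(0, 100, by = 10),
                       mean_curve = inverse_params(0.3, 1.5, 0.85),
                       cv_curve = weibull_params(0.8, 2, 2, 15, 0),
                       sd_species = 0.2, sd_phylo = 0.2, sd_study = 0.3,
                       sd_trait_type = 0.2, sd_residual = 0.3,
                       cv_noise_sd = 0.2,
                       sample_sizes = 5:50, birth_rate = 1,
                       guild_probs = c(carnivore = 0.2, omnivore = 0.2,
                                       herbivore = 0.2, granivore = 0.2,
                                       insectivore = 0.2),
                       p_gregarious = 0.5,
                       longevity_meanlog = log(10), longevity_sdlog = 0.5,
                       prop_inverted = 0.3,
                       slope_by_guild = NULL, slope_by_sociality = NULL,
                       rate_by_guild = NULL, rate_by_sociality = NULL,
                       seed = 1) {
  stopifnot(n_species >= 2, all(generations >= 0),
            all(c(sd_species, sd_phylo, sd_study, sd_trait_type,
                  sd_residual, cv_noise_sd) >= 0))
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate an ultrametric pure-birth tree
#'
#' A Yule (pure-birth) tree with `n_species` leaves labelled
#' `sp_001 ... sp_N`, rescaled to height 1.
#'
#' @param n_species Number of leaves (>= 2).
#' @param birth_rate Speciation rate.
#' @param seed Integer seed; the same seed yields the identical tree.
#' @return An ultrametric `ape::phylo` tree of height 1.
#' @export
simulate_tree <- function(n_species, birth_rate = 1, seed = 1) {
  stopifnot(n_species >= 2)
  tree <- with_seed(seed, ape::rphylo(n_species, birth = birth_rate, death = 0))
  tree$edge.length <- tree$edge.length / max(leaf_depths(tree))
  tree$tip.label <- sprintf("sp_%03d", seq_len(n_species))
  tree
}

#' Simulate a complete synthetic meta-analytic dataset
#'
#' Generates observation records whose statistical structure mirrors the
#' meta-regression's likelihood: for a record of study s (species j) on
#' trait t at generation x,
#' \deqn{\mu = f_{inv}(x) + u_{species,j} + u_{phylo,j} + u_{study,s} +
#'   u_{class(t)} + e, \quad e \sim N(0, \sigma^2_e / n),}
#' with the phylogenetic effects drawn jointly with covariance
#' \eqn{\sigma^2_{phylo} A} from the simulated tree. The reported SD is set
#' so the record's |CV| follows the Weibull trajectory times lognormal
#' noise. Traits drawn as "inverted scale" store `direction = -1` and a
#' sign-flipped mean, so the preparation pipeline must re-orient them.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_dataset` with elements `records`,
#'   `life_history`, `tree` and `truth` (the generating parameters).
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  tree <- simulate_tree(cf$n_species, cf$birth_rate, derive_seed(cf$seed, "tree"))
  A <- phylo_correlation(tree)
  species <- tree$tip.label

  trait_pool <- tibble::tibble(
    trait_id = c("fid", "vigilance", "flush_distance", "alarm_calls",
                 "latency_to_emerge", "boldness_latency", "cortisol", "heart_rate"),
    trait_class = c("behavioral", "behavioral", "behavioral", "behavioral",
                    "behavioral", "behavioral", "physiological", "physiological")
  )

  with_seed(derive_seed(cf$seed, "data"), {
    # species-level effects
    u_species <- rnorm(cf$n_species, 0, cf$sd_species)
    u_phylo <- if (cf$sd_phylo > 0) {
      as.numeric(t(chol(A + diag(1e-10, cf$n_species))) %*%
                   rnorm(cf$n_species)) * cf$sd_phylo
    } else numeric(cf$n_species)
    names(u_species) <- names(u_phylo) <- species

    life_history <- tibble::tibble(
      species_id = species,
      foraging_guild = sample(names(cf$guild_probs), cf$n_species,
                              replace = TRUE, prob = cf$guild_probs),
      sociality = sample(c("gregarious", "solitary"), cf$n_species,
                         replace = TRUE,
                         prob = c(cf$p_gregarious, 1 - cf$p_gregarious)),
      max_longevity = exp(rnorm(cf$n_species, cf$longevity_meanlog,
                                cf$longevity_sdlog)),
      taxon = sample(c("Mammals", "Birds", "Reptiles", "Fish"), cf$n_species,
                     replace = TRUE, prob = c(0.35, 0.4, 0.15, 0.1))
    )

    u_class <- setNames(rnorm(2, 0, cf$sd_trait_type),
                        c("behavioral", "physiological"))
    u_study <- rnorm(cf$n_studies, 0, cf$sd_study)
    # with replacement: several studies can follow the same species, which is
    # what lets the species and study variance components separate
    study_species <- sample(species, cf$n_studies, replace = TRUE)
    inverted <- setNames(runif(nrow(trait_pool)) < cf$prop_inverted,
                         trait_pool$trait_id)

    grid <- tidyr::expand_grid(
      study = seq_len(cf$n_studies),
      trait_slot = seq_len(cf$traits_per_study),
      generation = cf$generations
    )
    study_traits <- purrr::map(seq_len(cf$n_studies), function(s) {
      idx <- sample(nrow(trait_pool), cf$traits_per_study)
      trait_pool$trait_id[idx]
    })

    lh_mult <- function(sp, by_guild, by_sociality) {
      m <- 1
      if (!is.null(by_guild)) {
        g <- life_history$foraging_guild[match(sp, life_history$species_id)]
        m <- m * ifelse(is.na(by_guild[g]), 1, by_guild[g])
      }
      if (!is.null(by_sociality)) {
        so <- life_history$sociality[match(sp, life_history$species_id)]
        m <- m * ifelse(is.na(by_sociality[so]), 1, by_sociality[so])
      }
      as.numeric(m)
    }

    records <- grid |>
      dplyr::mutate(
        study_id = sprintf("study_%02d", .data$study),
        species_id = study_species[.data$study],
        trait_id = purrr::map2_chr(.data$study, .data$trait_slot,
                                   ~ study_traits[[.x]][.y]),
        trait_class = trait_pool$trait_class[match(.data$trait_id, trait_pool$trait_id)],
        sample_size = sample(cf$sample_sizes, dplyr::n(), replace = TRUE),
        context = cf$context
      )
    km <- lh_mult(records$species_id, cf$slope_by_guild, cf$slope_by_sociality)
    rm_ <- lh_mult(records$species_id, cf$rate_by_guild, cf$rate_by_sociality)
    curve_val <- cf$mean_curve$y_ini +
      km * cf$mean_curve$k * (cf$mean_curve$a^rm_)^records$generation
    mu <- curve_val +
      u_species[records$species_id] + u_phylo[records$species_id] +
      u_study[records$study] + u_class[records$trait_class] +
      rnorm(nrow(records), 0, cf$sd_residual / sqrt(records$sample_size))
    cv_target <- weibull_curve(records$generation, cf$cv_curve) *
      exp(rnorm(nrow(records), 0, cf$cv_noise_sd))
    if (any(cv_target < 0)) {
      abort("CV trajectory produced negative values; check cv_curve.",
            class = "relaxsel_generation_error")
    }
    dir <- unname(ifelse(inverted[records$trait_id], -1, 1))
    mu <- unname(mu)
    records <- records |>
      dplyr::mutate(
        direction = dir,
        raw_mean = dir * mu,
        raw_sd = unname(abs(cv_target * mu)),
        selected_for_high_fear = FALSE,
        generation = as.numeric(.data$generation)
      ) |>
      dplyr::select(dplyr::all_of(record_columns))

    structure(
      list(records = records, life_history = life_history, tree = tree,
           truth = list(mean_curve = unclass(cf$mean_curve),
                        cv_curve = unclass(cf$cv_curve),
                        sd_species = cf$sd_species, sd_phylo = cf$sd_phylo,
                        sd_study = cf$sd_study, sd_trait_type = cf$sd_trait_type,
                        sd_residual = cf$sd_residual, seed = cf$seed)),
      class = "sim_dataset"
    )
  })
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("<sim_dataset> ", nrow(x$records), " records, ",
      length(x$tree$tip.label), " species, ",
      dplyr::n_distinct(x$records$study_id), " studies\n", sep = "")
  invisible(x)
}

#' Write a simulated dataset as a plain-text fixture bundle
#'
#' Writes `records.csv`, `life_history.csv`, `tree.nwk` and `truth.json`
#' into `dir`. File contents are byte-identical for identical datasets.
#'
#' @param dataset A `sim_dataset` from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_fixture_bundle <- function(dataset, dir) {
  stopifnot(inherits(dataset, "sim_dataset"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("cannot create directory ", dir), class = "relaxsel_io_error")
  }
  paths <- c(
    records = file.path(dir, "records.csv"),
    life_history = file.path(dir, "life_history.csv"),
    tree = file.path(dir, "tree.nwk"),
    truth = file.path(dir, "truth.json")
  )
  readr::write_csv(dataset$records, paths[["records"]])
  readr::write_csv(dataset$life_history, paths[["life_history"]])
  ape::write.tree(dataset$tree, file = paths[["tree"]])
  jsonlite::write_json(dataset$truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Read a fixture bundle written by [write_fixture_bundle()]
#'
#' @param dir Directory holding the four fixture files.
#' @return A `sim_dataset` list.
#' @export
read_fixture_bundle <- function(dir) {
  records <- readr::read_csv(file.path(dir, "records.csv"),
                             show_col_types = FALSE)
  structure(
    list(records = validate_records(records),
         life_history = readr::read_csv(file.path(dir, "life_history.csv"),
                                        show_col_types = FALSE),
         tree = read_newick(file = file.path(dir, "tree.nwk")),
         truth = jsonlite::read_json(file.path(dir, "truth.json"),
                                     simplifyVector = TRUE)),
    class = "sim_dataset"
  )
}
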