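#' Convert time since colonization to generations
#'
#' For urbanized populations the number of generations of human contact is
#' estimated as the time since colonization of the urban habitat divided by
#' the average age at maturity of the species.
#'
#' @param time_since_colonization Years since colonization, non-negative.
#' @param age_at_maturity Average age at maturity in years, strictly positive.
#' @return The (unrounded) generation count; vectorized.
#' @examples
#' compute_generations(100, 2)
#' @export
compute_generations <- function(time_since_colonization, age_at_maturity) {
  if (any(!is.finite(age_at_maturity)) || any(age_at_maturity <= 0)) {
    abort("`age_at_maturity` must be strictly positive.",
          class = "relaxsel_invalid_input")
  }
  if (any(time_since_colonization < 0, na.rm = TRUE)) {
    abort("`time_since_colonization` must be non-negative.",
          class = "relaxsel_invalid_input")
  }
  time_since_colonization / age_at_maturity
}

record_columns <- c(
  "context", "study_id", "species_id", "trait_id", "trait_class",
  "generation", "raw_mean", "raw_sd", "sample_size", "direction",
  "selected_for_high_fear"
)

#' Validate a table of observation records
#'
#' Checks the schema and invariants of the per-record meta-analytic table:
#' one row per trait measurement (mean, SD, sample size) for one species in
#' one study at one generation of human contact.
#'
#' @param records A data frame with columns `context`, `study_id`,
#'   `species_id`, `trait_id`, `trait_class` (`"behavioral"` or
#'   `"physiological"`), `generation` (non-negative), `raw_mean`, `raw_sd`
#'   (non-negative, `NA` allowed), `sample_size` (integer >= 1), `direction`
#'   (+1 or -1; +1 means larger values indicate a stronger antipredator
#'   response), `selected_for_high_fear` (logical).
#' @return The records as a tibble, invisibly checked.
#' @export
validate_records <- function(records) {
  records <- tibble::as_tibble(records)
  missing <- setdiff(record_columns, names(records))
  if (length(missing)) {
    abort(paste0("records are missing columns: ", paste(missing, collapse = ", ")),
          class = "relaxsel_invalid_input")
  }
  bad <- function(cond, msg) if (any(cond, na.rm = TRUE)) {
    abort(paste0("invalid records: ", msg), class = "relaxsel_invalid_input")
  }
  bad(records$raw_sd < 0, "raw_sd must be >= 0")
  bad(records$sample_size < 1, "sample_size must be >= 1")
  bad(records$generation < 0, "generation must be >= 0")
  bad(!records$direction %in% c(-1, 1), "direction must be +1 or -1")
  bad(!records$context %in% c("urbanization", "captivity", "domestication"),
      "context must be urbanization, captivity or domestication")
  bad(!records$trait_class %in% c("behavioral", "physiological"),
      "trait_class must be behavioral or physiological")
  records
}

#' Filter records for analysis
#'
#' Applies the dataset inclusion rules: records from selection lines bred for
#' *high* fear/aggression are dropped, dog records are optionally dropped
#' (their between-breed variability reflects repeated selective breeding for
#' diverse goals, not generations of domestication), and every retained
#' `(study, trait)` group must hold at least `min_values_per_trait` records
#' (a trajectory needs more than one point).
#'
#' @param records A validated record table (see [validate_records()]).
#' @param remove_dogs Drop dog records? Default `TRUE`.
#' @param min_values_per_trait Minimum records per `(study_id, trait_id)`
#'   group; default 2.
#' @param dog_species Character vector of `species_id` values treated as dogs.
#' @return The retained records; the dropped rows with a `reason` column are
#'   attached as the `"exclusions"` attribute (see [exclusion_log()]).
#' @export
apply_filters <- function(records, remove_dogs = TRUE, min_values_per_trait = 2,
                          dog_species = c("Canis_familiaris", "Canis familiaris",
                                          "Canis_lupus_familiaris")) {
  records <- validate_records(records)
  if (nrow(records) == 0) {
    return(structure(records, exclusions = dplyr::mutate(records, reason = character(0))))
  }
  reason <- rep(NA_character_, nrow(records))
  reason[records$selected_for_high_fear] <- "high-fear selection line"
  if (remove_dogs) {
    is_dog <- records$species_id %in% dog_species & is.na(reason)
    reason[is_dog] <- "dog record (breed-level selection)"
  }
  keep <- is.na(reason)
  grp <- paste(records$context, records$study_id, records$trait_id, sep = "\r")
  counts <- table(grp[keep])
  small <- keep & counts[grp] < min_values_per_trait
  reason[small] <- sprintf("fewer than %d values for this (study, trait)",
                           min_values_per_trait)
  keep <- is.na(reason)
  exclusions <- dplyr::mutate(records[!keep, , drop = FALSE],
                              reason = reason[!keep])
  structure(records[keep, , drop = FALSE], exclusions = exclusions)
}

#' Retrieve the exclusion log attached by [apply_filters()]
#'
#' @param records A record table returned by [apply_filters()].
#' @return A tibble of dropped records with a `reason` column.
#' @export
exclusion_log <- function(records) {
  attr(records, "exclusions") %||%
    tibble::tibble(reason = character(0))
}

#' Orient trait means so larger always means more antipredator response
#'
#' Traits measured on an inverted scale (e.g. latency before fleeing, where
#' long latencies mean *weak* responses) carry `direction = -1`; their means
#' are multiplied by -1 so that across all traits a larger value reflects a
#' stronger antipredator response. Standard deviations are sign-invariant and
#' left untouched. After harmonization `direction` is reset to `+1`, making
#' the operation idempotent.
#'
#' @inheritParams apply_filters
#' @return Records with oriented `raw_mean` and `direction` set to 1.
#' @export
harmonize_direction <- function(records) {
  records <- validate_records(records)
  dplyr::mutate(records,
                raw_mean = .data$raw_mean * .data$direction,
                direction = 1)
}

#' Shift trait means to a non-negative baseline
#'
#' Within each `(context, trait_id)` group whose minimum oriented mean is
#' negative, adds the absolute value of that minimum to every mean so the
#' group minimum becomes exactly 0. Groups already non-negative are left
#' unchanged; all pairwise differences are preserved.
#'
#' @inheritParams apply_filters
#' @return Records with shifted `raw_mean`.
#' @export
shift_to_nonnegative <- function(records) {
  records <- validate_records(records)
  records |>
    dplyr::group_by(.data$context, .data$trait_id) |>
    dplyr::mutate(raw_mean = .data$raw_mean +
                    ifelse(min(.data$raw_mean) < 0, abs(min(.data$raw_mean)), 0)) |>
    dplyr::ungroup()
}

#' Standardize means within (context, study, trait) groups
#'
#' Rescales all oriented means to a common unitless scale: within each
#' `(context, study_id, trait_id)` group the mean is centred on the group
#' mean and divided by the group sample standard deviation (denominator
#' n - 1), yielding z-scores with mean 0 and SD 1. Degenerate groups (a
#' single record, or identical values) get `standardized_mean = 0` and are
#' reported with a warning, so their records remain available to the CV
#' analysis.
#'
#' @inheritParams apply_filters
#' @return Records with a `standardized_mean` column.
#' @export
standardize_within <- function(records) {
  records <- validate_records(records)
  out <- records |>
    dplyr::group_by(.data$context, .data$study_id, .data$trait_id) |>
    dplyr::mutate(
      .grp_sd = ifelse(dplyr::n() >= 2, sd(.data$raw_mean), 0),
      standardized_mean = ifelse(
        .data$.grp_sd > 0,
        (.data$raw_mean - mean(.data$raw_mean)) / .data$.grp_sd,
        0
      )
    ) |>
    dplyr::ungroup()
  n_degenerate <- out |>
    dplyr::filter(.data$.grp_sd == 0) |>
    dplyr::distinct(.data$context, .data$study_id, .data$trait_id) |>
    nrow()
  if (n_degenerate > 0) {
    warn(sprintf(
      "%d (context, study, trait) group(s) had zero spread; standardized_mean set to 0",
      n_degenerate
    ))
  }
  dplyr::select(out, -".grp_sd")
}

#' Absolute coefficient of variation per record
#'
#' The CV is the between-individual spread of the trait: the raw (oriented,
#' pre-standardization) SD divided by the raw mean. Because oriented means
#' can be negative, the absolute value is used. Records with a zero mean have
#' an undefined CV; they get `abs_cv = NA` and are listed in the
#' `"cv_exclusions"` attribute.
#'
#' @inheritParams apply_filters
#' @return Records with an `abs_cv` column.
#' @export
compute_abs_cv <- function(records) {
  records <- validate_records(records)
  out <- dplyr::mutate(records,
                       abs_cv = ifelse(.data$raw_mean == 0, NA_real_,
                                       abs(.data$raw_sd / .data$raw_mean)))
  dropped <- dplyr::filter(out, is.na(.data$abs_cv) & !is.na(.data$raw_sd))
  structure(out, cv_exclusions = dplyr::mutate(dropped, reason = "zero mean: CV undefined"))
}

#' Summarize a meta-analytic dataset
#'
#' Per-context (and overall) counts of studies, species, mean records and SD
#' records, plus the mean and SD of records-per-study and of distinct
#' traits-per-study.
#'
#' @inheritParams apply_filters
#' @return A tibble with one row per context plus an `"all"` row.
#' @export
summarize_dataset <- function(records) {
  records <- validate_records(records)
  one <- function(df, label) {
    per_study <- df |>
      dplyr::group_by(.data$study_id) |>
      dplyr::summarise(n_records = dplyr::n(),
                       n_traits = dplyr::n_distinct(.data$trait_id),
                       .groups = "drop")
    tibble::tibble(
      context = label,
      n_studies = dplyr::n_distinct(df$study_id),
      n_species = dplyr::n_distinct(df$species_id),
      n_mean_records = nrow(df),
      n_sd_records = sum(!is.na(df$raw_sd)),
      records_per_study_mean = mean(per_study$n_records),
      records_per_study_sd = sd(per_study$n_records),
      traits_per_study_mean = mean(per_study$n_traits),
      traits_per_study_sd = sd(per_study$n_traits)
    )
  }
  dplyr::bind_rows(
    records |>
      dplyr::group_by(.data$context) |>
      dplyr::group_map(~ one(.x |> dplyr::mutate(context = .y$context), .y$context)) |>
      dplyr::bind_rows(),
    one(records, "all")
  )
}

#' Full data-preparation pipeline
#'
#' Chains the preparation steps in the analysis order: validation, inclusion
#' filters, direction harmonization, per-trait shift to a non-negative
#' baseline, within-(context, study, trait) standardization, absolute-CV
#' computation, and the per-record precision weight.
#'
#' @inheritParams apply_filters
#' @param weighting Weighting scheme: `"n"` (weight = sample size, precision
#'   proportional to n; the default), `"inverse_n"` (weight = 1/n, the
#'   literal reading of "weighted by the inverse of the sample size"), or
#'   `"none"` (unit weights).
#' @return A standardized record tibble with `standardized_mean`, `abs_cv`
#'   and `weight` columns; exclusion logs are carried in the `"exclusions"`
#'   and `"cv_exclusions"` attributes.
#' @export
prepare_records <- function(records, remove_dogs = TRUE, min_values_per_trait = 2,
                            weighting = c("n", "inverse_n", "none")) {
  weighting <- match.arg(weighting)
  filtered <- apply_filters(records, remove_dogs = remove_dogs,
                            min_values_per_trait = min_values_per_trait)
  exclusions <- exclusion_log(filtered)
  out <- filtered |>
    harmonize_direction() |>
    shift_to_nonnegative() |>
    standardize_within() |>
    compute_abs_cv()
  out <- dplyr::mutate(out, weight = switch(weighting,
                                            n = as.numeric(.data$sample_size),
                                            inverse_n = 1 / as.numeric(.data$sample_size),
                                            none = 1))
  structure(out, exclusions = exclusions,
            cv_exclusions = attr(out, "cv_exclusions"))
}
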