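test_that("generation counts are the unrounded quotient, with a division guard", {
  expect_equal(compute_generations(100, 2), 50)
  expect_equal(compute_generations(0, 5), 0)
  expect_equal(compute_generations(c(10, 33), c(4, 3)), c(2.5, 11))
  expect_error(compute_generations(30, 0), class = "relaxsel_invalid_input")
  expect_error(compute_generations(30, -1), class = "relaxsel_invalid_input")
})

test_that("inclusion filters drop high-fear lines, dogs, and sparse trait groups", {
  # 6 records: exactly one (study, trait) group holds a single value
  rec <- toy_records(6,
                     study_id = "s1",
                     trait_id = c("t1", "t1", "t2", "t2", "t2", "t9"))
  out <- apply_filters(rec, min_values_per_trait = 2)
  expect_equal(nrow(out), 5)
  log <- exclusion_log(out)
  expect_equal(log$trait_id, "t9")
  expect_match(log$reason, "fewer than 2 values")

  # high-fear selection lines always go
  rec2 <- toy_records(4, selected_for_high_fear = c(TRUE, TRUE, FALSE, FALSE))
  out2 <- apply_filters(rec2)
  expect_false(any(out2$selected_for_high_fear))
  expect_equal(exclusion_log(out2)$reason,
               rep("high-fear selection line", 2))

  # dogs go only when requested
  rec3 <- toy_records(4, species_id = c("Canis_familiaris", "sp1", "sp1", "sp1"))
  expect_equal(nrow(apply_filters(rec3, remove_dogs = TRUE)), 3)
  expect_equal(nrow(apply_filters(rec3, remove_dogs = FALSE)), 4)

  # all pass -> identity
  rec4 <- toy_records(4)
  expect_equal(nrow(apply_filters(rec4)), 4)
  expect_equal(nrow(exclusion_log(apply_filters(rec4))), 0)

  # empty input -> empty output, no error
  expect_equal(nrow(apply_filters(toy_records(0))), 0)
})

test_that("filtering conserves records: retained + excluded = input", {
  set.seed(7)
  for (i in 1:5) {
    n <- 30
    rec <- toy_records(n,
                       study_id = sample(c("s1", "s2", "s3"), n, TRUE),
                       trait_id = sample(c("t1", "t2", "t3", "t4"), n, TRUE),
                       species_id = sample(c("sp1", "Canis_familiaris"), n, TRUE),
                       selected_for_high_fear = sample(c(TRUE, FALSE), n, TRUE, prob = c(.2, .8)))
    out <- apply_filters(rec)
    expect_equal(nrow(out) + nrow(exclusion_log(out)), n)
    expect_lte(nrow(out), n)
    grp <- dplyr::count(out, study_id, trait_id)
    expect_true(all(grp$n >= 2))
  }
})

test_that("direction harmonization orients means, leaves SDs, and is idempotent", {
  rec <- toy_records(2, raw_mean = c(5, 3), raw_sd = c(1.2, 0.7),
                     direction = c(-1, 1))
  out <- harmonize_direction(rec)
  expect_equal(out$raw_mean, c(-5, 3))
  expect_equal(out$raw_sd, c(1.2, 0.7))
  expect_equal(harmonize_direction(out)$raw_mean, out$raw_mean)
})

test_that("shift to non-negative zeroes negative-minimum trait groups only", {
  rec <- toy_records(5, trait_id = c("t1", "t1", "t1", "t2", "t2"),
                     raw_mean = c(-2, 0, 3, 1, 2))
  out <- shift_to_nonnegative(rec)
  expect_equal(out$raw_mean, c(0, 2, 5, 1, 2))

  single <- toy_records(1, raw_mean = -1.5)
  expect_equal(shift_to_nonnegative(single)$raw_mean, 0)

  # pairwise differences within a trait group are preserved
  set.seed(11)
  rnd <- toy_records(8, raw_mean = rnorm(8, 0, 3))
  shifted <- shift_to_nonnegative(rnd)
  expect_equal(diff(shifted$raw_mean), diff(rnd$raw_mean))
  expect_gte(min(shifted$raw_mean), 0)
})

test_that("within-group standardization yields sample z-scores and handles degeneracy", {
  rec <- toy_records(3, raw_mean = c(1, 2, 3))
  out <- standardize_within(rec)
  expect_equal(out$standardized_mean, c(-1, 0, 1))

  expect_warning(
    deg <- standardize_within(toy_records(2, raw_mean = c(4, 4))),
    "zero spread"
  )
  expect_equal(deg$standardized_mean, c(0, 0))

  # z-score property on arbitrary groups, and idempotence
  set.seed(3)
  rnd <- toy_records(12, study_id = rep(c("s1", "s2"), each = 6),
                     raw_mean = rnorm(12))
  z <- standardize_within(rnd)
  for (s in c("s1", "s2")) {
    v <- z$standardized_mean[z$study_id == s]
    expect_equal(mean(v), 0, tolerance = 1e-12)
    expect_equal(sd(v), 1, tolerance = 1e-12)
  }
  expect_equal(standardize_within(z)$standardized_mean, z$standardized_mean)
})

test_that("absolute CV is |sd/mean|, direction-invariant, undefined at zero mean", {
  rec <- toy_records(3, raw_mean = c(2, -2, 0), raw_sd = c(1, 1, 1))
  out <- compute_abs_cv(rec)
  expect_equal(out$abs_cv, c(0.5, 0.5, NA_real_))
  dropped <- attr(out, "cv_exclusions")
  expect_equal(nrow(dropped), 1)
  expect_match(dropped$reason, "zero mean")

  # invariant under direction flip of the mean
  flipped <- compute_abs_cv(harmonize_direction(
    toy_records(2, raw_mean = c(2, -2), raw_sd = 1, direction = c(-1, -1))))
  expect_equal(flipped$abs_cv, c(0.5, 0.5))
})

test_that("dataset summary counts studies, records and distinct traits", {
  rec <- toy_records(8,
                     study_id = rep(c("s1", "s2"), c(3, 5)),
                     trait_id = c("fid", "fid", "vig", rep("fid", 5)))
  s <- summarize_dataset(rec)
  all_row <- s[s$context == "all", ]
  expect_equal(all_row$n_studies, 2)
  expect_equal(all_row$n_mean_records, 8)
  expect_equal(all_row$records_per_study_mean, 4)
  expect_equal(all_row$traits_per_study_mean, 1.5)  # {fid, vig} and {fid}

  # repeated measurement of the same trait counts once
  rep_tr <- toy_records(4, trait_id = c("fid", "fid", "vig", "vig"))
  expect_equal(summarize_dataset(rep_tr)$traits_per_study_mean[1], 2)
})

test_that("prepare_records chains the steps and attaches the weight scheme", {
  rec <- toy_records(6, raw_mean = c(-3, 1, 2, 4, 5, 6), direction = c(-1, rep(1, 5)))
  out <- prepare_records(rec)
  expect_true(all(c("standardized_mean", "abs_cv", "weight") %in% names(out)))
  expect_equal(out$weight, as.numeric(out$sample_size))
  out_inv <- prepare_records(rec, weighting = "inverse_n")
  expect_equal(out_inv$weight, 1 / as.numeric(out_inv$sample_size))
  expect_equal(prepare_records(rec, weighting = "none")$weight, rep(1, 6))
})

test_that("record validation rejects schema violations", {
  expect_error(validate_records(toy_records(2)[, -1]), "missing columns")
  expect_error(validate_records(toy_records(2, raw_sd = -1)),
               class = "relaxsel_invalid_input")
  expect_error(validate_records(toy_records(2, direction = 2)),
               class = "relaxsel_invalid_input")
  expect_error(validate_records(toy_records(2, context = "zoo")),
               class = "relaxsel_invalid_input")
})
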