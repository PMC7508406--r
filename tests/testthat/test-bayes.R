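test_that("the design exposes the frozen curve as a basis covariate", {
  rec <- gibbs_records(y = c(1, 2, 3), x = c(0, 1, 2))
  d <- build_design(rec, inverse_params(0, 1, 0.5), random_levels = "study")
  expect_equal(unname(d$X[, "basis"]), c(1, 0.5, 0.25))
  expect_equal(colnames(d$X), c("(Intercept)", "basis"))

  # Weibull basis is zero before onset
  wrec <- gibbs_records(y = rnorm(4), x = c(0, 2, 6, 10))
  wd <- build_design(wrec, weibull_params(0.5, 1, 2, 5, t_min = 4),
                     random_levels = "study")
  expect_equal(unname(wd$X[1:2, "basis"]), c(0, 0))
  expect_gt(wd$X[3, "basis"], 0)
})

test_that("group interactions use reference-free coding, one intercept and slope per level", {
  rec <- gibbs_records(y = rnorm(8), x = rep(c(0, 5, 10, 20), 2),
                       species = rep(c("sp1", "sp2"), each = 4))
  lh <- tibble::tibble(species_id = c("sp1", "sp2"),
                       foraging_guild = c("herbivore", "carnivore"),
                       sociality = c("solitary", "gregarious"),
                       max_longevity = c(10, 20))
  d <- build_design(rec, inverse_params(0, 1, 0.9), group = "sociality",
                    random_levels = "study", life_history = lh)
  expect_equal(ncol(d$X), 4)  # 2 intercepts + 2 slopes
  expect_setequal(colnames(d$X),
                  c("sociality=gregarious", "sociality=solitary",
                    "sociality=gregarious:basis", "sociality=solitary:basis"))
  # each record loads exactly one intercept and one slope column
  expect_equal(unname(rowSums(d$X[, 1:2])), rep(1, 8))

  expect_error(build_design(rec, inverse_params(0, 1, 0.9), group = "sociality",
                            random_levels = "study"),
               class = "relaxsel_invalid_input")
  expect_error(build_design(rec, inverse_params(0, 1, 0.9), group = "sociality",
                            random_levels = "study",
                            life_history = lh[1, ]),
               regexp = "sp2", class = "relaxsel_missing_lifehistory")
})

test_that("collinear designs are rejected with the offending columns named", {
  rec <- gibbs_records(y = rnorm(6), x = rep(3, 6))  # constant basis
  expect_error(build_design(rec, inverse_params(0, 1, 0.9), random_levels = "study"),
               regexp = "basis", class = "relaxsel_singular_design")
})

test_that("Gibbs posterior matches the analytic conjugate posterior", {
  set.seed(5)
  n <- 120
  x <- rnorm(n)
  w <- runif(n, 0.5, 2)
  s2 <- 1.3
  y <- 0.7 * x + rnorm(n, 0, sqrt(s2 / w))
  rec <- gibbs_records(y = y, x = seq_len(n), weight = w)
  des <- build_design(rec, inverse_params(0, 1, 0.9), random_levels = "study")
  des$X <- cbind(slope = x)
  fit <- run_gibbs(des, quick_mcmc(n_iter = 6000, burn_in = 1000, thin = 5,
                                   n_chains = 2, seed = 3),
                   fixed_variances = list(residual = s2, study = 1e-9))
  draws <- fit$draws[, "slope"]
  post_mean <- sum(w * x * y) / sum(w * x^2)
  post_sd <- sqrt(s2 / sum(w * x^2))
  mcse <- sd(draws) / sqrt(ess_total(fit, "slope"))
  expect_lt(abs(mean(draws) - post_mean), 3 * mcse)
  expect_equal(sd(draws), post_sd, tolerance = 0.1)
})

test_that("variance components are recovered within a factor of two", {
  set.seed(21)
  n_study <- 40; per <- 10
  f <- rep(seq_len(n_study), each = per)
  u <- rnorm(n_study, 0, 1)
  x <- runif(n_study * per, 0, 50)
  y <- 0.5 + u[f] + rnorm(n_study * per, 0, 1)
  rec <- gibbs_records(y = y, x = x, study = sprintf("s%02d", f))
  des <- build_design(rec, inverse_params(0, 1, 0.9), random_levels = "study")
  fit <- run_gibbs(des, quick_mcmc(n_iter = 8000, burn_in = 1000, thin = 5, seed = 9))
  expect_gt(median(fit$draws[, "sigma2_study"]), 0.5)
  expect_lt(median(fit$draws[, "sigma2_study"]), 2.0)
  expect_gt(median(fit$draws[, "sigma2_residual"]), 0.5)
  expect_lt(median(fit$draws[, "sigma2_residual"]), 2.0)
})

test_that("chains are reproducible and consistent across replication", {
  set.seed(2)
  rec <- gibbs_records(y = rnorm(60), x = rep(seq(0, 40, 10), 12),
                       study = rep(sprintf("s%d", 1:6), each = 10))
  des <- build_design(rec, inverse_params(0, 1, 0.9), random_levels = "study")
  f1 <- run_gibbs(des, quick_mcmc(seed = 11))
  f2 <- run_gibbs(des, quick_mcmc(seed = 11))
  expect_identical(f1$draws, f2$draws)

  # 5 chains agree on the slope posterior within 3 combined MC SEs
  f5 <- run_gibbs(des, quick_mcmc(n_iter = 6000, burn_in = 1000, thin = 5,
                                  n_chains = 5, seed = 13))
  per_chain <- tapply(f5$draws[, "basis"], f5$chain, mean)
  mcse <- sd(f5$draws[, "basis"]) / sqrt(ess_total(f5, "basis"))
  expect_lt(max(per_chain) - min(per_chain), 2 * 3 * sqrt(5) * mcse)
})

test_that("doubling all weights leaves the fixed-effect posterior unchanged", {
  set.seed(31)
  rec <- gibbs_records(y = rnorm(80, 1), x = rep(seq(0, 70, 10), 10),
                       weight = runif(80, 1, 4),
                       study = rep(sprintf("s%d", 1:8), each = 10))
  des1 <- build_design(rec, inverse_params(0, 1, 0.9), random_levels = "study")
  des2 <- des1; des2$weights <- des1$weights * 2
  cfg <- quick_mcmc(n_iter = 6000, burn_in = 1000, thin = 5, seed = 17)
  f1 <- run_gibbs(des1, cfg)
  f2 <- run_gibbs(des2, cfg)
  for (term in c("(Intercept)", "basis")) {
    mcse <- sd(f1$draws[, term]) / sqrt(ess_total(f1, term))
    expect_lt(abs(mean(f1$draws[, term]) - mean(f2$draws[, term])), 4 * mcse)
  }
  # residual variance rescales by the weight factor
  expect_equal(median(f2$draws[, "sigma2_residual"]) /
                 median(f1$draws[, "sigma2_residual"]), 2, tolerance = 0.25)
})

test_that("with an identity phylogeny the species-linked variance sum is recovered", {
  set.seed(41)
  n_sp <- 25; per <- 12
  f <- rep(seq_len(n_sp), each = per)
  u <- rnorm(n_sp, 0, sqrt(1.0))   # combined species-linked variance 1
  y <- u[f] + rnorm(n_sp * per, 0, 1)
  rec <- gibbs_records(y = y, x = rep(seq(0, 55, 5), n_sp),
                       species = sprintf("sp%02d", f),
                       study = sprintf("s%02d", f))
  A <- diag(n_sp)
  rownames(A) <- colnames(A) <- sprintf("sp%02d", seq_len(n_sp))
  des <- build_design(rec, inverse_params(0, 1, 0.9),
                      random_levels = c("species", "phylogeny"), tree = A)
  fit <- run_gibbs(des, quick_mcmc(n_iter = 8000, burn_in = 1000, thin = 5, seed = 19))
  total <- fit$draws[, "sigma2_species"] + fit$draws[, "sigma2_phylogeny"]
  expect_gt(median(total), 0.4)
  expect_lt(median(total), 2.5)
})

test_that("config guards reject impossible MCMC settings and empty data", {
  expect_error(mcmc_config(n_iter = 100, burn_in = 100),
               class = "relaxsel_invalid_input")
  expect_error(mcmc_config(thin = 0), class = "relaxsel_invalid_input")
  expect_error(significance_of_fit(toy_records(0), inverse_params(0, 1, 0.9)),
               class = "relaxsel_invalid_input")
})

test_that("posterior summaries have the stated pMCMC and interval behavior", {
  # degenerate one-sided posterior
  all_pos <- fake_mcmc(matrix(1, 500, 1, dimnames = list(NULL, "b")))
  s <- summarize_posterior(all_pos)
  expect_equal(s$pmcmc, 1 / 500)
  expect_true(s$significant)

  # perfectly balanced posterior
  bal <- fake_mcmc(matrix(rep(c(-1, 1), 250), ncol = 1,
                          dimnames = list(NULL, "b")))
  s2 <- summarize_posterior(bal)
  expect_equal(s2$pmcmc, 1)
  expect_false(s2$significant)

  # standard-normal draws give the usual 95% interval
  set.seed(8)
  z <- fake_mcmc(matrix(rnorm(1000), ncol = 1, dimnames = list(NULL, "b")))
  s3 <- summarize_posterior(z)
  expect_equal(s3$conf.low, -1.96, tolerance = 0.15)
  expect_equal(s3$conf.high, 1.96, tolerance = 0.15)

  # variance terms are summarized without pMCMC
  v <- fake_mcmc(matrix(rexp(200), ncol = 1, dimnames = list(NULL, "sigma2_study")))
  expect_true(is.na(summarize_posterior(v)$pmcmc))
})

test_that("DIC collapses to the plug-in deviance for a degenerate posterior", {
  set.seed(3)
  rec <- gibbs_records(y = rnorm(40), x = rep(seq(0, 30, 10), 10),
                       study = rep(c("s1", "s2"), each = 20))
  des <- build_design(rec, inverse_params(0, 1, 0.9), random_levels = "study")
  fit <- run_gibbs(des, quick_mcmc(seed = 2))
  one <- fit$draws[17, , drop = FALSE]
  degen <- fit
  degen$draws <- one[rep(1, 200), ]
  d <- compute_dic(degen)
  expect_equal(d$p_d, 0, tolerance = 1e-10)
  expect_equal(d$dic, d$deviance_at_mean, tolerance = 1e-10)

  # determinism: recomputation from stored draws is bit-identical
  expect_identical(compute_dic(fit)$dic, compute_dic(fit)$dic)
})

test_that("adding a pure-noise fixed effect raises the effective parameter count by one", {
  pd_diff <- sapply(1:20, function(s) {
    set.seed(4000 + s)
    n_study <- 15; per <- 8
    f <- rep(seq_len(n_study), each = per)
    u <- rnorm(n_study, 0, 0.5)
    x <- rep(seq(0, 50, length.out = per), n_study)
    y <- 0.2 + 1.5 * 0.9^x + u[f] + rnorm(n_study * per)
    rec <- gibbs_records(y = y, x = x, study = sprintf("s%02d", f))
    d1 <- build_design(rec, inverse_params(0.2, 1.5, 0.9), random_levels = "study")
    d2 <- d1
    d2$X <- cbind(d1$X, noise = rnorm(nrow(rec)))
    cfg <- quick_mcmc(n_iter = 3000, burn_in = 500, thin = 3, seed = s)
    pd1 <- compute_dic(run_gibbs(d1, cfg))$p_d
    cfg$seed <- s + 500
    pd2 <- compute_dic(run_gibbs(d2, cfg))$p_d
    pd2 - pd1
  })
  expect_equal(mean(pd_diff), 1, tolerance = 0.5)
})

test_that("DIC weights follow the exponential-difference formula", {
  eq <- rank_models(tibble::tibble(model = paste0("m", 1:4), dic = rep(100, 4)))
  expect_equal(eq$dic_weight, rep(0.25, 4))
  expect_equal(eq$delta_dic, rep(0, 4))

  two <- rank_models(tibble::tibble(model = c("a", "b"), dic = c(10, 12)))
  expect_equal(two$dic_weight, c(0.731, 0.269), tolerance = 1e-3)
  expect_equal(two$delta_dic, c(0, 2))

  set.seed(10)
  many <- rank_models(tibble::tibble(dic = rnorm(7, 100, 5)))
  expect_equal(sum(many$dic_weight), 1)
  expect_equal(min(many$delta_dic), 0)
  expect_true(all(diff(many$delta_dic) >= 0))

  single <- rank_models(tibble::tibble(dic = 50))
  expect_equal(single$dic_weight, 1)
})
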