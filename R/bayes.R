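#' Build the meta-regression design from records and a fitted curve shape
#'
#' Constructs the response vector, fixed-effects matrix and random-effect
#' incidence maps for the Bayesian multilevel meta-regression. The nonlinear
#' trajectory enters as a single *basis covariate* with its shape frozen
#' from the CMA-ES stage: \eqn{a^x} for the inverse curve, the Weibull bump
#' term (zero before `t_min`) for the CV curve. The Bayesian model then
#' estimates an intercept (asymptote/baseline) and a slope on this basis;
#' the slope is the significance test of the curve.
#'
#' With a grouping factor (foraging guild or sociality) the model is fitted
#' reference-free: one intercept and one basis-slope column per group level
#' and no global intercept, so each level's trajectory is directly readable.
#'
#' @param records Prepared records (see [prepare_records()]) with a `weight`
#'   column.
#' @param params An [inverse_params()] or [weibull_params()] object, or a
#'   `traj_fit`.
#' @param response `"standardized_mean"` or `"abs_cv"`.
#' @param group `"none"`, `"foraging_guild"` or `"sociality"`; factors enter
#'   as level-wise intercepts plus level x basis interactions.
#' @param longevity Add (standardized) maximum longevity as a continuous
#'   fixed covariate? Default `FALSE`.
#' @param random_levels Subset of `c("study", "species", "phylogeny",
#'   "trait_type")`.
#' @param life_history Species life-history table with columns `species_id`,
#'   `foraging_guild`, `sociality`, `max_longevity`; required when `group`
#'   or `longevity` is requested.
#' @param tree Ultrametric `ape::phylo` tree covering all species; required
#'   when `"phylogeny"` is in `random_levels`.
#' @return A `relax_design` object.
#' @export
build_design <- function(records, params,
                         response = c("standardized_mean", "abs_cv"),
                         group = c("none", "foraging_guild", "sociality"),
                         longevity = FALSE,
                         random_levels = c("study", "species", "phylogeny", "trait_type"),
                         life_history = NULL, tree = NULL) {
  response <- match.arg(response)
  group <- match.arg(group)
  random_levels <- match.arg(random_levels, several.ok = TRUE,
                             choices = c("study", "species", "phylogeny", "trait_type"))
  if (inherits(params, "traj_fit")) params <- params$params
  records <- tibble::as_tibble(records)
  if (!response %in% names(records)) {
    abort(paste0("records lack a `", response, "` column; run prepare_records() first."),
          class = "relaxsel_invalid_input")
  }
  records <- dplyr::filter(records, !is.na(.data[[response]]))
  if (nrow(records) == 0) {
    abort("no usable records after dropping missing responses.",
          class = "relaxsel_invalid_input")
  }

  basis <- if (inherits(params, "inverse_params")) {
    params$a^records$generation
  } else {
    weibull_curve(records$generation, params) - params$y_ini
  }

  needs_lh <- group != "none" || longevity
  if (needs_lh) {
    if (is.null(life_history)) {
      abort("life_history table required for group/longevity terms.",
            class = "relaxsel_invalid_input")
    }
    miss <- setdiff(unique(records$species_id), life_history$species_id)
    if (length(miss)) {
      abort(paste0("life-history data missing for species: ",
                   paste(miss, collapse = ", ")),
            class = "relaxsel_missing_lifehistory")
    }
    records <- dplyr::left_join(
      records,
      dplyr::select(life_history, "species_id", "foraging_guild",
                    "sociality", "max_longevity"),
      by = "species_id"
    )
  }

  if (group == "none") {
    X <- cbind(`(Intercept)` = rep(1, nrow(records)), basis = basis)
  } else {
    g <- factor(records[[group]])
    levs <- levels(g)
    Xi <- sapply(levs, function(l) as.numeric(g == l))
    Xs <- Xi * basis
    colnames(Xi) <- paste0(group, "=", levs)
    colnames(Xs) <- paste0(group, "=", levs, ":basis")
    X <- cbind(Xi, Xs)
  }
  if (longevity) {
    lon <- records$max_longevity
    X <- cbind(X, longevity = as.numeric(scale(lon)))
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[-qrX$pivot[seq_len(qrX$rank)]]
    abort(paste0("fixed-effects matrix is singular; collinear columns: ",
                 paste(dropped, collapse = ", ")),
          class = "relaxsel_singular_design")
  }

  level_cols <- c(study = "study_id", species = "species_id",
                  phylogeny = "species_id", trait_type = "trait_class")
  levels_map <- list()
  A <- NULL
  for (lv in random_levels) {
    fac <- factor(records[[level_cols[[lv]]]])
    levels_map[[lv]] <- list(index = as.integer(fac), labels = levels(fac),
                             q = nlevels(fac), correlated = identical(lv, "phylogeny"))
  }
  if ("phylogeny" %in% random_levels) {
    if (is.null(tree)) {
      abort("a tree (or correlation matrix) is required for the phylogeny level.",
            class = "relaxsel_invalid_input")
    }
    A_full <- if (is.matrix(tree)) tree else phylo_correlation(tree)
    sp <- levels_map$phylogeny$labels
    miss <- setdiff(sp, rownames(A_full))
    if (length(miss)) {
      abort(paste0("species missing from phylogeny: ", paste(miss, collapse = ", ")),
            class = "relaxsel_missing_species")
    }
    A <- A_full[sp, sp, drop = FALSE]
  }

  w <- if ("weight" %in% names(records)) as.numeric(records$weight) else rep(1, nrow(records))
  if (any(w <= 0)) abort("weights must be positive.", class = "relaxsel_invalid_input")

  structure(
    list(y = as.numeric(records[[response]]), X = X, weights = w,
         levels = levels_map, A = A, response = response,
         basis = basis, n = nrow(records)),
    class = "relax_design"
  )
}

#' @export
print.relax_design <- function(x, ...) {
  cat("<relax_design> ", x$n, " records, ", ncol(x$X), " fixed effects (",
      paste(colnames(x$X), collapse = ", "), "), random levels: ",
      paste(names(x$levels), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' MCMC settings for the meta-regression
#'
#' Defaults follow the study settings: 1,000,000 iterations, burn-in 30,000,
#' thinning 100, inverse-Wishart variance prior with expected variance
#' `V = 1` and degree of belief `nu = 0.02` (the univariate inverse-Wishart
#' reduces to an inverse-gamma with shape `nu/2` and scale `nu * V / 2`),
#' and 5 chains to check consistency. Tests and interactive exploration
#' should scale `n_iter`/`burn_in`/`thin` down.
#'
#' @param n_iter Total Gibbs iterations per chain.
#' @param burn_in Discarded initial iterations; must be `< n_iter`.
#' @param thin Thinning interval (>= 1).
#' @param prior_V Expected variance of the inverse-Wishart prior.
#' @param prior_nu Degree of belief of the inverse-Wishart prior.
#' @param n_chains Number of independent chains.
#' @param seed Integer seed; chain `i` runs on a seed derived from it.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 1e6, burn_in = 30000, thin = 100,
                        prior_V = 1, prior_nu = 0.02, n_chains = 5, seed = 1) {
  if (burn_in >= n_iter) {
    abort("`burn_in` must be smaller than `n_iter`.", class = "relaxsel_invalid_input")
  }
  if (thin < 1) abort("`thin` must be >= 1.", class = "relaxsel_invalid_input")
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), prior_V = prior_V, prior_nu = prior_nu,
                 n_chains = as.integer(n_chains), seed = as.integer(seed)),
            class = "mcmc_config")
}

#' Gibbs sampler for the Gaussian multilevel meta-regression
#'
#' Samples the model
#' \deqn{y = X\beta + \sum_l Z_l u_l + e, \quad
#'   u_{phylo} \sim N(0, \sigma^2_{phylo} A), \quad
#'   u_l \sim N(0, \sigma^2_l I), \quad
#'   e_i \sim N(0, \sigma^2_e / w_i),}
#' with a flat prior on the fixed effects and scalar inverse-Wishart
#' (inverse-gamma) priors on every variance component. All full
#' conditionals are conjugate, so the chain is a plain Gibbs sampler,
#' deterministic given the seed.
#'
#' @param design A `relax_design` from [build_design()].
#' @param config An [mcmc_config()]; scale it down for interactive use.
#' @param fixed_variances Optional named list fixing variance components
#'   (names among the random levels and `"residual"`); fixed components are
#'   not sampled. Used for exact conjugate checks.
#' @return A `relax_mcmc` object with the retained draws (fixed effects and
#'   `sigma2_*` variance components), chain ids, and the design.
#' @export
run_gibbs <- function(design, config = mcmc_config(), fixed_variances = NULL) {
  stopifnot(inherits(design, "relax_design"))
  if (!inherits(config, "mcmc_config")) config <- do.call(mcmc_config, config)
  y <- design$y; X <- design$X; w <- design$weights
  n <- length(y); p <- ncol(X)
  levels_map <- design$levels
  lnames <- names(levels_map) %||% character(0)
  if (!is.null(fixed_variances)) {
    bad <- setdiff(names(fixed_variances), c(lnames, "residual"))
    if (length(bad)) {
      abort(paste0("fixed_variances names not in model: ", paste(bad, collapse = ", ")),
            class = "relaxsel_invalid_input")
    }
  }

  XtWX <- crossprod(X, X * w)
  Rxx <- chol(XtWX)
  Ainv <- NULL
  if ("phylogeny" %in% lnames) {
    Ainv <- chol2inv(chol(design$A + diag(1e-10, nrow(design$A))))
  }
  d_list <- lapply(levels_map, function(l) as.numeric(rowsum(w, l$index)))

  nu <- config$prior_nu; V0 <- config$prior_V
  n_keep <- (config$n_iter - config$burn_in) %/% config$thin
  var_names <- if (length(lnames)) paste0("sigma2_", lnames) else character(0)
  cn <- c(colnames(X), var_names, "sigma2_residual")

  run_chain <- function(chain_seed) {
    with_seed(chain_seed, {
      draws <- matrix(NA_real_, n_keep, length(cn), dimnames = list(NULL, cn))
      u <- lapply(levels_map, function(l) numeric(l$q))
      sig2 <- setNames(rep(1, length(lnames) + 1), c(lnames, "residual"))
      for (nm in names(fixed_variances)) sig2[[nm]] <- fixed_variances[[nm]]
      zu <- numeric(n)
      kept <- 0L
      for (iter in seq_len(config$n_iter)) {
        # fixed effects
        r <- y - zu
        b <- crossprod(X, w * r)
        mean_beta <- backsolve(Rxx, forwardsolve(t(Rxx), b))
        beta <- mean_beta + sqrt(sig2[["residual"]]) * backsolve(Rxx, rnorm(p))
        xb <- as.numeric(X %*% beta)
        # random levels
        for (lv in lnames) {
          l <- levels_map[[lv]]
          contrib <- u[[lv]][l$index]
          e_l <- y - xb - (zu - contrib)
          s <- as.numeric(rowsum(w * e_l, l$index))
          d <- d_list[[lv]]
          if (l$correlated) {
            P <- diag(d / sig2[["residual"]], l$q) + Ainv / sig2[[lv]]
            Rp <- chol(P)
            m <- backsolve(Rp, forwardsolve(t(Rp), s / sig2[["residual"]]))
            u_new <- as.numeric(m + backsolve(Rp, rnorm(l$q)))
          } else {
            prec <- d / sig2[["residual"]] + 1 / sig2[[lv]]
            u_new <- s / sig2[["residual"]] / prec + rnorm(l$q) / sqrt(prec)
          }
          u[[lv]] <- u_new
          zu <- zu - contrib + u_new[l$index]
          if (is.null(fixed_variances[[lv]])) {
            quad <- if (l$correlated) sum(u_new * (Ainv %*% u_new)) else sum(u_new^2)
            sig2[[lv]] <- 1 / rgamma(1, (nu + l$q) / 2, rate = (nu * V0 + quad) / 2)
          }
        }
        # residual variance
        if (is.null(fixed_variances[["residual"]])) {
          e <- y - xb - zu
          sig2[["residual"]] <- 1 / rgamma(1, (nu + n) / 2,
                                           rate = (nu * V0 + sum(w * e^2)) / 2)
        }
        if (iter > config$burn_in && (iter - config$burn_in) %% config$thin == 0) {
          kept <- kept + 1L
          draws[kept, ] <- c(beta, sig2[lnames], sig2[["residual"]])
        }
      }
      draws
    })
  }

  chain_draws <- purrr::map(seq_len(config$n_chains), function(i) {
    run_chain(derive_seed(config$seed, paste0("chain", i)))
  })
  structure(
    list(draws = do.call(rbind, chain_draws),
         chain = rep(seq_len(config$n_chains), each = n_keep),
         design = design, config = config,
         fixed_variances = fixed_variances),
    class = "relax_mcmc"
  )
}

#' @export
print.relax_mcmc <- function(x, ...) {
  cat("<relax_mcmc> ", nrow(x$draws), " retained draws (",
      x$config$n_chains, " chain(s)), terms: ",
      paste(colnames(x$draws), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Summarize a posterior sample
#'
#' Posterior mean, equal-tailed 95% credible interval, effective sample
#' size, and for fixed effects the MCMC p-value
#' `pMCMC = 2 * min(P(draw > 0), P(draw < 0))`, floored at one over the
#' number of retained draws. A fixed effect is flagged significant when its
#' credible interval excludes zero.
#'
#' @param fit A `relax_mcmc` from [run_gibbs()].
#' @param conf Credible-interval mass; default 0.95.
#' @return A tibble with columns `term`, `type`, `estimate`, `conf.low`,
#'   `conf.high`, `pmcmc`, `ess`, `significant`.
#' @export
summarize_posterior <- function(fit, conf = 0.95) {
  stopifnot(inherits(fit, "relax_mcmc"))
  draws <- fit$draws
  if (nrow(draws) < 100) {
    warn("fewer than 100 retained draws; summaries will be unstable.")
  }
  alpha <- (1 - conf) / 2
  purrr::map_dfr(colnames(draws), function(term) {
    v <- draws[, term]
    is_var <- startsWith(term, "sigma2_")
    ci <- unname(quantile(v, c(alpha, 1 - alpha), names = FALSE))
    pm <- if (is_var) NA_real_ else {
      max(2 * min(mean(v > 0), mean(v < 0)), 1 / length(v))
    }
    tibble::tibble(
      term = term,
      type = if (is_var) "variance" else "fixed",
      estimate = mean(v), conf.low = ci[1], conf.high = ci[2],
      pmcmc = min(pm, 1),
      ess = sum(purrr::map_dbl(split(v, fit$chain), ess_chain)),
      significant = if (is_var) NA else (ci[1] > 0 || ci[2] < 0)
    )
  })
}

#' @rdname summarize_posterior
#' @param x A `relax_mcmc`.
#' @param ... Unused.
#' @export
tidy.relax_mcmc <- function(x, conf = 0.95, ...) summarize_posterior(x, conf)

#' @rdname summarize_posterior
#' @param object A `relax_mcmc`.
#' @export
glance.relax_mcmc <- function(object, ...) {
  d <- compute_dic(object)
  tibble::tibble(n = object$design$n, n_draws = nrow(object$draws),
                 n_chains = object$config$n_chains, dic = d$dic, p_d = d$p_d)
}

#' Caterpillar plot of posterior estimates
#'
#' @param object A `relax_mcmc`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.relax_mcmc <- function(object, ...) {
  s <- summarize_posterior(object)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$estimate, y = .data$term,
                                  color = .data$type)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, color = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(x = "Posterior mean (95% CI)", y = NULL, color = NULL)
}

# Marginal -2 log-likelihood of each draw with random effects integrated
# out, computed through the Woodbury identity so the per-draw cost is a
# Q x Q solve (Q = total number of random-effect levels), not n x n.
deviance_terms <- function(fit) {
  design <- fit$design
  y <- design$y; X <- design$X; w <- design$weights; n <- length(y)
  lnames <- names(design$levels)
  Q <- sum(purrr::map_int(design$levels, "q"))
  # U = [Z_1, ..., Z_L] incidence; precompute weighted cross-products
  if (Q > 0) {
    U <- matrix(0, n, Q)
    off <- 0L
    blocks <- list()
    for (lv in lnames) {
      l <- design$levels[[lv]]
      U[cbind(seq_len(n), off + l$index)] <- 1
      blocks[[lv]] <- list(idx = off + seq_len(l$q), q = l$q,
                           correlated = l$correlated)
      off <- off + l$q
    }
    M <- crossprod(U, U * w)           # U' W U
    UtWy <- crossprod(U, w * y)
    UtWX <- crossprod(U, w * X)
    Kinv <- NULL
    ldK <- 0
    if ("phylogeny" %in% lnames) {
      cA <- chol(design$A + diag(1e-10, nrow(design$A)))
      Kinv <- chol2inv(cA)
      ldK <- 2 * sum(log(diag(cA)))
    }
  }
  yWy <- sum(w * y^2)
  XtWy <- crossprod(X, w * y)
  XtWX <- crossprod(X, X * w)
  sum_log_w <- sum(log(w))
  p <- ncol(X)

  function(beta, sig2) {
    s2e <- sig2[["residual"]]
    # r' D^{-1} r with D = diag(s2e / w)
    rDr <- (yWy - 2 * sum(beta * XtWy) + sum(beta * (XtWX %*% beta))) / s2e
    ldD <- n * log(s2e) - sum_log_w
    if (Q == 0) {
      return(n * log(2 * pi) + ldD + rDr)
    }
    Sinv <- matrix(0, Q, Q)
    ldS <- 0
    for (lv in lnames) {
      b <- blocks[[lv]]
      if (b$correlated) {
        Sinv[b$idx, b$idx] <- Kinv / sig2[[lv]]
        ldS <- ldS + b$q * log(sig2[[lv]]) + ldK
      } else {
        diag(Sinv)[b$idx] <- 1 / sig2[[lv]]
        ldS <- ldS + b$q * log(sig2[[lv]])
      }
    }
    Amat <- Sinv + M / s2e
    Ra <- chol(Amat)
    UDr <- (UtWy - UtWX %*% beta) / s2e
    z <- forwardsolve(t(Ra), UDr)
    quad <- rDr - sum(z^2)
    ldet <- ldD + ldS + 2 * sum(log(diag(Ra)))
    n * log(2 * pi) + ldet + quad
  }
}

#' Deviance information criterion of a fitted meta-regression
#'
#' DIC = 2 * mean(D) - D(posterior mean), where D is -2 times the Gaussian
#' log-likelihood with all random effects marginalized at the sampled
#' variance components. The effective number of parameters is
#' `p_d = mean(D) - D(posterior mean)`.
#'
#' @param fit A `relax_mcmc`.
#' @return A one-row tibble with `dic`, `p_d`, `mean_deviance`,
#'   `deviance_at_mean`.
#' @export
compute_dic <- function(fit) {
  stopifnot(inherits(fit, "relax_mcmc"))
  dev_fn <- deviance_terms(fit)
  draws <- fit$draws
  lnames <- names(fit$design$levels)
  p <- ncol(fit$design$X)
  beta_cols <- seq_len(p)
  get_sig2 <- function(row) {
    s <- as.list(row[paste0("sigma2_", c(lnames, "residual"))])
    names(s) <- c(lnames, "residual")
    s
  }
  D <- vapply(seq_len(nrow(draws)), function(i) {
    dev_fn(draws[i, beta_cols], get_sig2(draws[i, ]))
  }, numeric(1))
  means <- colMeans(draws)
  Dhat <- dev_fn(means[beta_cols], get_sig2(means))
  tibble::tibble(dic = 2 * mean(D) - Dhat, p_d = mean(D) - Dhat,
                 mean_deviance = mean(D), deviance_at_mean = Dhat)
}

#' Rank models by DIC
#'
#' Adds DIC differences and DIC weights
#' \eqn{w_i = \exp(-\Delta_i/2) / \sum_j \exp(-\Delta_j/2)} to a model
#' table, sorted best-first.
#'
#' @param data A data frame with a `dic` column (one row per model).
#' @return The table with `delta_dic` and `dic_weight` columns, sorted by
#'   `delta_dic`.
#' @examples
#' rank_models(tibble::tibble(model = c("m1", "m2"), dic = c(100, 102)))
#' @export
rank_models <- function(data) {
  stopifnot(is.data.frame(data), "dic" %in% names(data), nrow(data) >= 1)
  out <- dplyr::mutate(tibble::as_tibble(data),
                       delta_dic = .data$dic - min(.data$dic),
                       dic_weight = exp(-.data$delta_dic / 2) /
                         sum(exp(-(.data$dic - min(.data$dic)) / 2)))
  dplyr::arrange(out, .data$delta_dic)
}

#' Test the significance of a fitted trajectory in the full mixed model
#'
#' Freezes the curve shape from the CMA-ES stage, builds the design with all
#' requested random levels (species, phylogeny, study, trait type), runs the
#' Gibbs sampler and summarizes the posterior. The slope on the basis
#' covariate tests the curve's fit; the intercept is the asymptote (inverse)
#' or baseline (Weibull).
#'
#' @inheritParams build_design
#' @param fit A `traj_fit` (or parameter bundle) whose shape is frozen.
#' @param config An [mcmc_config()].
#' @return The posterior summary tibble (see [summarize_posterior()]), with
#'   the full `relax_mcmc` attached as attribute `"mcmc"`.
#' @export
significance_of_fit <- function(records, fit,
                                response = c("standardized_mean", "abs_cv"),
                                random_levels = c("study", "species",
                                                  "phylogeny", "trait_type"),
                                tree = NULL, config = mcmc_config()) {
  response <- match.arg(response)
  if (nrow(records) == 0) {
    abort("no records supplied.", class = "relaxsel_invalid_input")
  }
  design <- build_design(records, fit, response = response,
                         random_levels = random_levels, tree = tree)
  mcmc <- run_gibbs(design, config)
  out <- summarize_posterior(mcmc)
  attr(out, "mcmc") <- mcmc
  out
}
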