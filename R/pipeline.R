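#' Rank life-history interaction models by DIC
#'
#' Enumerates the 2^3 subsets of the life-history traits (foraging guild,
#' sociality, maximum longevity) and fits the meta-regression for each:
#' factors enter reference-free as level intercepts plus level x basis
#' interactions, longevity as a continuous fixed covariate. Models are
#' ranked by DIC with DIC weights.
#'
#' Because the reference-free coding cannot hold two factors at once without
#' collinearity, models containing both factors are fitted with a global
#' intercept plus treatment-coded main effects and basis interactions for
#' the second factor; single-factor models use the reference-free coding
#' that makes each level's trajectory directly readable.
#'
#' @inheritParams build_design
#' @param fit A `traj_fit` (or parameter bundle) fixing the curve shape.
#' @param config An [mcmc_config()].
#' @return A tibble with one row per model (`model`, term flags, `dic`,
#'   `p_d`, `delta_dic`, `dic_weight`), sorted best-first; each row's fitted
#'   `relax_mcmc` is carried in the list-column `mcmc`.
#' @export
rank_lifehistory_models <- function(records, fit, life_history, tree = NULL,
                                    response = "standardized_mean",
                                    random_levels = c("study", "species",
                                                      "phylogeny", "trait_type"),
                                    config = mcmc_config()) {
  combos <- tidyr::expand_grid(foraging = c(FALSE, TRUE),
                               sociality = c(FALSE, TRUE),
                               longevity = c(FALSE, TRUE))
  fits <- purrr::pmap(combos, function(foraging, sociality, longevity) {
    design <- build_lh_design(records, fit, response, foraging, sociality,
                              longevity, random_levels, life_history, tree)
    mcmc <- run_gibbs(design, config)
    list(mcmc = mcmc, dic = compute_dic(mcmc))
  })
  out <- combos |>
    dplyr::mutate(
      model = paste0("mean ~ basis",
                     ifelse(.data$foraging, " + foraging_guild * basis", ""),
                     ifelse(.data$sociality, " + sociality * basis", ""),
                     ifelse(.data$longevity, " + longevity", "")),
      dic = purrr::map_dbl(fits, ~ .x$dic$dic),
      p_d = purrr::map_dbl(fits, ~ .x$dic$p_d),
      mcmc = purrr::map(fits, "mcmc")
    )
  rank_models(out)
}

# Design for an arbitrary subset of life-history terms. Single-factor
# models reuse build_design()'s reference-free coding; the two-factor model
# needs treatment coding for the second factor to stay full-rank.
build_lh_design <- function(records, fit, response, foraging, sociality,
                            longevity, random_levels, life_history, tree) {
  if (!(foraging && sociality)) {
    group <- if (foraging) "foraging_guild" else if (sociality) "sociality" else "none"
    return(build_design(records, fit, response = response, group = group,
                        longevity = longevity, random_levels = random_levels,
                        life_history = life_history, tree = tree))
  }
  base <- build_design(records, fit, response = response,
                       group = "foraging_guild", longevity = longevity,
                       random_levels = random_levels,
                       life_history = life_history, tree = tree)
  records_used <- dplyr::filter(tibble::as_tibble(records),
                                !is.na(.data[[response]]))
  lh <- life_history[match(records_used$species_id, life_history$species_id), ]
  soc <- factor(lh$sociality)
  if (nlevels(soc) > 1) {
    extra <- sapply(levels(soc)[-1], function(l) as.numeric(soc == l))
    extra <- cbind(extra, extra * base$basis)
    colnames(extra) <- c(paste0("sociality=", levels(soc)[-1]),
                         paste0("sociality=", levels(soc)[-1], ":basis"))
    base$X <- cbind(base$X, extra)
    qrX <- qr(base$X)
    if (qrX$rank < ncol(base$X)) {
      # small datasets can confound sociality with guild; keep the model in
      # the ranking with the aliased columns dropped, as lm() would
      keep <- qrX$pivot[seq_len(qrX$rank)]
      warn(paste0("two-factor life-history design is rank-deficient; dropping ",
                  paste(colnames(base$X)[-keep], collapse = ", ")))
      base$X <- base$X[, sort(keep), drop = FALSE]
    }
  }
  base
}

#' Report the trait-type variance share
#'
#' The trait type (behavioral vs physiological) enters the meta-regression
#' as a random level; this reports its variance component and its share of
#' the total posterior variance.
#'
#' @param fit A `relax_mcmc` containing the `trait_type` level.
#' @return A one-row tibble: `sigma2_trait_type`, `share` (percent of total
#'   variance, posterior mean) and its 95% CI.
#' @export
trait_class_effect_report <- function(fit) {
  stopifnot(inherits(fit, "relax_mcmc"))
  if (!"sigma2_trait_type" %in% colnames(fit$draws)) {
    abort("model has no trait_type random level.", class = "relaxsel_invalid_input")
  }
  vcols <- grep("^sigma2_", colnames(fit$draws), value = TRUE)
  total <- rowSums(fit$draws[, vcols, drop = FALSE])
  share_draws <- 100 * fit$draws[, "sigma2_trait_type"] / total
  tibble::tibble(
    sigma2_trait_type = mean(fit$draws[, "sigma2_trait_type"]),
    share = mean(share_draws),
    conf.low = unname(quantile(share_draws, 0.025)),
    conf.high = unname(quantile(share_draws, 0.975))
  )
}

#' Run the full relaxed-selection analysis pipeline
#'
#' For each requested context and response (standardized mean, absolute
#' CV): loess exploration over candidate spans, parametric trajectory fit
#' by CMA-ES (inverse curve for the mean, Weibull for the CV), significance
#' test of the fitted curve in the full Bayesian mixed model (species,
#' phylogeny, study and trait-type random effects), heterogeneity
#' partition, and — for contexts whose mean-model slope is significant, or
#' always when `force_lifehistory = TRUE` — DIC ranking of the life-history
#' interaction models.
#'
#' @param records Raw observation records (see [validate_records()]).
#' @param life_history Species life-history table.
#' @param tree Ultrametric `ape::phylo` tree covering all species.
#' @param contexts Contexts to analyze; default all present in `records`.
#' @param responses Subset of `c("mean", "cv")`.
#' @param spans Candidate loess spans.
#' @param config An [mcmc_config()]; default is a scaled-down setting
#'   (20,000 iterations, burn-in 2,000, thinning 10, 2 chains) suitable for
#'   interactive use — raise it for final inference.
#' @param n_restarts CMA-ES restarts per curve fit.
#' @param seed Master seed; every stochastic stage derives its own seed
#'   from it.
#' @param force_lifehistory Run the life-history ranking even when the
#'   simple model slope is not significant.
#' @param out_dir Optional directory; when given, the report bundle is
#'   written there as TSV/JSON via [write_report_bundle()].
#' @return A `relax_report`: per context a list with elements `prep_summary`,
#'   and per response `loess`, `fit`, `posterior` (S1-style table),
#'   `heterogeneity` (S6-style), `derivatives` (mean response only),
#'   `lifehistory` (S2-style) and `interactions` (S3-style) when run; plus
#'   a `manifest` with the seed and configuration hash.
#' @export
run_pipeline <- function(records, life_history, tree,
                         contexts = NULL, responses = c("mean", "cv"),
                         spans = c(0.5, 0.75, 0.9),
                         config = mcmc_config(n_iter = 20000, burn_in = 2000,
                                              thin = 10, n_chains = 2),
                         n_restarts = 5, seed = 1,
                         force_lifehistory = FALSE, out_dir = NULL) {
  responses <- match.arg(responses, several.ok = TRUE)
  prepared <- prepare_records(records)
  contexts <- contexts %||% unique(prepared$context)
  A <- phylo_correlation(tree)

  result <- purrr::map(setNames(contexts, contexts), function(ctx) {
    ctx_records <- dplyr::filter(prepared, .data$context == ctx)
    out <- list(prep_summary = summarize_dataset(ctx_records))
    for (resp in responses) {
      resp_col <- if (resp == "mean") "standardized_mean" else "abs_cv"
      curve <- if (resp == "mean") "inverse" else "weibull"
      dat <- ctx_records |>
        dplyr::filter(!is.na(.data[[resp_col]])) |>
        dplyr::transmute(x = .data$generation, y = .data[[resp_col]],
                         weight = .data$weight)
      stage <- list()
      stage$loess <- select_smoothing(dat, spans)
      stage$fit <- fit_trajectory(dat, curve, n_restarts = n_restarts,
                                  seed = derive_seed(seed, paste0(ctx, resp, "fit")))
      mcfg <- config
      mcfg$seed <- derive_seed(seed, paste0(ctx, resp, "mcmc"))
      post <- significance_of_fit(ctx_records, stage$fit, response = resp_col,
                                  tree = A, config = mcfg)
      stage$posterior <- post
      mcmc <- attr(post, "mcmc")
      stage$heterogeneity <- posterior_partition(mcmc)
      stage$trait_class <- trait_class_effect_report(mcmc)
      if (resp == "mean") {
        grid <- seq(min(dat$x), max(dat$x), length.out = 101)
        stage$derivatives <- tibble::tibble(
          generation = grid,
          rate_of_change = curve_derivative(grid, stage$fit$params)
        )
        slope_sig <- post$significant[post$term == "basis"]
        if (isTRUE(slope_sig) || force_lifehistory) {
          lcfg <- config
          lcfg$seed <- derive_seed(seed, paste0(ctx, "lh"))
          lh_rank <- rank_lifehistory_models(ctx_records, stage$fit,
                                             life_history, tree = A,
                                             config = lcfg)
          stage$lifehistory <- dplyr::select(lh_rank, -"mcmc")
          stage$interactions <- purrr::map_dfr(
            c("foraging_guild", "sociality"),
            function(g) {
              d <- build_design(ctx_records, stage$fit, group = g,
                                random_levels = names(mcmc$design$levels),
                                life_history = life_history, tree = A)
              gcfg <- config
              gcfg$seed <- derive_seed(seed, paste0(ctx, g))
              dplyr::mutate(summarize_posterior(run_gibbs(d, gcfg)),
                            group = g, .before = 1)
            }
          )
        }
      }
      out[[resp]] <- stage
    }
    out
  })

  manifest <- list(
    seed = seed,
    contexts = contexts, responses = responses, spans = spans,
    mcmc = unclass(config), n_restarts = n_restarts,
    config_hash = rlang::hash(list(contexts, responses, spans,
                                   unclass(config), n_restarts, seed))
  )
  report <- structure(c(result, list(manifest = manifest)),
                      class = "relax_report")
  if (!is.null(out_dir)) write_report_bundle(report, out_dir)
  report
}

#' @export
print.relax_report <- function(x, ...) {
  ctx <- setdiff(names(x), "manifest")
  cat("<relax_report> contexts: ", paste(ctx, collapse = ", "),
      " (seed ", x$manifest$seed, ")\n", sep = "")
  invisible(x)
}

#' Write a pipeline report as plain-text tables
#'
#' Emits, per context and response, the posterior summary, heterogeneity
#' partition, model ranking and interaction tables as TSV, the curve fits
#' as JSON, and the run manifest as JSON.
#'
#' @param report A `relax_report` from [run_pipeline()].
#' @param dir Output directory.
#' @return Invisibly, the files written.
#' @export
write_report_bundle <- function(report, dir) {
  stopifnot(inherits(report, "relax_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  written <- character(0)
  emit_tsv <- function(df, name) {
    path <- file.path(dir, paste0(name, ".tsv"))
    readr::write_tsv(df, path)
    written <<- c(written, path)
  }
  for (ctx in setdiff(names(report), "manifest")) {
    res <- report[[ctx]]
    emit_tsv(res$prep_summary, paste0(ctx, "_dataset_summary"))
    for (resp in intersect(c("mean", "cv"), names(res))) {
      stage <- res[[resp]]
      fit_path <- file.path(dir, paste0(ctx, "_", resp, "_fit.json"))
      jsonlite::write_json(
        c(list(curve = stage$fit$curve, mae = stage$fit$mae,
               seed = stage$fit$seed, n_restarts = stage$fit$n_restarts),
          unclass(stage$fit$params)),
        fit_path, auto_unbox = TRUE, digits = NA
      )
      written <- c(written, fit_path)
      emit_tsv(stage$loess, paste0(ctx, "_", resp, "_loess"))
      emit_tsv(stage$posterior, paste0(ctx, "_", resp, "_posterior"))
      emit_tsv(stage$heterogeneity, paste0(ctx, "_", resp, "_heterogeneity"))
      if (!is.null(stage$derivatives)) {
        emit_tsv(stage$derivatives, paste0(ctx, "_", resp, "_derivatives"))
      }
      if (!is.null(stage$lifehistory)) {
        emit_tsv(stage$lifehistory, paste0(ctx, "_lifehistory_ranking"))
        emit_tsv(stage$interactions, paste0(ctx, "_lifehistory_estimates"))
      }
    }
  }
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(report$manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(c(written, manifest_path))
}
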