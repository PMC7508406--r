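#' Partition total heterogeneity into multilevel I-squared shares
#'
#' Multilevel-meta-analysis I-squared: each of the study, species and
#' phylogeny levels receives the share
#' \eqn{I^2_l = 100\,\sigma^2_l / (\sum_l \sigma^2_l + \bar v)} of the total
#' heterogeneity, where \eqn{\bar v} is the typical (mean) sampling
#' variance; the residual share absorbs both the residual variance and
#' \eqn{\bar v}, so the four shares sum to exactly 100.
#'
#' @param vc Named numeric vector (or one-row data frame) of variance
#'   components with names among `study`, `species`, `phylogeny`,
#'   `residual`; all non-negative, not all zero.
#' @param mean_sampling_variance Typical per-observation sampling variance
#'   \eqn{\bar v}; default 0 (all residual spread treated as heterogeneity).
#' @return A tibble with columns `level` and `i2` (percent).
#' @examples
#' partition_heterogeneity(c(study = 1, species = 1, phylogeny = 1, residual = 1))
#' @export
partition_heterogeneity <- function(vc, mean_sampling_variance = 0) {
  if (is.data.frame(vc)) vc <- unlist(vc[1, , drop = TRUE])
  vc <- vc[c("study", "species", "phylogeny", "residual")]
  names(vc) <- c("study", "species", "phylogeny", "residual")
  vc[is.na(vc)] <- 0
  if (any(vc < 0) || mean_sampling_variance < 0) {
    abort("variance components must be non-negative.",
          class = "relaxsel_invalid_input")
  }
  total <- sum(vc) + mean_sampling_variance
  if (total <= 0) {
    abort("all variance components are zero; partition undefined.",
          class = "relaxsel_undefined_partition")
  }
  i2 <- 100 * vc / total
  i2[["residual"]] <- 100 * (vc[["residual"]] + mean_sampling_variance) / total
  tibble::tibble(level = names(i2), i2 = as.numeric(i2))
}

#' Phylogenetic heritability H-squared
#'
#' The share of species-linked variance attributable to phylogeny,
#' \eqn{H^2 = \sigma^2_{phylo} / (\sigma^2_{phylo} + \sigma^2_{species})};
#' the analogue of Pagel's lambda for the meta-regression. Values near 1
#' indicate strong phylogenetic signal.
#'
#' @param vc Named numeric vector (or one-row data frame) with elements
#'   `phylogeny` and `species`.
#' @return H-squared in `[0, 1]`; `NA` (with a warning) when both
#'   components are zero.
#' @export
phylo_heritability <- function(vc) {
  if (is.data.frame(vc)) vc <- unlist(vc[1, , drop = TRUE])
  s_ph <- vc[["phylogeny"]]; s_sp <- vc[["species"]]
  if (s_ph < 0 || s_sp < 0) {
    abort("variance components must be non-negative.",
          class = "relaxsel_invalid_input")
  }
  if (s_ph + s_sp == 0) {
    warn("both species-linked variance components are zero; H^2 undefined.")
    return(NA_real_)
  }
  s_ph / (s_ph + s_sp)
}

#' Posterior heterogeneity partition
#'
#' Computes the I-squared partition and H-squared for every retained draw of
#' a fitted meta-regression and summarizes them with posterior means and
#' equal-tailed 95% credible intervals (the S6-style heterogeneity table).
#'
#' @param fit A `relax_mcmc` whose model contains the `study`, `species` and
#'   `phylogeny` random levels (missing levels contribute zero variance).
#' @param mean_sampling_variance Typical sampling variance; default 0.
#' @param conf Credible-interval mass.
#' @return A tibble with columns `level`, `estimate`, `conf.low`,
#'   `conf.high`; H-squared appears as level `"H2"` (fraction, not percent).
#' @export
posterior_partition <- function(fit, mean_sampling_variance = 0, conf = 0.95) {
  stopifnot(inherits(fit, "relax_mcmc"))
  draws <- fit$draws
  col_of <- function(lv) {
    nm <- paste0("sigma2_", lv)
    if (nm %in% colnames(draws)) draws[, nm] else numeric(nrow(draws))
  }
  sig <- cbind(study = col_of("study"), species = col_of("species"),
               phylogeny = col_of("phylogeny"), residual = col_of("residual"))
  total <- rowSums(sig) + mean_sampling_variance
  shares <- 100 * sig / total
  shares[, "residual"] <- 100 * (sig[, "residual"] + mean_sampling_variance) / total
  h2 <- ifelse(sig[, "phylogeny"] + sig[, "species"] > 0,
               sig[, "phylogeny"] / (sig[, "phylogeny"] + sig[, "species"]),
               NA_real_)
  alpha <- (1 - conf) / 2
  summarize_col <- function(v, label) {
    tibble::tibble(level = label, estimate = mean(v),
                   conf.low = unname(quantile(v, alpha, na.rm = TRUE)),
                   conf.high = unname(quantile(v, 1 - alpha, na.rm = TRUE)))
  }
  dplyr::bind_rows(
    purrr::map(colnames(shares), ~ summarize_col(shares[, .x], .x)),
    summarize_col(h2, "H2")
  )
}
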