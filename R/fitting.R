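#' Local polynomial (loess) smoother for trajectory exploration
#'
#' Fits a locally estimated scatterplot smoother with tricube weights to
#' describe the generation-trajectory of a response without parametric
#' assumptions. This is the exploratory stage run before committing to the
#' inverse-decay or Weibull curve.
#'
#' @param data A data frame with numeric columns `x` (generations) and `y`
#'   (response).
#' @param span Smoothing parameter in (0, 1]; fraction of points in each
#'   local neighborhood. Default 0.75.
#' @param degree Local polynomial degree, 0, 1 or 2. Default 2.
#' @param at Query points; defaults to the observed `x`.
#' @return A tibble with columns `x` and `fitted`.
#' @export
fit_loess <- function(data, span = 0.75, degree = 2, at = NULL) {
  stopifnot(is.data.frame(data), all(c("x", "y") %in% names(data)))
  if (!degree %in% 0:2) {
    abort("`degree` must be 0, 1 or 2.", class = "relaxsel_invalid_input")
  }
  if (length(unique(data$x)) < degree + 2) {
    abort("too few distinct x values for the requested degree.",
          class = "relaxsel_invalid_input")
  }
  at <- at %||% data$x
  fit <- loess(y ~ x, data = data, span = span, degree = degree,
               family = "gaussian",
               control = loess.control(surface = "direct", iterations = 1))
  tibble::tibble(x = at, fitted = as.numeric(predict(fit, tibble::tibble(x = at))))
}

#' Choose the loess span by in-sample mean absolute error
#'
#' Evaluates each candidate span and reports the MAE between the smoother
#' and the observations; the best (flagged) span minimizes MAE, with ties
#' going to the smallest span. Duplicate candidates are dropped.
#'
#' @inheritParams fit_loess
#' @param spans Numeric vector of at least 2 candidate spans.
#' @return A tibble with columns `span`, `mae` and logical `best`.
#' @export
select_smoothing <- function(data, spans, degree = 2) {
  spans <- sort(unique(spans))
  if (length(spans) < 2) {
    abort("supply at least 2 distinct candidate spans.",
          class = "relaxsel_invalid_input")
  }
  mae <- purrr::map_dbl(spans, function(s) {
    f <- fit_loess(data, span = s, degree = degree)
    mean(abs(data$y - f$fitted))
  })
  tibble::tibble(span = spans, mae = mae,
                 best = seq_along(spans) == which.min(mae))
}

weighted_mae <- function(y, yhat, w) sum(w * abs(y - yhat)) / sum(w)

#' Fit a trajectory curve by CMA-ES
#'
#' Fits the inverse-decay curve (for standardized means) or the Weibull
#' baseline-plus-bump curve (for absolute CVs) to `(x, y)` data by minimizing
#' the weighted mean absolute error with the covariance matrix adaptation
#' evolution strategy (CMA-ES). Box constraints (`a` in (0,1); `k`, `lambda`
#' positive; `t_min` non-negative) are imposed through smooth transforms
#' (logistic and log), keeping the optimizer's covariance adaptation
#' well-behaved. The best of `n_restarts` independently initialized runs is
#' returned; results are reproducible given `seed`.
#'
#' @param data A data frame with columns `x`, `y` and optionally `weight`.
#' @param curve `"inverse"` or `"weibull"`.
#' @param seed Integer seed controlling all optimizer randomness.
#' @param n_restarts Number of CMA-ES restarts (default 5).
#' @param max_evals Objective-evaluation budget per restart (default 5000).
#' @return A `traj_fit` object: fitted `params`, weighted `mae`,
#'   `n_restarts`, `converged`, `seed`, and the data used.
#' @examples
#' p <- inverse_params(0.3, 1.5, 0.85)
#' d <- tibble::tibble(x = 0:40, y = inverse_curve(0:40, p))
#' fit <- fit_trajectory(d, "inverse", seed = 1)
#' glance(fit)
#' @export
fit_trajectory <- function(data, curve = c("inverse", "weibull"), seed = 1,
                           n_restarts = 5, max_evals = 5000) {
  curve <- match.arg(curve)
  stopifnot(is.data.frame(data), all(c("x", "y") %in% names(data)))
  x <- as.numeric(data$x)
  y <- as.numeric(data$y)
  w <- if ("weight" %in% names(data)) as.numeric(data$weight) else rep(1, length(x))
  if (any(w <= 0)) abort("weights must be positive.", class = "relaxsel_invalid_input")
  n_min <- if (curve == "inverse") 4 else 6
  x_min <- if (curve == "inverse") 2 else 3
  if (length(x) < n_min) {
    abort(sprintf("need at least %d records to fit the %s curve.", n_min, curve),
          class = "relaxsel_invalid_input")
  }
  if (length(unique(x)) < x_min) {
    abort(sprintf("need at least %d distinct generations; curve unidentifiable.", x_min),
          class = "relaxsel_unidentifiable")
  }

  if (curve == "inverse") {
    to_params <- function(th) inverse_params(th[1], th[2], plogis(th[3]))
    objective <- function(th) {
      weighted_mae(y, th[1] + th[2] * plogis(th[3])^x, w)
    }
    y_tail <- mean(y[x >= quantile(x, 0.75)])
    y_head <- mean(y[x <= quantile(x, 0.25)])
    base_init <- c(y_tail, y_head - y_tail, qlogis(0.9))
    inits <- function(i) {
      a0 <- c(0.9, 0.7, 0.95, 0.5, 0.8)[(i - 1) %% 5 + 1]
      base_init * c(1, 1, 0) + c(0, 0, qlogis(a0)) +
        rnorm(3, 0, c(0.3, 0.3, 0.5)) * (i > 1)
    }
  } else {
    to_params <- function(th) weibull_params(th[1], th[2], exp(th[3]),
                                             exp(th[4]), exp(th[5]))
    objective <- function(th) {
      p <- list(y_ini = th[1], a = th[2], k = exp(th[3]),
                lambda = exp(th[4]), t_min = exp(th[5]))
      u <- (x - p$t_min) / p$lambda
      bump <- ifelse(u > 0, (p$k / p$lambda) * u^(p$k - 1) * exp(-u^p$k), 0)
      weighted_mae(y, p$y_ini + p$a * bump, w)
    }
    y_tail <- mean(y[x >= quantile(x, 0.75)])
    i_pk <- which.max(y)
    lambda0 <- max(x[i_pk], diff(range(x)) / 8, 1)
    k0 <- 2
    u0 <- ((k0 - 1) / k0)^(1 / k0)
    bmax <- (k0 / lambda0) * u0^(k0 - 1) * exp(-u0^k0)
    a0 <- max((max(y) - y_tail) / bmax, 0.1)
    base_init <- c(y_tail, a0, log(k0), log(lambda0), log(0.5))
    inits <- function(i) {
      k_i <- c(2, 1.5, 3, 2.5, 1.2)[(i - 1) %% 5 + 1]
      out <- base_init
      out[3] <- log(k_i)
      out + rnorm(5, 0, c(0.1, 0.3, 0.2, 0.3, 0.5)) * (i > 1)
    }
  }

  runs <- with_seed(seed, {
    purrr::map(seq_len(n_restarts), function(i) {
      cmaes_minimize(objective, inits(i), sigma0 = 0.3, max_evals = max_evals)
    })
  })
  best <- runs[[which.min(purrr::map_dbl(runs, "value"))]]
  params <- to_params(best$par)
  structure(
    list(curve = curve, params = params,
         mae = weighted_mae(y, eval_curve(x, params), w),
         restart_maes = purrr::map_dbl(runs, "value"),
         n_restarts = n_restarts, converged = best$converged,
         seed = seed, data = tibble::tibble(x = x, y = y, weight = w)),
    class = "traj_fit"
  )
}

eval_curve <- function(x, params) {
  if (inherits(params, "inverse_params")) inverse_curve(x, params)
  else weibull_curve(x, params)
}

#' @export
print.traj_fit <- function(x, ...) {
  cat("<traj_fit> ", x$curve, " curve, weighted MAE = ", signif(x$mae, 5),
      " (", x$n_restarts, " restarts, seed ", x$seed, ")\n", sep = "")
  print(x$params)
  invisible(x)
}

#' Predict from a fitted trajectory
#'
#' @param object A `traj_fit` from [fit_trajectory()].
#' @param newdata Optional data frame with an `x` column; defaults to the
#'   training data.
#' @param ... Unused.
#' @return A tibble with columns `x` and `fitted`.
#' @export
predict.traj_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x else newdata$x
  tibble::tibble(x = x, fitted = eval_curve(x, object$params))
}

#' @rdname fit_trajectory
#' @param x,object A `traj_fit`.
#' @param ... Unused.
#' @export
tidy.traj_fit <- function(x, ...) {
  tibble::tibble(term = names(x$params), estimate = as.numeric(unlist(x$params)))
}

#' @rdname fit_trajectory
#' @export
glance.traj_fit <- function(x, ...) {
  tibble::tibble(curve = x$curve, mae = x$mae, n = nrow(x$data),
                 n_restarts = x$n_restarts, converged = x$converged,
                 seed = x$seed)
}

#' Plot a fitted trajectory over the data
#'
#' @param object A `traj_fit`.
#' @param n_grid Number of grid points for the fitted line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.traj_fit <- function(object, n_grid = 200, ...) {
  grid <- tibble::tibble(x = seq(min(object$data$x), max(object$data$x),
                                 length.out = n_grid))
  grid$fitted <- eval_curve(grid$x, object$params)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$weight), alpha = 0.4,
                        show.legend = FALSE) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fitted),
                       color = "#2166ac", linewidth = 1) +
    ggplot2::labs(x = "Generations of human contact",
                  y = if (object$curve == "inverse") "Standardized mean" else "|CV|")
}
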