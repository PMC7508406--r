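#' Parameter bundle for the inverse-decay trajectory
#'
#' The inverse-decay curve \eqn{f(x) = y_{ini} + k \, a^x} describes how the
#' mean of an antipredator trait changes across generations \eqn{x} of human
#' contact: `y_ini` is the asymptotic trait value reached after many
#' generations, `k` the scaling coefficient (the total amount of change, in
#' standardized trait units), and `a` the per-generation decay factor.
#'
#' @param y_ini Asymptotic trait value (z-score units).
#' @param k Scaling coefficient (z-score units); the value at generation 0 is
#'   `y_ini + k`.
#' @param a Per-generation decay factor, strictly inside (0, 1).
#' @return An object of class `inverse_params`.
#' @examples
#' p <- inverse_params(y_ini = 0.3, k = 1.5, a = 0.85)
#' inverse_curve(c(0, 10, 50), p)
#' @export
inverse_params <- function(y_ini, k, a) {
  stopifnot(is.numeric(y_ini), is.numeric(k), is.numeric(a))
  if (!is.finite(a) || a <= 0 || a >= 1) {
    abort("`a` must lie strictly inside (0, 1).", class = "relaxsel_invalid_param")
  }
  structure(list(y_ini = as.numeric(y_ini), k = as.numeric(k), a = as.numeric(a)),
            class = c("inverse_params", "traj_params"))
}

#' Parameter bundle for the Weibull CV trajectory
#'
#' The coefficient of variation (CV) of antipredator traits is modelled as a
#' baseline plus a scaled Weibull-density bump:
#' \deqn{f(x) = y_{ini} + a \frac{k}{\lambda}
#'   \left(\frac{x - t_{min}}{\lambda}\right)^{k-1}
#'   e^{-\left((x - t_{min})/\lambda\right)^{k}},}
#' a rise in between-individual variance over the first generations of
#' relaxed selection followed by a gradual decline. Before the onset
#' generation `t_min` the curve equals the baseline `y_ini`.
#'
#' @param y_ini Baseline CV (unitless).
#' @param a Scaling coefficient (area of the bump; unitless).
#' @param k Shape exponent, positive.
#' @param lambda Scale coefficient, positive (generations).
#' @param t_min Generation at which the change starts, non-negative.
#' @return An object of class `weibull_params`.
#' @examples
#' p <- weibull_params(y_ini = 0.8, a = 2, k = 2, lambda = 15, t_min = 0)
#' weibull_curve(c(0, 10, 40), p)
#' @export
weibull_params <- function(y_ini, a, k, lambda, t_min = 0) {
  stopifnot(is.numeric(y_ini), is.numeric(a), is.numeric(k),
            is.numeric(lambda), is.numeric(t_min))
  if (!is.finite(k) || k <= 0 || !is.finite(lambda) || lambda <= 0) {
    abort("`k` and `lambda` must be positive.", class = "relaxsel_invalid_param")
  }
  if (!is.finite(t_min) || t_min < 0) {
    abort("`t_min` must be non-negative.", class = "relaxsel_invalid_param")
  }
  structure(list(y_ini = as.numeric(y_ini), a = as.numeric(a), k = as.numeric(k),
                 lambda = as.numeric(lambda), t_min = as.numeric(t_min)),
            class = c("weibull_params", "traj_params"))
}

#' @export
print.traj_params <- function(x, ...) {
  cat("<", class(x)[1], "> ", paste(names(x), signif(unlist(x), 4),
                                    sep = " = ", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Evaluate the inverse-decay trajectory
#'
#' @param x Generations of human contact, non-negative numeric vector.
#' @param params An [inverse_params()] object.
#' @return Numeric vector `y_ini + k * a^x`.
#' @export
inverse_curve <- function(x, params) {
  params <- as_inverse_params(params)
  params$y_ini + params$k * params$a^x
}

#' Evaluate the Weibull CV trajectory
#'
#' Returns the baseline `y_ini` for `x < t_min` (the bump is defined to be
#' zero before onset) and the baseline-plus-bump value afterwards.
#'
#' @param x Generations, numeric vector.
#' @param params A [weibull_params()] object.
#' @return Numeric vector of CV values.
#' @export
weibull_curve <- function(x, params) {
  params <- as_weibull_params(params)
  u <- (x - params$t_min) / params$lambda
  bump <- numeric(length(x))
  pos <- which(u > 0)
  if (length(pos)) {
    up <- u[pos]
    bump[pos] <- (params$k / params$lambda) * up^(params$k - 1) * exp(-up^params$k)
  }
  params$y_ini + params$a * bump
}

as_inverse_params <- function(p) {
  if (inherits(p, "inverse_params")) return(p)
  p <- as.list(p)
  inverse_params(p$y_ini, p$k, p$a)
}

as_weibull_params <- function(p) {
  if (inherits(p, "weibull_params")) return(p)
  p <- as.list(p)
  weibull_params(p$y_ini, p$a, p$k, p$lambda, p$t_min %||% 0)
}

#' First derivative of the inverse-decay trajectory
#'
#' The per-generation rate of change of the mean trait value,
#' \eqn{f'(x) = k \ln(a) a^x}; negative for `k > 0` (antipredator traits are
#' lost fastest in the first generations).
#'
#' @inheritParams inverse_curve
#' @return Numeric vector of rates of change per generation.
#' @export
curve_derivative <- function(x, params) {
  params <- as_inverse_params(params)
  params$k * log(params$a) * params$a^x
}

#' Generations needed to approach the asymptote
#'
#' Smallest generation count \eqn{x} at which the inverse-decay curve is
#' within `fraction` of its total change `|k|` from the asymptote `y_ini`;
#' in closed form \eqn{x = \ln(fraction)/\ln(a)}.
#'
#' @param params An [inverse_params()] object with `k != 0`.
#' @param fraction Remaining fraction of the total change, strictly in (0, 1).
#' @return Generation count (real, not rounded).
#' @examples
#' generations_to_asymptote(inverse_params(0, 1, 0.9), fraction = 0.05)
#' @export
generations_to_asymptote <- function(params, fraction = 0.05) {
  params <- as_inverse_params(params)
  if (params$k == 0) {
    abort("`k` must be non-zero.", class = "relaxsel_invalid_input")
  }
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      !is.finite(fraction) || fraction <= 0 || fraction >= 1) {
    abort("`fraction` must lie strictly inside (0, 1).",
          class = "relaxsel_invalid_input")
  }
  log(fraction) / log(params$a)
}
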