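# Covariance Matrix Adaptation Evolution Strategy (CMA-ES), the standard
# (mu/mu_w, lambda) formulation with rank-one and rank-mu covariance updates.
# Derivative-free, so it handles the non-smooth mean-absolute-error
# objectives used for trajectory fitting. Box constraints are handled by the
# callers through smooth reparameterizations, not here.
#
# Deterministic given the RNG state on entry.
cmaes_minimize <- function(fn, x0, sigma0 = 0.3, max_evals = 5000,
                           tol_fun = 1e-10, tol_x = 1e-12) {
  d <- length(x0)
  lambda <- 4L + floor(3 * log(d))
  mu <- floor(lambda / 2)
  w <- log(mu + 0.5) - log(seq_len(mu))
  w <- w / sum(w)
  mueff <- 1 / sum(w^2)

  cc <- (4 + mueff / d) / (d + 4 + 2 * mueff / d)
  cs <- (mueff + 2) / (d + mueff + 5)
  c1 <- 2 / ((d + 1.3)^2 + mueff)
  cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((d + 2)^2 + mueff))
  damps <- 1 + 2 * max(0, sqrt((mueff - 1) / (d + 1)) - 1) + cs
  chiN <- sqrt(d) * (1 - 1 / (4 * d) + 1 / (21 * d^2))

  xmean <- as.numeric(x0)
  sigma <- sigma0
  C <- diag(d)
  pc <- ps <- numeric(d)
  B <- diag(d)
  Dvec <- rep(1, d)
  invsqrtC <- diag(d)

  evals <- 0L
  best_x <- xmean
  best_f <- Inf
  hist_best <- numeric(0)
  hist_len <- 10L + ceiling(30 * d / lambda)
  converged <- FALSE

  while (evals < max_evals) {
    Z <- matrix(rnorm(d * lambda), d, lambda)
    Y <- B %*% (Dvec * Z)                      # N(0, C) steps
    X <- xmean + sigma * Y
    f <- apply(X, 2, fn)
    evals <- evals + lambda
    ord <- order(f)
    if (f[ord[1]] < best_f) {
      best_f <- f[ord[1]]
      best_x <- X[, ord[1]]
    }

    sel <- ord[seq_len(mu)]
    yw <- as.numeric(Y[, sel, drop = FALSE] %*% w)
    xmean <- xmean + sigma * yw

    ps <- (1 - cs) * ps + sqrt(cs * (2 - cs) * mueff) * as.numeric(invsqrtC %*% yw)
    hsig <- as.numeric(
      sqrt(sum(ps^2)) / sqrt(1 - (1 - cs)^(2 * evals / lambda)) / chiN <
        1.4 + 2 / (d + 1)
    )
    pc <- (1 - cc) * pc + hsig * sqrt(cc * (2 - cc) * mueff) * yw

    Ysel <- Y[, sel, drop = FALSE]
    C <- (1 - c1 - cmu) * C +
      c1 * (tcrossprod(pc) + (1 - hsig) * cc * (2 - cc) * C) +
      cmu * (Ysel %*% (w * t(Ysel)))
    sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chiN - 1))

    C <- (C + t(C)) / 2
    eig <- eigen(C, symmetric = TRUE)
    Dvec <- sqrt(pmax(eig$values, 1e-30))
    B <- eig$vectors
    invsqrtC <- B %*% (t(B) / Dvec)

    hist_best <- c(tail(hist_best, hist_len - 1L), f[ord[1]])
    if (length(hist_best) >= hist_len &&
        (max(hist_best) - min(hist_best)) < tol_fun) {
      converged <- TRUE
      break
    }
    if (sigma * max(Dvec) < tol_x) {
      converged <- TRUE
      break
    }
    if (!is.finite(sigma) || sigma > 1e8) break
  }

  list(par = best_x, value = best_f, evals = evals, converged = converged)
}
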