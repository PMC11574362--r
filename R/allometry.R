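#' Fit an allometric power law y = k * x^alpha
#'
#' Fits the two-parameter allometric equation by nonlinear least squares on
#' the original scale (Levenberg-Marquardt), minimising
#' \eqn{\sum_i (y_i - k x_i^\alpha)^2}. Starting values come from ordinary
#' least squares on \eqn{(\log x, \log y)}, where the model is linear:
#' \eqn{\log y = \alpha \log x + \log k}.
#'
#' @param x,y Positive numeric vectors of equal length (n >= 3). `x` is the
#'   reference size (e.g. limb-stump A-P width), `y` the trait size (e.g.
#'   blastema A-P width). Units are preserved in `k`; `alpha` is
#'   dimensionless.
#' @param n_boot Number of bootstrap replicates for the exponent s.d.
#'   (case resampling). Set to 0 to skip the bootstrap.
#' @param seed Integer seed for the bootstrap resampling.
#' @return An object of class `allometric_fit`: a list with `k`, `alpha`,
#'   `alpha_sd` (bootstrap s.d. of the exponent, `NA` if `n_boot = 0`),
#'   `n`, `n_boot`, `seed`, `residuals` and the number of dropped
#'   (non-converged) bootstrap refits.
#' @examples
#' x <- c(1, 4, 9, 16, 25)
#' fit_power_law(x, 2 * sqrt(x), n_boot = 0)
#' @export
fit_power_law <- function(x, y, n_boot = 1000L, seed = 1L) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values")
  if (any(x <= 0) || any(y <= 0)) stop("all sizes must be positive")

  est <- .fit_power_core(x, y)
  alpha_sd <- NA_real_
  n_failed <- 0L
  if (n_boot > 0L) {
    bs <- bootstrap_exponent_sd(x, y, n_boot = n_boot, seed = seed)
    alpha_sd <- bs$sd
    n_failed <- bs$n_failed
  }
  structure(
    list(k = est$k, alpha = est$alpha, alpha_sd = alpha_sd,
         n = length(x), n_boot = as.integer(n_boot), seed = as.integer(seed),
         residuals = y - est$k * x^est$alpha, n_boot_failed = n_failed),
    class = "allometric_fit")
}

# log-log OLS start, then Levenberg-Marquardt on the original scale
.fit_power_core <- function(x, y) {
  ols <- stats::lm.fit(cbind(1, log(x)), log(y))
  start <- list(k = exp(ols$coefficients[[1]]), alpha = ols$coefficients[[2]])
  fit <- try(minpack.lm::nlsLM(
    y ~ k * x^alpha, data = data.frame(x = x, y = y), start = start,
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    stop("power-law fit did not converge; log-log OLS start was k=",
         signif(start$k, 4), ", alpha=", signif(start$alpha, 4))
  }
  cf <- stats::coef(fit)
  if (cf[["k"]] <= 0) stop("fit converged to non-positive k")
  list(k = cf[["k"]], alpha = cf[["alpha"]])
}

#' Bootstrap standard deviation of the allometric exponent
#'
#' Resamples (x, y) pairs with replacement `n_boot` times, refits the power
#' law on each resample, and returns the standard deviation of the exponent
#' estimates. Refits that fail to converge (or have fewer than 3 distinct x
#' values) are dropped and counted; more than 20% failures is an error.
#'
#' @inheritParams fit_power_law
#' @return List with `sd` (s.d. of the bootstrap exponents), `alphas`
#'   (the successful draws) and `n_failed`.
#' @export
bootstrap_exponent_sd <- function(x, y, n_boot = 1000L, seed = 1L) {
  if (n_boot < 2L) stop("n_boot must be >= 2")
  n <- length(x)
  set.seed(as.integer(seed))
  alphas <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    if (length(unique(x[idx])) < 3L) next
    est <- try(.fit_power_core(x[idx], y[idx]), silent = TRUE)
    if (!inherits(est, "try-error")) alphas[b] <- est$alpha
  }
  ok <- !is.na(alphas)
  if (mean(!ok) > 0.2) {
    stop(sum(!ok), " of ", n_boot, " bootstrap refits failed to converge")
  }
  list(sd = stats::sd(alphas[ok]), alphas = alphas[ok],
       n_failed = sum(!ok))
}

#' @export
print.allometric_fit <- function(x, ...) {
  cat(sprintf("Allometric fit: y = %.3g * x^%.3g  (n = %d)\n",
              x$k, x$alpha, x$n))
  if (!is.na(x$alpha_sd)) {
    cat(sprintf("  bootstrap s.d. of exponent: %.3g (n_boot = %d, seed = %d)\n",
                x$alpha_sd, x$n_boot, x$seed))
  }
  invisible(x)
}

#' Relative-size curve of an allometric fit
#'
#' Converts a fit y = k x^alpha into the relative-size relation
#' y/x = k x^(alpha - 1). For alpha < 1 the trait becomes relatively
#' smaller as the reference size grows (negative allometry).
#'
#' @param fit An `allometric_fit`, or a list with elements `k` and `alpha`.
#' @return Object of class `relative_size_curve` with `k`,
#'   `exponent_minus_one`, and a vectorised `evaluate(x)` function.
#' @examples
#' rc <- relative_size_curve(list(k = 1.2, alpha = 0.61))
#' rc$evaluate(1)   # = k
#' @export
relative_size_curve <- function(fit) {
  k <- fit$k
  em1 <- fit$alpha - 1
  stopifnot(is.finite(k), k > 0, is.finite(em1))
  structure(
    list(k = k, exponent_minus_one = em1,
         evaluate = function(x) k * x^em1),
    class = "relative_size_curve")
}

#' Compose two allometric exponents
#'
#' If z scales as y^a and y scales as x^b, then z scales as x^(a*b)
#' (chain rule for power laws). For example, composing the crosstalk-region
#' exponent against blastema size with the blastema exponent against stump
#' size gives the crosstalk-region exponent against stump size.
#'
#' @param outer_alpha,inner_alpha Dimensionless exponents.
#' @return List with `exponent` (exact product) and `reported`
#'   (rounded to 2 decimals, the convention used for headline values).
#' @examples
#' compose_allometries(0.66, 0.61)  # exponent 0.4026, reported 0.40
#' @export
compose_allometries <- function(outer_alpha, inner_alpha) {
  e <- outer_alpha * inner_alpha
  list(exponent = e, reported = round(e, 2))
}

#' Pearson product-moment correlation
#'
#' Thin validated wrapper around [stats::cor()] used for gap-versus-size
#' and similar independence checks.
#'
#' @param x,y Numeric vectors, length >= 3, each with nonzero variance.
#' @return The correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance: correlation undefined")
  }
  stats::cor(x, y, method = "pearson")
}
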