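# Gaussian-process regression with a squared-exponential kernel.
# Hyperparameters (lengthscale, signal variance, noise variance) are set by
# maximising the log marginal likelihood; a jitter keeps the Cholesky stable.

.sqexp <- function(x1, x2, ell, sf2) {
  d <- outer(x1, x2, "-")
  sf2 * exp(-d^2 / (2 * ell^2))
}

.gp_nll <- function(logpar, x, y) {
  ell <- exp(logpar[1]); sf2 <- exp(logpar[2]); sn2 <- exp(logpar[3])
  n <- length(x)
  K <- .sqexp(x, x, ell, sf2) + diag(sn2 + 1e-6, n)
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  a <- backsolve(ch, forwardsolve(t(ch), y))
  as.numeric(0.5 * sum(y * a) + sum(log(diag(ch))) + 0.5 * n * log(2 * pi))
}

.gp_fit <- function(x, y, n_restarts = 5L, seed = 1L) {
  set.seed(as.integer(seed))
  yc <- y - mean(y)
  vy <- stats::var(yc)
  if (vy == 0) stop("degenerate input: all profile values are equal")
  starts <- rbind(
    c(log(0.2), log(vy), log(vy / 10)),
    matrix(stats::rnorm(3 * (n_restarts - 1),
                        mean = c(log(0.2), log(vy), log(vy / 10)), sd = 1),
           ncol = 3, byrow = TRUE))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    o <- try(stats::optim(starts[i, ], .gp_nll, x = x, y = yc,
                          method = "Nelder-Mead",
                          control = list(maxit = 500)), silent = TRUE)
    if (inherits(o, "try-error")) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) stop("GP hyperparameter optimisation failed")
  list(logpar = best$par, x = x, yc = yc, ymean = mean(y))
}

.gp_predict <- function(fit, xstar) {
  ell <- exp(fit$logpar[1]); sf2 <- exp(fit$logpar[2])
  sn2 <- exp(fit$logpar[3])
  n <- length(fit$x)
  K <- .sqexp(fit$x, fit$x, ell, sf2) + diag(sn2 + 1e-6, n)
  ch <- chol(K)
  a <- backsolve(ch, forwardsolve(t(ch), fit$yc))
  Ks <- .sqexp(xstar, fit$x, ell, sf2)
  mu <- as.numeric(Ks %*% a) + fit$ymean
  V <- forwardsolve(t(ch), t(Ks))
  var_f <- pmax(sf2 - colSums(V^2), 0)
  list(mean = mu, sd = sqrt(var_f))
}

#' Fit a smooth unimodal curve to pooled axial profiles
#'
#' Pools crosstalk-region-rescaled profiles from several specimens and fits
#' a Gaussian-process regression (squared-exponential kernel, marginal-
#' likelihood hyperparameters) on \[0, 1\]. Returns the posterior mean curve,
#' a pointwise 95% band, and the peak position (argmax of the mean on a
#' 1000-point grid). For tractability the pooled points are first averaged
#' within `n_bins` equal-width bins; the GP is fitted to the bin means.
#'
#' @param profiles A list of `axial_profile` data.frames carrying an
#'   `omega_rel` column, or a single such data.frame, or a list of
#'   `data.frame(omega_rel=, value=)`.
#' @param n_bins Maximum number of bins pooling the points (default 200).
#' @param n_grid Prediction grid size over \[0, 1\].
#' @param n_restarts Optimiser restarts for the hyperparameters.
#' @param seed Seed for the restart draws.
#' @return Object of class `unimodal_fit`: list with `grid`, `mean_curve`,
#'   `band_lower`, `band_upper` (95%), `peak_rel`, and the fitted
#'   hyperparameters.
#' @export
fit_unimodal <- function(profiles, n_bins = 200L, n_grid = 1000L,
                         n_restarts = 5L, seed = 1L) {
  if (is.data.frame(profiles)) profiles <- list(profiles)
  if (length(profiles) == 0L) stop("need at least one profile")
  pooled <- do.call(rbind, lapply(profiles, function(p) {
    if (!all(c("omega_rel", "value") %in% names(p)))
      stop("profiles must carry omega_rel and value columns")
    p[, c("omega_rel", "value")]
  }))
  pooled <- pooled[is.finite(pooled$omega_rel) & is.finite(pooled$value) &
                     pooled$omega_rel >= 0 & pooled$omega_rel <= 1, ]
  if (nrow(pooled) < 5L) stop("too few points inside the crosstalk region")
  # bin means keep the GP at most n_bins x n_bins
  bin <- cut(pooled$omega_rel, breaks = seq(0, 1, length.out = n_bins + 1L),
             include.lowest = TRUE)
  bx <- tapply(pooled$omega_rel, bin, mean)
  by <- tapply(pooled$value, bin, mean)
  ok <- !is.na(bx)
  x <- as.numeric(bx[ok]); y <- as.numeric(by[ok])
  fit <- .gp_fit(x, y, n_restarts = n_restarts, seed = seed)
  grid <- seq(0, 1, length.out = n_grid)
  pr <- .gp_predict(fit, grid)
  peak <- grid[which.max(pr$mean)]
  structure(list(grid = grid, mean_curve = pr$mean,
                 band_lower = pr$mean - 1.96 * pr$sd,
                 band_upper = pr$mean + 1.96 * pr$sd,
                 peak_rel = peak,
                 hyperparameters = exp(fit$logpar)),
            class = "unimodal_fit")
}

#' @export
print.unimodal_fit <- function(x, ...) {
  cat(sprintf("Unimodal GP fit: peak at %.3f of the crosstalk region\n",
              x$peak_rel))
  invisible(x)
}
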