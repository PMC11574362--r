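#' Construct the Shh/Fgf8 crosstalk region (Omega_SF)
#'
#' The crosstalk region spans from the posterior end of the *Shh* expression
#' domain to the anterior end of the *Fgf8* domain. Within it, the stretch
#' from the *Shh* posterior end to the *Ptch1* anterior end is the
#' Shh-signalling dominant region (size S + P) and the *Fgf8* domain is the
#' Fgf8-signalling dominant region (size F).
#'
#' @param shh_domain,fgf8_domain Numeric length-2 vectors
#'   `c(posterior_end, anterior_end)` in micrometres on the A-P axis
#'   (0 = posterior end of the blastema mesenchyme).
#' @return Object of class `crosstalk_region`: list with `posterior_end`,
#'   `anterior_end`, `size` (= L_Omega), `S` (*Shh*(+) size), `P` (the
#'   *Shh*-*Fgf8* gap; negative if the domains overlap, in which case
#'   `overlap` is `TRUE`), and `F` (*Fgf8*(+) size).
#' @examples
#' crosstalk_region(c(200, 500), c(800, 1000))  # size 800, S=300 P=300 F=200
#' @export
crosstalk_region <- function(shh_domain, fgf8_domain) {
  .check_domain(shh_domain, "shh_domain")
  .check_domain(fgf8_domain, "fgf8_domain")
  post <- shh_domain[1]
  ant <- fgf8_domain[2]
  P <- fgf8_domain[1] - shh_domain[2]
  structure(list(
    posterior_end = post, anterior_end = ant, size = ant - post,
    S = diff(shh_domain), P = P, F = diff(fgf8_domain),
    overlap = P < 0), class = "crosstalk_region")
}

.check_domain <- function(d, name) {
  if (is.null(d) || length(d) != 2L || any(!is.finite(d)))
    stop(name, " must be a finite length-2 vector (posterior, anterior)")
  if (d[2] < d[1]) stop(name, " endpoints must be ordered posterior <= anterior")
  invisible(d)
}

#' Dominant-region proportions from allometric equations
#'
#' Computes, across a grid of blastema sizes L, the shares of the Shh- and
#' Fgf8-signalling dominant regions within the crosstalk region, using
#' fitted allometric laws S(L) and F(L) and a size-independent gap P:
#' share_shh = (S + P) / (S + P + F), share_fgf8 = F / (S + P + F).
#' With the measured laws S = 2.1 L^0.69, F = 23 L^0.44 and P = 170 um,
#' the shares are nearly constant (~47% / 53%) over L in \[500, 3000\] um.
#'
#' @param shh_fit,fgf8_fit `allometric_fit` objects (or lists with `k` and
#'   `alpha`) for the *Shh*(+) and *Fgf8*(+) sizes against blastema size,
#'   sizes in micrometres.
#' @param gap Gap P between the domains, micrometres.
#' @param L_range Length-2 vector of blastema sizes (micrometres).
#' @param step Grid step in micrometres (a linear grid).
#' @return Object of class `proportion_curve`: data.frame with columns `L`,
#'   `S`, `P`, `F`, `shh_dominant_share`, `fgf8_dominant_share`; attributes
#'   `mean_shh_pct` and `mean_fgf8_pct` hold the grid means rounded to whole
#'   percent.
#' @export
proportions_from_equations <- function(shh_fit, fgf8_fit, gap = 170,
                                       L_range = c(500, 3000), step = 50) {
  stopifnot(length(L_range) == 2L, L_range[1] < L_range[2], step > 0)
  L <- seq(L_range[1], L_range[2], by = step)
  if (length(L) == 0L) stop("empty L grid")
  S <- shh_fit$k * L^shh_fit$alpha
  F_ <- fgf8_fit$k * L^fgf8_fit$alpha
  tot <- S + gap + F_
  out <- data.frame(L = L, S = S, P = gap, F = F_,
                    shh_dominant_share = (S + gap) / tot,
                    fgf8_dominant_share = F_ / tot)
  attr(out, "mean_shh_pct") <- round(100 * mean(out$shh_dominant_share))
  attr(out, "mean_fgf8_pct") <- round(100 * mean(out$fgf8_dominant_share))
  class(out) <- c("proportion_curve", "data.frame")
  out
}

#' Rescale an absolute A-P position into crosstalk-region coordinates
#'
#' @param position Absolute position(s) in micrometres.
#' @param region A `crosstalk_region`.
#' @return Fraction(s) of the region size measured from its posterior end.
#'   Values outside \[0, 1\] are permitted and carry the attribute
#'   `outside` marking them.
#' @export
rescale_position <- function(position, region) {
  if (region$size <= 0) stop("crosstalk region has non-positive size")
  rel <- (position - region$posterior_end) / region$size
  outside <- rel < 0 | rel > 1
  if (any(outside)) attr(rel, "outside") <- outside
  rel
}

#' Positional statistics of first-digit (digit II) formation
#'
#' Compares the variability of digit positions under two normalisations:
#' relative to the crosstalk region (Omega_SF) and relative to the whole
#' blastema. If digit placement scales with the crosstalk region, the
#' coefficient of variation (CV = s.d./mean) is smaller under the
#' crosstalk-region normalisation.
#'
#' @param positions Absolute digit positions in micrometres (A-P axis,
#'   0 = posterior end of the mesenchyme).
#' @param regions List of `crosstalk_region` objects, one per position.
#' @param blastema_sizes Blastema sizes L in micrometres, one per position.
#' @param bins Number of histogram bins over \[0, 1\] (relative coordinate).
#' @param sd_type `"population"` (divide by n, default) or `"sample"`.
#' @return List with `rel_omega`, `rel_blastema` (rescaled positions),
#'   `cv_omega`, `cv_blastema`, and `histogram` (counts over the bins).
#' @export
digit_position_stats <- function(positions, regions, blastema_sizes,
                                 bins = 10L, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  n <- length(positions)
  if (n < 2L) stop("need at least 2 positions")
  if (length(regions) != n || length(blastema_sizes) != n)
    stop("positions, regions and blastema_sizes must have matching lengths")
  rel_omega <- vapply(seq_len(n), function(i)
    as.numeric(rescale_position(positions[i], regions[[i]])), numeric(1))
  rel_blastema <- positions / blastema_sizes
  cv <- function(v) {
    s <- if (sd_type == "population") sqrt(mean((v - mean(v))^2)) else stats::sd(v)
    s / mean(v)
  }
  breaks <- seq(0, 1, length.out = bins + 1L)
  h <- table(cut(pmin(pmax(rel_omega, 0), 1), breaks, include.lowest = TRUE))
  list(rel_omega = rel_omega, rel_blastema = rel_blastema,
       cv_omega = cv(rel_omega), cv_blastema = cv(rel_blastema),
       histogram = h)
}

#' Size of the high-density region of an axial profile
#'
#' Total A-P length over which the normalised density exceeds a threshold
#' fraction of the profile maximum, and its share of the blastema size.
#' Because the density peak has a size-independent physical width while L
#' grows, the share decreases with blastema size.
#'
#' @param positions Column-centre positions in micrometres.
#' @param values Normalised densities at those positions.
#' @param threshold Fraction of the profile maximum (in (0, 1\]).
#' @param L Blastema size in micrometres (for the share).
#' @return List with `size_um` and `share`.
#' @export
high_density_region_size <- function(positions, values, threshold = 0.5,
                                     L = max(positions)) {
  if (length(positions) == 0L) stop("empty profile")
  stopifnot(length(positions) == length(values), threshold > 0, threshold <= 1)
  if (all(values == 0)) return(list(size_um = 0, share = 0))
  step <- stats::median(diff(positions))
  above <- values > threshold * max(values)
  size <- sum(above) * step
  list(size_um = size, share = size / L)
}
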