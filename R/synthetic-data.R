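#' Configuration for a synthetic measurement cohort
#'
#' Defines the generative conditions for cohorts of specimen measurements
#' that obey configured allometric laws with multiplicative lognormal noise.
#' Defaults reproduce the measured axolotl laws: forelimb width (mm) =
#' 0.38 * animal_length(cm)^0.90, blastema width (mm) = 1.2 * stump(mm)^0.61,
#' *Shh*(+) (um) = 2.1 * L(um)^0.69, *Fgf8*(+) (um) = 23 * L(um)^0.44, a
#' size-independent *Shh*-*Fgf8* gap of mean 170 um, and a cell-density peak
#' at 60% of the crosstalk region from its posterior end.
#'
#' @param n_specimens Number of specimens (>= 1).
#' @param animal_length_range Nose-to-tail length range in cm (animals are
#'   sampled log-uniformly over it; default 4-25 cm).
#' @param noise_sigma S.d. of the multiplicative lognormal noise on the log
#'   scale, applied to every size sampled from a law.
#' @param gap_mean,gap_sd Mean and s.d. (um) of the truncated-normal
#'   *Shh*-*Fgf8* gap, independent of blastema size.
#' @param density_peak_rel Position of the cell-density peak as a fraction
#'   of the crosstalk region from its posterior end.
#' @param anterior_shift_prob Probability that a specimen's expression
#'   domains are shifted anteriorly as a block (mirrors the occasional
#'   anterior shifts seen in real blastemas).
#' @param laws Named list of power laws, each `c(k = , alpha = )`:
#'   `forelimb` and `hindlimb` (mm vs cm), `blastema` and `reg_limb`
#'   (mm vs mm), `shh` and `fgf8` (um vs um).
#' @param seed Integer seed; fixing it makes all outputs bit-reproducible.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_specimens = 31L,
                          animal_length_range = c(4, 25),
                          noise_sigma = 0.15,
                          gap_mean = 170, gap_sd = 60,
                          density_peak_rel = 0.6,
                          anterior_shift_prob = 0.1,
                          laws = list(
                            forelimb = c(k = 0.38, alpha = 0.90),
                            hindlimb = c(k = 0.41, alpha = 0.91),
                            blastema = c(k = 1.2, alpha = 0.61),
                            reg_limb = c(k = 1.1, alpha = 0.43),
                            shh = c(k = 2.1, alpha = 0.69),
                            fgf8 = c(k = 23, alpha = 0.44)),
                          seed = 1L) {
  stopifnot(n_specimens >= 1L,
            length(animal_length_range) == 2L,
            all(animal_length_range > 0),
            animal_length_range[1] < animal_length_range[2],
            noise_sigma >= 0, gap_mean > 0, gap_sd >= 0,
            density_peak_rel >= 0, density_peak_rel <= 1,
            anterior_shift_prob >= 0, anterior_shift_prob <= 1)
  needed <- c("forelimb", "hindlimb", "blastema", "reg_limb", "shh", "fgf8")
  if (!all(needed %in% names(laws))) stop("laws must name: ",
                                          paste(needed, collapse = ", "))
  structure(list(n_specimens = as.integer(n_specimens),
                 animal_length_range = animal_length_range,
                 noise_sigma = noise_sigma, gap_mean = gap_mean,
                 gap_sd = gap_sd, density_peak_rel = density_peak_rel,
                 anterior_shift_prob = anterior_shift_prob,
                 laws = laws, seed = as.integer(seed)),
            class = "cohort_config")
}

.law <- function(law, x) law[["k"]] * x^law[["alpha"]]

#' Sample (x, y) pairs from a power law with lognormal noise
#'
#' The workhorse behind the exponent-recovery experiments: x is sampled
#' log-uniformly over `x_range` and y = k x^alpha * exp(eps) with
#' eps ~ Normal(0, sigma^2).
#'
#' @param k,alpha Power-law parameters.
#' @param n Number of pairs.
#' @param x_range Length-2 positive range for x.
#' @param sigma Lognormal noise s.d. on the log scale.
#' @param seed Integer seed.
#' @return data.frame with columns `x`, `y`.
#' @export
generate_power_law_pairs <- function(k, alpha, n, x_range, sigma, seed = 1L) {
  stopifnot(n >= 1, all(x_range > 0), x_range[1] < x_range[2], sigma >= 0)
  set.seed(as.integer(seed))
  x <- exp(stats::runif(n, log(x_range[1]), log(x_range[2])))
  y <- k * x^alpha * exp(stats::rnorm(n, 0, sigma))
  data.frame(x = x, y = y)
}

#' Generate a synthetic measurement cohort
#'
#' Samples animal lengths log-uniformly, derives limb, stump, blastema and
#' regenerating-limb widths and the *Shh*(+)/*Fgf8*(+) expression domains
#' from the configured allometric laws with multiplicative lognormal noise,
#' and places the domains on the A-P axis with a truncated-normal gap.
#' The *Shh* domain sits at the posterior end (small random offset), except
#' that with probability `anterior_shift_prob` both domains are shifted
#' anteriorly by a random block offset. Specimens whose sampled geometry
#' cannot fit inside the blastema (S + P + F > available span) are resampled
#' up to 100 times, then an error is raised.
#'
#' A *Ptch1*(+) domain is included: it covers *Shh*(+) and extends
#' anteriorly by the same gap (the anterior ends of *Ptch1*(+) and the
#' posterior end of *Fgf8*(+) nearly coincide in the data).
#'
#' @param config A `cohort_config`.
#' @return data.frame with one row per specimen: `id`, `animal_length_cm`,
#'   `forelimb_mm`, `hindlimb_mm`, `limb` ("fore"/"hind"), `stump_um`,
#'   `reg_limb_um`, `blastema_um`, `shh_post_um`, `shh_ant_um`,
#'   `fgf8_post_um`, `fgf8_ant_um`, `ptch1_post_um`, `ptch1_ant_um`,
#'   `gap_um`, `shifted`, `n_sections`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_specimens
  sig <- config$noise_sigma
  lu <- function(r, m) exp(stats::runif(m, log(r[1]), log(r[2])))
  noise <- function(m) exp(stats::rnorm(m, 0, sig))

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try_i in seq_len(100L)) {
      animal <- lu(config$animal_length_range, 1L)
      fore <- .law(config$laws$forelimb, animal) * noise(1L)
      hind <- .law(config$laws$hindlimb, animal) * noise(1L)
      limb <- if (stats::runif(1) < 0.5) "fore" else "hind"
      stump_mm <- if (limb == "fore") fore else hind
      blastema_mm <- .law(config$laws$blastema, stump_mm) * noise(1L)
      reg_mm <- .law(config$laws$reg_limb, stump_mm) * noise(1L)
      L <- blastema_mm * 1000
      S <- .law(config$laws$shh, L) * noise(1L)
      F_ <- .law(config$laws$fgf8, L) * noise(1L)
      gap <- if (config$gap_sd == 0) config$gap_mean else {
        g <- -1
        while (g <= 0) g <- stats::rnorm(1, config$gap_mean, config$gap_sd)
        g
      }
      span <- S + gap + F_
      if (span > L) next
      # Shh near the posterior end; occasional anterior block shift
      slack <- L - span
      shifted <- stats::runif(1) < config$anterior_shift_prob
      offset <- if (shifted) stats::runif(1, 0, slack) else
        stats::runif(1, 0, min(0.05 * L, slack))
      shh <- c(offset, offset + S)
      fgf8 <- c(offset + S + gap, offset + S + gap + F_)
      ptch1 <- c(shh[1], min(shh[2] + gap, L))
      ok <- TRUE
      break
    }
    if (!ok) stop("specimen ", i, ": could not sample a feasible geometry ",
                  "(S + P + F > L) within 100 attempts")
    rows[[i]] <- data.frame(
      id = sprintf("sp%03d", i), animal_length_cm = animal,
      forelimb_mm = fore, hindlimb_mm = hind, limb = limb,
      stump_um = stump_mm * 1000, reg_limb_um = reg_mm * 1000,
      blastema_um = L,
      shh_post_um = shh[1], shh_ant_um = shh[2],
      fgf8_post_um = fgf8[1], fgf8_ant_um = fgf8[2],
      ptch1_post_um = ptch1[1], ptch1_ant_um = ptch1[2],
      gap_um = gap, shifted = shifted,
      n_sections = sample(2:3, 1))
  }
  do.call(rbind, rows)
}

#' Generate synthetic digit-II positions scaling with the crosstalk region
#'
#' Positions are placed at
#' posterior_end + (rel_position_mean + eps) * |Omega_SF| with
#' eps ~ Normal(0, rel_sd^2), clipped to the region.
#'
#' @param regions List of `crosstalk_region` objects.
#' @param rel_position_mean Mean relative position within the region.
#' @param rel_sd S.d. of the relative position.
#' @param seed Integer seed.
#' @return Numeric vector of absolute positions (um).
#' @export
generate_digit_positions <- function(regions, rel_position_mean = 0.6,
                                     rel_sd = 0.08, seed = 1L) {
  set.seed(as.integer(seed))
  vapply(regions, function(r) {
    if (r$size <= 0) stop("region with non-positive size")
    rel <- rel_position_mean + stats::rnorm(1, 0, rel_sd)
    rel <- min(max(rel, 0), 1)
    r$posterior_end + rel * r$size
  }, numeric(1))
}

#' Write / read a cohort as CSV
#' @param cohort data.frame from [generate_cohort()].
#' @param path File path.
#' @return `read_cohort_csv` returns the cohort data.frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
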