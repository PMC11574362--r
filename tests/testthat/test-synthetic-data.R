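test_that("noise-free cohorts sit exactly on the configured power laws", {
  cc <- cohort_config(n_specimens = 5, noise_sigma = 0, gap_sd = 0, seed = 3)
  co <- generate_cohort(cc)
  stump_mm <- co$stump_um / 1000
  expect_equal(co$blastema_um / 1000, 1.2 * stump_mm^0.61, tolerance = 1e-12)
  expect_equal(co$reg_limb_um / 1000, 1.1 * stump_mm^0.43, tolerance = 1e-12)
  expect_equal(co$shh_ant_um - co$shh_post_um, 2.1 * co$blastema_um^0.69,
               tolerance = 1e-12)
  expect_equal(co$fgf8_ant_um - co$fgf8_post_um, 23 * co$blastema_um^0.44,
               tolerance = 1e-12)
  expect_equal(co$gap_um, rep(170, 5))
  fl <- co$forelimb_mm
  expect_equal(fl, 0.38 * co$animal_length_cm^0.90, tolerance = 1e-12)
})

test_that("generation is bit-reproducible under a fixed seed", {
  cc <- cohort_config(n_specimens = 12, seed = 99)
  expect_identical(generate_cohort(cc), generate_cohort(cc))
  img1 <- demo_image(seed = 5)
  img2 <- demo_image(seed = 5)
  expect_identical(img1$channels, img2$channels)
  regions <- replicate(6, make_region(), simplify = FALSE)
  expect_identical(generate_digit_positions(regions, seed = 2),
                   generate_digit_positions(regions, seed = 2))
})

test_that("lognormal noise has the configured spread on the log scale", {
  d <- generate_power_law_pairs(1.2, 0.61, 1000, c(1.5, 10),
                                sigma = 0.15, seed = 1)
  resid <- log(d$y) - log(1.2 * d$x^0.61)
  expect_lt(abs(sd(resid) - 0.15) / 0.15, 0.10)
  # and through the cohort generator
  cc <- cohort_config(n_specimens = 1000, noise_sigma = 0.15, seed = 21)
  co <- generate_cohort(cc)
  r2 <- log(co$blastema_um / 1000) - log(1.2 * (co$stump_um / 1000)^0.61)
  expect_lt(abs(sd(r2) - 0.15) / 0.15, 0.10)
})

test_that("gap sizes are independent of blastema size", {
  co <- generate_cohort(cohort_config(n_specimens = 1000, seed = 14))
  expect_lt(abs(pearson_r(co$gap_um, co$blastema_um)), 0.1)
  expect_true(all(co$gap_um > 0))
})

test_that("domains stay inside the blastema, ordered posterior to anterior", {
  co <- generate_cohort(cohort_config(n_specimens = 200, seed = 8,
                                      anterior_shift_prob = 0.3))
  expect_true(all(co$shh_post_um >= 0))
  expect_true(all(co$fgf8_ant_um <= co$blastema_um))
  expect_true(all(co$shh_ant_um <= co$fgf8_post_um))
  expect_true(all(co$ptch1_ant_um <= co$blastema_um))
  expect_true(any(co$shifted))
})

test_that("infeasible geometry errors after the retry cap", {
  # animals this small force S + P + F > L for every draw
  cc <- cohort_config(n_specimens = 2, animal_length_range = c(0.2, 0.25),
                      seed = 1)
  expect_error(generate_cohort(cc), "feasible geometry")
})

test_that("ISH stripes land on the configured columns", {
  img <- generate_section_image(1000, c(200, 500), c(600, 900),
                                microns_per_pixel = 2, noise_sd = 0, seed = 2)
  support <- which(colSums(img$channels$ISH_Shh) > 0)
  # 0-based columns 100..250 for a [200, 500] um domain at 2 um/px
  expect_equal(min(support), 101)
  expect_equal(max(support), 251)
  expect_error(generate_section_image(1000, c(200, 1200), c(600, 900)),
               "within")
})

test_that("noise-free density field peaks at the configured position", {
  m <- list(L = 2000, shh = c(50, 420), fgf8 = c(600, 1300))
  img <- generate_section_image(m$L, m$shh, m$fgf8, density_peak_rel = 0.6,
                                shape = "rect", smooth_nuclei = TRUE,
                                noise_sd = 0, seed = 1)
  region <- crosstalk_region(m$shh, m$fgf8)
  sums <- colSums(img$channels$Hoechst)
  xc <- (seq_along(sums) - 0.5) * img$microns_per_pixel
  inside <- xc >= region$posterior_end & xc <= region$anterior_end
  peak_rel <- rescale_position(xc[inside][which.max(sums[inside])], region)
  expect_equal(as.numeric(peak_rel), 0.6, tolerance = 0.01)
})

test_that("digit positions follow the requested relative placement", {
  regions <- list(make_region(c(0, 300), c(500, 800)),
                  make_region(c(100, 400), c(700, 1300)))
  exact <- generate_digit_positions(regions, rel_position_mean = 0.6,
                                    rel_sd = 0, seed = 1)
  expect_equal(vapply(seq_along(regions), function(i)
    as.numeric(rescale_position(exact[i], regions[[i]])), numeric(1)),
    c(0.6, 0.6))
  at_post <- generate_digit_positions(regions, rel_position_mean = 0,
                                      rel_sd = 0, seed = 1)
  expect_equal(at_post, vapply(regions, `[[`, numeric(1), "posterior_end"))
})

test_that("generated digit CV matches the closed-form of the noise model", {
  # CV of Omega-rescaled positions ~ rel_sd/rel_mean, shrunk by the
  # population-s.d. factor sqrt((n-1)/n) at n = 11
  regions <- lapply(1:11, function(i)
    make_region(c(0, 200 + 30 * i), c(400 + 30 * i, 900 + 60 * i)))
  cvs <- vapply(1:200, function(s) {
    pos <- generate_digit_positions(regions, rel_position_mean = 0.6,
                                    rel_sd = 0.08, seed = s)
    digit_position_stats(pos, regions, rep(2000, 11))$cv_omega
  }, numeric(1))
  expect_equal(mean(cvs), 0.08 / 0.6, tolerance = 0.1)
})

test_that("cohort CSV round-trips", {
  co <- generate_cohort(cohort_config(n_specimens = 6, seed = 33))
  path <- tempfile(fileext = ".csv")
  write_cohort_csv(co, path)
  back <- read_cohort_csv(path)
  expect_equal(back$blastema_um, co$blastema_um)
  expect_equal(back$id, co$id)
})

test_that("section images round-trip through TIFF plus sidecar", {
  img <- demo_image(seed = 9)
  path <- tempfile(fileext = ".tif")
  write_section_tiff(img, path)
  back <- read_section_tiff(path)
  expect_equal(names(back$channels), names(img$channels))
  expect_identical(back$epithelium_mask, img$epithelium_mask)
  expect_equal(back$microns_per_pixel, img$microns_per_pixel)
  # 16-bit quantisation: intensities agree to one grey level
  expect_lt(max(abs(back$channels$Hoechst - img$channels$Hoechst)), 1.01)
})
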