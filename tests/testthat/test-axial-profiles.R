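test_that("binarize_signal thresholds manually and by Otsu", {
  m <- matrix(c(0, 100, 0, 100), 2)
  expect_identical(binarize_signal(m, "manual", threshold = 50), m == 100)
  expect_false(any(binarize_signal(matrix(0, 4, 4), "manual", threshold = 10)))
  expect_error(binarize_signal(matrix(7, 5, 5)), "constant")
})

test_that("Otsu recovers stripe bounds on a noisy bimodal image", {
  set.seed(11)
  img <- matrix(rnorm(100 * 400, 10, 5), 100, 400)
  img[, 120:280] <- rnorm(100 * 161, 200, 5)
  mask <- binarize_signal(img)
  cols <- which(colSums(mask) > 50)
  expect_lte(abs(min(cols) - 120), 2)
  expect_lte(abs(max(cols) - 280), 2)
})

test_that("domain bounds use the half-open column convention", {
  mask <- matrix(FALSE, 50, 300)
  mask[10:40, 101:251] <- TRUE   # 0-based columns 100..250
  d <- domain_bounds_from_mask(mask, 2)
  expect_equal(d, c(200, 502))
})

test_that("speckles below the area floor are removed; empty masks error", {
  mask <- matrix(FALSE, 50, 300)
  mask[25, 150] <- TRUE  # single-pixel speckle
  expect_error(domain_bounds_from_mask(mask, 2), "speckle")
  expect_error(domain_bounds_from_mask(matrix(FALSE, 5, 5), 2), "empty")
  # speckle plus a real component: bounds come from the component alone
  mask[10:40, 101:251] <- TRUE
  mask[45, 290] <- TRUE
  expect_equal(domain_bounds_from_mask(mask, 2), c(200, 502))
})

test_that("generated expression domains are recovered within 2 px", {
  img <- demo_image(seed = 4)
  m <- demo_measurement()
  tol <- 2 * img$microns_per_pixel
  for (ch in c("ISH_Shh", "ISH_Fgf8")) {
    truth <- if (ch == "ISH_Shh") m$shh else m$fgf8
    mask <- binarize_signal(img$channels[[ch]])
    d <- domain_bounds_from_mask(mask, img$microns_per_pixel,
                                 img$epithelium_mask)
    expect_lt(max(abs(d - truth)), tol + 1e-9)
  }
})

test_that("domains average endpoint-wise over 2-3 sections", {
  expect_equal(average_domains_over_sections(list(c(200, 500), c(220, 520))),
               c(210, 510))
  expect_equal(average_domains_over_sections(list(c(100, 300), c(100, 300))),
               c(100, 300))
  expect_equal(average_domains_over_sections(
    list(c(90, 300), c(120, 360), c(150, 300))), c(120, 320))
  expect_error(average_domains_over_sections(list(c(1, 2))), "2 or 3")
  expect_error(average_domains_over_sections(
    replicate(4, c(1, 2), simplify = FALSE)), "2 or 3")
})

test_that("axial projection sums columns, excluding the epithelium", {
  sig <- matrix(1, 20, 30)
  mes <- matrix(TRUE, 20, 30)
  epi <- matrix(FALSE, 20, 30)
  pr <- axial_projection(sig, mes, epi)
  expect_equal(pr$values, rep(20, 30))
  epi[1:5, ] <- TRUE
  pr2 <- axial_projection(sig, mes, epi)
  expect_equal(pr2$values, rep(15, 30))
  expect_error(axial_projection(sig, matrix(FALSE, 20, 30), epi),
               "no mesenchyme")
})

test_that("width normalization flattens geometry out of uniform density", {
  widths <- c(5, 10, 20, 40, 80)
  values <- 3 * widths  # uniform volumetric density
  expect_equal(width_normalize(values, widths), rep(3, 5))
  expect_error(width_normalize(values, c(5, 10, 0, 40, 80)), "width")
})

test_that("median normalization is idempotent and scale invariant", {
  v <- c(2, 4, 6, 8, 100)
  mn <- median_normalize(v)
  expect_equal(median(mn), 1)
  expect_equal(median_normalize(mn), mn)
  expect_equal(median_normalize(7 * v), mn)
  expect_equal(median_normalize(rep(4, 9)), rep(1, 9))
  expect_error(median_normalize(rep(0, 5)), "median")
})

test_that("moving average preserves constants and spreads an impulse", {
  expect_equal(moving_average(rep(3, 120), 50), rep(3, 120))
  imp <- c(rep(0, 100), 1, rep(0, 100))
  sm <- moving_average(imp, 50)
  expect_equal(max(sm), 1 / 50)
  # centred even window spans window + 1 samples (half weight at extremes)
  expect_equal(sum(sm > 0), 51)
  expect_equal(sm, rev(sm))  # symmetric kernel
  expect_error(moving_average(1:30, 50), "exceed")
})

test_that("moving average cuts white-noise variance by the window factor", {
  set.seed(20)
  v <- rnorm(6000)
  sm <- moving_average(v, 50)
  interior <- sm[100:5900]
  ratio <- var(interior) / var(v)
  expect_gt(ratio, 0.7 / 50)
  expect_lt(ratio, 1.3 / 50)
})

test_that("region means separate signal inside vs outside", {
  pos <- seq(5, 995, by = 10)
  v <- rep(1, 100)
  rm1 <- region_mean_signal(pos, v, c(200, 600))
  expect_equal(rm1$inside, rm1$outside)
  v2 <- ifelse(pos >= 200 & pos <= 600, 2, 0)
  rm2 <- region_mean_signal(pos, v2, c(200, 600))
  expect_equal(rm2$outside, 0)
  expect_error(region_mean_signal(pos, v, c(2000, 3000)), "overlap")
})

test_that("Hoechst and BrdU are denser inside the crosstalk region", {
  m <- demo_measurement()
  region <- crosstalk_region(m$shh, m$fgf8)
  img <- generate_section_image(m$L, m$shh, m$fgf8, seed = 17)
  for (ch in c("Hoechst", "BrdU")) {
    prof <- section_axial_profile(img, ch, region = region)
    rm <- region_mean_signal(prof$position_um, prof$value, region)
    expect_gt(rm$inside, rm$outside)
  }
})

test_that("GP fit recovers noise-free and symmetric peaks", {
  x <- seq(0, 1, length.out = 120)
  mk <- function(peak) data.frame(omega_rel = x,
                                  value = exp(-(x - peak)^2 / 0.02))
  f6 <- fit_unimodal(mk(0.6), seed = 1)
  expect_equal(f6$peak_rel, 0.6, tolerance = 0.01)
  f5 <- fit_unimodal(mk(0.5), seed = 1)
  expect_equal(f5$peak_rel, 0.5, tolerance = 0.01)
  expect_true(all(f6$band_lower <= f6$mean_curve + 1e-9))
  expect_true(all(f6$mean_curve <= f6$band_upper + 1e-9))
  expect_error(fit_unimodal(data.frame(omega_rel = x, value = 1)),
               "degenerate")
})

test_that("GP peak agrees with an independent spline smoother on noisy data", {
  skip_if_not_installed("mgcv")
  set.seed(30)
  x <- runif(400)
  y <- exp(-(x - 0.6)^2 / 0.03) + rnorm(400, 0, 0.1)
  gp <- fit_unimodal(data.frame(omega_rel = x, value = y), seed = 2)
  gam <- mgcv::gam(y ~ s(x, k = 20))
  grid <- seq(0, 1, length.out = 1000)
  gam_peak <- grid[which.max(mgcv::predict.gam(gam,
                                               data.frame(x = grid)))]
  expect_lt(abs(gp$peak_rel - gam_peak), 0.03)
  expect_lt(abs(gp$peak_rel - 0.6), 0.05)
})

test_that("noisy multi-sample GP recovery stays within 5% of truth", {
  x <- seq(0, 1, length.out = 80)
  hits <- 0L
  for (s in 1:20) {
    set.seed(700 + s)
    profs <- lapply(1:8, function(i)
      data.frame(omega_rel = x,
                 value = exp(-(x - 0.6)^2 / 0.03) + rnorm(80, 0, 0.1)))
    f <- fit_unimodal(profs, seed = s)
    if (abs(f$peak_rel - 0.6) <= 0.05) hits <- hits + 1L
  }
  expect_gte(hits / 20, 0.9)
})

test_that("full pipeline recovers the generated density peak on one image", {
  m <- demo_measurement()
  region <- crosstalk_region(m$shh, m$fgf8)
  img <- generate_section_image(m$L, m$shh, m$fgf8, density_peak_rel = 0.6,
                                seed = 23)
  prof <- section_axial_profile(img, "Hoechst", region = region)
  f <- fit_unimodal(prof, seed = 1)
  expect_lt(abs(f$peak_rel - 0.6), 0.05)
})

test_that("a horizontal flip with swapped tags leaves relative outputs unchanged", {
  m <- demo_measurement()
  img <- generate_section_image(m$L, m$shh, m$fgf8, seed = 3)
  region <- crosstalk_region(m$shh, m$fgf8)
  prof <- section_axial_profile(img, "Hoechst", region = region)

  flip <- function(mat) mat[, rev(seq_len(ncol(mat))), drop = FALSE]
  img2 <- img
  img2$channels <- lapply(img$channels, flip)
  img2$epithelium_mask <- flip(img$epithelium_mask)
  # posterior/anterior tags swap: coordinates reflect about L
  region2 <- crosstalk_region(m$L - rev(m$fgf8), m$L - rev(m$shh))
  prof2 <- section_axial_profile(img2, "Hoechst", region = region2)

  ord <- order(1 - prof2$omega_rel)
  expect_equal(1 - prof2$omega_rel[ord], prof$omega_rel, tolerance = 1e-9)
  expect_equal(prof2$value[ord], prof$value, tolerance = 1e-9)
})
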