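#' Generate a synthetic multi-channel tissue-section image
#'
#' Builds a section-like image of a blastema with four channels (Hoechst,
#' BrdU, ISH_Shh, ISH_Fgf8) plus an epithelium mask, mimicking the inputs of
#' the axial-profile quantification pipeline. Columns run posterior to
#' anterior (column 1 = posterior end of the mesenchyme); intensities use a
#' 16-bit range (0-65535).
#'
#' Nuclei (Hoechst) are placed as a point process whose per-unit-area
#' density follows a smooth unimodal function of A-P position peaking at
#' `density_peak_rel` of the crosstalk region; BrdU-positive nuclei are a
#' constant-fraction thinning of the Hoechst nuclei, so the BrdU rate is
#' proportional to the cell-density profile. ISH channels are noisy stripes over the expression
#' domains. The epithelium is a 2-px ring around the mesenchyme, with
#' Hoechst-stained nuclei of its own (which the pipeline must exclude).
#'
#' @param L Blastema mesenchyme A-P width in micrometres.
#' @param shh_domain,fgf8_domain Expression intervals
#'   `c(posterior, anterior)` in micrometres, inside \[0, L\].
#' @param density_peak_rel Peak position of the cell-density profile as a
#'   fraction of the crosstalk region from its posterior end.
#' @param microns_per_pixel Pixel size (um/px).
#' @param height_px Image height in pixels.
#' @param shape Mesenchyme silhouette: `"dome"` (width varies along A-P,
#'   the realistic case) or `"rect"` (constant width).
#' @param nuclei_per_um2 Baseline nuclear density (nuclei per square um)
#'   scaling the point process.
#' @param brdu_max_prob Fraction of nuclei retained as BrdU-positive.
#' @param noise_sd Gaussian pixel noise s.d. (16-bit units) added to every
#'   channel. Zero gives a noise-free image.
#' @param smooth_nuclei If `TRUE`, Hoechst/BrdU are deterministic smooth
#'   intensity fields proportional to the density profile instead of a
#'   sampled point process (useful for exact self-consistency checks).
#' @param density_base Baseline (offset) of the unimodal density profile
#'   relative to its peak amplitude.
#' @param density_width_rel S.d. of the Gaussian density bump, as a
#'   fraction of the crosstalk-region size.
#' @param seed Integer seed.
#' @return Object of class `section_image`: list with `channels` (named
#'   list of matrices), `epithelium_mask` (logical matrix),
#'   `microns_per_pixel`, `ap_axis = "posterior_left"` and `meta` (the
#'   generative truth: domains, crosstalk region, peak position).
#' @export
generate_section_image <- function(L, shh_domain, fgf8_domain,
                                   density_peak_rel = 0.6,
                                   microns_per_pixel = 2,
                                   height_px = 180L,
                                   shape = c("dome", "rect"),
                                   nuclei_per_um2 = 0.02,
                                   brdu_max_prob = 0.5,
                                   noise_sd = 800,
                                   density_base = 0.25,
                                   density_width_rel = 0.22,
                                   smooth_nuclei = FALSE,
                                   seed = 1L) {
  shape <- match.arg(shape)
  stopifnot(L > 0, microns_per_pixel > 0, height_px >= 30L)
  .check_domain(shh_domain, "shh_domain")
  .check_domain(fgf8_domain, "fgf8_domain")
  if (min(shh_domain, fgf8_domain) < 0 || max(shh_domain, fgf8_domain) > L)
    stop("expression domains must lie within [0, L]")
  set.seed(as.integer(seed))

  mpp <- microns_per_pixel
  ncol_ <- as.integer(round(L / mpp))
  nrow_ <- as.integer(height_px)
  xc <- (seq_len(ncol_) - 0.5) * mpp  # column-centre positions, um

  region <- crosstalk_region(shh_domain, fgf8_domain)

  # mesenchyme silhouette: per-column half-width in px
  mid <- (nrow_ + 1) / 2
  u01 <- (seq_len(ncol_) - 0.5) / ncol_
  max_half <- (nrow_ - 8) / 2          # leave room for the epithelium ring
  half <- if (shape == "dome") {
    pmax(4, max_half * sqrt(pmax(0, 1 - (2 * u01 - 1)^2 * 0.64)))
  } else rep(max_half, ncol_)
  top <- pmax(1, ceiling(mid - half))
  bot <- pmin(nrow_, floor(mid + half))

  mes <- matrix(FALSE, nrow_, ncol_)
  for (j in seq_len(ncol_)) mes[top[j]:bot[j], j] <- TRUE
  # 2-px epithelium ring = dilation of the mesenchyme minus the mesenchyme
  kern <- EBImage::makeBrush(5, shape = "box")
  epi <- EBImage::dilate(mes * 1, kern) > 0.5 & !mes

  # unimodal density profile in crosstalk-region coordinates
  u <- (xc - region$posterior_end) / region$size
  dens <- density_base + exp(-(u - density_peak_rel)^2 /
                               (2 * density_width_rel^2))
  dens <- dens / max(dens)

  blank <- matrix(0, nrow_, ncol_)
  hoechst <- blank; brdu <- blank
  nuc_val <- 45000
  if (smooth_nuclei) {
    for (j in seq_len(ncol_)) {
      hoechst[top[j]:bot[j], j] <- nuc_val * dens[j]
      brdu[top[j]:bot[j], j] <- nuc_val * brdu_max_prob * dens[j]
    }
  } else
  # mesenchymal nuclei: Poisson count per column, rate = density * area
  for (j in seq_len(ncol_)) {
    h_px <- bot[j] - top[j] + 1L
    lam <- nuclei_per_um2 * dens[j] * h_px * mpp^2
    cnt <- stats::rpois(1, lam)
    if (cnt == 0) next
    ys <- sample(top[j]:bot[j], cnt, replace = TRUE)
    hoechst[cbind(ys, j)] <- nuc_val
    keep <- stats::runif(cnt) < brdu_max_prob
    if (any(keep)) brdu[cbind(ys[keep], j)] <- nuc_val
  }
  # epithelial nuclei (uniform): the pipeline must mask these out
  epi_idx <- which(epi)
  epi_pick <- epi_idx[stats::runif(length(epi_idx)) < 0.3]
  hoechst[epi_pick] <- nuc_val

  stripe <- function(domain) {
    m <- blank
    # columns whose pixel interval [(j-1)*mpp, j*mpp) meets [post, ant]
    j0 <- max(1L, as.integer(floor(domain[1] / mpp)) + 1L)
    j1 <- min(ncol_, as.integer(floor(domain[2] / mpp)) + 1L)
    m[, j0:j1][mes[, j0:j1]] <- 30000
    m
  }
  ish_shh <- stripe(shh_domain)
  ish_fgf8 <- stripe(fgf8_domain)

  addnoise <- function(m) {
    if (noise_sd > 0) m <- m + matrix(stats::rnorm(length(m), 0, noise_sd),
                                      nrow(m))
    pmin(pmax(m, 0), 65535)
  }
  channels <- lapply(list(Hoechst = hoechst, BrdU = brdu,
                          ISH_Shh = ish_shh, ISH_Fgf8 = ish_fgf8), addnoise)

  structure(list(
    channels = channels, epithelium_mask = epi,
    microns_per_pixel = mpp, ap_axis = "posterior_left",
    meta = list(L = L, shh_domain = shh_domain, fgf8_domain = fgf8_domain,
                region = region, density_peak_rel = density_peak_rel,
                seed = as.integer(seed))),
    class = "section_image")
}

#' Mesenchyme mask enclosed by the epithelium ring
#'
#' Recovers the mesenchymal region of a section image as the area strictly
#' inside the epithelium ring, column by column.
#'
#' @param epithelium_mask Logical matrix marking epithelium pixels.
#' @return Logical matrix of the same shape marking mesenchyme pixels.
#' @export
mesenchyme_from_epithelium <- function(epithelium_mask) {
  out <- matrix(FALSE, nrow(epithelium_mask), ncol(epithelium_mask))
  for (j in seq_len(ncol(epithelium_mask))) {
    rows <- which(epithelium_mask[, j])
    if (length(rows) < 2L) next
    inner <- setdiff(seq(min(rows), max(rows)), rows)
    if (length(inner)) out[inner, j] <- TRUE
  }
  out
}

#' Write / read a section image as multi-page TIFF plus JSON sidecar
#'
#' Pages are written in the order Hoechst, BrdU, ISH_Shh, ISH_Fgf8,
#' epithelium mask (0/1), as 16-bit grayscale. The sidecar records channel
#' names, page order and `microns_per_pixel`.
#'
#' @param img A `section_image`.
#' @param path TIFF path; the sidecar is written at `paste0(path, ".json")`
#'   unless `sidecar` is given.
#' @param sidecar Optional sidecar path.
#' @return `read_section_tiff` returns a `section_image` (without `meta`).
#' @export
write_section_tiff <- function(img, path, sidecar = paste0(path, ".json")) {
  stopifnot(inherits(img, "section_image"))
  pages <- lapply(img$channels, function(m) m / 65535)
  pages$epithelium_mask <- img$epithelium_mask * 1
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(
    list(channels = names(img$channels),
         pages = c(names(img$channels), "epithelium_mask"),
         microns_per_pixel = img$microns_per_pixel,
         ap_axis = img$ap_axis),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_section_tiff
#' @export
read_section_tiff <- function(path, sidecar = paste0(path, ".json")) {
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  names(pages) <- meta$pages
  channels <- lapply(pages[meta$channels], function(m) m * 65535)
  structure(list(
    channels = channels,
    epithelium_mask = pages[["epithelium_mask"]] > 0.5,
    microns_per_pixel = meta$microns_per_pixel,
    ap_axis = meta$ap_axis, meta = NULL),
    class = "section_image")
}
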