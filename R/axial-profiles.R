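#' Binarize a single-channel image
#'
#' Thresholds an intensity image into a logical mask. The default method
#' computes the threshold from the intensity histogram (Otsu); a manual
#' threshold can be supplied instead, mirroring interactive thresholding of
#' in situ hybridization signals whose intensity varies between samples.
#'
#' @param channel Numeric matrix of intensities (any scale).
#' @param method `"otsu"` or `"manual"`.
#' @param threshold Manual threshold (same scale as `channel`); required
#'   when `method = "manual"`.
#' @return Logical matrix: pixels strictly above the threshold.
#' @export
binarize_signal <- function(channel, method = c("otsu", "manual"),
                            threshold = NULL) {
  method <- match.arg(method)
  stopifnot(is.matrix(channel), is.numeric(channel))
  if (method == "manual") {
    if (is.null(threshold)) stop("manual method requires a threshold")
    return(channel > threshold)
  }
  rng <- range(channel)
  if (rng[1] == rng[2]) stop("constant image: Otsu threshold undefined")
  scaled <- (channel - rng[1]) / (rng[2] - rng[1])
  th <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1), levels = 256L)
  scaled > th
}

#' Expression-domain bounds from a binarized mask
#'
#' Removes epithelium pixels and small connected components (speckles, e.g.
#' auto-fluorescent blood cells), then reports the A-P extent of the
#' remaining signal. Columns are half-open in pixel space: a mask supported
#' on 0-based columns \[c0, c1\] maps to \[c0 * mpp, (c1 + 1) * mpp\] um.
#'
#' @param mask Logical matrix from [binarize_signal()].
#' @param microns_per_pixel Pixel size (um/px).
#' @param epithelium_mask Optional logical matrix of pixels to exclude.
#' @param min_area Connected components smaller than this (pixels) are
#'   treated as speckles and removed.
#' @return Numeric `c(posterior, anterior)` in micrometres.
#' @export
domain_bounds_from_mask <- function(mask, microns_per_pixel,
                                    epithelium_mask = NULL, min_area = 20L) {
  stopifnot(is.matrix(mask), microns_per_pixel > 0)
  m <- mask
  if (!is.null(epithelium_mask)) m <- m & !epithelium_mask
  if (!any(m)) stop("empty mask after removing epithelium")
  lab <- EBImage::bwlabel(EBImage::Image(m * 1))
  sizes <- table(lab[lab > 0])
  keep <- as.integer(names(sizes)[sizes >= min_area])
  m <- matrix(as.numeric(lab) %in% keep, nrow(mask))
  if (!any(m)) stop("no signal component of at least ", min_area,
                    " px remains after speckle removal")
  cols <- which(colSums(m) > 0)
  c((min(cols) - 1L) * microns_per_pixel, max(cols) * microns_per_pixel)
}

#' Average expression domains over adjacent sections
#'
#' Expression-domain bounds vary with the proximodistal level of the
#' section, so two or three sections of the same blastema are averaged
#' endpoint-wise.
#'
#' @param domains List of 2 or 3 length-2 domain vectors (um).
#' @return Endpoint-wise mean domain `c(posterior, anterior)`.
#' @export
average_domains_over_sections <- function(domains) {
  if (!is.list(domains) || length(domains) < 2L || length(domains) > 3L)
    stop("expected a list of 2 or 3 domains")
  lapply(domains, .check_domain, name = "domain")
  colMeans(do.call(rbind, domains))
}

#' Project a binarized signal onto the A-P axis
#'
#' Sums signal per image column after deleting epithelial pixels,
#' restricted to columns containing mesenchyme.
#'
#' @param signal Logical or numeric matrix (typically a binarized mask).
#' @param mesenchyme_mask Logical matrix marking mesenchyme pixels.
#' @param epithelium_mask Logical matrix marking epithelium pixels to
#'   exclude.
#' @return List with `columns` (indices of mesenchyme columns) and
#'   `values` (per-column sums).
#' @export
axial_projection <- function(signal, mesenchyme_mask, epithelium_mask) {
  stopifnot(all(dim(signal) == dim(mesenchyme_mask)),
            all(dim(signal) == dim(epithelium_mask)))
  s <- signal * 1
  s[epithelium_mask] <- 0
  s[!mesenchyme_mask] <- 0
  cols <- which(colSums(mesenchyme_mask) > 0)
  if (length(cols) == 0L) stop("no mesenchyme columns in the image")
  list(columns = cols, values = colSums(s)[cols])
}

#' Normalize a projected profile by local mesenchyme width
#'
#' Divides each column's projected signal by the dorsoventral mesenchyme
#' width (in pixels) at that column, converting a column sum into a mean
#' density and removing silhouette geometry from the profile.
#'
#' @param values Per-column projected signal.
#' @param widths_px Per-column mesenchyme width in pixels (> 0).
#' @return Width-normalized values.
#' @export
width_normalize <- function(values, widths_px) {
  stopifnot(length(values) == length(widths_px))
  if (any(widths_px <= 0)) stop("zero mesenchyme width inside the profile")
  values / widths_px
}

#' Normalize a profile by its median
#'
#' @param values Positive-median numeric vector.
#' @return Values divided by their median (resulting median = 1).
#' @export
median_normalize <- function(values) {
  if (length(values) == 0L) stop("empty profile")
  med <- stats::median(values)
  if (med <= 0) stop("profile median must be positive")
  values / med
}

#' Centered simple moving average with shrinking edges
#'
#' Interior points use a centred window of `window` samples. For an even
#' window the classic centred form is used (a span of `window + 1` samples
#' with half weight at the two extremes), which keeps the kernel symmetric
#' so the profile is invariant under a coordinate flip. Near the edges the
#' window shrinks to the available samples (no padding, no invented data).
#'
#' @param values Numeric vector, longer than `window`.
#' @param window Window size in samples (default 50).
#' @return Smoothed vector of the same length.
#' @export
moving_average <- function(values, window = 50L) {
  n <- length(values)
  if (n <= window) stop("profile length must exceed the window")
  if (window %% 2 == 1) {
    half <- (window - 1L) %/% 2L
    w <- rep(1, window)
  } else {
    half <- window %/% 2L
    w <- c(0.5, rep(1, window - 1L), 0.5)
  }
  offs <- -half:half
  vapply(seq_len(n), function(i) {
    j <- i + offs
    ok <- j >= 1L & j <= n
    sum(values[j[ok]] * w[ok]) / sum(w[ok])
  }, numeric(1))
}

#' Mean normalized signal inside versus outside a region
#'
#' @param positions Profile positions (um).
#' @param values Normalized profile values.
#' @param region Length-2 interval (um) or a `crosstalk_region`.
#' @return List with `inside` and `outside` means.
#' @export
region_mean_signal <- function(positions, values, region) {
  if (inherits(region, "crosstalk_region"))
    region <- c(region$posterior_end, region$anterior_end)
  stopifnot(length(region) == 2L, region[1] < region[2])
  inside <- positions >= region[1] & positions <= region[2]
  if (!any(inside)) stop("region does not overlap the profile")
  list(inside = mean(values[inside]),
       outside = if (any(!inside)) mean(values[!inside]) else NA_real_)
}

#' Full axial-profile quantification of one section image
#'
#' Runs the complete per-image pipeline on one channel: binarization,
#' epithelium deletion, projection onto the A-P axis, width normalization
#' by the local mesenchyme width, median normalization, and a 50-sample
#' moving average. If a crosstalk region is supplied, positions are also
#' rescaled into region-relative coordinates.
#'
#' @param img A `section_image`.
#' @param channel Channel name (default `"Hoechst"`).
#' @param region Optional `crosstalk_region` for relative coordinates.
#' @param window Moving-average window (samples).
#' @param method,threshold Passed to [binarize_signal()].
#' @return data.frame of class `axial_profile` with columns `position_um`,
#'   `value`, and `omega_rel` when a region is given.
#' @export
section_axial_profile <- function(img, channel = "Hoechst", region = NULL,
                                  window = 50L, method = "otsu",
                                  threshold = NULL) {
  stopifnot(inherits(img, "section_image"),
            channel %in% names(img$channels))
  mes <- mesenchyme_from_epithelium(img$epithelium_mask)
  mask <- binarize_signal(img$channels[[channel]], method = method,
                          threshold = threshold)
  proj <- axial_projection(mask, mes, img$epithelium_mask)
  widths <- colSums(mes)[proj$columns]
  v <- width_normalize(proj$values, widths)
  v <- median_normalize(v)
  v <- moving_average(v, window)
  out <- data.frame(position_um = (proj$columns - 0.5) * img$microns_per_pixel,
                    value = v)
  if (!is.null(region)) out$omega_rel <- as.numeric(
    rescale_position(out$position_um, region))
  class(out) <- c("axial_profile", "data.frame")
  out
}
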