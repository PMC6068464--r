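# Image and trace quantifiers: spot detection, off-cluster intensity
# fraction, per-spot overlap fold change, isotope-ratio fold over baseline,
# winner-take-all ratio/fluorescence overlay, pH-probe releasable fraction,
# and calcium burst detection. Morphology and labeling go through EBImage;
# everything downstream of the masks is plain arithmetic on matrices.

#' Two-channel microscopy containers
#'
#' \code{channel_image} wraps a 2-D non-negative intensity matrix with its
#' pixel size; \code{spot_mask} wraps an integer label matrix (0 =
#' background) as produced by connected-component labeling.
#'
#' @param pixels numeric matrix of non-negative intensities.
#' @param pixel_size pixel edge length, nm.
#' @param labels integer matrix of component labels (0 background).
#' @return a \code{"channel_image"} or \code{"spot_mask"} object.
#' @export
channel_image <- function(pixels, pixel_size = 20) {
  pixels <- as.matrix(pixels)
  if (any(!is.finite(pixels)) || any(pixels < 0))
    stop("pixels must be finite and non-negative")
  if (pixel_size <= 0) stop("pixel_size must be positive (nm)")
  structure(list(pixels = pixels, pixel_size = pixel_size),
            class = "channel_image")
}

#' @rdname channel_image
#' @export
spot_mask <- function(labels) {
  labels <- as.matrix(labels)
  if (any(labels < 0) || any(labels != round(labels)))
    stop("labels must be non-negative integers")
  structure(list(labels = labels, n_spots = length(setdiff(unique(c(labels)), 0L))),
            class = "spot_mask")
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("channel_image %dx%d px (%.3g nm/px), max intensity %.4g\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size, max(x$pixels)))
  invisible(x)
}

#' @export
print.spot_mask <- function(x, ...) {
  cat(sprintf("spot_mask %dx%d px, %d spots\n",
              nrow(x$labels), ncol(x$labels), x$n_spots))
  invisible(x)
}

#' Detect fluorescence spots
#'
#' Gaussian smoothing, intensity threshold at the background median plus
#' \code{k} robust standard deviations (MAD), connected-component labeling,
#' and a minimum-area filter. Deterministic for fixed input.
#'
#' @param img a \code{\link{channel_image}}.
#' @param smooth_sigma Gaussian smoothing sigma, nm (0 disables smoothing).
#' @param k threshold stringency in MAD units above the median.
#' @param min_area minimum component area, pixels.
#' @return a \code{\link{spot_mask}}.
#' @export
detect_spots <- function(img, smooth_sigma = 40, k = 5, min_area = 4) {
  stopifnot(inherits(img, "channel_image"))
  if (smooth_sigma < 0) stop("smooth_sigma must be non-negative")
  if (min_area < 1) stop("min_area must be at least 1")
  px <- img$pixels
  if (max(px) == 0) return(spot_mask(matrix(0L, nrow(px), ncol(px))))
  sigma_px <- smooth_sigma / img$pixel_size
  sm <- if (sigma_px > 0) EBImage::gblur(px, sigma = sigma_px) else px
  bg_med <- stats::median(sm)
  bg_mad <- stats::mad(sm)
  thr <- bg_med + k * max(bg_mad, .Machine$double.eps)
  bw <- sm > thr
  lab <- EBImage::bwlabel(bw)
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0])
    drop <- which(areas < min_area)
    if (length(drop)) lab[lab %in% drop] <- 0L
    # relabel compactly
    kept <- sort(setdiff(unique(c(lab)), 0L))
    if (length(kept)) {
      map <- integer(max(kept)); map[kept] <- seq_along(kept)
      lab[lab > 0] <- map[lab[lab > 0]]
    }
  }
  spot_mask(matrix(as.integer(lab), nrow(px), ncol(px)))
}

# disc-dilated binary mask; radius in pixels (0 = no dilation)
dilate_mask <- function(binary, radius) {
  if (radius <= 0) return(binary)
  size <- 2L * as.integer(ceiling(radius)) + 1L
  brush <- EBImage::makeBrush(size, shape = "disc")
  EBImage::dilate(binary * 1, brush) > 0
}

#' Off-cluster intensity fraction
#'
#' Percentage of the (background-subtracted) intensity of one channel that
#' falls outside the dilated spots of the reference channel — the
#' fraction of tagged molecules found away from bona fide vesicle-marker
#' clusters. Background is the median of the pixels outside all masks and
#' is subtracted as a per-region total (pixel count times background), so
#' zero-mean shot noise cancels rather than rectifying into a positive
#' off-cluster signal. Dilation by one PSF sigma (the default) counts
#' PSF-blurred rim light as in-cluster.
#'
#' @param chanA the quantified \code{\link{channel_image}}.
#' @param maskB the reference-channel \code{\link{spot_mask}}.
#' @param dilation_px mask dilation radius, pixels.
#' @return percent of intensity off-cluster (0-100).
#' @export
off_cluster_fraction <- function(chanA, maskB, dilation_px = 2) {
  stopifnot(inherits(chanA, "channel_image"), inherits(maskB, "spot_mask"))
  px <- chanA$pixels
  if (!all(dim(px) == dim(maskB$labels))) stop("image and mask shapes differ")
  if (maskB$n_spots == 0L) {
    warning("empty reference mask: all intensity counted as off-cluster")
    return(100)
  }
  inside <- dilate_mask(maskB$labels > 0, dilation_px)
  bg <- stats::median(px[!inside])
  off <- max(sum(px[!inside]) - bg * sum(!inside), 0)
  on <- max(sum(px[inside]) - bg * sum(inside), 0)
  if (off + on == 0) {
    # degenerate: the image is indistinguishable from flat background, so
    # background subtraction annihilates it; report the raw intensity split
    if (sum(px) == 0) return(0)
    return(100 * sum(px[!inside]) / sum(px))
  }
  100 * off / (off + on)
}

#' Per-spot overlap intensity fold change
#'
#' Mean per-spot background-subtracted intensity of a protein channel
#' within reference spots, condition B over condition A — e.g. the fold
#' enrichment of SNAP25 signal overlapping aged versus freshly tagged
#' vesicle-protein spots. Background is the per-image median outside the
#' mask.
#'
#' @param protein_img_condA,protein_img_condB \code{channel_image}s of the
#'   protein of interest in the two conditions.
#' @param spotsA,spotsB per-condition reference \code{spot_mask}s.
#' @return fold change (condition B / condition A).
#' @export
overlap_intensity_fold <- function(protein_img_condA, protein_img_condB,
                                   spotsA, spotsB) {
  mean_spot_intensity <- function(img, mask) {
    stopifnot(inherits(img, "channel_image"), inherits(mask, "spot_mask"))
    if (!all(dim(img$pixels) == dim(mask$labels)))
      stop("image and mask shapes differ")
    if (mask$n_spots == 0L) stop("empty spot mask")
    labs <- mask$labels
    bg <- stats::median(img$pixels[labs == 0])
    vals <- tapply(img$pixels[labs > 0] - bg, labs[labs > 0], mean)
    mean(pmax(vals, 0))
  }
  a <- mean_spot_intensity(protein_img_condA, spotsA)
  b <- mean_spot_intensity(protein_img_condB, spotsB)
  if (a == 0) stop("zero overlap intensity in condition A: fold undefined")
  b / a
}

#' Isotope-ratio container and fold over baseline
#'
#' \code{ratio_image_pair} holds paired heavy- and light-isotope count
#' images (e.g. 15N and 14N). \code{fold_over_baseline} computes the mean
#' pixel-wise heavy/light ratio over regions of interest divided by the
#' mean ratio over baseline regions; pixels with zero light counts are
#' excluded. With \code{pixelwise = FALSE} the ratio of summed counts per
#' region is used instead.
#'
#' @param heavy,light non-negative count matrices of equal shape.
#' @param pair a \code{ratio_image_pair}.
#' @param rois,baseline disjoint \code{\link{spot_mask}}s selecting the
#'   evaluated and the reference pixels.
#' @param pixelwise average pixel ratios (default) or ratio region sums.
#' @return \code{fold_over_baseline} returns the fold (unitless).
#' @export
ratio_image_pair <- function(heavy, light) {
  heavy <- as.matrix(heavy); light <- as.matrix(light)
  if (!all(dim(heavy) == dim(light))) stop("heavy and light shapes differ")
  if (any(heavy < 0) || any(light < 0)) stop("counts must be non-negative")
  structure(list(heavy = heavy, light = light), class = "ratio_image_pair")
}

#' @rdname ratio_image_pair
#' @export
fold_over_baseline <- function(pair, rois, baseline, pixelwise = TRUE) {
  stopifnot(inherits(pair, "ratio_image_pair"),
            inherits(rois, "spot_mask"), inherits(baseline, "spot_mask"))
  roi_sel <- rois$labels > 0
  base_sel <- baseline$labels > 0
  if (!any(roi_sel) || !any(base_sel)) stop("empty roi or baseline mask")
  if (any(roi_sel & base_sel)) stop("roi and baseline masks must be disjoint")
  region_ratio <- function(sel) {
    ok <- sel & pair$light > 0
    if (!any(ok)) stop("no evaluable pixels (light counts all zero) in region")
    if (pixelwise) mean(pair$heavy[ok] / pair$light[ok])
    else sum(pair$heavy[ok]) / sum(pair$light[ok])
  }
  region_ratio(roi_sel) / region_ratio(base_sel)
}

#' Winner-take-all overlay of a ratio image and a fluorescence image
#'
#' Both images are normalized to [0, 1] by their own maxima; each pixel of
#' the composite takes the larger of the two normalized values, and the
#' source map records which image won (ties go to the ratio image).
#'
#' @param ratio_img,fluor_img numeric matrices of equal shape.
#' @return list with \code{composite} (matrix in [0, 1]) and \code{source}
#'   (character matrix, \code{"ratio"} or \code{"fluorescence"}).
#' @export
coin_overlay <- function(ratio_img, fluor_img) {
  ratio_img <- as.matrix(ratio_img); fluor_img <- as.matrix(fluor_img)
  if (!all(dim(ratio_img) == dim(fluor_img))) stop("image shapes differ")
  norm <- function(m) if (max(m) > 0) m / max(m) else m
  r <- norm(ratio_img); f <- norm(fluor_img)
  src <- matrix("ratio", nrow(r), ncol(r))
  src[f > r] <- "fluorescence"
  list(composite = pmax(r, f), source = src)
}

#' Releasable fraction from a pH-sensitive probe
#'
#' Fraction of all labeled vesicles still able to exocytose, from CypHer
#' style measurements: fluorescence at rest minus fluorescence after
#' exhaustive stimulation (the dimming reports exocytosis), normalized by
#' the total labeled signal revealed at pH 5.5 after fixation and
#' permeabilization. An optional linear bleach correction divides the
#' stimulated reading by the retained fraction measured in unstimulated
#' controls.
#'
#' @param F_rest fluorescence before stimulation.
#' @param F_stim fluorescence after stimulation.
#' @param F_total_pH55 total labeled fluorescence at pH 5.5 (> 0).
#' @param bleach_retention fraction of signal retained over the protocol in
#'   unstimulated controls (1 = no correction).
#' @return list with \code{fraction} and a \code{quality_flag} set when
#'   the fraction is negative (stimulated signal above resting signal).
#' @export
releasable_fraction_cypher <- function(F_rest, F_stim, F_total_pH55,
                                       bleach_retention = 1) {
  if (F_total_pH55 <= 0) stop("total pH 5.5 fluorescence must be positive")
  if (bleach_retention <= 0 || bleach_retention > 1)
    stop("bleach_retention must lie in (0, 1]")
  frac <- (F_rest - F_stim / bleach_retention) / F_total_pH55
  list(fraction = frac, quality_flag = frac < 0)
}

#' Calcium trace container
#'
#' A uniformly sampled fluorescence trace (time in seconds, value in
#' dF/F).
#'
#' @param time sampling times, seconds (uniform).
#' @param value dF/F values.
#' @return a \code{"trace"} object with the sampling rate attached.
#' @export
fluor_trace <- function(time, value) {
  if (length(time) != length(value)) stop("time and value lengths differ")
  if (any(!is.finite(value))) stop("values must be finite")
  dt <- diff(time)
  if (length(dt) && (max(dt) - min(dt)) > 1e-9 * mean(dt))
    stop("sampling must be uniform")
  structure(list(time = time, value = value, rate = 1 / mean(dt)),
            class = "trace")
}

#' Read/write traces as delimited text
#'
#' Two-column CSV with header \code{time_s,dff}.
#'
#' @param tr a \code{trace}.
#' @param path file path.
#' @export
write_trace <- function(tr, path) {
  stopifnot(inherits(tr, "trace"))
  utils::write.csv(data.frame(time_s = tr$time, dff = tr$value),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "dff") %in% names(df)))
    stop("expected header time_s,dff")
  fluor_trace(df$time_s, df$dff)
}

#' Detect network activity bursts in a calcium trace
#'
#' The dF/F trace is smoothed with a \code{boxcar_s}-second boxcar and
#' burst onsets are found on its rise: the lag-\code{boxcar_s} difference
#' of the smoothed trace is thresholded at \code{z} noise standard
#' deviations, with the per-sample noise estimated robustly from
#' successive differences of the raw trace (transients are slow relative
#' to the sampling interval, so successive differences isolate the noise
#' even when bursts pile up and lift the absolute dF/F level). Upward
#' threshold crossings separated by at least \code{refractory} seconds
#' are counted as onsets.
#'
#' Because the refractory window (and the decay of the preceding
#' transient) hides any burst arriving within it, the primary \code{rate}
#' is the standard non-paralyzable dead-time estimate
#' \eqn{n / (T - n \tau_r)}, which for Poisson bursts removes the pile-up
#' bias at high frequencies; the plain onset count over the duration is
#' also returned as \code{raw_rate}.
#'
#' @param tr a \code{\link{trace}} of at least 60 s.
#' @param z threshold stringency, noise standard deviations (> 0).
#' @param refractory minimum onset separation, seconds.
#' @param boxcar_s smoothing window, seconds.
#' @return list with \code{burst_times} (onset times, s), \code{rate}
#'   (dead-time-corrected burst frequency, Hz) and \code{raw_rate}
#'   (onset count over duration, Hz).
#' @export
detect_bursts <- function(tr, z = 3.5, refractory = 2, boxcar_s = 0.5) {
  stopifnot(inherits(tr, "trace"))
  duration <- max(tr$time) - min(tr$time)
  if (duration < 60) stop("trace must span at least 60 s")
  if (z <= 0) stop("z must be positive")
  w <- max(1L, round(boxcar_s * tr$rate))
  sm <- as.numeric(stats::filter(tr$value, rep(1 / w, w), sides = 2))
  sm[is.na(sm)] <- tr$value[is.na(sm)]
  # per-sample noise sd, robust to slow transients (Gaussian: the median
  # absolute successive difference is sigma * sqrt(2) * qnorm(0.75))
  sigma <- stats::median(abs(diff(tr$value))) / (sqrt(2) * stats::qnorm(0.75))
  d <- c(rep(0, w), diff(sm, lag = w))
  thr <- stats::median(d) +
    z * max(sigma * sqrt(2 / w), .Machine$double.eps)
  above <- d > thr
  onsets_idx <- which(above & !c(FALSE, above[-length(above)]))
  onset_t <- tr$time[onsets_idx]
  keep <- numeric(0)
  last <- -Inf
  for (ot in onset_t) {
    if (ot - last >= refractory) { keep <- c(keep, ot); last <- ot }
  }
  n <- length(keep)
  live_time <- duration - n * refractory
  list(burst_times = keep,
       rate = if (live_time > 0) n / live_time else n / duration,
       raw_rate = n / duration)
}

#' Per-burst release fraction from paired calcium/pHluorin traces
#'
#' For each burst onset, the sypHy upstroke is the mean of the pHluorin
#' trace over \code{window_s} after the onset minus its mean over
#' \code{baseline_s} before it (window means rather than a single peak
#' sample, so trace noise averages out instead of biasing the peak
#' upward); the release fraction is the mean upstroke divided by the
#' full-pool reference amplitude.
#'
#' @param burst_times burst onset times, seconds (non-empty, within the
#'   trace span).
#' @param syphy_trace a \code{\link{trace}} of the pHluorin signal.
#' @param pool_amplitude signal amplitude of the full labeled pool (> 0).
#' @param window_s post-onset window for the upstroke peak, seconds.
#' @param baseline_s pre-onset averaging window, seconds.
#' @return mean fraction of the pool released per burst.
#' @export
per_burst_release_fraction <- function(burst_times, syphy_trace,
                                       pool_amplitude, window_s = 1,
                                       baseline_s = 0.5) {
  stopifnot(inherits(syphy_trace, "trace"))
  if (length(burst_times) == 0L) stop("no bursts: release fraction undefined")
  if (pool_amplitude <= 0) stop("pool_amplitude must be positive")
  tt <- syphy_trace$time; vv <- syphy_trace$value
  if (any(burst_times < min(tt)) || any(burst_times > max(tt)))
    stop("burst times outside the trace span")
  upstrokes <- vapply(burst_times, function(bt) {
    pre <- vv[tt >= bt - baseline_s & tt < bt]
    base <- if (length(pre)) mean(pre) else vv[which.min(abs(tt - bt))]
    post <- vv[tt >= bt & tt <= bt + window_s]
    mean(post) - base
  }, numeric(1L))
  mean(pmax(upstrokes, 0)) / pool_amplitude
}

#' Read/write 16-bit TIFF channel images
#'
#' Images are stored as single-page 16-bit grayscale TIFF; intensities are
#' scaled by \code{scale} on write (counts per unit intensity) and
#' unscaled on read.
#'
#' @param img a \code{\link{channel_image}}.
#' @param path file path.
#' @param scale intensity-to-count scaling for the 16-bit container.
#' @param pixel_size pixel size to attach on read, nm.
#' @export
write_channel_tiff <- function(img, path, scale = 1) {
  stopifnot(inherits(img, "channel_image"))
  m <- img$pixels * scale
  if (max(m) > 65535) stop("scaled intensities exceed the 16-bit range")
  tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_channel_tiff
#' @export
read_channel_tiff <- function(path, scale = 1, pixel_size = 20) {
  m <- tiff::readTIFF(path) * 65535 / scale
  channel_image(round(m, 6), pixel_size = pixel_size)
}
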