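test_that("spot detection finds generated spots and handles degenerate images", {
  g <- gen_two_channel_image(seed = 1)
  m <- detect_spots(g$channel2)
  expect_equal(m$n_spots, 50L)
  # flat images yield no spots
  flat <- channel_image(matrix(0, 64, 64))
  expect_equal(detect_spots(flat)$n_spots, 0L)
  const <- channel_image(matrix(5, 64, 64))
  expect_equal(detect_spots(const)$n_spots, 0L)
  # two spots closer than the resolution merge into one component
  img <- matrix(0, 64, 64)
  for (cc in list(c(30, 30), c(33, 33))) {
    xg <- outer(1:64, rep(1, 64)); yg <- t(xg)
    img <- img + 100 * exp(-((xg - cc[1])^2 + (yg - cc[2])^2) / (2 * 2^2))
  }
  merged <- detect_spots(channel_image(img + 1), k = 3)
  expect_equal(merged$n_spots, 1L)
})

test_that("off-cluster fraction is exact on constructed cases", {
  # all intensity inside the mask
  px <- matrix(0, 32, 32); px[10:12, 10:12] <- 50
  lab <- matrix(0L, 32, 32); lab[9:13, 9:13] <- 1L
  expect_equal(off_cluster_fraction(channel_image(px), spot_mask(lab),
                                    dilation_px = 0), 0)
  # uniform image, mask covering exactly half the pixels: 50%
  half <- matrix(0L, 32, 32); half[1:16, ] <- 1L
  expect_equal(off_cluster_fraction(channel_image(matrix(7, 32, 32)),
                                    spot_mask(half), dilation_px = 0), 50)
  # empty mask warns and reports 100%
  expect_warning(
    v <- off_cluster_fraction(channel_image(matrix(1, 8, 8)),
                              spot_mask(matrix(0L, 8, 8))),
    "empty")
  expect_equal(v, 100)
})

test_that("off-cluster fraction is invariant to global intensity scaling", {
  g <- gen_two_channel_image(seed = 4)
  m <- detect_spots(g$channel2)
  v1 <- off_cluster_fraction(g$channel1, m, dilation_px = 2)
  scaled <- channel_image(g$channel1$pixels * 10, g$channel1$pixel_size)
  v2 <- off_cluster_fraction(scaled, m, dilation_px = 2)
  expect_equal(v1, v2, tolerance = 1e-9)
})

test_that("overlap fold is 1 for identical conditions and tracks enrichment", {
  g <- gen_two_channel_image(seed = 6)
  m <- detect_spots(g$channel2)
  expect_equal(overlap_intensity_fold(g$channel1, g$channel1, m, m), 1)
  # generator enrichment 2.0 recovered within 15%
  ga <- gen_two_channel_image(cfg = list(enrichment_fold = 1), seed = 41)
  gb <- gen_two_channel_image(cfg = list(enrichment_fold = 2), seed = 42)
  fold <- overlap_intensity_fold(ga$channel1, gb$channel1,
                                 detect_spots(ga$channel2),
                                 detect_spots(gb$channel2))
  expect_gt(fold, 2 * 0.85)
  expect_lt(fold, 2 * 1.15)
  # all-zero condition-B protein channel gives fold 0
  zero <- channel_image(matrix(0, nrow(gb$channel1$pixels),
                               ncol(gb$channel1$pixels)))
  expect_equal(overlap_intensity_fold(ga$channel1, zero,
                                      detect_spots(ga$channel2),
                                      detect_spots(gb$channel2)), 0)
})

test_that("ratio fold over baseline: arithmetic, reciprocity, recovery", {
  # constant patches: 0.012 over 0.004 is fold 3
  heavy <- matrix(4, 20, 20); light <- matrix(1000, 20, 20)
  heavy[1:10, ] <- 12
  roi <- matrix(0L, 20, 20); roi[1:10, ] <- 1L
  base <- matrix(0L, 20, 20); base[11:20, ] <- 1L
  pair <- ratio_image_pair(heavy, light)
  expect_equal(fold_over_baseline(pair, spot_mask(roi), spot_mask(base)), 3)
  # uniform image: fold 1
  upair <- ratio_image_pair(matrix(4, 20, 20), light)
  expect_equal(fold_over_baseline(upair, spot_mask(roi), spot_mask(base)), 1)
  # reciprocal under swapping roi and baseline
  g <- gen_ratio_image(seed = 2)
  f <- fold_over_baseline(g$pair, g$truth$roi_mask, g$truth$baseline_mask)
  fr <- fold_over_baseline(g$pair, g$truth$baseline_mask, g$truth$roi_mask)
  expect_equal(f * fr, 1, tolerance = 1e-9)
  # generator truth recovered within 5%
  expect_lt(abs(f - 1.5), 0.075)
  expect_error(fold_over_baseline(pair, spot_mask(roi), spot_mask(roi)),
               "disjoint")
})

test_that("overlay picks the per-pixel winner with ties to the ratio image", {
  r <- matrix(c(1, 0, 0, 1), 2, 2)
  f <- matrix(c(0, 1, 1, 0), 2, 2)
  ov <- coin_overlay(r, f)
  expect_equal(ov$source, matrix(c("ratio", "fluorescence",
                                   "fluorescence", "ratio"), 2, 2))
  expect_equal(ov$composite, matrix(1, 2, 2))
  # zero fluorescence: everything sourced from ratio
  expect_true(all(coin_overlay(r, matrix(0, 2, 2))$source == "ratio"))
  # equal images: all-ratio by the tie rule
  expect_true(all(coin_overlay(r, r)$source == "ratio"))
  expect_error(coin_overlay(r, matrix(0, 3, 3)), "shapes")
})

test_that("pH-probe releasable fraction handles release, none, and inversion", {
  expect_equal(releasable_fraction_cypher(100, 40, 120)$fraction, 0.5)
  expect_equal(releasable_fraction_cypher(100, 100, 120)$fraction, 0)
  inv <- releasable_fraction_cypher(40, 100, 120)
  expect_equal(inv$fraction, -0.5)
  expect_true(inv$quality_flag)
  # bleach correction rescales the stimulated reading
  bc <- releasable_fraction_cypher(100, 40, 120, bleach_retention = 0.8)
  expect_equal(bc$fraction, (100 - 50) / 120)
  expect_error(releasable_fraction_cypher(100, 40, 0), "positive")
})

test_that("burst detection: degenerate traces, constructed events, recovery", {
  tt <- seq(0, 100, by = 0.1)
  flat <- fluor_trace(tt, rep(0, length(tt)))
  expect_equal(detect_bursts(flat)$rate, 0)
  # 10 clean kernel events in 100 s: raw rate 0.1 Hz
  onsets <- seq(5, 95, by = 10)
  v <- rep(0, length(tt))
  for (o in onsets) v <- v + ifelse(tt >= o, exp(-(tt - o)), 0)
  v <- v + stats::rnorm(length(tt), 0, 0.01)
  det <- detect_bursts(fluor_trace(tt, v))
  expect_equal(det$raw_rate, 0.1, tolerance = 1e-9)
  expect_equal(length(det$burst_times), 10L)
  expect_error(detect_bursts(fluor_trace(seq(0, 30, 0.1), rep(0, 301))),
               "60 s")
  # generator recovery at the default burst frequency, 20 traces
  rates <- vapply(1:20, function(s) {
    detect_bursts(gen_calcium_syphy_pair(seed = s)$calcium)$rate
  }, numeric(1L))
  expect_lt(abs(mean(rates) - 0.09), 0.2 * 0.09)
})

test_that("burst-rate estimate is unbiased across frequencies", {
  for (fb in c(0.03, 0.09, 0.3)) {
    rates <- vapply(1:20, function(s) {
      g <- gen_calcium_syphy_pair(cfg = list(burst_rate_hz = fb),
                                  seed = 400 + s)
      detect_bursts(g$calcium)$rate
    }, numeric(1L))
    se <- stats::sd(rates) / sqrt(length(rates))
    expect_lt(abs(mean(rates) - fb), 3 * se + 0.01 * fb)
  }
})

test_that("per-burst release fraction recovers the generator ground truth", {
  # constructed full-pool steps give fraction 1
  tt <- seq(0, 120, by = 0.1)
  v <- ifelse(tt >= 50, 1, 0)
  expect_equal(per_burst_release_fraction(50, fluor_trace(tt, v),
                                          pool_amplitude = 1), 1)
  # zero-amplitude trace gives 0
  expect_equal(per_burst_release_fraction(50, fluor_trace(tt, rep(0, length(tt))),
                                          pool_amplitude = 1), 0)
  expect_error(per_burst_release_fraction(numeric(0), fluor_trace(tt, v), 1),
               "no bursts")
  expect_error(per_burst_release_fraction(500, fluor_trace(tt, v), 1), "span")
  # generator: 20 paired traces recover p_b = 0.0675 within 20%
  fr <- vapply(1:20, function(s) {
    g <- gen_calcium_syphy_pair(seed = 600 + s)
    per_burst_release_fraction(g$truth$burst_times, g$syphy,
                               g$truth$pool_amplitude)
  }, numeric(1L))
  expect_lt(abs(mean(fr) - 0.0675), 0.2 * 0.0675)
})

test_that("channel images round-trip through 16-bit TIFF", {
  g <- gen_two_channel_image(cfg = list(img_size = 128L, n_spots = 5L), seed = 3)
  path <- tempfile(fileext = ".tif")
  write_channel_tiff(g$channel1, path)
  back <- read_channel_tiff(path, pixel_size = g$channel1$pixel_size)
  expect_equal(back$pixels, g$channel1$pixels, tolerance = 1e-6)
  tr <- gen_calcium_syphy_pair(cfg = list(duration_s = 100), seed = 1)
  tpath <- tempfile(fileext = ".csv")
  write_trace(tr$calcium, tpath)
  back_tr <- read_trace(tpath)
  expect_equal(back_tr$value, tr$calcium$value, tolerance = 1e-9)
  expect_equal(back_tr$rate, tr$calcium$rate, tolerance = 1e-6)
})
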