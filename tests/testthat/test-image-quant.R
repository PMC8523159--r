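test_that("segmentation finds well-separated nuclei at their true centers", {
  expect_equal(segment_nuclei(matrix(0, 50, 50), 0.1), list())
  expect_error(segment_nuclei(array(0, c(4, 4, 2)), 0.1), class = "mtoc_input_error")

  sc <- render_scene(3, ring_fraction = 0, noise_sd = 0, seed = 12)
  rois <- segment_nuclei(sc$channels$dapi, sc$pixel_size_um)
  expect_length(rois, 3L)
  planted <- do.call(rbind, lapply(sc$truth$nuclei, function(n) n$center_px))
  for (roi in rois) {
    d <- sqrt(min(colSums((t(planted) - roi$centroid)^2)))
    expect_lt(d, 1) # centroid within 1 px of a planted center
  }
})

test_that("touching nuclei merge into one component", {
  img <- matrix(0, 80, 80)
  for (ctr in list(c(40, 30), c(40, 48))) { # discs overlap by 8 px
    d2 <- outer((1:80 - ctr[1])^2, (1:80 - ctr[2])^2, "+")
    img[d2 <= 13^2] <- 100
  }
  rois <- segment_nuclei(img, 0.1, threshold = 50, min_area_um2 = 1)
  expect_length(rois, 1L)
})

test_that("band masks reproduce the analytic annulus and thin-band limit", {
  px <- 0.1
  nuc <- circle_nucleus(c(150, 150), 5, px)
  band <- make_band(nuc, c(300, 300), width_um = 1, pixel_size_um = px)
  area_um2 <- band$n_px * px^2
  expect_lt(abs(area_um2 - pi * (5.5^2 - 4.5^2)) / (pi * (5.5^2 - 4.5^2)), 0.03)
  # thin-band limit: area ~ perimeter x width
  thin <- make_band(nuc, c(300, 300), width_um = 0.3, pixel_size_um = px)
  expect_lt(abs(thin$n_px * px^2 / 0.3 - 2 * pi * 5) / (2 * pi * 5), 0.05)
  # disjoint nuclei give disjoint bands
  nuc2 <- circle_nucleus(c(60, 60), 4, px)
  band2 <- make_band(nuc2, c(300, 300), width_um = 1, pixel_size_um = px)
  expect_false(any(band$mask & band2$mask))
})

test_that("one-sided band alignments sit on the requested side of the outline", {
  px <- 0.1
  nuc <- circle_nucleus(c(100, 100), 4, px)
  outer_b <- make_band(nuc, c(200, 200), 1, px, align = "outer")
  inner_b <- make_band(nuc, c(200, 200), 1, px, align = "inner")
  r_of <- function(mask) {
    idx <- which(mask, arr.ind = TRUE)
    sqrt((idx[, 1] - 100)^2 + (idx[, 2] - 100)^2) * px
  }
  expect_true(all(r_of(outer_b$mask) >= 4 - 2 * px))
  expect_true(all(r_of(inner_b$mask) <= 4 + 2 * px))
  expect_false(any(outer_b$mask & inner_b$mask))
})

test_that("band coverage reads out threshold crossings and angular fraction", {
  px <- 0.1
  nuc <- circle_nucleus(c(100, 100), 4, px)
  band <- make_band(nuc, c(200, 200), 1, px)
  hi <- matrix(100, 200, 200)
  lo <- matrix(1, 200, 200)
  expect_equal(band_coverage(hi, band, 50)$coverage_percent, 100)
  expect_equal(band_coverage(lo, band, 50)$coverage_percent, 0)
  empty <- band
  empty$n_px <- 0L
  expect_error(band_coverage(hi, empty, 50), class = "mtoc_input_error")

  sc <- render_scene(1, ring_fraction = 0.5, noise_sd = 0, seed = 3)
  roi <- segment_nuclei(sc$channels$dapi, sc$pixel_size_um)[[1]]
  b <- make_band(roi, dim(sc$channels$dapi),
    width_um = sc$truth$ring_thickness_um / 2,
    pixel_size_um = sc$pixel_size_um
  )
  cov <- band_coverage(sc$channels$envelope, b, sc$truth$ring_intensity / 2)
  expect_lt(abs(cov$coverage_percent - 50), 2)
})

test_that("coverage is monotone non-increasing in the threshold", {
  sc <- render_scene(1, ring_fraction = 0.6, noise_sd = 5, seed = 7)
  roi <- segment_nuclei(sc$channels$dapi, sc$pixel_size_um)[[1]]
  b <- make_band(roi, dim(sc$channels$dapi),
    width_um = 1,
    pixel_size_um = sc$pixel_size_um
  )
  covs <- vapply(
    c(20, 50, 100, 150, 250),
    function(thr) band_coverage(sc$channels$envelope, b, thr)$coverage_percent,
    numeric(1)
  )
  expect_true(all(diff(covs) <= 0))
})

test_that("rotating the scene by 90 degrees barely changes coverage", {
  sc <- render_scene(2, ring_fraction = 0.5, noise_sd = 2, seed = 15)
  px <- sc$pixel_size_um
  measure <- function(dapi, env) {
    rois <- segment_nuclei(dapi, px)
    sort(vapply(rois, function(r) {
      b <- make_band(r, dim(dapi), width_um = 1, pixel_size_um = px)
      band_coverage(env, b, 150)$coverage_percent
    }, numeric(1)))
  }
  rot90 <- function(m) t(m)[, nrow(m):1]
  c1 <- measure(sc$channels$dapi, sc$channels$envelope)
  c2 <- measure(rot90(sc$channels$dapi), rot90(sc$channels$envelope))
  expect_lt(max(abs(c1 - c2)), 2)
})

test_that("focus detection hits planted centers and separates nearby foci", {
  px <- 0.1
  expect_equal(nrow(detect_foci(matrix(0, 100, 100), px, min_prominence = 10)), 0L)
  sc1 <- render_scene(0,
    foci_spec = data.frame(row_um = 5, col_um = 7, amplitude = 200, sigma_um = 0.25),
    noise_sd = 0, seed = 1, dim_px = c(100, 100)
  )
  hit <- detect_foci(sc1$channels$foci, px, min_prominence = 50)
  expect_equal(nrow(hit), 1L)
  expect_lt(sqrt((hit[1, 1] - 50.5)^2 + (hit[1, 2] - 70.5)^2), 1)
  sc2 <- render_scene(0,
    foci_spec = data.frame(
      row_um = c(5, 5), col_um = c(4, 7),
      amplitude = c(200, 150), sigma_um = 0.25
    ),
    noise_sd = 0, seed = 1, dim_px = c(100, 100)
  )
  expect_equal(nrow(detect_foci(sc2$channels$foci, px, min_prominence = 50)), 2L)
})

test_that("focus ROI mean matches uniform, half-plane and degenerate oracles", {
  px <- 0.1
  u <- matrix(7, 60, 60)
  expect_equal(focus_intensity(u, c(30, 30), 0.5, px)$mean_intensity, 7)
  half <- matrix(rep(c(10, 20), each = 30), 60, 60, byrow = FALSE)
  half[] <- ifelse(col(half) <= 30, 10, 20)
  fi <- focus_intensity(half, c(30, 30.5), 0.5, px)
  expect_lt(abs(fi$mean_intensity - 15), 0.5)
  tiny <- focus_intensity(u, c(30, 30), radius_um = 0.04, pixel_size_um = px)
  expect_equal(tiny$n_px, 1L)
  expect_error(
    focus_intensity(u, c(-50, -50), 0.5, px),
    class = "mtoc_input_error"
  )
})

test_that("radial profiles peak at the envelope and are flat on uniform input", {
  sc <- render_scene(1, ring_fraction = 1, noise_sd = 0, seed = 21)
  px <- sc$pixel_size_um
  roi <- segment_nuclei(sc$channels$dapi, px)[[1]]
  pr <- radial_profiles(sc$channels$envelope, roi, pixel_size_um = px)
  expect_lt(abs(pr$distance_um[which.max(pr$intensity)] - 0.5), 0.2)
  u <- matrix(3, nrow(sc$channels$dapi), ncol(sc$channels$dapi))
  pu <- radial_profiles(u, roi, pixel_size_um = px)
  expect_true(all(abs(pu$intensity - 3) < 1e-9))
  z <- matrix(0, nrow(u), ncol(u))
  pz <- radial_profiles(z, roi, pixel_size_um = px)
  expect_true(all(pz$intensity == 0))
  expect_error(
    radial_profiles(u, roi, shrink_um = 50, pixel_size_um = px),
    class = "mtoc_input_error"
  )
})

test_that("control threshold is the maximal in-band control intensity", {
  m <- matrix(FALSE, 10, 10)
  m[5, 5:7] <- TRUE
  ctrl <- matrix(10, 10, 10)
  ctrl[5, 6] <- 80
  expect_equal(control_threshold(list(ctrl), m), 80)
  expect_error(control_threshold(list(), m), class = "mtoc_input_error")
  # an experimental band with nothing above the control max scores negative
  res <- tibble::tibble(coverage_percent = 0)
  calls <- classify_positive(res)
  expect_false(calls$calls$positive[1])
})

test_that("positivity calls aggregate to per-replicate percentages", {
  res <- tibble::tibble(
    coverage_percent = c(rep(100, 3), rep(0, 2)),
    replicate = c(1, 1, 2, 1, 2)
  )
  out <- classify_positive(res)
  expect_equal(out$per_replicate$percent_positive, c(200 / 3, 50))
  all_hi <- tibble::tibble(coverage_percent = rep(100, 4))
  expect_equal(classify_positive(all_hi)$per_replicate$percent_positive, 100)
  expect_error(
    classify_positive(tibble::tibble(coverage_percent = numeric())),
    class = "mtoc_input_error"
  )
  planted <- tibble::tibble(coverage_percent = c(rep(95, 20), rep(2, 80)))
  expect_equal(classify_positive(planted)$per_replicate$percent_positive, 20)
})
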