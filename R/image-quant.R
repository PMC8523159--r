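#' Segment nuclei from a DAPI channel
#'
#' Thresholds the DAPI image (fixed value or Otsu when `threshold = "auto"`),
#' fills holes, labels connected components, discards components smaller than
#' `min_area_um2` and traces each component's outer boundary as a closed
#' pixel-chain polygon. Touching nuclei are returned as a single merged
#' component (no watershed splitting); callers can exclude merged objects via
#' the reported area and eccentricity.
#'
#' @param dapi 2-D numeric matrix.
#' @param pixel_size_um Pixel size in um.
#' @param threshold Intensity threshold, or `"auto"` for Otsu.
#' @param min_area_um2 Minimum nucleus area in um^2 (default 20).
#' @return List of nucleus ROIs, each a list with `label`, `outline`
#'   (n x 2 matrix of (row, col) pixel coordinates, closed chain), `area_px`,
#'   `area_um2`, `centroid` (row, col), `eccentricity`.
#' @export
segment_nuclei <- function(dapi, pixel_size_um, threshold = "auto",
                           min_area_um2 = 20) {
  if (!is.matrix(dapi)) {
    stop_mtoc("dapi must be a 2-D matrix", class = "mtoc_input_error")
  }
  thr <- resolve_threshold(dapi, threshold)
  mask <- dapi > thr
  if (!any(mask)) {
    return(list())
  }
  lab <- EBImage::bwlabel(EBImage::fillHull(mask * 1))
  min_px <- min_area_um2 / pixel_size_um^2
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_px)
  if (length(keep) == 0L) {
    return(list())
  }
  contours <- EBImage::ocontour(lab)
  rois <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    i <- keep[k]
    outline <- contours[[i]] + 1 # ocontour is 0-based
    px <- which(lab == i, arr.ind = TRUE)
    ctr <- colMeans(px)
    cen <- sweep(px, 2, ctr)
    cv <- crossprod(cen) / nrow(cen)
    ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
      decreasing = TRUE
    )
    ecc <- if (ev[1] > 0) sqrt(1 - ev[2] / ev[1]) else 0
    rois[[k]] <- list(
      label = k,
      outline = outline,
      area_px = areas[i],
      area_um2 = areas[i] * pixel_size_um^2,
      centroid = ctr,
      eccentricity = ecc
    )
  }
  rois
}

resolve_threshold <- function(img, threshold) {
  if (identical(threshold, "auto")) {
    rng <- range(img)
    if (diff(rng) == 0) {
      return(rng[1])
    }
    norm <- (img - rng[1]) / diff(rng)
    EBImage::otsu(EBImage::Image(norm), range = c(0, 1)) * diff(rng) + rng[1]
  } else {
    stopifnot(is.numeric(threshold), length(threshold) == 1L)
    threshold
  }
}

# Minimum distance (um) from each of a set of pixel centers to a closed
# polygon outline, by running minimum over point-to-segment distances.
dist_to_outline_um <- function(points, outline, pixel_size_um) {
  p1 <- outline
  p2 <- outline[c(2:nrow(outline), 1L), , drop = FALSE]
  best <- rep(Inf, nrow(points))
  for (s in seq_len(nrow(p1))) {
    d <- c(p2[s, 1] - p1[s, 1], p2[s, 2] - p1[s, 2])
    len2 <- sum(d^2)
    wy <- points[, 1] - p1[s, 1]
    wx <- points[, 2] - p1[s, 2]
    t <- if (len2 > 0) pmin(pmax((wy * d[1] + wx * d[2]) / len2, 0), 1) else 0
    dy <- wy - t * d[1]
    dx <- wx - t * d[2]
    best <- pmin(best, dy * dy + dx * dx)
  }
  sqrt(best) * pixel_size_um
}

#' Build a band of given width around a nucleus outline
#'
#' The band is the set of pixels whose centre lies within `width_um / 2` of
#' the nucleus outline (symmetric straddle, the default reading of a
#' "1-um-wide band" around an outline; see `align`). Distances are exact
#' point-to-segment distances to the closed outline polygon, in um. When the
#' nucleus is smaller than the half-width the inner edge simply reaches the
#' centroid and the band fills the nucleus.
#'
#' @param nucleus A nucleus ROI from [segment_nuclei()] (or any list with an
#'   `outline` matrix).
#' @param dim_px Image dimensions `c(rows, cols)`.
#' @param width_um Band width in um (default 1.0, i.e. +/- 0.5 um about the
#'   outline).
#' @param pixel_size_um Pixel size in um.
#' @param align `"center"` (straddle, default), `"outer"` (band outside the
#'   outline) or `"inner"` (inside).
#' @return A band ROI: list with `parent` (nucleus label), `mask` (logical
#'   matrix of `dim_px`), `n_px`, `width_um`, `align`.
#' @export
make_band <- function(nucleus, dim_px, width_um = 1.0, pixel_size_um,
                      align = c("center", "outer", "inner")) {
  stopifnot(width_um > 0)
  align <- match.arg(align)
  outline <- nucleus$outline
  half_px <- ceiling((width_um / 2) / pixel_size_um) + 2L
  rr <- max(1, min(outline[, 1]) - half_px):min(dim_px[1], max(outline[, 1]) + half_px)
  cc <- max(1, min(outline[, 2]) - half_px):min(dim_px[2], max(outline[, 2]) + half_px)
  pts <- cbind(
    rep(rr, times = length(cc)),
    rep(cc, each = length(rr))
  )
  d <- dist_to_outline_um(pts, outline, pixel_size_um)
  if (align == "center") {
    inside <- d <= width_um / 2
  } else {
    # one-sided bands: full width on the chosen side of the outline
    inpoly <- points_in_polygon(pts, outline)
    inside <- d <= width_um & (if (align == "outer") !inpoly else inpoly)
  }
  mask <- matrix(FALSE, dim_px[1], dim_px[2])
  mask[pts[inside, , drop = FALSE]] <- TRUE
  list(
    parent = nucleus$label %||% NA_integer_, mask = mask,
    n_px = sum(inside), width_um = width_um, align = align
  )
}

# Even-odd ray-crossing test, vectorized over points.
points_in_polygon <- function(pts, poly) {
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1L))
  inside <- rep(FALSE, nrow(pts))
  px <- pts[, 2]
  py <- pts[, 1]
  for (k in seq_len(n)) {
    yi <- poly[k, 1]
    xi <- poly[k, 2]
    yj <- poly[j[k], 1]
    xj <- poly[j[k], 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses & (yj != yi))
  }
  inside
}

#' Marker coverage inside a nuclear-envelope band
#'
#' The percentage of band pixels whose marker intensity exceeds the
#' threshold, after binarizing the marker channel — the per-nucleus coverage
#' statistic used to quantify nuclear-envelope recruitment of MTOC proteins.
#'
#' @param marker 2-D numeric matrix (same dims as the band mask).
#' @param band Band ROI from [make_band()].
#' @param threshold Intensity threshold, or `"auto"` for Otsu on the marker
#'   image (note the reference protocol used manually chosen thresholds;
#'   explicit values are preferred and always recorded in the result).
#' @return List with `parent`, `coverage_percent` in `[0, 100]`,
#'   `threshold_used`, `positive_px`, `total_px`.
#' @export
band_coverage <- function(marker, band, threshold) {
  if (band$n_px == 0L) {
    stop_mtoc("band mask is empty", class = "mtoc_input_error")
  }
  thr <- resolve_threshold(marker, threshold)
  vals <- marker[band$mask]
  pos <- sum(vals > thr)
  list(
    parent = band$parent,
    coverage_percent = 100 * pos / length(vals),
    threshold_used = thr,
    positive_px = pos,
    total_px = length(vals)
  )
}

#' Detect centrosomal foci as local intensity maxima
#'
#' Finds pixels that are local maxima within a `min_distance_um`
#' neighbourhood and rise at least `min_prominence` above the image
#' background (median intensity), then applies greedy non-maximum
#' suppression so returned foci are at least `min_distance_um` apart.
#'
#' @param channel 2-D numeric matrix (e.g. gamma-tubulin).
#' @param pixel_size_um Pixel size in um.
#' @param min_distance_um Minimum separation between foci (default 1.0).
#' @param min_prominence Required intensity rise above background.
#' @return Integer matrix with columns `row`, `col` (possibly 0 rows),
#'   ordered by decreasing intensity.
#' @export
detect_foci <- function(channel, pixel_size_um, min_distance_um = 1.0,
                        min_prominence) {
  r_px <- max(1L, round(min_distance_um / pixel_size_um))
  brush <- EBImage::makeBrush(2L * r_px + 1L, shape = "disc")
  dil <- as.matrix(EBImage::dilate(channel, brush))
  bg <- median(channel)
  cand <- which(channel == dil & channel >= bg + min_prominence, arr.ind = TRUE)
  if (nrow(cand) == 0L) {
    return(cbind(row = integer(), col = integer()))
  }
  ord <- order(channel[cand], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  keep <- logical(nrow(cand))
  min_d2 <- (min_distance_um / pixel_size_um)^2
  for (i in seq_len(nrow(cand))) {
    sel <- which(keep)
    if (length(sel) == 0L ||
      all((cand[sel, 1] - cand[i, 1])^2 + (cand[sel, 2] - cand[i, 2])^2 >= min_d2)) {
      keep[i] <- TRUE
    }
  }
  out <- cand[keep, , drop = FALSE]
  colnames(out) <- c("row", "col")
  out
}

#' Mean intensity in a circular ROI around a focus
#'
#' Averages the channel over the disc of radius `radius_um` centred on
#' `center` (1-um-diameter discs at detected maxima by default, matching the
#' centrosome-intensity protocol).
#'
#' @param channel 2-D numeric matrix.
#' @param center Pixel coordinates `c(row, col)`.
#' @param radius_um Disc radius in um (default 0.5).
#' @param pixel_size_um Pixel size in um.
#' @return List with `center`, `radius_um`, `mean_intensity`, `n_px`.
#' @export
focus_intensity <- function(channel, center, radius_um = 0.5, pixel_size_um) {
  stopifnot(radius_um > 0)
  mask <- disc_mask(dim(channel), center, radius_um, pixel_size_um)
  if (sum(mask) == 0L) {
    stop_mtoc("focus ROI lies fully outside the image",
      class = "mtoc_input_error"
    )
  }
  list(
    center = center, radius_um = radius_um,
    mean_intensity = mean(channel[mask]), n_px = sum(mask)
  )
}

disc_mask <- function(dim_px, center, radius_um, pixel_size_um) {
  r_px <- radius_um / pixel_size_um
  rr <- max(1, floor(center[1] - r_px)):min(dim_px[1], ceiling(center[1] + r_px))
  cc <- max(1, floor(center[2] - r_px)):min(dim_px[2], ceiling(center[2] + r_px))
  mask <- matrix(FALSE, dim_px[1], dim_px[2])
  if (length(rr) == 0L || length(cc) == 0L) {
    return(mask)
  }
  d2 <- outer((rr - center[1])^2, (cc - center[2])^2, "+")
  sub <- d2 <= r_px^2
  mask[as.matrix(expand.grid(rr, cc))[as.vector(sub), , drop = FALSE]] <- TRUE
  mask
}

#' Mean radial intensity profile perpendicular to a nucleus outline
#'
#' Shrinks the nucleus outline inward by `shrink_um` (the reference protocol
#' decreases the ROI diameter by 1 um, i.e. 0.5 um in radius), then casts
#' `n_rays` rays outward along the local outward normals, sampling the
#' channel by bilinear interpolation at `pixel_size_um` steps up to
#' `length_um`, and averages the rays pointwise. For a marker concentrated at
#' the nuclear envelope the mean profile peaks near `shrink_um` from the
#' start points.
#'
#' @param channel 2-D numeric matrix.
#' @param nucleus Nucleus ROI from [segment_nuclei()].
#' @param shrink_um Inward offset of the ray start points (default 0.5).
#' @param length_um Ray length in um (default 3.0).
#' @param n_rays Number of rays, equally spaced along the outline arc length
#'   (default 72).
#' @param pixel_size_um Pixel size in um.
#' @return Tibble with columns `distance_um` and `intensity` (mean over
#'   rays; rays leaving the image contribute only in-bounds samples).
#' @export
radial_profiles <- function(channel, nucleus, shrink_um = 0.5, length_um = 3.0,
                            n_rays = 72, pixel_size_um) {
  eq_radius <- sqrt(nucleus$area_px / pi) * pixel_size_um
  if (eq_radius <= shrink_um) {
    stop_mtoc(
      "cannot shrink outline by ", shrink_um, " um: nucleus equivalent ",
      "radius is ", round(eq_radius, 2), " um", class = "mtoc_input_error"
    )
  }
  ol <- resample_outline(nucleus$outline, n_rays)
  nrm <- outline_normals(ol, nucleus$centroid)
  starts <- ol - nrm * (shrink_um / pixel_size_um)
  t_um <- seq(0, length_um, by = pixel_size_um)
  prof <- matrix(NA_real_, length(t_um), n_rays)
  for (k in seq_len(n_rays)) {
    pos_r <- starts[k, 1] + nrm[k, 1] * t_um / pixel_size_um
    pos_c <- starts[k, 2] + nrm[k, 2] * t_um / pixel_size_um
    prof[, k] <- bilinear(channel, pos_r, pos_c)
  }
  tibble::tibble(
    distance_um = t_um,
    intensity = rowMeans(prof, na.rm = TRUE)
  )
}

# Resample a closed pixel-chain outline to n points equally spaced in arc
# length.
resample_outline <- function(outline, n) {
  closed <- rbind(outline, outline[1L, , drop = FALSE])
  seg <- sqrt(rowSums(diff(closed)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  target <- seq(0, total, length.out = n + 1L)[-(n + 1L)]
  i <- findInterval(target, s, rightmost.closed = TRUE)
  frac <- (target - s[i]) / pmax(seg[i], .Machine$double.eps)
  closed[i, , drop = FALSE] + frac * (closed[i + 1L, , drop = FALSE] - closed[i, , drop = FALSE])
}

# Unit outward normals from central differences along the resampled outline,
# oriented away from the centroid.
outline_normals <- function(pts, centroid) {
  n <- nrow(pts)
  nxt <- pts[c(2:n, 1L), , drop = FALSE]
  prv <- pts[c(n, 1:(n - 1L)), , drop = FALSE]
  tang <- nxt - prv
  nrm <- cbind(-tang[, 2], tang[, 1])
  len <- sqrt(rowSums(nrm^2))
  nrm <- nrm / pmax(len, .Machine$double.eps)
  out <- pts - matrix(centroid, n, 2, byrow = TRUE)
  flip <- rowSums(nrm * out) < 0
  nrm[flip, ] <- -nrm[flip, ]
  nrm
}

bilinear <- function(img, r, c) {
  ny <- nrow(img)
  nx <- ncol(img)
  r0 <- floor(r)
  c0 <- floor(c)
  fr <- r - r0
  fc <- c - c0
  ok <- r0 >= 1 & c0 >= 1 & r0 + 1 <= ny & c0 + 1 <= nx
  out <- rep(NA_real_, length(r))
  if (any(ok)) {
    i00 <- cbind(r0[ok], c0[ok])
    i10 <- cbind(r0[ok] + 1, c0[ok])
    i01 <- cbind(r0[ok], c0[ok] + 1)
    i11 <- cbind(r0[ok] + 1, c0[ok] + 1)
    out[ok] <- img[i00] * (1 - fr[ok]) * (1 - fc[ok]) +
      img[i10] * fr[ok] * (1 - fc[ok]) +
      img[i01] * (1 - fr[ok]) * fc[ok] +
      img[i11] * fr[ok] * fc[ok]
  }
  out
}

#' Control-derived positivity threshold
#'
#' Returns the maximal in-band marker intensity observed across control
#' images (e.g. undifferentiated cultures, where only residual marker signal
#' is present). Experimental nuclei are then scored against this threshold,
#' implementing threshold-by-control-subtraction.
#'
#' @param control_images List of 2-D matrices.
#' @param band_masks List of logical band masks, parallel to
#'   `control_images`, or a single mask recycled for all.
#' @return Intensity threshold (numeric scalar).
#' @export
control_threshold <- function(control_images, band_masks) {
  if (length(control_images) == 0L) {
    stop_mtoc("no control images supplied", class = "mtoc_input_error")
  }
  if (!is.list(band_masks)) band_masks <- list(band_masks)
  band_masks <- rep_len(band_masks, length(control_images))
  vals <- unlist(Map(
    function(img, m) img[m],
    control_images, band_masks
  ))
  if (length(vals) == 0L) {
    stop_mtoc("control band masks contain no pixels",
      class = "mtoc_input_error"
    )
  }
  max(vals)
}

#' Call marker-positive nuclei and summarize per replicate
#'
#' A nucleus is positive when its band coverage reaches
#' `rule$min_coverage` percent (default 10). Returns the per-nucleus calls
#' and the percentage of positive nuclei per replicate — the per-replicate
#' statistic plotted as replicate points with mean and SD in the screen's
#' figures.
#'
#' @param results Tibble/data frame with a `coverage_percent` column and
#'   optionally `replicate` (defaults to a single replicate).
#' @param rule List with `min_coverage` (percent, default 10).
#' @return List with `calls` (input plus logical `positive`) and
#'   `per_replicate` (tibble: `replicate`, `n`, `n_positive`,
#'   `percent_positive`).
#' @export
classify_positive <- function(results, rule = list(min_coverage = 10)) {
  results <- tibble::as_tibble(results)
  if (nrow(results) == 0L) {
    stop_mtoc("no nuclei to classify", class = "mtoc_input_error")
  }
  min_cov <- rule$min_coverage %||% 10
  results$positive <- results$coverage_percent >= min_cov
  if (!"replicate" %in% names(results)) results$replicate <- 1L
  per_rep <- dplyr::summarise(
    dplyr::group_by(results, .data$replicate),
    n = dplyr::n(),
    n_positive = sum(.data$positive),
    percent_positive = 100 * mean(.data$positive),
    .groups = "drop"
  )
  list(calls = results, per_replicate = per_rep)
}
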