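# Shared helpers for building tiny in-code fixtures and brute-force oracles.

# Closed polygon approximating a circle, in (row, col) pixel coordinates.
circle_outline <- function(center_px, radius_um, pixel_size_um, n = 720) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(
    center_px[1] + (radius_um / pixel_size_um) * sin(th),
    center_px[2] + (radius_um / pixel_size_um) * cos(th)
  )
}

# Nucleus-ROI stand-in built from an analytic circle (no segmentation).
circle_nucleus <- function(center_px, radius_um, pixel_size_um) {
  list(
    label = 1L,
    outline = circle_outline(center_px, radius_um, pixel_size_um),
    area_px = pi * (radius_um / pixel_size_um)^2,
    centroid = center_px
  )
}

# Literal per-pixel, per-segment distance oracle for band masks.
oracle_band_mask <- function(outline, dim_px, width_um, pixel_size_um) {
  mask <- matrix(FALSE, dim_px[1], dim_px[2])
  nseg <- nrow(outline)
  for (r in seq_len(dim_px[1])) {
    for (c in seq_len(dim_px[2])) {
      best <- Inf
      for (s in seq_len(nseg)) {
        p1 <- outline[s, ]
        p2 <- outline[if (s == nseg) 1L else s + 1L, ]
        d <- p2 - p1
        len2 <- sum(d^2)
        t <- if (len2 > 0) min(max(sum((c(r, c) - p1) * d) / len2, 0), 1) else 0
        best <- min(best, sum((c(r, c) - p1 - t * d)^2))
      }
      if (sqrt(best) * pixel_size_um <= width_um / 2) mask[r, c] <- TRUE
    }
  }
  mask
}

# Brute-force promoter assignment: double loop over (peak, gene) pairs.
oracle_bound_genes <- function(peaks, genes, max_tss_distance, min_neg_log10_p) {
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  hits <- character()
  for (i in seq_len(nrow(peaks))) {
    if (peaks$neg_log10_p[i] <= min_neg_log10_p) next
    anchor <- if (peaks$summit_offset[i] >= 0) {
      peaks$start[i] + peaks$summit_offset[i]
    } else {
      floor((peaks$start[i] + peaks$end[i]) / 2)
    }
    for (j in seq_len(nrow(genes))) {
      if (peaks$chrom[i] == genes$chrom[j] &&
        abs(anchor - genes$tss[j]) <= max_tss_distance) {
        hits <- c(hits, genes$gene_id[j])
      }
    }
  }
  sort(unique(hits))
}

# Random peak fixture (not via the planted generator) for oracle comparisons.
random_peak_fixture <- function(n_peaks, n_genes, seed) {
  set.seed(seed)
  genes <- tibble::tibble(
    gene_id = sprintf("r%03d", seq_len(n_genes)),
    chrom = sample(c("chr1", "chr2"), n_genes, replace = TRUE),
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    start = round(runif(n_genes, 1e4, 5e6))
  )
  genes$end <- genes$start + round(runif(n_genes, 1e3, 1e4))
  peaks <- tibble::tibble(
    chrom = sample(c("chr1", "chr2", "chrUn"), n_peaks, replace = TRUE),
    start = round(runif(n_peaks, 1e4, 5e6)),
    name = sprintf("p%04d", seq_len(n_peaks)),
    score = 0,
    strand = ".",
    signal = runif(n_peaks, 1, 10),
    neg_log10_p = runif(n_peaks, 2, 9),
    neg_log10_q = runif(n_peaks, 1, 8)
  )
  peaks$end <- peaks$start + round(runif(n_peaks, 200, 800))
  width <- peaks$end - peaks$start
  peaks$summit_offset <- ifelse(
    runif(n_peaks) < 0.2, -1, floor(runif(n_peaks) * width)
  )
  list(peaks = peaks[, c(
    "chrom", "start", "end", "name", "score", "strand",
    "signal", "neg_log10_p", "neg_log10_q", "summit_offset"
  )], genes = genes)
}
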