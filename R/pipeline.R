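#' Validate a run configuration
#'
#' Checks that all required keys are present and that every referenced input
#' path exists; errors list all offending keys at once.
#'
#' @param config Named list or path to a YAML file.
#' @param required Character vector of required key names.
#' @param paths Keys whose values (possibly named vectors/lists) must be
#'   existing file paths.
#' @return The config as a named list, invisibly on success.
#' @export
validate_config <- function(config, required = character(), paths = character()) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  missing <- setdiff(required, names(config))
  bad_paths <- character()
  for (key in intersect(paths, names(config))) {
    p <- unlist(config[[key]])
    bad <- p[!file.exists(p)]
    if (length(bad) > 0L) {
      bad_paths <- c(bad_paths, paste0(key, ": ", bad))
    }
  }
  if (length(missing) > 0L || length(bad_paths) > 0L) {
    stop_mtoc(
      "invalid configuration",
      if (length(missing)) paste0(
        "; missing key(s): ",
        paste(missing, collapse = ", ")
      ) else "",
      if (length(bad_paths)) paste0(
        "; missing input path(s): ",
        paste(bad_paths, collapse = "; ")
      ) else "",
      class = "mtoc_config_error"
    )
  }
  invisible(config)
}

write_provenance <- function(out_dir, config, extra = list()) {
  prov <- c(
    list(
      package = "mtocscreen",
      version = as.character(utils::packageVersion("mtocscreen")),
      r_version = R.version.string,
      timestamp = format(Sys.time(), tz = "UTC"),
      config = config
    ),
    extra
  )
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
    auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE
  )
}

#' Run the candidate-gene screen from a configuration
#'
#' Reads the gene models, per-timepoint narrowPeak files, DE table,
#' time-course table and GO map named in the config, runs [run_cascade()]
#' and writes a JSON report, per-stage gene lists and a provenance record to
#' `config$out_dir`.
#'
#' @param config Named list or YAML path with keys `genes`, `peaks` (named
#'   map label -> narrowPeak path), `de`, `time_courses`, `go`, `out_dir`,
#'   and optionally `params` (see [run_cascade()]).
#' @return The `CascadeReport`, invisibly.
#' @export
run_screen <- function(config) {
  config <- validate_config(config,
    required = c("genes", "peaks", "de", "time_courses", "go", "out_dir"),
    paths = c("genes", "peaks", "de", "time_courses", "go")
  )
  genes <- read_gene_models(config$genes)
  de <- tibble::as_tibble(read.delim(config$de))
  tc <- tibble::as_tibble(read.delim(config$time_courses))
  go <- tibble::as_tibble(read.delim(config$go))
  peak_files <- unlist(config$peaks)
  report <- run_cascade(peak_files, genes, de, tc, go,
    params = config$params %||% list()
  )
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(
      counts = as.list(report$counts),
      by_timepoint = as.list(report$by_timepoint),
      params = report$params
    ),
    file.path(out, "cascade_report.json"),
    auto_unbox = TRUE, digits = NA
  )
  for (stage in names(report$genes)) {
    writeLines(report$genes[[stage]], file.path(out, paste0(stage, "_genes.txt")))
  }
  write_provenance(out, config)
  invisible(report)
}

#' Run image quantification from a configuration
#'
#' For each image prefix in the config, reads the multi-page TIFF and its
#' sidecar, segments nuclei in the DAPI channel, measures band coverage of
#' the marker channel per nucleus, detects foci in the focus channel and
#' measures their ROI intensities, and writes per-nucleus and per-focus CSV
#' tables plus provenance.
#'
#' @param config Named list or YAML path with keys `images` (vector of
#'   prefixes accepted by [read_labeled_image()]), `out_dir`, and optional
#'   `channels` (names for dapi/marker/foci; defaults `dapi`, `envelope`,
#'   `foci`), `threshold` (marker threshold or `"auto"`), `dapi_threshold`,
#'   `band_width_um` (default 1), `min_coverage` (default 10),
#'   `min_prominence` (default 50), `min_distance_um` (default 1).
#' @return List with `coverage` and `foci` tibbles, invisibly.
#' @export
run_quant <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  config <- validate_config(config, required = c("images", "out_dir"))
  ch <- modifyList(
    list(dapi = "dapi", marker = "envelope", foci = "foci"),
    config$channels %||% list()
  )
  thr <- config$threshold %||% "auto"
  dapi_thr <- config$dapi_threshold %||% "auto"
  bw <- config$band_width_um %||% 1.0
  cov_rows <- list()
  foci_rows <- list()
  for (prefix in config$images) {
    img <- read_labeled_image(prefix)
    px <- img$pixel_size_um
    nuclei <- segment_nuclei(img$channels[[ch$dapi]], px, threshold = dapi_thr)
    for (nuc in nuclei) {
      band <- make_band(nuc, dim(img$channels[[ch$dapi]]),
        width_um = bw,
        pixel_size_um = px
      )
      cv <- band_coverage(img$channels[[ch$marker]], band, thr)
      cov_rows[[length(cov_rows) + 1L]] <- tibble::tibble(
        image = prefix, nucleus = nuc$label,
        coverage_percent = cv$coverage_percent,
        threshold_used = cv$threshold_used,
        positive_px = cv$positive_px, total_px = cv$total_px
      )
    }
    if (!is.null(img$channels[[ch$foci]])) {
      pts <- detect_foci(img$channels[[ch$foci]], px,
        min_distance_um = config$min_distance_um %||% 1.0,
        min_prominence = config$min_prominence %||% 50
      )
      for (i in seq_len(nrow(pts))) {
        fi <- focus_intensity(img$channels[[ch$foci]], pts[i, ],
          pixel_size_um = px
        )
        foci_rows[[length(foci_rows) + 1L]] <- tibble::tibble(
          image = prefix, focus = i,
          row = pts[i, 1], col = pts[i, 2],
          mean_intensity = fi$mean_intensity, n_px = fi$n_px
        )
      }
    }
  }
  coverage <- dplyr::bind_rows(cov_rows)
  foci <- dplyr::bind_rows(foci_rows)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(coverage, file.path(out, "coverage.csv"), row.names = FALSE)
  utils::write.csv(foci, file.path(out, "foci.csv"), row.names = FALSE)
  if (nrow(coverage) > 0L) {
    calls <- classify_positive(coverage,
      rule = list(min_coverage = config$min_coverage %||% 10)
    )
    utils::write.csv(calls$per_replicate, file.path(out, "percent_positive.csv"),
      row.names = FALSE
    )
  }
  write_provenance(out, config)
  invisible(list(coverage = coverage, foci = foci))
}

#' End-to-end synthetic round trip with planted-truth verification
#'
#' Generates a genomics fixture with a planted candidate cascade
#' (200 genes; 30 persistently promoter-bound; 40 RNA-seq-upregulated with
#' an intersection of 12; 7 heart-course-upregulated; 2 GO-matched), runs
#' the full screen from the written files, and checks the recovered counts
#' and gene lists against the planted truth. Also renders a small imaging
#' scene, round-trips it through TIFF, and checks that segmentation recovers
#' the planted nuclei and that band coverage ranks the planted ring
#' fractions correctly. Errors (so the CLI exits non-zero) on any mismatch.
#'
#' @param seed Integer seed; the whole demo is deterministic given it.
#' @param dir Working directory for fixture files (default a fresh tempdir
#'   subdirectory).
#' @return List with `cascade` (the report), `truth`, `imaging`
#'   (per-nucleus coverage vs planted fraction) and `ok = TRUE`.
#' @export
run_demo <- function(seed = 7, dir = file.path(tempdir(), paste0("mtoc_demo_", seed))) {
  fix <- make_screen_fixture(dir, seed = seed)
  report <- run_screen(list(
    genes = unname(fix$files["genes"]),
    peaks = as.list(fix$files[c("myoblast", "24h", "60h", "7d")]),
    de = unname(fix$files["de"]),
    time_courses = unname(fix$files["time_courses"]),
    go = unname(fix$files["go"]),
    out_dir = file.path(dir, "screen_out"),
    params = list(seed = seed)
  ))
  checks <- c(
    persistent = identical(report$genes$persistent, fix$truth$persistent),
    rnaseq_up = identical(report$genes$rnaseq_up, fix$truth$upregulated_rnaseq),
    intersection = identical(report$genes$intersection, fix$truth$intersection),
    heart_up = identical(report$genes$heart_up, fix$truth$upregulated_heart),
    candidates = identical(report$genes$go_matched, fix$truth$expected_candidates)
  )
  if (!all(checks)) {
    stop_mtoc(
      "demo cascade mismatch at stage(s): ",
      paste(names(checks)[!checks], collapse = ", "),
      class = "mtoc_demo_error"
    )
  }
  scene <- render_scene(
    n_nuclei = 4, ring_fraction = c(0, 1, 0.5, 0.75),
    foci_spec = 3, noise_sd = 0, seed = seed, dim_px = c(300, 300)
  )
  prefix <- file.path(dir, "demo_scene")
  write_labeled_image(scene, prefix)
  img <- read_labeled_image(prefix)
  nuclei <- segment_nuclei(img$channels$dapi, img$pixel_size_um)
  if (length(nuclei) != 4L) {
    stop_mtoc("demo imaging mismatch: expected 4 nuclei, segmented ",
      length(nuclei),
      class = "mtoc_demo_error"
    )
  }
  # match segmented nuclei to planted ones by centroid distance
  planted <- do.call(rbind, lapply(img$truth$nuclei, function(n) n$center_px))
  cov <- vapply(nuclei, function(nuc) {
    # band half as wide as the planted ring: stays radially inside the ring
    # even with the segmented outline's sub-pixel inward bias, so coverage
    # reads out angular fraction alone
    band <- make_band(nuc, dim(img$channels$dapi),
      width_um = img$truth$ring_thickness_um / 2,
      pixel_size_um = img$pixel_size_um
    )
    band_coverage(img$channels$envelope, band,
      threshold = img$truth$ring_intensity / 2
    )$coverage_percent
  }, numeric(1))
  idx <- vapply(nuclei, function(nuc) {
    which.min(colSums((t(planted) - nuc$centroid)^2))
  }, integer(1))
  frac <- unlist(img$truth$ring_fraction)[idx]
  if (any(abs(cov - 100 * frac) > 5)) {
    stop_mtoc("demo imaging mismatch: band coverage deviates from planted ",
      "ring fractions",
      class = "mtoc_demo_error"
    )
  }
  list(
    cascade = report,
    truth = fix$truth,
    imaging = tibble::tibble(
      nucleus = vapply(nuclei, `[[`, integer(1), "label"),
      planted_fraction = frac, coverage_percent = cov
    ),
    ok = TRUE
  )
}
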