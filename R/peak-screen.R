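#' Parse an ENCODE narrowPeak file
#'
#' Reads a BED6+4 narrowPeak file into a tibble with one row per peak.
#' Track definition lines and `#` comment lines are skipped. Coordinates are
#' kept 0-based half-open as in the file; column 8 is the peak significance as
#' -log10(p) and column 10 the summit offset relative to `start` (-1 when the
#' caller reported no point source).
#'
#' @param path Path to a narrowPeak file.
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`, `signal`, `neg_log10_p`, `neg_log10_q`, `summit_offset`.
#' @examples
#' f <- tempfile(fileext = ".narrowPeak")
#' writeLines("chr1\t100\t600\tp1\t500\t.\t8.1\t6.2\t5.3\t250", f)
#' parse_narrowpeak(f)
#' @export
parse_narrowpeak <- function(path) {
  if (!file.exists(path)) {
    stop_mtoc("narrowPeak file not found: ", path, class = "mtoc_io_error")
  }
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  if (!any(keep)) {
    return(empty_peaks())
  }
  idx <- which(keep)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 10L)) {
    bad <- idx[which(nf < 10L)[1L]]
    stop_mtoc(
      "narrowPeak format error at line ", bad, ": expected >= 10 tab-separated ",
      "columns, found ", nf[which(nf < 10L)[1L]],
      class = "mtoc_format_error"
    )
  }
  m <- do.call(rbind, lapply(fields, function(f) f[1:10]))
  num <- function(col, what) {
    v <- suppressWarnings(as.numeric(m[, col]))
    if (anyNA(v)) {
      bad <- idx[which(is.na(v))[1L]]
      stop_mtoc(
        "narrowPeak format error at line ", bad, ": non-numeric ", what,
        class = "mtoc_format_error"
      )
    }
    v
  }
  peaks <- tibble::tibble(
    chrom = m[, 1L],
    start = num(2L, "start coordinate"),
    end = num(3L, "end coordinate"),
    name = m[, 4L],
    score = num(5L, "score"),
    strand = m[, 6L],
    signal = num(7L, "signal value"),
    neg_log10_p = num(8L, "-log10 p-value"),
    neg_log10_q = num(9L, "-log10 q-value"),
    summit_offset = num(10L, "summit offset")
  )
  bad <- peaks$start >= peaks$end
  if (any(bad)) {
    stop_mtoc(
      "narrowPeak format error at line ", idx[which(bad)[1L]],
      ": start must be < end", class = "mtoc_format_error"
    )
  }
  peaks
}

empty_peaks <- function() {
  tibble::tibble(
    chrom = character(), start = numeric(), end = numeric(),
    name = character(), score = numeric(), strand = character(),
    signal = numeric(), neg_log10_p = numeric(), neg_log10_q = numeric(),
    summit_offset = numeric()
  )
}

#' Anchor position of a peak
#'
#' The single base-pair position used for promoter-distance tests: the summit
#' (`start + summit_offset`) when the caller reported one, otherwise the
#' interval midpoint `floor((start + end) / 2)`.
#'
#' @param peaks A peak tibble as returned by [parse_narrowpeak()].
#' @return Numeric vector of anchor positions, one per peak.
#' @export
peak_anchor <- function(peaks) {
  ifelse(peaks$summit_offset >= 0,
    peaks$start + peaks$summit_offset,
    floor((peaks$start + peaks$end) / 2)
  )
}

#' Genes with a significant peak near their transcription start site
#'
#' A gene is promoter-bound when at least one peak on the same chromosome has
#' `neg_log10_p > min_neg_log10_p` (encoding p < 10^-min_neg_log10_p, strict)
#' and its anchor lies within `max_tss_distance` base pairs of the gene TSS
#' (inclusive bound). The TSS is strand-aware: `start` for `+` genes and
#' `end - 1` for `-` genes. Genes with several rows (transcripts) count as
#' bound if any row qualifies. Peaks on contigs absent from the gene table are
#' ignored.
#'
#' @param peaks Peak tibble ([parse_narrowpeak()]).
#' @param genes Gene-model tibble with columns `gene_id`, `chrom`, `start`,
#'   `end`, `strand` (and optionally a precomputed `tss`).
#' @param max_tss_distance Maximum summit-to-TSS distance in bp (default 1000).
#' @param min_neg_log10_p Significance cutoff on the -log10 p scale
#'   (default 5, i.e. p < 1e-5).
#' @return Character vector of bound gene ids (unique, sorted).
#' @export
promoter_bound_genes <- function(peaks, genes, max_tss_distance = 1000,
                                 min_neg_log10_p = 5) {
  stopifnot(max_tss_distance >= 0)
  genes <- add_tss(genes)
  sig <- peaks[peaks$neg_log10_p > min_neg_log10_p, , drop = FALSE]
  if (nrow(sig) == 0L || nrow(genes) == 0L) {
    return(character())
  }
  anchors <- peak_anchor(sig)
  bound <- character()
  for (chr in unique(genes$chrom)) {
    g <- genes[genes$chrom == chr, , drop = FALSE]
    a <- anchors[sig$chrom == chr]
    if (length(a) == 0L) next
    # distance from each TSS to its nearest anchor; sorted anchors + findInterval
    a <- sort(a)
    pos <- findInterval(g$tss, a)
    d_lo <- ifelse(pos >= 1L, g$tss - a[pmax(pos, 1L)], Inf)
    d_hi <- ifelse(pos < length(a), a[pmin(pos + 1L, length(a))] - g$tss, Inf)
    nearest <- pmin(abs(d_lo), abs(d_hi))
    bound <- c(bound, g$gene_id[nearest <= max_tss_distance])
  }
  sort(unique(bound))
}

# Strand-aware TSS column: start for '+', end - 1 for '-'.
add_tss <- function(genes) {
  if (!"tss" %in% names(genes)) {
    genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  }
  genes
}

#' Genes persistently bound across required time points
#'
#' Intersects per-timepoint bound-gene sets over the required labels only;
#' additional timepoints in `by_timepoint` (e.g. undifferentiated myoblasts)
#' are ignored. Persistence across differentiation time points selects binding
#' events maintained while cells form and keep a nuclear-envelope MTOC.
#'
#' @param by_timepoint Named list mapping timepoint label to a character
#'   vector of gene ids.
#' @param required Labels that must all contain a gene
#'   (default `c("24h", "60h", "7d")`).
#' @return Character vector of persistently bound gene ids (sorted).
#' @export
persistent_targets <- function(by_timepoint, required = c("24h", "60h", "7d")) {
  missing <- setdiff(required, names(by_timepoint))
  if (length(missing) > 0L) {
    stop_mtoc(
      "required timepoint label(s) missing from by_timepoint: ",
      paste(missing, collapse = ", "), class = "mtoc_input_error"
    )
  }
  out <- unique(by_timepoint[[required[1L]]])
  for (lab in required[-1L]) {
    out <- intersect(out, by_timepoint[[lab]])
  }
  sort(out)
}

#' Run the promoter-binding screen over several narrowPeak files
#'
#' Convenience wrapper: parses one narrowPeak file per timepoint, computes
#' promoter-bound gene sets and their persistent intersection.
#'
#' @param peak_files Named character vector `label = path`.
#' @param genes Gene-model tibble (see [promoter_bound_genes()]).
#' @param required Timepoint labels whose intersection defines persistence.
#' @inheritParams promoter_bound_genes
#' @return List with `by_timepoint` (named list of gene-id vectors),
#'   `persistent` (gene ids) and `params`.
#' @export
screen_peaks <- function(peak_files, genes, max_tss_distance = 1000,
                         min_neg_log10_p = 5, required = c("24h", "60h", "7d")) {
  by_timepoint <- lapply(peak_files, function(p) {
    promoter_bound_genes(parse_narrowpeak(p), genes,
      max_tss_distance = max_tss_distance,
      min_neg_log10_p = min_neg_log10_p
    )
  })
  names(by_timepoint) <- names(peak_files)
  list(
    by_timepoint = by_timepoint,
    persistent = persistent_targets(by_timepoint, required = required),
    params = list(
      max_tss_distance = max_tss_distance,
      min_neg_log10_p = min_neg_log10_p,
      required_timepoints = required,
      anchor = "summit, midpoint fallback"
    )
  )
}
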