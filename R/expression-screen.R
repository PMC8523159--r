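#' Genes upregulated in both RNA-seq contrasts
#'
#' A gene passes when its fold change is positive and its p-value is below
#' `alpha` (strict) in both contrasts: myoblasts vs early differentiation
#' (C1 vs C2) and myoblasts vs late differentiation (C1 vs C3). Only the
#' sign of the fold change is used, so log2 and linear fold-change columns
#' are interchangeable here.
#'
#' @param records DE tibble with columns `gene_id`, `log2fc_c1_c2`,
#'   `p_c1_c2`, `log2fc_c1_c3`, `p_c1_c3` (fold-change columns may also be
#'   named `fc_c1_c2` / `fc_c1_c3`).
#' @param alpha Significance cutoff (default 0.05, strict `<`).
#' @return Character vector of upregulated gene ids (sorted).
#' @export
rnaseq_upregulated <- function(records, alpha = 0.05) {
  fc2 <- records[["log2fc_c1_c2"]] %||% records[["fc_c1_c2"]]
  fc3 <- records[["log2fc_c1_c3"]] %||% records[["fc_c1_c3"]]
  p2 <- records$p_c1_c2
  p3 <- records$p_c1_c3
  if (any(c(p2, p3) < 0 | c(p2, p3) > 1, na.rm = TRUE)) {
    stop_mtoc("p-values must lie in [0, 1]", class = "mtoc_input_error")
  }
  keep <- fc2 > 0 & fc3 > 0 & p2 < alpha & p3 < alpha
  sort(unique(records$gene_id[keep & !is.na(keep)]))
}

#' Area-under-profile deviation statistic
#'
#' Trapezoidal integral over time of `|x(t) - x_0|`, where `x(t)` is the
#' per-timepoint mean profile and `x_0` its initial value: the total area
#' between the profile and the constant profile pinned at the initial
#' expression level. Zero iff the mean profile is constantly equal to its
#' initial value. Adding a constant to the whole profile leaves the statistic
#' unchanged; scaling deviations scales it linearly.
#'
#' @param values Mean expression per timepoint (numeric, length >= 2).
#' @param times Timepoint positions (strictly increasing; default equally
#'   spaced at unit intervals).
#' @return Non-negative number in expression units x time units.
#' @export
area_statistic <- function(values, times = seq_along(values) - 1) {
  stopifnot(length(values) >= 2, length(times) == length(values))
  if (any(diff(times) <= 0)) {
    stop_mtoc("times must be strictly increasing", class = "mtoc_input_error")
  }
  dev <- abs(values - values[1L])
  sum(diff(times) * (dev[-length(dev)] + dev[-1L]) / 2)
}

# Composite trapezoid weights so the statistic is a weighted sum w . |dev|.
trapezoid_weights <- function(times) {
  dt <- diff(times)
  n <- length(times)
  w <- numeric(n)
  w[1L] <- dt[1L] / 2
  w[n] <- dt[n - 1L] / 2
  if (n > 2L) w[2:(n - 1L)] <- (dt[-(n - 1L)] + dt[-1L]) / 2
  w
}

#' Permutation test for differential expression along a time course
#'
#' Tests whether a replicated expression profile deviates from a constant
#' profile more than chance, using [area_statistic()] on the per-timepoint
#' means. The null distribution is built by pooling all replicate values of
#' the gene and permuting them across timepoint slots `n_null` times; the
#' profile is called differential iff the observed statistic strictly exceeds
#' the empirical `1 - alpha` quantile of the permuted statistics.
#' Deterministic under a fixed seed.
#'
#' @param values Numeric matrix of expression values, timepoints in rows and
#'   replicates in columns (>= 2 replicates).
#' @param times Timepoint positions (default unit spacing).
#' @param n_null Number of permutations (default 1000).
#' @param alpha Test level (default 0.05).
#' @param seed Integer seed for the permutation draw.
#' @return Logical scalar.
#' @export
profile_is_differential <- function(values, times = seq_len(nrow(values)) - 1,
                                    n_null = 1000, alpha = 0.05, seed = 1) {
  if (!is.matrix(values) || ncol(values) < 2L) {
    stop_mtoc(
      "profile_is_differential needs >= 2 replicates per timepoint ",
      "(matrix timepoints x replicates); supply replicate data or skip the ",
      "test with the no-test option",
      class = "mtoc_input_error"
    )
  }
  n_t <- nrow(values)
  n_r <- ncol(values)
  obs <- area_statistic(rowMeans(values), times)
  w <- trapezoid_weights(times)
  pool <- as.vector(values)
  null <- with_seed(seed, {
    # each permutation is the pooled values in a random order, refolded into
    # the timepoints x replicates layout; the shuffles are drawn for all
    # n_null permutations at once by sorting uniforms within permutation
    m <- n_t * n_r
    u <- runif(m * n_null)
    o <- order(rep(seq_len(n_null), each = m), u)
    perm <- matrix(pool[((o - 1L) %% m) + 1L], nrow = m)
    means <- rowsum(perm, group = rep(seq_len(n_t), times = n_r)) / n_r
    dev <- abs(means - rep(means[1L, ], each = n_t))
    colSums(w * dev)
  })
  obs > unname(quantile(null, 1 - alpha, type = 7))
}

#' Max/min upregulation criterion for a time-course profile
#'
#' True iff the rise above the initial value exceeds the drop below it:
#' `(max_t x_t - x_0) > (x_0 - min_t x_t)`, strict, evaluated on the
#' per-timepoint mean profile. Ties (including flat profiles) fail.
#'
#' @param values Mean expression per timepoint (numeric, length >= 2).
#' @return Logical scalar.
#' @export
profile_is_upregulated <- function(values) {
  stopifnot(length(values) >= 2)
  (max(values) - values[1L]) > (values[1L] - min(values))
}

#' Genes upregulated along a developmental time course
#'
#' A gene is upregulated when (1) its profile is differentially expressed by
#' the area-under-profile permutation test and (2) it satisfies the max/min
#' upregulation criterion.
#'
#' @param profiles Long tibble with columns `gene_id`, `timepoint_index`,
#'   `replicate`, `value` and optionally `time` (defaults to
#'   `timepoint_index - 1`).
#' @param n_null,alpha,seed Passed to [profile_is_differential()].
#' @return Character vector of upregulated gene ids (sorted).
#' @export
heart_upregulated <- function(profiles, n_null = 1000, alpha = 0.05, seed = 1) {
  ids <- unique(profiles$gene_id)
  up <- vapply(seq_along(ids), function(k) {
    g <- profiles[profiles$gene_id == ids[k], , drop = FALSE]
    m <- profile_matrix(g)
    profile_is_upregulated(rowMeans(m$values)) &&
      profile_is_differential(m$values, m$times,
        n_null = n_null, alpha = alpha, seed = seed + k
      )
  }, logical(1))
  sort(ids[up])
}

# Long tibble for one gene -> matrix (timepoints x replicates) + times.
profile_matrix <- function(g) {
  tp <- sort(unique(g$timepoint_index))
  reps <- sort(unique(g$replicate))
  m <- matrix(NA_real_, length(tp), length(reps))
  m[cbind(match(g$timepoint_index, tp), match(g$replicate, reps))] <- g$value
  if (anyNA(m)) {
    stop_mtoc("unbalanced time-course table (missing replicate values)",
      class = "mtoc_input_error"
    )
  }
  times <- if ("time" %in% names(g)) {
    vapply(tp, function(t) g$time[g$timepoint_index == t][1L], numeric(1))
  } else {
    tp - 1
  }
  list(values = m, times = times)
}

#' Filter genes by Gene Ontology cellular-component terms
#'
#' Keeps genes annotated with at least one term whose name equals any search
#' term, compared case-insensitively after trimming whitespace. No
#' ontology-graph descendant expansion is performed; the match is on term
#' names as annotated. Genes absent from the map are dropped.
#'
#' @param gene_ids Character vector of gene ids.
#' @param go_map Tibble with columns `gene_id`, `term_name`.
#' @param terms Search terms
#'   (default `c("nuclear membrane", "nuclear envelope")`).
#' @return Character vector of matching gene ids (sorted).
#' @export
go_filter <- function(gene_ids, go_map,
                      terms = c("nuclear membrane", "nuclear envelope")) {
  norm <- function(x) tolower(trimws(x))
  hit <- go_map$gene_id[norm(go_map$term_name) %in% norm(terms)]
  sort(intersect(unique(gene_ids), unique(hit)))
}

#' Run the full candidate-gene cascade
#'
#' Executes the screen end to end: promoter-bound genes per timepoint and
#' their persistent intersection, the RNA-seq upregulation filter, the
#' intersection of both, the developmental time-course upregulation filter
#' applied within that intersection, and the GO cellular-component filter.
#'
#' @param peak_files Named character vector `timepoint label = narrowPeak
#'   path`; must include the labels in `params$required_timepoints`.
#' @param genes Gene-model tibble.
#' @param de DE tibble (see [rnaseq_upregulated()]).
#' @param heart_profiles Long time-course tibble (see [heart_upregulated()]).
#' @param go_map GO tibble (see [go_filter()]).
#' @param params Optional list overriding defaults: `max_tss_distance`,
#'   `min_neg_log10_p`, `required_timepoints`, `alpha_de`, `alpha_profile`,
#'   `n_null`, `go_terms`, `seed`.
#' @return A `CascadeReport` list: `counts` (named: `chip_persistent`,
#'   `rnaseq_up`, `intersection`, `heart_up`, `go_matched`), `genes` (the
#'   per-stage gene lists), `by_timepoint` counts, and `params`.
#' @export
run_cascade <- function(peak_files, genes, de, heart_profiles, go_map,
                        params = list()) {
  p <- modifyList(list(
    max_tss_distance = 1000, min_neg_log10_p = 5,
    required_timepoints = c("24h", "60h", "7d"),
    alpha_de = 0.05, alpha_profile = 0.05, n_null = 1000,
    go_terms = c("nuclear membrane", "nuclear envelope"), seed = 1L
  ), params)
  scr <- screen_peaks(peak_files, genes,
    max_tss_distance = p$max_tss_distance,
    min_neg_log10_p = p$min_neg_log10_p,
    required = p$required_timepoints
  )
  rna_up <- rnaseq_upregulated(de, alpha = p$alpha_de)
  inter <- sort(intersect(scr$persistent, rna_up))
  hp <- heart_profiles[heart_profiles$gene_id %in% inter, , drop = FALSE]
  heart_up <- heart_upregulated(hp,
    n_null = p$n_null,
    alpha = p$alpha_profile, seed = p$seed
  )
  go_matched <- go_filter(heart_up, go_map, terms = p$go_terms)
  structure(list(
    counts = c(
      chip_persistent = length(scr$persistent),
      rnaseq_up = length(rna_up),
      intersection = length(inter),
      heart_up = length(heart_up),
      go_matched = length(go_matched)
    ),
    genes = list(
      persistent = scr$persistent, rnaseq_up = rna_up,
      intersection = inter, heart_up = heart_up, go_matched = go_matched
    ),
    by_timepoint = vapply(scr$by_timepoint, length, integer(1)),
    params = utils::modifyList(p, scr$params)
  ), class = "cascade_report")
}

#' @export
print.cascade_report <- function(x, ...) {
  cat("Candidate-gene cascade\n")
  cat(sprintf(
    "  promoter-bound, persistent : %d\n  RNA-seq upregulated        : %d\n",
    x$counts[["chip_persistent"]], x$counts[["rnaseq_up"]]
  ))
  cat(sprintf(
    "  intersection               : %d\n  time-course upregulated    : %d\n",
    x$counts[["intersection"]], x$counts[["heart_up"]]
  ))
  cat(sprintf(
    "  GO nuclear membrane/envelope: %d  [%s]\n",
    x$counts[["go_matched"]], paste(x$genes$go_matched, collapse = ", ")
  ))
  invisible(x)
}
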