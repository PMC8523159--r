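#' Generate synthetic gene models
#'
#' Places `n_genes` genes on a single synthetic chromosome with pairwise TSS
#' spacing of at least 10 kb, so 1-kb promoter windows can never overlap and
#' every planted peak is attributable to exactly one gene. Both strands are
#' used; the TSS is `start` for `+` genes and `end - 1` for `-` genes
#' (0-based half-open coordinates).
#'
#' @param n_genes Number of genes (>= 0).
#' @param chrom_length Chromosome length in bp; must accommodate
#'   `n_genes * 10 kb`.
#' @param seed Integer seed; output is deterministic given the seed.
#' @param chrom Chromosome name (default `"chrS"`).
#' @return Tibble with columns `gene_id`, `chrom`, `strand`, `start`, `end`,
#'   `tss`.
#' @export
make_gene_models <- function(n_genes, chrom_length, seed, chrom = "chrS") {
  stopifnot(is_count(n_genes), chrom_length > 0)
  n_slots <- floor(chrom_length / 10000)
  if (n_genes > n_slots) {
    stop_mtoc(
      "cannot place ", n_genes, " genes with 10 kb spacing on a ",
      chrom_length, " bp chromosome (capacity ", n_slots, ")",
      class = "mtoc_capacity_error"
    )
  }
  if (n_genes == 0L) {
    return(tibble::tibble(
      gene_id = character(), chrom = character(), strand = character(),
      start = numeric(), end = numeric(), tss = numeric()
    ))
  }
  with_seed(seed, {
    slots <- sort(sample.int(n_slots, n_genes)) - 1L
    tss <- slots * 10000 + 5000
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    len <- sample(2000:8000, n_genes, replace = TRUE)
    start <- ifelse(strand == "+", tss, tss + 1 - len)
    end <- ifelse(strand == "+", tss + len, tss + 1)
    tibble::tibble(
      gene_id = sprintf("g%04d", seq_len(n_genes)),
      chrom = chrom, strand = strand,
      start = start, end = end, tss = tss
    )
  })
}

#' Write / read gene models as a BED-like TSV
#'
#' Columns: chrom, start, end, gene_id, score, strand (tab-separated, no
#' header), the conventional BED6 layout.
#'
#' @param genes Gene-model tibble from [make_gene_models()].
#' @param path Output path.
#' @return `path`, invisibly (writer); gene-model tibble (reader).
#' @export
write_gene_models <- function(genes, path) {
  bed <- data.frame(
    chrom = genes$chrom, start = format_bp(genes$start),
    end = format_bp(genes$end), gene_id = genes$gene_id,
    score = 0L, strand = genes$strand
  )
  write.table(bed, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' @rdname write_gene_models
#' @export
read_gene_models <- function(path) {
  bed <- read.delim(path,
    header = FALSE,
    col.names = c("chrom", "start", "end", "gene_id", "score", "strand")
  )
  add_tss(tibble::tibble(
    gene_id = as.character(bed$gene_id), chrom = as.character(bed$chrom),
    strand = as.character(bed$strand),
    start = as.numeric(bed$start), end = as.numeric(bed$end)
  ))
}

format_bp <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Write per-timepoint narrowPeak files with planted promoter peaks
#'
#' For each timepoint label, writes a valid BED6+4 narrowPeak file containing
#' one qualifying promoter peak (-log10 p > 5, summit within 1 kb of the TSS)
#' per requested gene. Decoy classes are always planted alongside so that
#' downstream filters are exercised rather than vacuous:
#' \itemize{
#'   \item distal peaks (summit 1.5-4 kb from a TSS) with significant p,
#'   \item sub-threshold promoter peaks (-log10 p in 3-4.9) at the TSS,
#' }
#' and the per-timepoint request itself supplies wrong-timepoint decoys
#' (genes bound at only a subset of timepoints).
#'
#' @param genes Gene-model tibble.
#' @param bound_request Named list `timepoint label -> gene ids` that must
#'   receive a qualifying promoter peak at that timepoint. Every id must be
#'   present in `genes`.
#' @param dir Output directory (created if needed).
#' @param seed Integer seed; identical seeds give byte-identical files.
#' @param n_decoys Number of distal and of sub-threshold decoy peaks per
#'   timepoint (drawn from non-requested genes).
#' @return List with `files` (named vector of paths) and `truth`, a list with
#'   `bound_genes_by_timepoint` recording exactly the planted qualifying
#'   genes per timepoint.
#' @export
make_peak_files <- function(genes, bound_request, dir, seed, n_decoys = 10) {
  absent <- setdiff(unique(unlist(bound_request)), genes$gene_id)
  if (length(absent) > 0L) {
    stop_mtoc(
      "requested gene(s) absent from gene models: ",
      paste(absent, collapse = ", "), class = "mtoc_input_error"
    )
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  truth <- list()
  with_seed(seed, {
    for (lab in names(bound_request)) {
      ids <- sort(unique(bound_request[[lab]]))
      g <- genes[match(ids, genes$gene_id), , drop = FALSE]
      qual <- plant_peaks(g, offset_range = c(-500, 500), nlp_range = c(6, 12))
      pool <- setdiff(genes$gene_id, ids)
      n_dist <- min(n_decoys, length(pool))
      distal_ids <- if (n_dist > 0) sample(pool, n_dist) else character()
      dg <- genes[match(distal_ids, genes$gene_id), , drop = FALSE]
      distal <- plant_peaks(dg,
        offset_range = c(1500, 4000),
        nlp_range = c(6, 12), random_sign = TRUE
      )
      sub_ids <- if (n_dist > 0) sample(pool, n_dist) else character()
      sg <- genes[match(sub_ids, genes$gene_id), , drop = FALSE]
      subthr <- plant_peaks(sg, offset_range = c(-200, 200), nlp_range = c(3, 4.9))
      pk <- rbind(qual, distal, subthr)
      pk <- pk[order(pk$start), , drop = FALSE]
      pk$name <- sprintf("%s_peak_%03d", lab, seq_len(nrow(pk)))
      path <- file.path(dir, paste0("myog_", lab, ".narrowPeak"))
      write_narrowpeak(pk, path)
      files[lab] <- path
      truth[[lab]] <- ids
    }
  })
  list(files = files, truth = list(bound_genes_by_timepoint = truth))
}

# One peak per gene row; summit offset from the TSS drawn from offset_range
# (sign randomized when random_sign so distal decoys fall on either side).
plant_peaks <- function(g, offset_range, nlp_range, random_sign = FALSE) {
  n <- nrow(g)
  if (n == 0L) {
    return(data.frame(
      chrom = character(), start = numeric(), end = numeric(),
      name = character(), score = numeric(), strand = character(),
      signal = numeric(), neg_log10_p = numeric(), neg_log10_q = numeric(),
      summit_offset = numeric()
    ))
  }
  off <- runif(n, offset_range[1], offset_range[2])
  if (random_sign) off <- off * sample(c(-1, 1), n, replace = TRUE)
  summit <- round(g$tss + off)
  nlp <- round(runif(n, nlp_range[1], nlp_range[2]), 3)
  half <- round(runif(n, 100, 250))
  data.frame(
    chrom = g$chrom, start = summit - half, end = summit + half,
    name = "", score = round(nlp * 10), strand = ".",
    signal = round(runif(n, 2, 20), 3), neg_log10_p = nlp,
    neg_log10_q = round(pmax(nlp - 1, 0), 3), summit_offset = half
  )
}

write_narrowpeak <- function(pk, path) {
  out <- data.frame(
    pk$chrom, format_bp(pk$start), format_bp(pk$end), pk$name, pk$score,
    pk$strand, pk$signal, pk$neg_log10_p, pk$neg_log10_q,
    format_bp(pk$summit_offset)
  )
  write.table(out, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Synthetic differential-expression table
#'
#' Emulates a two-contrast DE result (myoblasts vs day 3, myoblasts vs day 7
#' of differentiation). Genes in `up_set` get positive fold changes >= 1 with
#' p <= 0.01 in both contrasts, passing the upregulation filter with margin.
#' The remaining genes are split among decoy classes that each fail exactly
#' one condition: down in both, up in one contrast only, or positive but
#' non-significant.
#'
#' @param genes Gene-model tibble.
#' @param up_set Gene ids to plant as upregulated (subset of `genes$gene_id`).
#' @param seed Integer seed.
#' @return Tibble with columns `gene_id`, `log2fc_c1_c2`, `p_c1_c2`,
#'   `log2fc_c1_c3`, `p_c1_c3`.
#' @export
make_de_table <- function(genes, up_set, seed) {
  check_subset(up_set, genes$gene_id)
  n <- nrow(genes)
  with_seed(seed, {
    up <- genes$gene_id %in% up_set
    fc2 <- numeric(n)
    fc3 <- numeric(n)
    p2 <- numeric(n)
    p3 <- numeric(n)
    fc2[up] <- runif(sum(up), 1, 3)
    fc3[up] <- runif(sum(up), 1, 3)
    p2[up] <- runif(sum(up), 1e-6, 0.01)
    p3[up] <- runif(sum(up), 1e-6, 0.01)
    rest <- which(!up)
    cls <- rep_len(c("down", "one_sided", "nonsig"), length(rest))
    for (k in seq_along(rest)) {
      i <- rest[k]
      if (cls[k] == "down") {
        fc2[i] <- runif(1, -3, -0.5)
        fc3[i] <- runif(1, -3, -0.5)
        p2[i] <- runif(1, 1e-6, 0.04)
        p3[i] <- runif(1, 1e-6, 0.04)
      } else if (cls[k] == "one_sided") {
        fc2[i] <- runif(1, 1, 3)
        fc3[i] <- runif(1, -3, -0.5)
        p2[i] <- runif(1, 1e-6, 0.01)
        p3[i] <- runif(1, 1e-6, 0.01)
      } else {
        fc2[i] <- runif(1, 0.1, 1)
        fc3[i] <- runif(1, 0.1, 1)
        p2[i] <- runif(1, 0.2, 0.9)
        p3[i] <- runif(1, 0.2, 0.9)
      }
    }
    tibble::tibble(
      gene_id = genes$gene_id,
      log2fc_c1_c2 = round(fc2, 4), p_c1_c2 = signif(p2, 4),
      log2fc_c1_c3 = round(fc3, 4), p_c1_c3 = signif(p3, 4)
    )
  })
}

#' Synthetic replicated expression time courses
#'
#' Emulates a developmental expression time course (e.g. heart development
#' across embryonic to postnatal stages). Genes in `up_set` get monotone
#' increasing mean profiles whose total rise is at least `5 * noise_sd`
#' (floor of 2 expression units), so they are recovered with margin by the
#' area-under-profile test plus the max/min upregulation criterion. The
#' remaining genes alternate between flat profiles and monotone decreasing
#' decoys (differential but not upregulated).
#'
#' @param genes Gene-model tibble.
#' @param up_set Gene ids to plant as upregulated.
#' @param n_timepoints Number of timepoints (default 5).
#' @param n_replicates Replicates per timepoint (default 3).
#' @param noise_sd Gaussian noise SD in expression units (>= 0).
#' @param seed Integer seed.
#' @return Long tibble with columns `gene_id`, `timepoint_index` (1-based),
#'   `time`, `replicate`, `value`.
#' @export
make_time_courses <- function(genes, up_set, n_timepoints = 5,
                              n_replicates = 3, noise_sd = 0, seed = 1) {
  if (noise_sd < 0) {
    stop_mtoc("noise_sd must be >= 0", class = "mtoc_input_error")
  }
  check_subset(up_set, genes$gene_id)
  stopifnot(n_timepoints >= 2, n_replicates >= 1)
  tt <- seq_len(n_timepoints) - 1
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(genes)), function(i) {
      id <- genes$gene_id[i]
      base <- runif(1, 5, 10)
      rise <- max(5 * noise_sd, 2)
      if (id %in% up_set) {
        mu <- base + rise * (tt / max(tt))
      } else if (i %% 2 == 0L) {
        mu <- base - rise * (tt / max(tt)) # monotone-down decoy
      } else {
        mu <- rep(base, n_timepoints) # flat
      }
      vals <- rep(mu, each = n_replicates) +
        rnorm(n_timepoints * n_replicates, 0, noise_sd)
      tibble::tibble(
        gene_id = id,
        timepoint_index = rep(seq_len(n_timepoints), each = n_replicates),
        time = rep(tt, each = n_replicates),
        replicate = rep(seq_len(n_replicates), n_timepoints),
        value = round(vals, 6)
      )
    })
    dplyr::bind_rows(rows)
  })
}

#' Synthetic Gene Ontology cellular-component map
#'
#' @param genes Gene-model tibble.
#' @param term_assignments Named list `gene_id -> character vector of term
#'   names`. Genes not listed are absent from the map (as in real GO
#'   annotation, where unannotated genes simply have no rows).
#' @return Tibble with columns `gene_id`, `term_name`, one row per
#'   annotation.
#' @export
make_go_map <- function(genes, term_assignments) {
  check_subset(names(term_assignments), genes$gene_id)
  if (length(term_assignments) == 0L) {
    return(tibble::tibble(gene_id = character(), term_name = character()))
  }
  tibble::tibble(
    gene_id = rep(names(term_assignments), lengths(term_assignments)),
    term_name = unlist(term_assignments, use.names = FALSE)
  )
}

check_subset <- function(x, universe) {
  absent <- setdiff(x, universe)
  if (length(absent) > 0L) {
    stop_mtoc(
      "gene id(s) not in gene models: ", paste(absent, collapse = ", "),
      class = "mtoc_input_error"
    )
  }
  invisible(TRUE)
}

#' Generate a complete screen fixture with a planted candidate cascade
#'
#' Builds gene models, per-timepoint narrowPeak files, a DE table, heart-style
#' time courses and a GO map in one call, with the full cascade planted:
#' `n_persistent` genes bound at all differentiation timepoints,
#' `n_rnaseq_up` genes upregulated in the DE table such that exactly
#' `n_intersection` overlap the persistent set, `n_heart_up` of the
#' intersection upregulated in the time course, and `n_go` of those annotated
#' with nuclear-membrane/nuclear-envelope GO terms. Wrong-timepoint decoys
#' (genes bound in myoblasts only, or at only some differentiation
#' timepoints) are planted as well. In noise-free mode the expected candidate
#' set is verified against the real pipeline at generation time
#' (self-consistency).
#'
#' @param dir Directory for the fixture files.
#' @param seed Integer seed.
#' @param n_genes,n_persistent,n_rnaseq_up,n_intersection,n_heart_up,n_go
#'   Cascade sizes; must satisfy `n_go <= n_heart_up <= n_intersection <=
#'   min(n_persistent, n_rnaseq_up)`.
#' @param noise_sd Time-course noise SD (0 = noise-free mode).
#' @param chrom_length Synthetic chromosome length in bp.
#' @param check Verify self-consistency by running the pipeline (default
#'   `TRUE` when `noise_sd == 0`).
#' @return List with `files` (named paths: gene models, peaks per timepoint,
#'   DE, time courses, GO), `genes`, and `truth` (a ScreenTruth-style list
#'   incl. `expected_candidates`).
#' @export
make_screen_fixture <- function(dir, seed, n_genes = 200, n_persistent = 30,
                                n_rnaseq_up = 40, n_intersection = 12,
                                n_heart_up = 7, n_go = 2, noise_sd = 0,
                                chrom_length = 3e6,
                                check = noise_sd == 0) {
  stopifnot(
    n_go <= n_heart_up, n_heart_up <= n_intersection,
    n_intersection <= min(n_persistent, n_rnaseq_up),
    n_persistent + (n_rnaseq_up - n_intersection) <= n_genes
  )
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genes <- make_gene_models(n_genes, chrom_length, seed = seed)
  ids <- genes$gene_id
  sets <- with_seed(seed + 1L, {
    persistent <- sample(ids, n_persistent)
    inter <- sample(persistent, n_intersection)
    rna_only <- sample(setdiff(ids, persistent), n_rnaseq_up - n_intersection)
    rnaseq_up <- c(inter, rna_only)
    heart_up_cand <- sample(inter, n_heart_up)
    go_matched <- sample(heart_up_cand, n_go)
    # wrong-timepoint decoys: bound early or intermittently, never persistent
    rest <- setdiff(ids, c(persistent, rnaseq_up))
    myoblast_only <- sample(rest, min(8, length(rest)))
    partial <- sample(setdiff(rest, myoblast_only), min(8, length(rest) - 8))
    list(
      persistent = persistent, rnaseq_up = rnaseq_up, inter = inter,
      heart_up = heart_up_cand, go = go_matched,
      myoblast_only = myoblast_only, partial = partial
    )
  })
  bound_request <- list(
    myoblast = c(sets$myoblast_only, sets$partial),
    "24h" = c(sets$persistent, sets$partial),
    "60h" = c(sets$persistent, sets$partial[seq_len(length(sets$partial) %/% 2)]),
    "7d" = sets$persistent
  )
  pk <- make_peak_files(genes, bound_request, dir, seed = seed + 2L)
  de <- make_de_table(genes, sets$rnaseq_up, seed = seed + 3L)
  # heart time course planted only for genes whose heart-stage fate matters;
  # planting up-profiles also for some non-candidates exercises the
  # intersection logic (heart-up outside the intersection must not leak in)
  heart_extra <- with_seed(seed + 4L, {
    sample(setdiff(ids, sets$inter), 5)
  })
  tc <- make_time_courses(genes, c(sets$heart_up, heart_extra),
    noise_sd = noise_sd, seed = seed + 5L
  )
  terms <- c(
    "cytoplasm", "mitochondrion", "plasma membrane", "nucleolus",
    "endoplasmic reticulum"
  )
  assign <- with_seed(seed + 6L, {
    a <- lapply(seq_len(nrow(genes)), function(i) sample(terms, 2))
    names(a) <- ids
    ne_terms <- c("nuclear membrane", "nuclear envelope")
    for (k in seq_along(sets$go)) {
      a[[sets$go[k]]] <- c(a[[sets$go[k]]], ne_terms[1 + (k %% 2)])
    }
    # unannotated genes are dropped from the map entirely
    drop <- sample(setdiff(ids, sets$go), 10)
    a[drop] <- NULL
    a
  })
  go <- make_go_map(genes, assign)

  files <- c(
    genes = file.path(dir, "gene_models.tsv"),
    de = file.path(dir, "de_table.tsv"),
    time_courses = file.path(dir, "time_courses.tsv"),
    go = file.path(dir, "go_map.tsv")
  )
  write_gene_models(genes, files["genes"])
  write_tsv_plain(de, files["de"])
  write_tsv_plain(tc, files["time_courses"])
  write_tsv_plain(go, files["go"])
  files <- c(files, pk$files)

  truth <- list(
    bound_genes_by_timepoint = lapply(pk$truth$bound_genes_by_timepoint, sort),
    persistent = sort(sets$persistent),
    upregulated_rnaseq = sort(sets$rnaseq_up),
    intersection = sort(sets$inter),
    upregulated_heart = sort(sets$heart_up),
    go_terms = assign,
    expected_candidates = sort(sets$go)
  )
  if (check) {
    rep <- run_cascade(
      peak_files = pk$files[c("myoblast", "24h", "60h", "7d")],
      genes = genes, de = de, heart_profiles = tc, go_map = go,
      params = list(seed = seed + 99L)
    )
    ok <- identical(rep$genes$persistent, truth$persistent) &&
      identical(rep$genes$rnaseq_up, truth$upregulated_rnaseq) &&
      identical(rep$genes$heart_up, truth$upregulated_heart) &&
      identical(rep$genes$go_matched, truth$expected_candidates)
    if (!ok) {
      stop_mtoc("fixture self-consistency check failed",
        class = "mtoc_consistency_error"
      )
    }
  }
  list(files = files, genes = genes, truth = truth)
}

write_tsv_plain <- function(df, path) {
  write.table(as.data.frame(df), path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE
  )
  invisible(path)
}
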