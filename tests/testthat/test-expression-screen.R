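test_that("RNA-seq filter requires positive fold change and p < alpha in both contrasts", {
  de <- tibble::tibble(
    gene_id = c("a", "b", "c", "d"),
    log2fc_c1_c2 = c(1.2, 1.2, 1.2, 0.8),
    p_c1_c2 = c(0.01, 0.01, 0.05, 0.02),
    log2fc_c1_c3 = c(0.8, -0.3, 1.0, 0.5),
    p_c1_c3 = c(0.02, 0.001, 0.01, 0.04)
  )
  expect_equal(rnaseq_upregulated(de), c("a", "d"))
  # one contrast down -> excluded; boundary p == alpha -> excluded (strict)
  expect_false("b" %in% rnaseq_upregulated(de))
  expect_false("c" %in% rnaseq_upregulated(de))
  de$p_c1_c2[1] <- 1.5
  expect_error(rnaseq_upregulated(de), class = "mtoc_input_error")
})

test_that("area statistic matches hand-computed trapezoids and its invariances", {
  expect_equal(area_statistic(c(5, 5, 5), 0:2), 0)
  expect_equal(area_statistic(c(0, 1, 2), 0:2), 2.0)
  expect_equal(area_statistic(c(0, -1, -2), 0:2), 2.0) # symmetric deviation
  # shift invariance and linear scaling of deviations
  v <- c(1, 4, 2, 8, 3)
  expect_equal(area_statistic(v + 100), area_statistic(v))
  base <- area_statistic(v)
  expect_equal(area_statistic(v[1] + 3 * (v - v[1])), 3 * base)
  # uneven spacing weighs intervals by their length
  expect_equal(area_statistic(c(0, 2), times = c(0, 5)), 5)
  expect_error(area_statistic(c(1, 2), times = c(1, 1)), class = "mtoc_input_error")
})

test_that("permutation test calls planted profiles and not degenerate ones", {
  flat0 <- matrix(5, 4, 3)
  expect_false(profile_is_differential(flat0, seed = 1)) # zero-variance flat
  rise <- matrix(rep(seq(0, 10, length.out = 5), 3), 5, 3) +
    matrix(rnorm(15, 0, 1), 5, 3) # 10-sigma rise
  expect_true(profile_is_differential(rise, seed = 2))
  expect_identical(
    profile_is_differential(rise, seed = 5),
    profile_is_differential(rise, seed = 5)
  )
  expect_error(
    profile_is_differential(matrix(1:4, 4, 1)),
    class = "mtoc_input_error"
  )
})

test_that("max/min upregulation criterion is strict about ties", {
  expect_true(profile_is_upregulated(c(1, 2, 3)))
  expect_false(profile_is_upregulated(c(3, 2, 1)))
  expect_false(profile_is_upregulated(c(2, 1, 3))) # rise 1 == drop 1
  expect_false(profile_is_upregulated(c(4, 4, 4)))
})

test_that("heart filter is the conjunction of the two profile criteria", {
  genes <- make_gene_models(9, 1e6, 31)
  up <- genes$gene_id[c(1, 5)]
  tc <- make_time_courses(genes, up, noise_sd = 0, seed = 6)
  got <- heart_upregulated(tc, seed = 11)
  expect_equal(got, sort(up))
  # monotone-down decoys are differential but fail the up criterion
  down_id <- genes$gene_id[2] # even index -> down profile in the generator
  g <- tc[tc$gene_id == down_id, ]
  means <- tapply(g$value, g$timepoint_index, mean)
  expect_false(profile_is_upregulated(as.numeric(means)))
  expect_gt(area_statistic(as.numeric(means)), 0)
})

test_that("GO filter matches term names case-insensitively, no expansion", {
  go <- tibble::tibble(
    gene_id = c("a", "b", "b", "c"),
    term_name = c("Nuclear Membrane", "cytoplasm", "nuclear envelope", "nuclear pore")
  )
  expect_equal(go_filter(c("a", "b", "c", "zz"), go), c("a", "b"))
  expect_equal(go_filter("c", go), character()) # related term, no closure
  expect_equal(go_filter("zz", go), character()) # absent from map
})

test_that("cascade report recovers planted counts and satisfies containment", {
  dir <- withr::local_tempdir()
  fix <- make_screen_fixture(dir,
    seed = 19, n_genes = 150, n_persistent = 25,
    n_rnaseq_up = 35, n_intersection = 10, n_heart_up = 6, n_go = 3
  )
  de <- tibble::as_tibble(utils::read.delim(fix$files[["de"]]))
  tc <- tibble::as_tibble(utils::read.delim(fix$files[["time_courses"]]))
  go <- tibble::as_tibble(utils::read.delim(fix$files[["go"]]))
  rep <- run_cascade(
    fix$files[c("myoblast", "24h", "60h", "7d")],
    fix$genes, de, tc, go,
    params = list(seed = 2)
  )
  expect_equal(unname(rep$counts), c(25, 35, 10, 6, 3))
  cn <- rep$counts
  expect_lte(cn[["go_matched"]], cn[["heart_up"]])
  expect_lte(cn[["heart_up"]], cn[["intersection"]])
  expect_lte(cn[["intersection"]], min(cn[["chip_persistent"]], cn[["rnaseq_up"]]))
  expect_equal(
    rep$genes$intersection,
    sort(intersect(rep$genes$persistent, rep$genes$rnaseq_up))
  )
  # vacuous GO filter: every annotated heart-up gene passes
  all_terms <- unique(go$term_name)
  rep2 <- run_cascade(
    fix$files[c("myoblast", "24h", "60h", "7d")],
    fix$genes, de, tc, go,
    params = list(seed = 2, go_terms = all_terms)
  )
  annotated <- intersect(rep2$genes$heart_up, unique(go$gene_id))
  expect_equal(rep2$genes$go_matched, sort(annotated))
})

test_that("cascade on empty inputs reports zeros", {
  dir <- withr::local_tempdir()
  genes <- make_gene_models(5, 1e6, 3)
  empty_pk <- file.path(dir, "empty.narrowPeak")
  writeLines(character(), empty_pk)
  files <- c("24h" = empty_pk, "60h" = empty_pk, "7d" = empty_pk)
  de <- make_de_table(genes, character(), seed = 1)
  tc <- make_time_courses(genes, character(), seed = 1)
  go <- make_go_map(genes, list())
  rep <- run_cascade(files, genes, de, tc, go)
  expect_equal(unname(rep$counts), rep(0L, 5))
})
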