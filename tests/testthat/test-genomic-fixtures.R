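test_that("gene models respect spacing, determinism and capacity", {
  expect_equal(nrow(make_gene_models(0, 1e6, 7)), 0L)
  g1 <- make_gene_models(5, 1e6, 7)
  g2 <- make_gene_models(5, 1e6, 7)
  expect_identical(g1, g2)
  expect_true(all(dist(g1$tss) >= 10000)) # pairwise scan
  expect_true(all(g1$start < g1$end))
  expect_equal(
    g1$tss,
    ifelse(g1$strand == "+", g1$start, g1$end - 1)
  )
  g3 <- make_gene_models(60, 1e6, 3)
  expect_setequal(unique(g3$strand), c("+", "-"))
  expect_error(make_gene_models(101, 1e6, 7), class = "mtoc_capacity_error")
})

test_that("planted promoter peaks qualify and decoys never do", {
  dir <- withr::local_tempdir()
  genes <- make_gene_models(20, 1e6, 11)
  ids <- genes$gene_id
  req <- list(
    "24h" = ids[1:5], "60h" = ids[1:5], "7d" = ids[1:5],
    myoblast = ids[6:8]
  )
  out <- make_peak_files(genes, req, dir, seed = 5)
  recovered <- lapply(out$files, function(f) {
    promoter_bound_genes(parse_narrowpeak(f), genes)
  })
  for (lab in names(req)) {
    expect_setequal(recovered[[lab]], req[[lab]])
    expect_setequal(
      out$truth$bound_genes_by_timepoint[[lab]],
      sort(unique(req[[lab]]))
    )
  }
  # decoys exist in the files but never qualify
  pk <- parse_narrowpeak(out$files[["7d"]])
  expect_gt(nrow(pk), 5L)
  expect_true(any(pk$neg_log10_p <= 5))
  expect_error(
    make_peak_files(genes, list("24h" = "nope"), dir, seed = 1),
    "absent"
  )
})

test_that("identical seeds give byte-identical fixture files", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  genes <- make_gene_models(10, 1e6, 2)
  req <- list("24h" = genes$gene_id[1:3])
  f1 <- make_peak_files(genes, req, d1, seed = 9)$files
  f2 <- make_peak_files(genes, req, d2, seed = 9)$files
  expect_identical(readLines(f1[["24h"]]), readLines(f2[["24h"]]))
})

test_that("DE table decoy classes each fail exactly one filter condition", {
  genes <- make_gene_models(100, 2e6, 13)
  up <- genes$gene_id[1:50]
  de <- make_de_table(genes, up, seed = 4)
  expect_setequal(rnaseq_upregulated(de), up) # exact recovery of the 50
  expect_equal(rnaseq_upregulated(make_de_table(genes, character(), 4)), character())
  rest <- de[!de$gene_id %in% up, ]
  expect_true(all(
    rest$log2fc_c1_c2 <= 0 | rest$log2fc_c1_c3 <= 0 |
      rest$p_c1_c2 >= 0.05 | rest$p_c1_c3 >= 0.05
  ))
})

test_that("planted time-course genes pass the heart filter with margin", {
  genes <- make_gene_models(12, 2e6, 17)
  up <- genes$gene_id[1:4]
  tc <- make_time_courses(genes, up, noise_sd = 0, seed = 8)
  expect_equal(heart_upregulated(tc, seed = 3), sort(up))
  expect_error(
    make_time_courses(genes, up, noise_sd = -1),
    class = "mtoc_input_error"
  )
  # small noise: planted effect is >= 5 sigma, recovery still exact
  tc2 <- make_time_courses(genes, up, noise_sd = 0.2, seed = 8)
  expect_equal(heart_upregulated(tc2, seed = 3), sort(up))
})

test_that("fixture truth is self-consistent with the real pipeline", {
  dir <- withr::local_tempdir()
  fix <- make_screen_fixture(dir, seed = 23) # check = TRUE re-runs the cascade
  expect_setequal(
    fix$truth$expected_candidates,
    go_filter(fix$truth$upregulated_heart, tibble::as_tibble(
      utils::read.delim(fix$files[["go"]])
    ))
  )
  expect_true(all(fix$truth$upregulated_heart %in% fix$truth$intersection))
  expect_true(all(fix$truth$intersection %in% fix$truth$persistent))
})
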