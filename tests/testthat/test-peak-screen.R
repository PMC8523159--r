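test_that("narrowPeak lines map onto peak fields and bad lines are rejected", {
  f <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines(c(
    "track name=test",
    "chr1\t100\t600\tp1\t500\t.\t8.1\t6.2\t5.3\t250",
    "chr2\t900\t1400\tp2\t300\t.\t4.0\t4.9\t3.0\t-1"
  ), f)
  pk <- parse_narrowpeak(f)
  expect_equal(nrow(pk), 2L)
  expect_equal(pk$start[1], 100)
  expect_equal(pk$end[1], 600)
  expect_equal(pk$neg_log10_p[1], 6.2)
  expect_equal(pk$summit_offset[1], 250)

  writeLines(character(), f)
  expect_equal(nrow(parse_narrowpeak(f)), 0L)

  writeLines(c(
    "chr1\t100\t600\tp1\t500\t.\t8.1\t6.2\t5.3\t250",
    "chr1\t1\t2\tp\t0\t.\t1\t2\t3" # 9 columns
  ), f)
  expect_error(parse_narrowpeak(f), "line 2")

  writeLines("chr1\tabc\t600\tp1\t500\t.\t8.1\t6.2\t5.3\t250", f)
  expect_error(parse_narrowpeak(f), "non-numeric")
})

test_that("peak anchor is the summit when present, else the floored midpoint", {
  pk <- tibble::tibble(
    start = c(100, 100, 100), end = c(600, 600, 101),
    summit_offset = c(250, -1, -1)
  )
  expect_equal(peak_anchor(pk), c(350, 350, 100))
})

test_that("promoter assignment enforces the distance and significance rules", {
  genes <- tibble::tibble(
    gene_id = "g1", chrom = "chr1", strand = "+", start = 1000, end = 3000
  )
  mk <- function(anchor, nlp) {
    tibble::tibble(
      chrom = "chr1", start = anchor - 50, end = anchor + 50, name = "p",
      score = 0, strand = ".", signal = 1, neg_log10_p = nlp,
      neg_log10_q = 1, summit_offset = 50
    )
  }
  expect_equal(promoter_bound_genes(mk(1400, 8), genes), "g1") # 400 bp away
  expect_equal(promoter_bound_genes(mk(2500, 8), genes), character()) # 1500 bp
  expect_equal(promoter_bound_genes(mk(1000, 4.9), genes), character()) # weak
  expect_equal(promoter_bound_genes(mk(2000, 8), genes), "g1") # exactly 1 kb
  expect_equal(promoter_bound_genes(mk(1000, 5), genes), character()) # strict >
})

test_that("TSS is strand-aware and any transcript row can qualify a gene", {
  genes <- tibble::tibble(
    gene_id = c("gm", "gm"), chrom = "chr1", strand = c("-", "-"),
    start = c(5000, 9000), end = c(8000, 12000) # TSSs at 7999 and 11999
  )
  pk <- tibble::tibble(
    chrom = "chr1", start = 11900, end = 12100, name = "p", score = 0,
    strand = ".", signal = 1, neg_log10_p = 7, neg_log10_q = 1,
    summit_offset = 99 # anchor 11999, at the second transcript's TSS
  )
  expect_equal(promoter_bound_genes(pk, genes), "gm")
})

test_that("persistence intersects required timepoints and ignores others", {
  bt <- list(
    myoblast = c("A", "Z"), "24h" = c("A", "B", "C"),
    "60h" = c("B", "C"), "7d" = c("B", "C", "D")
  )
  expect_equal(persistent_targets(bt), c("B", "C"))
  bt$`60h` <- character()
  expect_equal(persistent_targets(bt), character())
  expect_error(persistent_targets(bt[c("24h", "60h")]), "7d")
})

test_that("relaxing the distance or significance cutoff never loses genes", {
  for (seed in 1:5) {
    fx <- random_peak_fixture(300, 30, seed)
    base <- promoter_bound_genes(fx$peaks, fx$genes, 1000, 5)
    wider <- promoter_bound_genes(fx$peaks, fx$genes, 5000, 5)
    weaker <- promoter_bound_genes(fx$peaks, fx$genes, 1000, 3)
    expect_true(all(base %in% wider))
    expect_true(all(base %in% weaker))
  }
})

test_that("persistent genes are contained in every required timepoint set", {
  fix <- make_screen_fixture(withr::local_tempdir(), seed = 41)
  scr <- screen_peaks(
    fix$files[c("myoblast", "24h", "60h", "7d")],
    fix$genes
  )
  for (lab in c("24h", "60h", "7d")) {
    expect_true(all(scr$persistent %in% scr$by_timepoint[[lab]]))
  }
  expect_equal(scr$persistent, fix$truth$persistent)
})
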