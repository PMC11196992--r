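test_that("derive_regions places the promoter window by strand", {
  # + strand: TSS at the BED start
  g <- make_gene("chr1", 1001, 5000, "+")       # BED [1000, 5000)
  r <- derive_regions(g)
  expect_equal(r$tss, 1000L)
  expect_equal(c(start(r$prg5), end(r$prg5)), c(701L, 1300L))  # [700,1300) BED
  expect_equal(c(start(r$body), end(r$body)), c(1301L, 5000L)) # [1300,5000)
  expect_false(r$short_body)

  # - strand: TSS at the BED end
  g <- make_gene("chr1", 1001, 5000, "-")
  r <- derive_regions(g)
  expect_equal(r$tss, 5000L)
  expect_equal(c(start(r$prg5), end(r$prg5)), c(4701L, 5300L)) # [4700,5300)
  expect_equal(c(start(r$body), end(r$body)), c(1001L, 4700L)) # [1000,4700)

  # interior TSS never happens for a collapsed model, but a promoter at the
  # chromosome start is clipped and the short body is flagged
  g <- make_gene("chr1", 1, 400, "+")           # BED [0, 400)
  expect_warning(r <- derive_regions(g), "clipped")
  expect_equal(c(start(r$prg5), end(r$prg5)), c(1L, 300L))     # [0,300) BED
  expect_equal(c(start(r$body), end(r$body)), c(301L, 400L))
  expect_true(r$short_body)
})

test_that("promoter_window_max finds the best window placement", {
  expect_equal(promoter_window_max(GRanges(), "chr1", 5000L), 0L)

  # 10 reads inside one 200 bp span all fit a single 600 bp window
  r <- GRanges("chr1", IRanges(rep(4901, 10), width = 50))
  expect_equal(promoter_window_max(r, "chr1", 5000L), 10L)
  # reads on another chromosome do not count
  expect_equal(promoter_window_max(r, "chr9", 5000L), 0L)
})

test_that("promoter_window_max with step 1 equals exhaustive enumeration", {
  set.seed(101)
  tss <- 5000L
  for (k in 1:40) {
    reads <- random_reads(sample(0:60, 1), tss - 2600L, tss + 2600L)
    got <- promoter_window_max(reads, "chr1", tss)
    want <- naive_window_max(start(reads) - 1L, end(reads),
                             tss - 2500L, tss + 2500L - 600L, 600L)
    expect_identical(as.integer(got), as.integer(want))
  }
})

test_that("coarser window steps never beat the exhaustive step-1 scan", {
  set.seed(202)
  for (k in 1:10) {
    reads <- random_reads(40, 2000L, 8000L)
    exact <- promoter_window_max(reads, "chr1", 5000L, step = 1L)
    for (s in c(10L, 50L, 300L)) {
      expect_lte(promoter_window_max(reads, "chr1", 5000L, step = s), exact)
    }
  }
})

test_that("body_median tiles windows and takes the median count", {
  # body [1300, 4300) BED = 5 windows; plant counts {0, 1, 2, 3, 10}
  body <- IRanges(1301, 4300)
  reads <- reads_with_window_counts(c(0, 1, 2, 3, 10), 1301L)
  bm <- body_median(reads, "chr1", body)
  expect_equal(bm$n_windows, 5L)
  expect_equal(bm$body_median, 2)

  # read-free body
  bm0 <- body_median(GRanges(), "chr1", body)
  expect_equal(bm0$body_median, 0)

  # trailing fragment < 600 bp dropped: width 900 -> 1 window
  bm1 <- body_median(reads, "chr1", IRanges(1301, 2200))
  expect_equal(bm1$n_windows, 1L)

  # no full window at all
  bm2 <- body_median(reads, "chr1", IRanges(1301, 1500))
  expect_equal(bm2$n_windows, 0L)
  expect_true(is.na(bm2$body_median))

  # even number of windows: mean of the two central values
  bm3 <- body_median(reads_with_window_counts(c(0, 1, 3, 8), 1301L),
                     "chr1", IRanges(1301, 3700))
  expect_equal(bm3$body_median, 2)
})

test_that("stalling_index reproduces its closed form", {
  expect_equal(stalling_index(5, 5), 0)
  expect_equal(stalling_index(0, 0), 0)
  expect_equal(stalling_index(10, 1), log2(11 / 2))
  expect_equal(stalling_index(0, 7), -3)
  expect_equal(stalling_index(10, 1, pseudocount = 0.5), log2(10.5 / 1.5))
  expect_error(stalling_index(-1, 2), "non-negative")
  expect_error(stalling_index(1, 2, pseudocount = 0), "> 0")
})

test_that("si_table composes the per-gene operations", {
  genes <- c(make_gene("chr1", 10001, 16000, "+", "gA"),
             make_gene("chr1", 40001, 46000, "-", "gB"),
             make_gene("chr1", 70001, 70500, "+", "gShort"))
  set.seed(33)
  reads <- sort(c(random_reads(80, 7000L, 13000L),
                  random_reads(120, 37000L, 47000L)), ignore.strand = TRUE)
  tab <- si_table(genes, reads)
  expect_equal(tab$gene_id, c("gA", "gB", "gShort"))

  for (i in 1:2) {
    reg <- derive_regions(genes[i])
    P <- promoter_window_max(reads, "chr1", reg$tss)
    B <- body_median(reads, "chr1", reg$body)
    expect_equal(tab$promoter_max[i], as.integer(P))
    expect_equal(tab$body_median[i], B$body_median)
    expect_equal(tab$n_body_windows[i], B$n_windows)
    expect_equal(tab$si[i], stalling_index(P, B$body_median))
  }
  # short gene: flagged, excluded from the distribution
  expect_equal(tab$flag[3], "short_gene")
  expect_true(is.na(tab$si[3]))

  # empty read set: P = 0, B = 0, si = 0
  tab0 <- si_table(genes[1:2], GRanges())
  expect_equal(tab0$promoter_max, c(0L, 0L))
  expect_equal(tab0$body_median, c(0, 0))
  expect_equal(tab0$si, c(0, 0))
})

test_that("adding promoter reads raises SI, adding body reads lowers it", {
  gene <- make_gene("chr1", 10001, 16000, "+", "g")
  set.seed(44)
  reads <- random_reads(60, 7000L, 16000L)
  base <- si_table(gene, reads)

  # an extra promoter read leaves the body untouched and can only help the
  # best window
  up <- sort(c(reads, GRanges("chr1", IRanges(10001, 10040))),
             ignore.strand = TRUE)
  expect_gte(si_table(gene, up)$si, base$si)

  # on the count scale: a read in the best window never lowers SI, a read
  # in every body window (median + 1) never raises it
  grid <- expand.grid(P = c(0, 1, 5, 40, 200), B = c(0, 1, 3, 17))
  expect_true(all(stalling_index(grid$P + 1, grid$B) >=
                    stalling_index(grid$P, grid$B)))
  expect_true(all(stalling_index(grid$P, grid$B + 1) <=
                    stalling_index(grid$P, grid$B)))
})

test_that("SI is independent of gene size for equal window counts", {
  pat <- c(2, 0, 5, 1, 3)
  g1 <- make_gene("chr1", 10001, 10600 + 600 * length(pat), "+", "g")
  r1 <- reads_with_window_counts(pat, 10601L)
  g2 <- make_gene("chr1", 10001, 10600 + 600 * 2 * length(pat), "+", "g")
  r2 <- reads_with_window_counts(c(pat, pat), 10601L)
  t1 <- si_table(g1, sort(r1, ignore.strand = TRUE))
  t2 <- si_table(g2, sort(r2, ignore.strand = TRUE))
  expect_equal(t1$body_median, t2$body_median)
  expect_equal(t1$si, t2$si)
})

test_that("SI is invariant under a constant coordinate shift", {
  gene <- make_gene("chr1", 10001, 16000, "-", "g")
  set.seed(55)
  reads <- random_reads(80, 9000L, 19000L)
  t0 <- si_table(gene, reads)
  for (delta in c(137L, 5000L)) {
    t1 <- si_table(shift(gene, delta), shift(reads, delta))
    expect_equal(t1$si, t0$si)
    expect_equal(t1$promoter_max, t0$promoter_max)
    expect_equal(t1$body_median, t0$body_median)
  }
})
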