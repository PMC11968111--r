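test_that("intron-centered near-site clusters are excluded, others kept", {
  gm <- toyGeneModels()
  cl <- c(simpleClusters("chr1", 1090, 1110, "+"),   # exonic center
          simpleClusters("chr1", 1790, 1810, "+"),   # intronic center
          simpleClusters("chr1", 9000, 9020, "+"))   # intergenic center
  parts <- filterIntronicNearsite(cl, gm)
  expect_length(parts$kept, 2L)
  expect_length(parts$excluded, 1L)
  expect_equal(BiocGenerics::start(parts$excluded), 1790L)
})

test_that("adjustment distance is the read-weighted mean over single-TSS genes", {
  # two single-exon, single-TSS genes; clusters displaced 100 and 200 bp
  ex <- GenomicRanges::GRangesList(
    t1 = GenomicRanges::GRanges("chr1", IRanges::IRanges(10000, 12000),
                                strand = "+"),
    t2 = GenomicRanges::GRanges("chr1", IRanges::IRanges(30000, 32000),
                                strand = "+"))
  gm <- makeGeneModelSet(ex, c(t1 = "g1", t2 = "g2"))
  ann <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(10000, 30000), c(10000, 30000)), strand = "+")
  S4Vectors::mcols(ann)$gene_id <- c("g1", "g2")
  cl <- c(simpleClusters("chr1", 10100, 10100, "+", count = 10L),
          simpleClusters("chr1", 30200, 30200, "+", count = 30L))
  model <- learnAdjustmentDistance(cl, ann, gm)
  expect_equal(adjustmentDistance(model), (100 * 10 + 200 * 30) / 40)
  expect_equal(model@nGenes, 2L)

  # distances beyond 1,000 bp are dropped from the mean
  far <- c(cl, simpleClusters("chr1", 11500, 11500, "+", count = 100L))
  # gene g1 now has candidates at 100 and 1500; the smaller wins, so add
  # a third single-TSS gene whose only cluster is 1,500 bp away
  ex3 <- GenomicRanges::GRangesList(
    t1 = ex$t1, t2 = ex$t2,
    t3 = GenomicRanges::GRanges("chr1", IRanges::IRanges(50000, 52000),
                                strand = "+"))
  gm3 <- makeGeneModelSet(ex3, c(t1 = "g1", t2 = "g2", t3 = "g3"))
  ann3 <- c(ann, GenomicRanges::GRanges("chr1",
    IRanges::IRanges(50000, 50000), strand = "+"))
  S4Vectors::mcols(ann3)$gene_id <- c("g1", "g2", "g3")
  cl3 <- c(cl, simpleClusters("chr1", 51500, 51500, "+", count = 100L))
  model3 <- learnAdjustmentDistance(cl3, ann3, gm3)
  expect_equal(adjustmentDistance(model3), 175)  # g3 ignored
  expect_false(model3@samples$used[model3@samples$gene == "g3"])

  # single gene at distance zero
  model0 <- learnAdjustmentDistance(
    simpleClusters("chr1", 10000, 10000, "+", count = 5L), ann, gm)
  expect_equal(adjustmentDistance(model0), 0)

  # no usable gene: actionable error (seqlevel mismatch noise silenced)
  suppressWarnings(expect_error(learnAdjustmentDistance(
    simpleClusters("chr9", 1, 1, "+"), ann, gm), "manually"))
})

test_that("clusters shift 5' by the adjustment distance, intron-aware", {
  # single-exon transcript: transcript shift equals genomic shift
  ex <- GenomicRanges::GRangesList(
    t1 = GenomicRanges::GRanges("chr1", IRanges::IRanges(10000, 12000),
                                strand = "+"))
  gm <- makeGeneModelSet(ex, c(t1 = "g1"))
  cl <- simpleClusters("chr1", 10490, 10510, "+", gene = "g1")
  adj <- adjustClusters(cl, 175, gm)
  expect_equal(BiocGenerics::start(adj) + 10L, 10325L)  # center moved
  expect_equal(BiocGenerics::width(adj), BiocGenerics::width(cl))
  expect_equal(adj$origStart, 10490L)

  # two-exon transcript: shift crosses the intron
  ex2 <- GenomicRanges::GRangesList(
    tx1 = GenomicRanges::GRanges("chr1",
      IRanges::IRanges(c(10000, 20000), c(10100, 20200)), strand = "+"))
  gm2 <- makeGeneModelSet(ex2, c(tx1 = "g1"))
  cl2 <- simpleClusters("chr1", 20050, 20050, "+", gene = "g1")
  adj2 <- adjustClusters(cl2, 100, gm2)
  expect_equal(BiocGenerics::start(adj2), 10051L)

  # adjustment larger than the transcript offset clamps at the start
  adj3 <- adjustClusters(cl2, 5000, gm2)
  expect_equal(BiocGenerics::start(adj3), 10000L)

  # '-' strand: a 5' shift increases the genomic coordinate
  exm <- GenomicRanges::GRangesList(
    tm = GenomicRanges::GRanges("chr1", IRanges::IRanges(10000, 12000),
                                strand = "-"))
  gmm <- makeGeneModelSet(exm, c(tm = "g1"))
  clm <- simpleClusters("chr1", 11000, 11000, "-", gene = "g1")
  adjm <- adjustClusters(clm, 200, gmm)
  expect_equal(BiocGenerics::start(adjm), 11200L)

  # adjusted center never moves 3' of the original
  expect_lte(BiocGenerics::start(adj2), 20050L)

  # outside every exon: genomic fallback with a warning
  clOut <- simpleClusters("chr1", 30000, 30000, "+", gene = "g1")
  expect_warning(adjOut <- adjustClusters(clOut, 100, gm2), "genomic")
  expect_equal(BiocGenerics::start(adjOut), 29900L)
})

test_that("transcript-space and genomic shifts agree when no intron intervenes", {
  set.seed(5)
  for (rep in 1:20) {
    w <- sample(2000:5000, 1)
    st <- sample(c("+", "-"), 1)
    s0 <- sample(10000:50000, 1)
    ex <- GenomicRanges::GRangesList(
      tx = GenomicRanges::GRanges("chr1", IRanges::IRanges(s0, s0 + w),
                                  strand = st))
    gm <- makeGeneModelSet(ex, c(tx = "g"))
    ctr <- s0 + sample(500:(w - 500), 1)
    d <- sample(50:400, 1)
    cl <- simpleClusters("chr1", ctr, ctr, st, gene = "g")
    adj <- adjustClusters(cl, d, gm)
    expected <- if (st == "+") ctr - d else ctr + d
    expect_equal(BiocGenerics::start(adj), expected)
  }
})
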