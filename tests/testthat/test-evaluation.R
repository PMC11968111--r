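test_that("signed distances follow the 5'-positive convention", {
  expect_equal(signedDistance(980, 1000, "+"), 20)
  expect_equal(signedDistance(1020, 1000, "-"), 20)
  expect_equal(signedDistance(1000, 1000, "+"), 0)
  expect_equal(signedDistance(1020, 1000, "+"), -20)
})

singleTssSetup <- function() {
  ex <- GenomicRanges::GRangesList(
    t1 = GenomicRanges::GRanges("chr1", IRanges::IRanges(1000, 3000),
                                strand = "+"),
    t2 = GenomicRanges::GRanges("chr1", IRanges::IRanges(8000, 10000),
                                strand = "-"))
  gm <- makeGeneModelSet(ex, c(t1 = "g1", t2 = "g2"))
  ann <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(1000, 10000), c(1000, 10000)),
    strand = c("+", "-"))
  S4Vectors::mcols(ann)$gene_id <- c("g1", "g2")
  list(gm = gm, ann = ann)
}

test_that("distance distributions summarize single-TSS genes inside the window", {
  s <- singleTssSetup()
  cl <- c(simpleClusters("chr1", 890, 910, "+", dominant = 900,
                         gene = "g1"),
          simpleClusters("chr1", 10090, 10110, "-", dominant = 10100,
                         gene = "g2"))
  dd <- distanceDistribution(cl, s$ann, mode = "dominant")
  # +100 on both: predicted 5' of annotation on each strand
  expect_equal(sort(dd$distances$distance), c(100, 100))
  expect_equal(dd$mean, 100)

  # opposite displacements: mean 0, sample sd (n-1) = 141.4
  cl2 <- c(simpleClusters("chr1", 890, 910, "+", dominant = 900,
                          gene = "g1"),
           simpleClusters("chr1", 9890, 9910, "-", dominant = 9900,
                          gene = "g2"))
  dd2 <- distanceDistribution(cl2, s$ann, mode = "dominant")
  expect_equal(dd2$mean, 0)
  expect_equal(dd2$sd, sd(c(100, -100)))
  expect_equal(round(dd2$sd, 1), 141.4)

  # beyond the window: excluded
  cl3 <- simpleClusters("chr1", 390, 410, "+", dominant = 400,
                        gene = "g1")
  dd3 <- distanceDistribution(cl3, s$ann, window = 500)
  expect_equal(nrow(dd3$distances), 0L)

  # exact predictions: mean 0, sd 0
  cl4 <- c(simpleClusters("chr1", 990, 1010, "+", dominant = 1000,
                          gene = "g1"),
           simpleClusters("chr1", 9990, 10010, "-", dominant = 10000,
                          gene = "g2"))
  dd4 <- distanceDistribution(cl4, s$ann)
  expect_equal(dd4$mean, 0)
  expect_equal(dd4$sd, 0)
})

test_that("a constant displacement shifts the mean and zeroes the sd", {
  s <- singleTssSetup()
  k <- 37
  cl <- c(simpleClusters("chr1", 1000 - k, 1000 - k, "+",
                         dominant = 1000 - k, gene = "g1"),
          simpleClusters("chr1", 10000 + k, 10000 + k, "-",
                         dominant = 10000 + k, gene = "g2"))
  dd <- distanceDistribution(cl, s$ann)
  expect_equal(dd$mean, k)
  expect_equal(dd$sd, 0)
})

test_that("precision/recall/F1 match hand-computed gene-level tables", {
  s <- singleTssSetup()
  # perfect predictions: P = R = F1 = 1
  perfect <- c(simpleClusters("chr1", 995, 1005, "+", gene = "g1"),
               simpleClusters("chr1", 9995, 10005, "-", gene = "g2"))
  acc <- precisionRecallF1(perfect, s$ann)
  expect_equal(acc$precision, 1)
  expect_equal(acc$recall, 1)
  expect_equal(acc$f1, 1)

  # g1: two predictions, one overlapping its only annotated TSS
  two <- c(simpleClusters("chr1", c(995, 2000), c(1005, 2050), "+",
                          gene = c("g1", "g1")),
           simpleClusters("chr1", 9995, 10005, "-", gene = "g2"))
  acc2 <- precisionRecallF1(two, s$ann)
  g1row <- acc2$perGene[acc2$perGene$gene == "g1", ]
  expect_equal(g1row$precision, 0.5)
  expect_equal(g1row$recall, 1)
  expect_equal(acc2$precision, mean(c(0.5, 1)))
  expect_equal(acc2$f1,
               2 * acc2$precision * acc2$recall /
                 (acc2$precision + acc2$recall))

  # F1 at P = 0.5, R = 0.5 is 0.5
  expect_equal(2 * 0.5 * 0.5 / (0.5 + 0.5), 0.5)

  # a gene with no predictions contributes recall 0 but no precision term
  only1 <- simpleClusters("chr1", 995, 1005, "+", gene = "g1")
  acc3 <- precisionRecallF1(only1, s$ann)
  expect_equal(acc3$precision, 1)
  expect_equal(acc3$recall, 0.5)

  # zero precision and recall: F1 defined as 0
  off <- simpleClusters("chr1", 2000, 2050, "+", gene = "g1")
  acc4 <- precisionRecallF1(off, s$ann)
  expect_equal(acc4$f1, 0)
})

test_that("recall never decreases as predicted clusters widen", {
  s <- singleTssSetup()
  base <- simpleClusters("chr1", 1100, 1150, "+", gene = "g1")
  wide <- simpleClusters("chr1", 950, 1300, "+", gene = "g1")
  expect_gte(precisionRecallF1(wide, s$ann)$recall,
             precisionRecallF1(base, s$ann)$recall)
})

test_that("category summaries partition clusters and reads", {
  gm <- toyGeneModels()
  cl <- c(simpleClusters("chr1", 1090, 1110, "+", count = 30L,
                         dominant = 1100),
          simpleClusters("chr1", 2290, 2310, "+", count = 70L,
                         dominant = 2300))
  cs <- categoryUsageSummary(cl, gm, mode = "dominant")
  expect_equal(sum(cs$clusterFraction), 1)
  expect_equal(sum(cs$readFraction), 1)
  expect_equal(cs$readFraction[cs$category == "five_prime_most_exon"],
               0.3)
  expect_equal(cs$readFraction[cs$category == "other_exon"], 0.7)

  allFirst <- simpleClusters("chr1", 1090, 1110, "+", count = 10L,
                             dominant = 1100)
  csf <- categoryUsageSummary(allFirst, gm)
  expect_equal(
    csf$clusterFraction[csf$category == "five_prime_most_exon"], 1)
})
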