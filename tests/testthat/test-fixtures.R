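test_that("synthetic annotations are deterministic and respect the multi-TSS fraction", {
  g1 <- makeAnnotation(nGenes = 10, multiTssFraction = 0.5, seed = 4)
  g2 <- makeAnnotation(nGenes = 10, multiTssFraction = 0.5, seed = 4)
  expect_identical(BiocGenerics::start(g1$tss), BiocGenerics::start(g2$tss))
  expect_identical(g1$usage, g2$usage)

  none <- makeAnnotation(nGenes = 10, multiTssFraction = 0, seed = 1)
  expect_equal(length(none$tss), 10L)
  all2 <- makeAnnotation(nGenes = 10, multiTssFraction = 1, seed = 1)
  perGene <- table(all2$tss$gene_id)
  expect_true(all(perGene >= 2))

  # genes never overlap and every true TSS is its transcript's 5' end
  gm <- g1$geneModels
  spans <- gm@geneSpan
  ov <- GenomicRanges::findOverlaps(spans, spans, ignore.strand = TRUE)
  expect_equal(length(ov), length(spans))
  expect_identical(unname(gm@txTss[g1$tss$transcript_id]),
                   BiocGenerics::start(g1$tss))

  # files round-trip through the standard parsers
  dir <- withr::local_tempdir()
  gWritten <- makeAnnotation(nGenes = 5, seed = 9, dir = dir)
  back <- readGeneModels(file.path(dir, "annotation.gtf"))
  expect_setequal(geneIds(back), geneIds(gWritten$geneModels))
  annBack <- readTssAnnotation(file.path(dir, "true_tss.bed"))
  expect_setequal(BiocGenerics::start(annBack),
                  BiocGenerics::start(gWritten$tss))
})

test_that("on-site reads sit exactly at true TSSs when jitter is zero", {
  genome <- makeAnnotation(nGenes = 8, multiTssFraction = 0.4, seed = 2)
  tabs <- makeOnsiteReads(genome, nSamples = 1, cellsPerSample = 5,
                          readsPerCell = 40, tssJitterSd = 0, seed = 3)
  tab <- tabs[[1]]
  expect_true(all(BiocGenerics::start(tab) %in%
                    BiocGenerics::start(genome$tss)))
  # per-cell totals equal readsPerCell
  perCell <- tapply(tab$count, tab$barcode, sum)
  expect_true(all(perCell == 40))
})

test_that("near-site reads are displaced 3' in transcript space and stay exonic", {
  genome <- makeAnnotation(nGenes = 10, multiTssFraction = 0.3, seed = 6)
  tabs <- makeNearsiteReads(genome, nSamples = 1, cellsPerSample = 10,
                            readsPerCell = 60, displacementMean = 150,
                            displacementSd = 40, seed = 8)
  tab <- tabs[[1]]
  gm <- genome$geneModels
  cats <- classifyPosition(GenomicRanges::granges(tab), gm)
  expect_true(all(cats %in% c("five_prime_most_exon", "other_exon")))
  # reproducibility
  tabs2 <- makeNearsiteReads(genome, nSamples = 1, cellsPerSample = 10,
                             readsPerCell = 60, displacementMean = 150,
                             displacementSd = 40, seed = 8)
  expect_identical(BiocGenerics::start(tabs2[[1]]),
                   BiocGenerics::start(tab))
})

test_that("the on-site pipeline recovers true TSSs as dominant positions", {
  genome <- makeAnnotation(nGenes = 15, multiTssFraction = 0.3, seed = 10)
  tabs <- makeOnsiteReads(genome, nSamples = 2, cellsPerSample = 20,
                          readsPerCell = 150, tssJitterSd = 3, seed = 11)
  cls <- lapply(names(tabs), function(s)
    clusterTss(tabs[[s]], sampleId = s))
  dom <- unique(unlist(lapply(cls, function(cl) cl$dominantPos)))
  trueTss <- BiocGenerics::start(genome$tss)
  hit <- vapply(trueTss, function(t) any(abs(dom - t) <= 2), logical(1))
  expect_gte(mean(hit), 0.95)
})

test_that("quantified usage matches the generator's true usage within sampling error", {
  genome <- makeAnnotation(nGenes = 12, multiTssFraction = 1, seed = 20)
  tabs <- makeOnsiteReads(genome, nSamples = 2, cellsPerSample = 25,
                          readsPerCell = 400, tssJitterSd = 2, seed = 21)
  cls <- lapply(names(tabs), function(s)
    clusterTss(tabs[[s]], sampleId = s))
  unified <- mergeClustersDisjoin(cls)
  unified <- assignGene(unified, genome$geneModels, at = "midpoint")
  mats <- lapply(names(tabs), function(s)
    quantifyClusters(tabs[[s]], unified, sampleId = s))
  comb <- combineSamples(mats)
  counts <- SummarizedExperiment::assay(comb)
  gene <- geneOf(comb)
  gt <- geneTotals(comb)
  # per gene: the cluster containing each true TSS should capture that
  # transcript's usage share, pooled over cells
  for (g in unique(genome$tss$gene_id)) {
    gTss <- genome$tss[genome$tss$gene_id == g]
    rows <- which(!is.na(gene) & gene == g)
    if (!length(rows) || sum(gt[g, ]) < 500) next
    for (k in seq_along(gTss)) {
      pos <- BiocGenerics::start(gTss)[k]
      inCluster <- rows[BiocGenerics::start(unified[rows]) - 5 <= pos &
                          BiocGenerics::end(unified[rows]) + 5 >= pos]
      if (!length(inCluster)) next
      est <- sum(counts[inCluster, ]) / sum(gt[g, ])
      truth <- genome$usage[gTss$transcript_id[k]]
      expect_lt(abs(est - unname(truth)), 0.1)
    }
  }
})

test_that("near-site adjustment brings cluster centers closer to true TSSs", {
  genome <- makeAnnotation(nGenes = 15, multiTssFraction = 0, seed = 30)
  tabs <- makeNearsiteReads(genome, nSamples = 1, cellsPerSample = 20,
                            readsPerCell = 200, displacementMean = 150,
                            displacementSd = 30, seed = 31)
  gm <- genome$geneModels
  cl <- clusterTss(tabs[[1]], maxGap = 50, sampleId = "s1")
  cl <- filterIntronicNearsite(cl, gm)$kept
  cl <- assignGene(cl, gm, at = "center")
  model <- learnAdjustmentDistance(cl, genome$tss, gm)
  expect_equal(adjustmentDistance(model), 150, tolerance = 0.15)
  adj <- suppressWarnings(adjustClusters(cl, model, gm))
  trueOf <- function(centers, genes) {
    vapply(seq_along(centers), function(i) {
      t <- genome$tss[genome$tss$gene_id == genes[i]]
      min(abs(BiocGenerics::start(t) - centers[i]))
    }, numeric(1))
  }
  keep <- !is.na(cl$gene_id)
  before <- trueOf(clusterCenters(cl)[keep], cl$gene_id[keep])
  after <- trueOf(clusterCenters(adj)[keep], adj$gene_id[keep])
  expect_lt(median(after), median(before))
})

test_that("a deterministic displacement is learned back exactly", {
  genome <- makeAnnotation(nGenes = 10, multiTssFraction = 0, seed = 40)
  tabs <- makeNearsiteReads(genome, nSamples = 1, cellsPerSample = 10,
                            readsPerCell = 50, displacementMean = 120,
                            displacementSd = 0, seed = 41)
  gm <- genome$geneModels
  cl <- clusterTss(tabs[[1]], sampleId = "s1")
  cl <- filterIntronicNearsite(cl, gm)$kept
  cl <- assignGene(cl, gm, at = "center")
  model <- learnAdjustmentDistance(cl, genome$tss, gm)
  expect_equal(adjustmentDistance(model), 120)
})
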