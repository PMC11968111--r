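# Hand-built gene models used across tests.
#
# geneA (+, chr1): two transcripts
#   txA1: exons 1000-1600, 2200-2500   (TSS 1000)
#   txA2: exon  1300-1600, 2200-2500   (TSS 1300)
# geneB (-, chr1): one transcript
#   txB1: exons 5000-5300, 6000-6500   (TSS 6500)
# geneC (+, chr2): single exon 100-900 (TSS 100)
toyGeneModels <- function() {
  ex <- GenomicRanges::GRangesList(
    txA1 = GenomicRanges::GRanges("chr1",
      IRanges::IRanges(c(1000, 2200), c(1600, 2500)), strand = "+"),
    txA2 = GenomicRanges::GRanges("chr1",
      IRanges::IRanges(c(1300, 2200), c(1600, 2500)), strand = "+"),
    txB1 = GenomicRanges::GRanges("chr1",
      IRanges::IRanges(c(5000, 6000), c(5300, 6500)), strand = "-"),
    txC1 = GenomicRanges::GRanges("chr2",
      IRanges::IRanges(100, 900), strand = "+"))
  makeGeneModelSet(ex, c(txA1 = "geneA", txA2 = "geneA",
                         txB1 = "geneB", txC1 = "geneC"))
}

toyTssAnnotation <- function() {
  gr <- GenomicRanges::GRanges(
    c("chr1", "chr1", "chr1", "chr2"),
    IRanges::IRanges(c(1000, 1300, 6500, 100), c(1000, 1300, 6500, 100)),
    strand = c("+", "+", "-", "+"))
  S4Vectors::mcols(gr)$gene_id <- c("geneA", "geneA", "geneB", "geneC")
  gr
}

mappedTss <- function(chrom, pos, count, strand, barcode = NULL) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos),
                               strand = strand)
  S4Vectors::mcols(gr)$count <- as.integer(count)
  if (!is.null(barcode)) S4Vectors::mcols(gr)$barcode <- barcode
  gr
}

simpleClusters <- function(chrom, start, end, strand, count = 10L,
                           dominant = NULL, gene = NULL) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                               strand = strand)
  S4Vectors::mcols(gr)$totalCount <- as.integer(rep_len(count, length(gr)))
  S4Vectors::mcols(gr)$dominantPos <-
    if (is.null(dominant)) as.integer(round((start + end) / 2)) else
      as.integer(dominant)
  if (!is.null(gene)) S4Vectors::mcols(gr)$gene_id <- gene
  names(gr) <- paste0(chrom, ":", start, "-", end, ":", strand)
  gr
}
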