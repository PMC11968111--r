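#' @include AllClasses.R gene-models.R
NULL

## Deterministic synthetic-data generators: a toy genome with known gene
## models and true TSSs, plus on-site and near-site read tables with known
## per-gene usage, so the whole pipeline is testable without downloads.

#' Build a synthetic annotation with known true TSSs
#'
#' Lays out non-overlapping genes with 1-3 exons on a synthetic
#' chromosome, alternating strands. A fraction of genes get a second
#' transcript whose start lies 150-400 bp (transcript space) downstream
#' inside the first exon, giving the gene two true TSSs. Deterministic
#' under \code{seed}.
#'
#' @param nGenes number of genes.
#' @param multiTssFraction fraction of genes with two TSSs.
#' @param seed RNG seed.
#' @param dir if given, a GTF (\code{annotation.gtf}) and TSS BED
#'   (\code{true_tss.bed}) are written there.
#' @return list: \code{geneModels} ([GeneModelSet-class]), \code{tss}
#'   (\code{GRanges} of true TSSs with \code{gene_id} and
#'   \code{transcript_id}), \code{geneWeights} (relative expression
#'   weights), and \code{usage} (per-transcript true usage, summing to 1
#'   per gene).
#' @export
makeAnnotation <- function(nGenes = 20L, multiTssFraction = 0.3,
                           seed = 1L, dir = NULL) {
  set.seed(seed)
  cursor <- 10000L
  exList <- list()
  txGene <- character()
  strands <- rep(c("+", "-"), length.out = nGenes)
  usage <- numeric(); usageTx <- character()
  multi <- stats::runif(nGenes) < multiTssFraction
  for (g in seq_len(nGenes)) {
    gid <- sprintf("gene%03d", g)
    nEx <- sample(1:3, 1L)
    st <- strands[g]
    exW <- c(sample(500:700, 1L), sample(200:400, nEx))[seq_len(nEx)]
    if (st == "-") exW <- rev(exW)  # 5'-most exon (genomic-last) is wide
    intronW <- if (nEx > 1L) sample(300:800, nEx - 1L, replace = TRUE)
      else integer()
    starts <- cursor + cumsum(c(0L, exW[-nEx] + intronW))
    ends <- starts + exW - 1L
    ex <- GenomicRanges::GRanges("chrS1", IRanges::IRanges(starts, ends),
                                 strand = st)
    tx1 <- paste0(gid, ".1")
    exList[[tx1]] <- ex
    txGene[tx1] <- gid
    if (multi[g]) {
      off <- sample(150:400, 1L)  # second TSS inside exon 1 (width >= 500)
      s2 <- starts; e2 <- ends
      if (st == "+") s2[1L] <- starts[1L] + off else
        e2[nEx] <- ends[nEx] - off
      ex2 <- GenomicRanges::GRanges("chrS1", IRanges::IRanges(s2, e2),
                                    strand = st)
      tx2 <- paste0(gid, ".2")
      exList[[tx2]] <- ex2
      txGene[tx2] <- gid
      u <- stats::runif(1L, 0.3, 0.7)
      usage <- c(usage, u, 1 - u)
      usageTx <- c(usageTx, tx1, tx2)
    } else {
      usage <- c(usage, 1)
      usageTx <- c(usageTx, tx1)
    }
    cursor <- ends[nEx] + sample(3000:6000, 1L)
  }
  gm <- makeGeneModelSet(GenomicRanges::GRangesList(exList), txGene)
  names(usage) <- usageTx
  txs <- names(gm@exons)
  tss <- GenomicRanges::GRanges(
    "chrS1", IRanges::IRanges(gm@txTss[txs], gm@txTss[txs]),
    strand = vapply(txs, function(tx)
      as.character(BiocGenerics::strand(gm@exons[[tx]])[1L]), character(1)))
  S4Vectors::mcols(tss)$gene_id <- unname(gm@txGene[txs])
  S4Vectors::mcols(tss)$transcript_id <- txs
  geneWeights <- stats::setNames(
    stats::rlnorm(nGenes, meanlog = 0, sdlog = 0.6), geneIds(gm))
  out <- list(geneModels = gm, tss = tss, geneWeights = geneWeights,
              usage = usage[txs])
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeGtf(gm, file.path(dir, "annotation.gtf"))
    writeTssAnnotation(tss, file.path(dir, "true_tss.bed"))
    out$files <- c(gtf = file.path(dir, "annotation.gtf"),
                   tss = file.path(dir, "true_tss.bed"))
  }
  out
}

#' Write a GeneModelSet as GTF
#'
#' @param gm a [GeneModelSet-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGtf <- function(gm, path) {
  ex <- BiocGenerics::unlist(gm@exons)
  S4Vectors::mcols(ex) <- S4Vectors::DataFrame(
    source = "tssUsage", type = "exon",
    gene_id = unname(gm@txGene[names(ex)]),
    transcript_id = names(ex))
  names(ex) <- NULL
  rtracklayer::export(ex, path, format = "gtf")
  invisible(path)
}

## draw transcripts for reads: gene weight x within-gene usage
drawTranscripts <- function(genome, n) {
  txs <- names(genome$geneModels@exons)
  w <- genome$geneWeights[genome$geneModels@txGene[txs]] *
    genome$usage[txs]
  sample(txs, n, replace = TRUE, prob = w)
}

barcodeOf <- function(i) sprintf("%04d-1", i)

#' Generate barcoded on-site read tables
#'
#' Emulates paired-end 5' data in which the 5' end of Read 1 captures the
#' genuine TSS: each read's position is its transcript's true TSS plus
#' rounded Gaussian jitter. Every cell receives exactly
#' \code{readsPerCell} reads.
#'
#' @param genome output of [makeAnnotation()].
#' @param nSamples number of samples.
#' @param cellsPerSample,readsPerCell cells per sample and reads per cell.
#' @param tssJitterSd Gaussian jitter SD in bp (0 = exact TSS positions).
#' @param seed RNG seed.
#' @param dir if given, per-sample mapped-TSS tables
#'   (\code{sample<j>.tsv}) are written there.
#' @return list of per-sample barcoded mapped-TSS \code{GRanges} (names
#'   \code{sample1}, ...), with the generating \code{genome} attached as
#'   an attribute.
#' @export
makeOnsiteReads <- function(genome, nSamples = 2L, cellsPerSample = 30L,
                            readsPerCell = 100L, tssJitterSd = 0,
                            seed = 1L, dir = NULL) {
  set.seed(seed)
  gm <- genome$geneModels
  tables <- vector("list", nSamples)
  for (sIdx in seq_len(nSamples)) {
    n <- cellsPerSample * readsPerCell
    txs <- drawTranscripts(genome, n)
    pos <- unname(gm@txTss[txs])
    if (tssJitterSd > 0)
      pos <- pmax(1L, pos + as.integer(round(stats::rnorm(n, 0,
                                                          tssJitterSd))))
    strand <- vapply(txs, function(tx)
      as.character(BiocGenerics::strand(gm@exons[[tx]])[1L]), character(1))
    gr <- GenomicRanges::GRanges("chrS1", IRanges::IRanges(pos, pos),
                                 strand = strand)
    S4Vectors::mcols(gr)$count <- 1L
    S4Vectors::mcols(gr)$barcode <-
      barcodeOf(rep(seq_len(cellsPerSample), each = readsPerCell))
    tables[[sIdx]] <- aggregateMappedTss(gr)
  }
  names(tables) <- paste0("sample", seq_len(nSamples))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (sIdx in seq_len(nSamples))
      writeMappedTss(tables[[sIdx]],
                     file.path(dir, paste0("sample", sIdx, ".tsv")))
  }
  attr(tables, "genome") <- genome
  tables
}

#' Generate barcoded near-site read tables
#'
#' Emulates single-end 5' data in which only Read 2 carries cDNA: each
#' read's 5' end is displaced 3' of the true TSS by
#' \code{|N(displacementMean, displacementSd)|} in transcript
#' coordinates (clamped at the transcript 3' end) and projected back to
#' the genome through the exon chain, so displaced positions are always
#' exonic.
#'
#' @inheritParams makeOnsiteReads
#' @param displacementMean,displacementSd displacement distribution in bp
#'   of transcript space.
#' @return as [makeOnsiteReads()].
#' @export
makeNearsiteReads <- function(genome, nSamples = 2L, cellsPerSample = 30L,
                              readsPerCell = 100L, displacementMean = 150,
                              displacementSd = 30, seed = 1L, dir = NULL) {
  set.seed(seed)
  gm <- genome$geneModels
  txLens <- stats::setNames(
    vapply(as.list(gm@exons), function(ex)
      sum(BiocGenerics::width(ex)), integer(1)), names(gm@exons))
  tables <- vector("list", nSamples)
  for (sIdx in seq_len(nSamples)) {
    n <- cellsPerSample * readsPerCell
    txs <- drawTranscripts(genome, n)
    disp <- if (displacementSd > 0)
      abs(stats::rnorm(n, displacementMean, displacementSd)) else
        rep(displacementMean, n)
    txPos <- pmin(1L + as.integer(round(disp)), txLens[txs])
    pos <- integer(n)
    for (tx in unique(txs)) {
      i <- which(txs == tx)
      pos[i] <- txToGenome(gm, tx, txPos[i])
    }
    strand <- vapply(txs, function(tx)
      as.character(BiocGenerics::strand(gm@exons[[tx]])[1L]), character(1))
    gr <- GenomicRanges::GRanges("chrS1", IRanges::IRanges(pos, pos),
                                 strand = strand)
    S4Vectors::mcols(gr)$count <- 1L
    S4Vectors::mcols(gr)$barcode <-
      barcodeOf(rep(seq_len(cellsPerSample), each = readsPerCell))
    tables[[sIdx]] <- aggregateMappedTss(gr)
  }
  names(tables) <- paste0("sample", seq_len(nSamples))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (sIdx in seq_len(nSamples))
      writeMappedTss(tables[[sIdx]],
                     file.path(dir, paste0("sample", sIdx, ".tsv")))
  }
  attr(tables, "genome") <- genome
  tables
}
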