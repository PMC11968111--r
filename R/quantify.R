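#' @include AllClasses.R clustering.R
#' @importFrom Matrix sparseMatrix
NULL

#' Quantify unified TSS clusters per cell
#'
#' Counts, for every cell, the UMIs whose mapped 5' end lies inside each
#' unified cluster (closed on both ends, strand-matched). For near-site
#' data the counting intervals are the original near-site intervals
#' (\code{origStart}/\code{origEnd} columns produced by
#' [adjustClusters()]) while the reported rows are the adjusted clusters,
#' in 1:1 correspondence. Records falling in no cluster are dropped and
#' tallied in \code{metadata()$dropped}.
#'
#' @param records barcoded mapped-TSS \code{GRanges} (a \code{barcode}
#'   column is required).
#' @param clusters unified cluster \code{GRanges} with \code{gene_id}; for
#'   on-site data the intervals must be non-overlapping per strand.
#' @param mode \code{"onsite"} or \code{"nearsite"}.
#' @param sampleId sample label recorded in the column data.
#' @return a [TssCountMatrix-class] (clusters x cells, sparse).
#' @export
quantifyClusters <- function(records, clusters,
                             mode = c("onsite", "nearsite"),
                             sampleId = "sample1") {
  mode <- match.arg(mode)
  if (is.null(records$barcode))
    stop("records carry no barcode column; per-cell quantification ",
         "requires barcoded input")
  if (is.null(clusters$gene_id))
    S4Vectors::mcols(clusters)$gene_id <- NA_character_
  if (mode == "nearsite") {
    if (is.null(clusters$origStart))
      stop("nearsite mode requires origStart/origEnd columns from ",
           "adjustClusters()")
    counting <- GenomicRanges::GRanges(
      GenomeInfoDb::seqnames(clusters),
      IRanges::IRanges(clusters$origStart, clusters$origEnd),
      strand = BiocGenerics::strand(clusters))
  } else {
    counting <- GenomicRanges::granges(clusters)
  }
  self <- GenomicRanges::findOverlaps(counting, counting,
                                      ignore.strand = FALSE)
  if (length(self) > length(counting))
    stop("counting intervals overlap within a strand; unified clusters ",
         "must come from mergeClustersDisjoin()")
  hits <- GenomicRanges::findOverlaps(records, counting,
                                      ignore.strand = FALSE)
  barcodes <- sort(unique(records$barcode))
  qh <- S4Vectors::queryHits(hits)
  counts <- Matrix::sparseMatrix(
    i = S4Vectors::subjectHits(hits),
    j = match(records$barcode[qh], barcodes),
    x = as.numeric(records$count[qh]),
    dims = c(length(clusters), length(barcodes)))
  rownames(counts) <- if (!is.null(names(clusters))) names(clusters) else
    as.character(seq_along(clusters))
  colnames(counts) <- barcodes
  dropped <- sum(records$count) - sum(counts)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowRanges = clusters,
    colData = S4Vectors::DataFrame(barcode = barcodes,
                                   sample_id = sampleId,
                                   row.names = barcodes))
  S4Vectors::metadata(se)$dropped <- dropped
  methods::new("TssCountMatrix", se)
}

#' Combine per-sample count matrices
#'
#' Column-binds [TssCountMatrix-class] objects quantified against the same
#' unified clusters; barcodes are prefixed by sample id to stay unique.
#'
#' @param matrices list of [TssCountMatrix-class] objects.
#' @return a single [TssCountMatrix-class].
#' @export
combineSamples <- function(matrices) {
  stopifnot(length(matrices) >= 1L)
  ref <- rownames(matrices[[1L]])
  for (m in matrices[-1L])
    if (!identical(rownames(m), ref))
      stop("all matrices must share the same unified clusters")
  out <- do.call(SummarizedExperiment::cbind, lapply(matrices, function(m) {
    colnames(m) <- paste(m$sample_id, m$barcode, sep = ":")
    m
  }))
  methods::new("TssCountMatrix", out)
}

#' Gene-level totals per cell
#'
#' Sums cluster counts over the clusters assigned to each gene; clusters
#' without a gene are excluded.
#'
#' @param tcm a [TssCountMatrix-class].
#' @return sparse gene x cell matrix.
#' @export
geneTotals <- function(tcm) {
  gene <- geneOf(tcm)
  keep <- !is.na(gene)
  counts <- SummarizedExperiment::assay(tcm, "counts")[keep, , drop = FALSE]
  gene <- gene[keep]
  genes <- sort(unique(gene))
  agg <- Matrix::sparseMatrix(i = match(gene, genes),
                              j = seq_along(gene), x = 1,
                              dims = c(length(genes), length(gene)))
  out <- agg %*% counts
  rownames(out) <- genes
  colnames(out) <- colnames(counts)
  out
}

#' TSS cluster usage
#'
#' The usage of cluster t on a gene is its count divided by the gene's
#' total over all its clusters. A zero gene total leaves the usage
#' undefined (\code{NA}).
#'
#' @param x non-negative count vector over the clusters of one gene (one
#'   cell or one pseudo-bulk sample).
#' @return numeric usage vector summing to 1, or all-\code{NA} when the
#'   total is zero.
#' @examples
#' computeUsage(c(30, 70))  # 0.3 0.7
#' @export
computeUsage <- function(x) {
  if (any(x < 0)) stop("counts must be non-negative")
  s <- sum(x)
  if (s == 0) return(rep(NA_real_, length(x)))
  x / s
}

#' Write / read a 10x-style count triplet
#'
#' Writes \code{matrix.mtx} (MatrixMarket), \code{barcodes.tsv}, and
#' \code{clusters.bed} into a directory; \code{readCountsMM} restores a
#' [TssCountMatrix-class] from such a directory.
#'
#' @param tcm a [TssCountMatrix-class].
#' @param dir output directory (created if missing).
#' @return \code{dir} (write) or a [TssCountMatrix-class] (read).
#' @export
writeCountsMM <- function(tcm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(SummarizedExperiment::assay(tcm, "counts"),
                              "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  utils::write.table(
    data.frame(barcode = tcm$barcode, sample_id = tcm$sample_id),
    file.path(dir, "barcodes.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  writeClustersBed(SummarizedExperiment::rowRanges(tcm),
                   file.path(dir, "clusters.bed"))
  invisible(dir)
}

#' @rdname writeCountsMM
#' @export
readCountsMM <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                        "CsparseMatrix")
  bc <- utils::read.table(file.path(dir, "barcodes.tsv"), sep = "\t",
                          stringsAsFactors = FALSE)
  clusters <- readClustersBed(file.path(dir, "clusters.bed"))
  if (is.null(clusters$gene_id))
    S4Vectors::mcols(clusters)$gene_id <- NA_character_
  rownames(counts) <- names(clusters)
  colnames(counts) <- bc[[1L]]
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), rowRanges = clusters,
    colData = S4Vectors::DataFrame(barcode = bc[[1L]],
                                   sample_id = bc[[2L]],
                                   row.names = bc[[1L]]))
  methods::new("TssCountMatrix", se)
}
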