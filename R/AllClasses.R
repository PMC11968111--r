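#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges GRangesList
#' @importFrom IRanges IRanges
NULL

#' Gene models: transcripts, exon chains, and transcript start positions
#'
#' A \code{GeneModelSet} holds the exon structure needed for strand-aware
#' classification of genomic positions and for projecting positions between
#' genomic and transcript coordinates. Exons of each transcript are stored
#' ordered 5' to 3' in transcript orientation (ascending starts on \code{+},
#' descending on \code{-}).
#'
#' @slot exons \code{GRangesList} of exons, one element per transcript,
#'   ordered 5' to 3'.
#' @slot txGene named \code{character}, transcript id to gene id.
#' @slot geneSpan \code{GRanges} named by gene id, spanning the gene's
#'   outermost exon coordinates.
#' @slot txTss named \code{integer}, genomic position of each transcript's
#'   5'-most base.
#'
#' @seealso [readGeneModels()], [makeGeneModelSet()], [classifyPosition()]
#' @export
setClass("GeneModelSet",
  slots = c(
    exons = "CompressedGRangesList",
    txGene = "character",
    geneSpan = "GRanges",
    txTss = "integer"
  )
)

setValidity("GeneModelSet", function(object) {
  msg <- character()
  txs <- names(object@exons)
  if (is.null(txs) || anyDuplicated(txs))
    msg <- c(msg, "exons must be named by unique transcript ids")
  if (!setequal(txs, names(object@txGene)))
    msg <- c(msg, "txGene must be named by the same transcript ids as exons")
  if (!setequal(txs, names(object@txTss)))
    msg <- c(msg, "txTss must be named by the same transcript ids as exons")
  if (!all(object@txGene %in% names(object@geneSpan)))
    msg <- c(msg, "every gene referenced in txGene needs a geneSpan entry")
  nStrand <- sum(vapply(runValue(strand(object@exons)), function(s)
    length(unique(s)) > 1L, logical(1)))
  if (nStrand > 0)
    msg <- c(msg, "all exons of a transcript must share one strand")
  if (length(msg)) msg else TRUE
})

#' Learned near-site adjustment distance
#'
#' Result of [learnAdjustmentDistance()]: the read-weighted mean
#' transcript-space distance between near-site cluster centers and annotated
#' TSSs of single-TSS genes, together with the per-gene distance samples it
#' was computed from.
#'
#' @slot distance non-negative numeric, the weighted mean adjustment
#'   distance in bp.
#' @slot nGenes number of genes contributing to the mean (distance within
#'   the retention horizon).
#' @slot samples \code{data.frame} with one row per candidate gene:
#'   \code{gene}, \code{distance} (bp), \code{weight} (supporting reads),
#'   \code{used} (logical, retained in the mean).
#'
#' @export
setClass("AdjustmentModel",
  slots = c(
    distance = "numeric",
    nGenes = "integer",
    samples = "data.frame"
  )
)

setValidity("AdjustmentModel", function(object) {
  msg <- character()
  if (length(object@distance) != 1L || is.na(object@distance) ||
      object@distance < 0)
    msg <- c(msg, "distance must be a single non-negative number")
  need <- c("gene", "distance", "weight", "used")
  if (!all(need %in% names(object@samples)))
    msg <- c(msg, paste("samples must have columns:",
                        paste(need, collapse = ", ")))
  else if (any(object@samples$weight[object@samples$used] <= 0))
    msg <- c(msg, "weights of used samples must be positive")
  if (length(msg)) msg else TRUE
})

#' Cluster-by-cell count matrix for one or more samples
#'
#' A thin extension of \code{SummarizedExperiment} holding sparse UMI counts
#' of unified TSS clusters (rows) per cell (columns). Row ranges are the
#' cluster intervals with their gene assignment in \code{gene_id}; column
#' data carry the cell \code{barcode} and \code{sample_id}.
#'
#' @seealso [quantifyClusters()], [geneTotals()], [testDifferentialUsage()]
#' @export
setClass("TssCountMatrix", contains = "RangedSummarizedExperiment")

setValidity("TssCountMatrix", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "a 'counts' assay is required")
  else if (min(SummarizedExperiment::assay(object, "counts")) < 0)
    msg <- c(msg, "counts must be non-negative")
  rr <- SummarizedExperiment::rowRanges(object)
  if (!"gene_id" %in% names(S4Vectors::mcols(rr)))
    msg <- c(msg, "rowRanges must carry a 'gene_id' column")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("barcode", "sample_id") %in% names(cd)))
    msg <- c(msg, "colData must carry 'barcode' and 'sample_id'")
  if (length(msg)) msg else TRUE
})

#' Simulation scenario for the differential-usage benchmark
#'
#' All knobs for one cell of the type-I-error/power benchmark: number of
#' samples per condition (\code{J}), cells per sample (\code{I}), null and
#' alternative gene counts, the outlier mixture (\code{piOutlier},
#' \code{c1}, \code{c2}), and the second Beta shape parameter governing
#' cell-level usage dispersion.
#'
#' @seealso [simScenario()], [simulateDuDataset()], [evaluateDuMethods()]
#' @export
setClass("SimScenario",
  slots = c(
    J = "integer", I = "integer",
    nNull = "integer", nAlt = "integer",
    piOutlier = "numeric", c1 = "numeric", c2 = "numeric",
    betaShape = "numeric",
    symmetricOutliers = "logical",
    seed = "integer"
  )
)

setValidity("SimScenario", function(object) {
  msg <- character()
  if (object@piOutlier < 0 || object@piOutlier > 1)
    msg <- c(msg, "piOutlier must be in [0, 1]")
  if (!(object@c1 > 0 && object@c1 < object@c2))
    msg <- c(msg, "need 0 < c1 < c2")
  if (object@J < 1L || object@I < 1L || object@nNull < 1L || object@nAlt < 1L)
    msg <- c(msg, "J, I, nNull, nAlt must all be >= 1")
  if (object@betaShape <= 0)
    msg <- c(msg, "betaShape must be positive")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GeneModelSet", function(object) {
  cat("GeneModelSet with", length(object@geneSpan), "genes,",
      length(object@exons), "transcripts\n")
  cat("  chromosomes:",
      paste(GenomeInfoDb::seqlevelsInUse(object@geneSpan), collapse = ", "),
      "\n")
})

setMethod("show", "AdjustmentModel", function(object) {
  cat("AdjustmentModel\n")
  cat(sprintf("  adjustment distance: %.2f bp\n", object@distance))
  cat(sprintf("  genes used: %d of %d candidates\n",
              object@nGenes, nrow(object@samples)))
})

setMethod("show", "SimScenario", function(object) {
  cat("SimScenario:",
      sprintf("J=%d samples/condition, I=%d cells/sample", object@J, object@I),
      "\n")
  cat(sprintf("  genes: %d null + %d alternative\n", object@nNull, object@nAlt))
  cat(sprintf("  outliers: pi=%.2f, deviation in [%.2f, %.2f]%s\n",
              object@piOutlier, object@c1, object@c2,
              if (object@symmetricOutliers) " (symmetric)" else ""))
  cat(sprintf("  cell-level Beta shape: %g, seed: %d\n",
              object@betaShape, object@seed))
})
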