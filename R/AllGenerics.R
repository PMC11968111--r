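#' @include AllClasses.R
NULL

#' Accessors for tssUsage classes
#'
#' Small accessor generics: \code{adjustmentDistance} extracts the learned
#' shift in bp from an [AdjustmentModel-class]; \code{adjustmentSamples}
#' the per-gene distance/weight table behind it; \code{geneOf} the
#' cluster-to-gene map of a [TssCountMatrix-class]; \code{clusterRanges}
#' its cluster intervals.
#'
#' @param object an object of the documented class.
#' @return \code{adjustmentDistance}: numeric scalar (bp).
#'   \code{adjustmentSamples}: \code{data.frame}. \code{geneOf}: character
#'   vector named by cluster. \code{clusterRanges}: \code{GRanges}.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("adjustmentDistance", function(object)
  standardGeneric("adjustmentDistance"))

#' @rdname accessors
#' @export
setGeneric("adjustmentSamples", function(object)
  standardGeneric("adjustmentSamples"))

#' @rdname accessors
#' @export
setGeneric("geneOf", function(object) standardGeneric("geneOf"))

#' @rdname accessors
#' @export
setGeneric("clusterRanges", function(object) standardGeneric("clusterRanges"))

#' @rdname accessors
#' @export
setMethod("adjustmentDistance", "AdjustmentModel",
          function(object) object@distance)

#' @rdname accessors
#' @export
setMethod("adjustmentSamples", "AdjustmentModel",
          function(object) object@samples)

#' @rdname accessors
#' @export
setMethod("geneOf", "TssCountMatrix", function(object) {
  rr <- SummarizedExperiment::rowRanges(object)
  stats::setNames(S4Vectors::mcols(rr)$gene_id, names(rr))
})

#' @rdname accessors
#' @export
setMethod("clusterRanges", "TssCountMatrix",
          function(object) SummarizedExperiment::rowRanges(object))

#' @rdname geneIds
#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))

#' Gene and transcript identifiers of a GeneModelSet
#'
#' @param object a [GeneModelSet-class].
#' @return character vector of gene ids (\code{geneIds}) or transcript ids
#'   (\code{transcriptIds}).
#' @name geneIds
#' @export
setMethod("geneIds", "GeneModelSet",
          function(object) names(object@geneSpan))

#' @rdname geneIds
#' @export
setGeneric("transcriptIds", function(object) standardGeneric("transcriptIds"))

#' @rdname geneIds
#' @export
setMethod("transcriptIds", "GeneModelSet",
          function(object) names(object@exons))
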