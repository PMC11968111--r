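#' @include AllClasses.R clustering.R gene-models.R
NULL

#' Signed distance between predicted and annotated TSS
#'
#' A positive distance means the prediction lies on the 5' side (upstream)
#' of the annotation: \code{annotated - predicted} on \code{+},
#' \code{predicted - annotated} on \code{-}.
#'
#' @param predicted,annotated genomic positions (same chromosome).
#' @param strand \code{"+"} or \code{"-"}, recycled.
#' @return integer vector of signed distances in bp.
#' @examples
#' signedDistance(980, 1000, "+")   # +20, predicted upstream
#' signedDistance(1020, 1000, "-")  # +20
#' @export
signedDistance <- function(predicted, annotated, strand) {
  ifelse(rep_len(strand, length(predicted)) == "+",
         annotated - predicted, predicted - annotated)
}

#' Distance distribution of predictions around annotated TSSs
#'
#' Restricted to genes with a single annotated TSS: for each cluster of
#' such a gene the signed distance from the cluster's reference point
#' (dominant TSS for on-site, read-weighted center for near-site data) to
#' the annotated TSS is collected; distances beyond \code{window} bp are
#' excluded as likely unannotated TSSs.
#'
#' @param clusters cluster \code{GRanges} carrying \code{gene_id} (and
#'   \code{dominantPos} when \code{mode = "dominant"}).
#' @param annotation TSS annotation \code{GRanges} with \code{gene_id}.
#' @param mode reference point: \code{"dominant"} or \code{"center"}.
#' @param window retention window in bp (default 500).
#' @return list with \code{distances} (data.frame: gene, cluster,
#'   distance), \code{mean}, and \code{sd} (sample SD, n - 1 denominator).
#' @export
distanceDistribution <- function(clusters, annotation,
                                 mode = c("dominant", "center"),
                                 window = 500) {
  mode <- match.arg(mode)
  annGene <- S4Vectors::mcols(annotation)$gene_id
  singleTss <- names(which(table(annGene) == 1L))
  if (!length(singleTss)) {
    warning("annotation contains no single-TSS gene")
    return(list(distances = data.frame(gene = character(),
                                       cluster = character(),
                                       distance = numeric()),
                mean = NA_real_, sd = NA_real_))
  }
  point <- if (mode == "dominant") clusters$dominantPos else
    clusterCenters(clusters)
  keep <- which(!is.na(clusters$gene_id) & clusters$gene_id %in% singleTss)
  rows <- lapply(keep, function(i) {
    g <- clusters$gene_id[i]
    annPos <- BiocGenerics::start(annotation[annGene == g])[1L]
    d <- signedDistance(point[i],
                        annPos,
                        as.character(BiocGenerics::strand(clusters)[i]))
    data.frame(gene = g,
               cluster = if (!is.null(names(clusters)))
                 names(clusters)[i] else as.character(i),
               distance = d)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), cluster = character(),
               distance = numeric())
  df <- df[abs(df$distance) <= window, , drop = FALSE]
  list(distances = df,
       mean = if (nrow(df)) mean(df$distance) else NA_real_,
       sd = if (nrow(df) > 1L) stats::sd(df$distance) else NA_real_)
}

#' Precision, recall, and F1 of cluster predictions
#'
#' Gene-level precision is the fraction of a gene's predicted clusters
#' whose interval overlaps one of its annotated TSS positions; gene-level
#' recall the fraction of its annotated TSSs contained in a predicted
#' cluster. Sample-level P and R are unweighted means over genes (a gene
#' with annotation but no predictions contributes recall 0 and no
#' precision term; genes without annotation are excluded), and
#' F1 = 2PR / (P + R), taken as 0 when P + R = 0.
#'
#' @param clusters predicted cluster \code{GRanges} with \code{gene_id}.
#' @param annotation TSS annotation \code{GRanges} with \code{gene_id}.
#' @return list: \code{precision}, \code{recall}, \code{f1}, and
#'   \code{perGene} (data.frame with gene-level terms).
#' @export
precisionRecallF1 <- function(clusters, annotation) {
  annGene <- S4Vectors::mcols(annotation)$gene_id
  genes <- sort(unique(annGene))
  perGene <- lapply(genes, function(g) {
    ann <- annotation[annGene == g]
    cl <- clusters[!is.na(clusters$gene_id) & clusters$gene_id == g]
    prec <- if (length(cl))
      mean(IRanges::overlapsAny(cl, ann, ignore.strand = FALSE)) else
        NA_real_
    rec <- if (length(cl))
      mean(IRanges::overlapsAny(ann, cl, ignore.strand = FALSE)) else 0
    data.frame(gene = g, nPredicted = length(cl), nAnnotated = length(ann),
               precision = prec, recall = rec)
  })
  perGene <- do.call(rbind, perGene)
  P <- mean(perGene$precision, na.rm = TRUE)
  R <- mean(perGene$recall)
  f1 <- if (is.na(P) || P + R == 0) 0 else 2 * P * R / (P + R)
  list(precision = P, recall = R, f1 = f1, perGene = perGene)
}

#' Genomic-category composition of clusters and their read usage
#'
#' Classifies each cluster's reference point with [classifyPosition()] and
#' reports, per category, the fraction of clusters and the fraction of
#' reads (cluster total counts); each set of fractions sums to 1.
#'
#' @param clusters cluster \code{GRanges} with \code{totalCount} (and
#'   \code{dominantPos} for \code{mode = "dominant"}).
#' @param gm a [GeneModelSet-class].
#' @param mode reference point: \code{"dominant"} or \code{"center"}.
#' @return data.frame with \code{category}, \code{clusterFraction},
#'   \code{readFraction}.
#' @export
categoryUsageSummary <- function(clusters, gm,
                                 mode = c("dominant", "center")) {
  mode <- match.arg(mode)
  point <- if (mode == "dominant") clusters$dominantPos else
    clusterCenters(clusters)
  cat4 <- classifyPosition(
    GenomicRanges::GRanges(GenomeInfoDb::seqnames(clusters),
                           IRanges::IRanges(point, point),
                           strand = BiocGenerics::strand(clusters)), gm)
  reads <- if (!is.null(clusters$totalCount))
    as.numeric(clusters$totalCount) else rep(1, length(clusters))
  data.frame(
    category = levels(cat4),
    clusterFraction = as.vector(table(cat4)) / length(cat4),
    readFraction = as.vector(tapply(reads, cat4, sum, default = 0)) /
      sum(reads))
}
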