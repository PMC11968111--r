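#' @include AllClasses.R gene-models.R clustering.R
NULL

## Near-site (single-end) data: only Read 2 carries cDNA, so clusters of
## Read-2 5' ends sit a roughly predictable distance 3' of the genuine TSS.
## The adjustment learns that distance from single-annotated-TSS genes and
## shifts clusters 5' in transcript coordinates so introns are skipped.

#' Exclude near-site clusters centered in introns
#'
#' A near-site cluster whose center lies in an intronic region points to a
#' missing annotation: the genuine TSS cannot be located, so the cluster is
#' excluded from adjustment and downstream analysis. Intergenic centers are
#' not intronic and are kept.
#'
#' @param clusters near-site cluster \code{GRanges}.
#' @param gm a [GeneModelSet-class].
#' @return list with elements \code{kept} and \code{excluded}.
#' @export
filterIntronicNearsite <- function(clusters, gm) {
  if (!length(clusters))
    return(list(kept = clusters, excluded = clusters))
  ctr <- clusterCenters(clusters)
  cat4 <- classifyPosition(
    GenomicRanges::GRanges(GenomeInfoDb::seqnames(clusters),
                           IRanges::IRanges(ctr, ctr),
                           strand = BiocGenerics::strand(clusters)), gm)
  intronic <- cat4 == "intron"
  list(kept = clusters[!intronic], excluded = clusters[intronic])
}

## Transcript of `gene` whose exons contain `pos` and whose annotated
## start is most 5' (maximal room for upstream shifting); NA if none.
chooseTranscript <- function(gm, gene, pos) {
  txs <- names(gm@txGene)[gm@txGene == gene]
  containing <- txs[vapply(txs, function(tx)
    !is.na(genomeToTx(gm, tx, pos)), logical(1))]
  if (!length(containing)) return(NA_character_)
  neg <- as.character(BiocGenerics::strand(gm@geneSpan[gene])) == "-"
  starts <- gm@txTss[containing]
  containing[if (neg) which.max(starts) else which.min(starts)]
}

#' Learn the near-site adjustment distance
#'
#' For every gene with a single annotated TSS, the smallest transcript-
#' coordinate distance between any near-site cluster center and the
#' annotated TSS is recorded, weighted by the reads supporting that
#' cluster. Distances beyond \code{maxDistance} (default 1,000 bp) are
#' dropped as likely unannotated TSSs, and the read-weighted mean of the
#' remaining distances is the adjustment distance.
#'
#' @param clusters near-site cluster \code{GRanges} (intronic centers
#'   already excluded), carrying \code{gene_id} assignments from
#'   [assignGene()] (assigned here if absent).
#' @param tssAnnotation \code{GRanges} of annotated TSS positions with
#'   \code{gene_id} (see [readTssAnnotation()]).
#' @param gm a [GeneModelSet-class].
#' @param maxDistance retention horizon in bp, applied in transcript
#'   coordinates.
#' @return an [AdjustmentModel-class].
#' @export
learnAdjustmentDistance <- function(clusters, tssAnnotation, gm,
                                    maxDistance = 1000) {
  if (is.null(clusters$gene_id))
    clusters <- assignGene(clusters, gm, at = "center")
  annGene <- S4Vectors::mcols(tssAnnotation)$gene_id
  singleTss <- names(which(table(annGene) == 1L))
  ctr <- clusterCenters(clusters)
  rows <- list()
  for (g in singleTss) {
    idx <- which(!is.na(clusters$gene_id) & clusters$gene_id == g)
    if (!length(idx)) next
    annPos <- BiocGenerics::start(tssAnnotation[annGene == g])[1L]
    dists <- vapply(idx, function(i) {
      tx <- chooseTranscript(gm, g, ctr[i])
      if (!is.na(tx)) {
        tAnn <- genomeToTx(gm, tx, annPos)
        tCtr <- genomeToTx(gm, tx, ctr[i])
        if (!is.na(tAnn) && !is.na(tCtr)) return(abs(tCtr - tAnn))
      }
      abs(ctr[i] - annPos)  # fall back to genomic distance
    }, numeric(1))
    best <- which.min(dists)
    rows[[g]] <- data.frame(gene = g, distance = dists[best],
                            weight = as.numeric(clusters$totalCount[idx[best]]))
  }
  if (!length(rows))
    stop("no single-annotated-TSS gene has a usable near-site cluster; ",
         "supply an adjustment distance manually via adjustClusters()")
  samples <- do.call(rbind, rows)
  rownames(samples) <- NULL
  samples$used <- samples$distance <= maxDistance
  if (!any(samples$used))
    stop("all candidate distances exceed ", maxDistance, " bp; ",
         "supply an adjustment distance manually via adjustClusters()")
  use <- samples[samples$used, ]
  dist <- sum(use$distance * use$weight) / sum(use$weight)
  methods::new("AdjustmentModel", distance = dist,
               nGenes = nrow(use), samples = samples)
}

#' Shift near-site clusters 5' by the adjustment distance
#'
#' Each cluster's center is projected into the coordinates of a transcript
#' of its assigned gene, shifted towards the 5' end by the adjustment
#' distance (clamped at transcript position 1), and projected back to the
#' genome, so introns between source and target are skipped. The adjusted
#' cluster keeps the original width, centered on the shifted position.
#' Clusters whose center falls in no exon of the chosen transcript (or with
#' no gene) are shifted in genomic coordinates with a warning.
#'
#' @param clusters near-site cluster \code{GRanges} with \code{gene_id}.
#' @param model an [AdjustmentModel-class], or a bare numeric distance in
#'   bp.
#' @param gm a [GeneModelSet-class].
#' @return adjusted clusters; original intervals are preserved in
#'   \code{origStart}/\code{origEnd} metadata columns so near-site
#'   quantification can count reads in the original intervals.
#' @export
adjustClusters <- function(clusters, model, gm) {
  dist <- if (methods::is(model, "AdjustmentModel"))
    adjustmentDistance(model) else as.numeric(model)
  stopifnot(length(dist) == 1L, dist >= 0)
  d <- as.integer(round(dist))
  if (!length(clusters)) return(clusters)
  if (is.null(clusters$gene_id))
    stop("clusters must carry gene_id; run assignGene() first")
  ctr <- clusterCenters(clusters)
  neg <- as.character(BiocGenerics::strand(clusters)) == "-"
  newCtr <- integer(length(clusters))
  nFallback <- 0L
  for (i in seq_along(clusters)) {
    g <- clusters$gene_id[i]
    tx <- if (!is.na(g)) chooseTranscript(gm, g, ctr[i]) else NA_character_
    if (!is.na(tx)) {
      tPos <- genomeToTx(gm, tx, ctr[i])
      tNew <- max(1L, tPos - d)  # 5' shift, clamped at transcript start
      newCtr[i] <- txToGenome(gm, tx, tNew)
    } else {
      nFallback <- nFallback + 1L
      newCtr[i] <- if (neg[i]) ctr[i] + d else max(1L, ctr[i] - d)
    }
  }
  if (nFallback > 0L)
    warning(nFallback, " cluster(s) outside any exon of their gene's ",
            "transcripts; shifted in genomic coordinates")
  w <- BiocGenerics::width(clusters)
  newStart <- pmax(1L, newCtr - as.integer(floor((w - 1L) / 2)))
  out <- clusters
  S4Vectors::mcols(out)$origStart <- BiocGenerics::start(clusters)
  S4Vectors::mcols(out)$origEnd <- BiocGenerics::end(clusters)
  delta <- newCtr - ctr
  if (!is.null(out$dominantPos))
    S4Vectors::mcols(out)$dominantPos <- out$dominantPos + delta
  ## per-position detail belongs to the original coordinates; drop it so
  ## centers of adjusted clusters are recomputed from the new interval
  S4Vectors::mcols(out)$posList <- NULL
  S4Vectors::mcols(out)$countList <- NULL
  IRanges::ranges(out) <- IRanges::IRanges(newStart, newStart + w - 1L)
  names(out) <- paste0(GenomeInfoDb::seqnames(out), ":",
                       BiocGenerics::start(out), "-",
                       BiocGenerics::end(out), ":",
                       BiocGenerics::strand(out))
  out
}
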