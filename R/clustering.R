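#' @include AllClasses.R gene-models.R
NULL

#' Distance-based clustering of mapped TSS positions
#'
#' Positions with at least \code{minPosCount} reads on the same chromosome
#' and strand are chained whenever consecutive kept positions are at most
#' \code{maxGap} bp apart; chains whose summed count reaches
#' \code{minClusterCount} become TSS clusters. The dominant TSS is the
#' position with the maximal count; ties break towards the 5' end in
#' transcript orientation (smallest coordinate on \code{+}, largest on
#' \code{-}).
#'
#' @param records \code{GRanges} of width-1 mapped TSS positions with a
#'   \code{count} column (a barcoded table is pooled over cells first).
#' @param maxGap maximum gap in bp between consecutive kept positions
#'   within one cluster.
#' @param minPosCount minimum read count for a position to enter a cluster.
#' @param minClusterCount minimum summed count for a chain to be reported.
#' @param sampleId optional sample label stored on each cluster.
#' @return \code{GRanges} of clusters with metadata columns
#'   \code{totalCount}, \code{dominantPos}, \code{posList}/\code{countList}
#'   (per-position detail as \code{IntegerList}s), and \code{sample_id}.
#' @seealso [mergeClustersDisjoin()], [assignGene()], [clusterCenters()]
#' @export
clusterTss <- function(records, maxGap = 20L, minPosCount = 3L,
                       minClusterCount = 5L, sampleId = NA_character_) {
  stopifnot(maxGap >= 0L)
  empty <- function() {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      totalCount = integer(), dominantPos = integer(),
      posList = IRanges::IntegerList(), countList = IRanges::IntegerList(),
      sample_id = character())
    gr
  }
  if (!length(records)) return(empty())
  if (!is.null(records$barcode)) {
    pooled <- records
    S4Vectors::mcols(pooled)$barcode <- NULL
    records <- aggregateMappedTss(pooled)
  } else {
    records <- aggregateMappedTss(records)
  }
  records <- records[records$count >= minPosCount]
  if (!length(records)) return(empty())
  chrom <- as.character(GenomeInfoDb::seqnames(records))
  strand <- as.character(BiocGenerics::strand(records))
  pos <- BiocGenerics::start(records)
  ord <- order(chrom, strand, pos)
  chrom <- chrom[ord]; strand <- strand[ord]; pos <- pos[ord]
  count <- records$count[ord]
  n <- length(pos)
  newChain <- c(TRUE, chrom[-1L] != chrom[-n] | strand[-1L] != strand[-n] |
                  pos[-1L] - pos[-n] > maxGap)
  chain <- cumsum(newChain)
  keepChain <- as.vector(rowsum(as.numeric(count), chain)) >= minClusterCount
  res <- lapply(which(keepChain), function(k) {
    i <- which(chain == k)
    p <- pos[i]; ct <- count[i]
    best <- which(ct == max(ct))
    dom <- if (strand[i[1L]] == "+") p[best[1L]] else p[best[length(best)]]
    list(chrom = chrom[i[1L]], strand = strand[i[1L]],
         start = p[1L], end = p[length(i)],
         total = sum(ct), dom = dom, p = p, ct = ct)
  })
  if (!length(res)) return(empty())
  gr <- GenomicRanges::GRanges(
    vapply(res, `[[`, character(1), "chrom"),
    IRanges::IRanges(vapply(res, `[[`, integer(1), "start"),
                     vapply(res, `[[`, integer(1), "end")),
    strand = vapply(res, `[[`, character(1), "strand"))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    totalCount = vapply(res, function(r) as.integer(r$total), integer(1)),
    dominantPos = vapply(res, `[[`, integer(1), "dom"),
    posList = IRanges::IntegerList(lapply(res, `[[`, "p")),
    countList = IRanges::IntegerList(lapply(res, `[[`, "ct")),
    sample_id = sampleId)
  names(gr) <- paste0(GenomeInfoDb::seqnames(gr), ":",
                      BiocGenerics::start(gr), "-", BiocGenerics::end(gr),
                      ":", BiocGenerics::strand(gr))
  gr
}

#' Read-weighted centers of TSS clusters
#'
#' The center of a cluster is the read-count-weighted mean of its per-
#' position counts, rounded to the nearest integer; clusters lacking
#' per-position detail fall back to the interval midpoint.
#'
#' @param clusters cluster \code{GRanges} from [clusterTss()].
#' @return integer vector of genomic center positions.
#' @export
clusterCenters <- function(clusters) {
  if (!length(clusters)) return(integer())
  if (is.null(clusters$posList)) {
    return(as.integer(round((BiocGenerics::start(clusters) +
                               BiocGenerics::end(clusters)) / 2)))
  }
  p <- clusters$posList
  ct <- clusters$countList
  vapply(seq_along(clusters), function(i) {
    if (!length(p[[i]]))
      return(as.integer(round((BiocGenerics::start(clusters)[i] +
                                 BiocGenerics::end(clusters)[i]) / 2)))
    as.integer(round(sum(as.numeric(p[[i]]) * ct[[i]]) / sum(ct[[i]])))
  }, integer(1))
}

#' Merge clusters across samples into unified non-overlapping intervals
#'
#' Clusters predicted per sample overlap imperfectly across samples; to make
#' them comparable the pooled intervals are partitioned into the minimal set
#' of disjoint intervals whose breakpoints include every input breakpoint
#' ("disjoin" semantics, computed with \code{GenomicRanges::disjoin}).
#' Strands never mix: \code{+} and \code{-} clusters are partitioned
#' separately.
#'
#' @param clustersBySample a list (or \code{GRangesList}) of per-sample
#'   cluster \code{GRanges}, or a single \code{GRanges} pooling them.
#' @return sorted \code{GRanges} of unified clusters, named
#'   \code{chrom:start-end:strand}.
#' @export
mergeClustersDisjoin <- function(clustersBySample) {
  if (methods::is(clustersBySample, "GRanges")) {
    pooled <- GenomicRanges::granges(clustersBySample)
  } else {
    pooled <- unlist(GenomicRanges::GRangesList(
      lapply(clustersBySample, GenomicRanges::granges)), use.names = FALSE)
  }
  out <- BiocGenerics::sort(GenomicRanges::disjoin(pooled,
                                                   ignore.strand = FALSE))
  names(out) <- paste0(GenomeInfoDb::seqnames(out), ":",
                       BiocGenerics::start(out), "-",
                       BiocGenerics::end(out), ":",
                       BiocGenerics::strand(out))
  out
}

#' Assign TSS clusters to genes
#'
#' A cluster is matched by its reference point (the dominant TSS for
#' on-site data, the read-weighted center for near-site data, or the
#' interval midpoint for unified clusters without per-position detail) to
#' the same-strand gene whose span, extended upstream by a promoter window,
#' contains the point. When several genes qualify the one whose nearest
#' annotated transcript start is closest to the point wins. Unmatched
#' clusters receive \code{NA} and are excluded from usage computation.
#'
#' @param clusters cluster \code{GRanges}.
#' @param gm a [GeneModelSet-class].
#' @param promoterWindow upstream extension of gene spans in bp.
#' @param at reference point: \code{"dominant"}, \code{"center"}, or
#'   \code{"midpoint"}.
#' @return the input with a \code{gene_id} metadata column added.
#' @export
assignGene <- function(clusters, gm, promoterWindow = 1000L,
                       at = c("dominant", "center", "midpoint")) {
  at <- match.arg(at)
  if (!length(clusters)) {
    S4Vectors::mcols(clusters)$gene_id <- character()
    return(clusters)
  }
  point <- switch(at,
    dominant = clusters$dominantPos,
    center = clusterCenters(clusters),
    midpoint = as.integer(round((BiocGenerics::start(clusters) +
                                   BiocGenerics::end(clusters)) / 2)))
  if (is.null(point))
    stop("clusters lack the '", at, "' reference point")
  pts <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(clusters),
                                IRanges::IRanges(point, point),
                                strand = BiocGenerics::strand(clusters))
  spans <- gm@geneSpan
  neg <- as.character(BiocGenerics::strand(spans)) == "-"
  ext <- GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(spans),
    IRanges::IRanges(pmax(1L, BiocGenerics::start(spans) -
                            ifelse(neg, 0L, promoterWindow)),
                     BiocGenerics::end(spans) +
                       ifelse(neg, promoterWindow, 0L)),
    strand = BiocGenerics::strand(spans))
  names(ext) <- names(spans)
  hits <- GenomicRanges::findOverlaps(pts, ext, ignore.strand = FALSE)
  geneId <- rep(NA_character_, length(clusters))
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  ## per-gene annotated transcript starts, for tie-breaking
  tssByGene <- split(unname(gm@txTss), unname(gm@txGene[names(gm@txTss)]))
  for (q in unique(qh)) {
    cand <- names(ext)[sh[qh == q]]
    if (length(cand) > 1L) {
      d <- vapply(cand, function(g)
        min(abs(tssByGene[[g]] - point[q])), numeric(1))
      cand <- cand[which.min(d)]
    }
    geneId[q] <- cand[1L]
  }
  S4Vectors::mcols(clusters)$gene_id <- geneId
  clusters
}

#' Serialize clusters as BED
#'
#' Clusters are written BED6-style (0-based half-open on disk) with three
#' extra columns: total count, dominant position (1-based), and gene id.
#' Unified clusters without those columns are written as plain BED6.
#'
#' @param clusters cluster \code{GRanges}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeClustersBed <- function(clusters, path) {
  df <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(clusters)),
    start = BiocGenerics::start(clusters) - 1L,
    end = BiocGenerics::end(clusters),
    name = if (!is.null(names(clusters))) names(clusters) else
      paste0("cluster", seq_along(clusters)),
    score = if (!is.null(clusters$totalCount)) clusters$totalCount else 0L,
    strand = as.character(BiocGenerics::strand(clusters)))
  if (!is.null(clusters$totalCount)) {
    df$totalCount <- clusters$totalCount
    df$dominantPos <- if (!is.null(clusters$dominantPos))
      clusters$dominantPos else NA_integer_
    df$geneId <- if (!is.null(clusters$gene_id)) clusters$gene_id else
      NA_character_
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, eol = "\n")
  invisible(path)
}

#' @rdname writeClustersBed
#' @export
readClustersBed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  gr <- GenomicRanges::GRanges(df[[1L]],
                               IRanges::IRanges(df[[2L]] + 1L, df[[3L]]),
                               strand = df[[6L]])
  names(gr) <- df[[4L]]
  if (ncol(df) >= 9L) {
    S4Vectors::mcols(gr)$totalCount <- as.integer(df[[7L]])
    S4Vectors::mcols(gr)$dominantPos <- as.integer(df[[8L]])
    S4Vectors::mcols(gr)$gene_id <- as.character(df[[9L]])
  }
  gr
}
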