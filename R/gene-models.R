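#' @include AllClasses.R
NULL

#' Build a GeneModelSet from exon chains
#'
#' Coordinates are 1-based and fully closed throughout the package (GTF
#' convention); BED input/output converts at the boundary.
#'
#' @param exonsByTx \code{GRangesList} (or plain list of \code{GRanges}) of
#'   exons, one element per transcript, named by transcript id. Exons of a
#'   transcript must be non-overlapping and on one strand; any order is
#'   accepted and re-sorted 5' to 3'.
#' @param txGene named character vector mapping transcript id to gene id.
#' @return a [GeneModelSet-class].
#' @examples
#' ex <- GenomicRanges::GRangesList(
#'   tx1 = GenomicRanges::GRanges("chr1",
#'     IRanges::IRanges(c(100, 500), c(200, 650)), strand = "+"))
#' gm <- makeGeneModelSet(ex, c(tx1 = "geneA"))
#' @export
makeGeneModelSet <- function(exonsByTx, txGene) {
  if (!methods::is(exonsByTx, "GRangesList"))
    exonsByTx <- GenomicRanges::GRangesList(exonsByTx)
  if (is.null(names(exonsByTx)))
    stop("exonsByTx must be named by transcript id")
  txGene <- txGene[names(exonsByTx)]
  if (anyNA(txGene))
    stop("txGene must cover every transcript in exonsByTx")
  ## sort exons 5'->3' in transcript orientation
  exonsByTx <- S4Vectors::endoapply(exonsByTx, function(ex) {
    neg <- as.character(BiocGenerics::strand(ex)[1]) == "-"
    ex[order(BiocGenerics::start(ex), decreasing = neg)]
  })
  txTss <- vapply(as.list(exonsByTx), function(ex) {
    if (as.character(BiocGenerics::strand(ex)[1]) == "+")
      BiocGenerics::start(ex)[1L]
    else BiocGenerics::end(ex)[1L]
  }, integer(1))
  flat <- BiocGenerics::unlist(exonsByTx, use.names = FALSE)
  geneOfExon <- rep(txGene, lengths(exonsByTx))
  genes <- sort(unique(geneOfExon))
  gi <- match(geneOfExon, genes)
  geneSpan <- GenomicRanges::GRanges(
    as.character(GenomeInfoDb::seqnames(flat))[match(genes, geneOfExon)],
    IRanges::IRanges(
      as.integer(tapply(BiocGenerics::start(flat), gi, min)),
      as.integer(tapply(BiocGenerics::end(flat), gi, max))),
    strand = as.character(BiocGenerics::strand(flat))[match(genes,
                                                            geneOfExon)])
  names(geneSpan) <- genes
  methods::new("GeneModelSet", exons = exonsByTx,
               txGene = txGene, geneSpan = geneSpan,
               txTss = txTss)
}

#' Read gene models from GTF or BED12
#'
#' GTF files need \code{exon} features with \code{gene_id} and
#' \code{transcript_id} attributes. BED12 blocks are expanded into exon
#' chains; the BED \code{name} field is used as both transcript id and (after
#' stripping a trailing \code{".<n>"} version suffix) gene id.
#'
#' @param path path to a \code{.gtf}/\code{.gff} or \code{.bed} file.
#' @param format override format detection ("gtf" or "bed12").
#' @return a [GeneModelSet-class].
#' @export
readGeneModels <- function(path, format = c("auto", "gtf", "bed12")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE))
      "bed12" else "gtf"
  }
  if (format == "gtf") {
    gr <- rtracklayer::import(path, format = "gtf")
    gr <- gr[gr$type == "exon"]
    if (!length(gr)) stop("no exon features found in ", path)
    exonsByTx <- GenomicRanges::split(
      GenomicRanges::granges(gr), gr$transcript_id)
    txGene <- vapply(split(gr$gene_id, gr$transcript_id),
                     `[`, character(1), 1L)
    makeGeneModelSet(exonsByTx, txGene)
  } else {
    bed <- rtracklayer::import(path, format = "bed")
    if (is.null(bed$blocks))
      stop("BED12 blocks required to derive exon structure from ", path)
    txIds <- if (!is.null(bed$name)) bed$name else
      paste0("tx", seq_along(bed))
    exons <- IRanges::shift(bed$blocks, BiocGenerics::start(bed) - 1L)
    exonsByTx <- GenomicRanges::GRangesList(lapply(seq_along(bed), function(i)
      GenomicRanges::GRanges(GenomeInfoDb::seqnames(bed)[i], exons[[i]],
                             strand = BiocGenerics::strand(bed)[i])))
    names(exonsByTx) <- txIds
    txGene <- stats::setNames(sub("\\.\\d+$", "", txIds), txIds)
    makeGeneModelSet(exonsByTx, txGene)
  }
}

#' Transcript length in bases
#' @param gm a [GeneModelSet-class].
#' @param tx transcript id(s).
#' @return integer vector of summed exon widths.
#' @export
transcriptLength <- function(gm, tx) {
  vapply(as.list(gm@exons[tx]), function(ex)
    sum(BiocGenerics::width(ex)), integer(1))
}

#' Project between genomic and transcript coordinates
#'
#' Transcript coordinates are 1-based from the transcript's 5' end.
#' \code{genomeToTx} returns \code{NA} for positions outside the
#' transcript's exons; \code{txToGenome} errors on coordinates outside
#' \code{[1, transcript length]}.
#'
#' @param gm a [GeneModelSet-class].
#' @param tx a single transcript id.
#' @param pos genomic position(s) for \code{genomeToTx}; transcript
#'   position(s) for \code{txToGenome}.
#' @return integer vector of projected positions.
#' @examples
#' ex <- GenomicRanges::GRangesList(
#'   tx1 = GenomicRanges::GRanges("chr1",
#'     IRanges::IRanges(c(10000, 20000), c(10100, 20200)), strand = "+"))
#' gm <- makeGeneModelSet(ex, c(tx1 = "g1"))
#' genomeToTx(gm, "tx1", 20050)  # 152
#' txToGenome(gm, "tx1", 52)     # 10051
#' @export
genomeToTx <- function(gm, tx, pos) {
  ex <- gm@exons[[tx]]
  starts <- BiocGenerics::start(ex)
  ends <- BiocGenerics::end(ex)
  offs <- cumsum(c(0L, BiocGenerics::width(ex)))[seq_along(ex)]
  neg <- as.character(BiocGenerics::strand(ex)[1]) == "-"
  out <- rep(NA_integer_, length(pos))
  for (e in seq_along(ex)) {
    hit <- !is.na(pos) & pos >= starts[e] & pos <= ends[e]
    out[hit] <- offs[e] + if (neg) ends[e] - pos[hit] + 1L else
      pos[hit] - starts[e] + 1L
  }
  out
}

#' @rdname genomeToTx
#' @export
txToGenome <- function(gm, tx, pos) {
  ex <- gm@exons[[tx]]
  w <- BiocGenerics::width(ex)
  offs <- cumsum(c(0L, w))
  total <- offs[length(offs)]
  if (any(pos < 1L | pos > total, na.rm = TRUE))
    stop("transcript coordinate outside [1, ", total, "] for ", tx)
  neg <- as.character(BiocGenerics::strand(ex)[1]) == "-"
  out <- rep(NA_integer_, length(pos))
  for (e in seq_along(ex)) {
    hit <- !is.na(pos) & pos > offs[e] & pos <= offs[e + 1L]
    within <- pos[hit] - offs[e]
    out[hit] <- if (neg) BiocGenerics::end(ex)[e] - within + 1L else
      BiocGenerics::start(ex)[e] + within - 1L
  }
  out
}

## 5'-most exon of each transcript, as a GRanges with gene ids
firstExons <- function(gm) {
  fe <- BiocGenerics::unlist(S4Vectors::endoapply(gm@exons, `[`, 1L))
  S4Vectors::mcols(fe)$gene_id <- unname(gm@txGene[names(fe)])
  fe
}

allExons <- function(gm) {
  ex <- BiocGenerics::unlist(gm@exons, use.names = FALSE)
  S4Vectors::mcols(ex)$gene_id <- rep(unname(gm@txGene), lengths(gm@exons))
  ex
}

#' Classify genomic positions relative to gene structure
#'
#' Each strand-aware position falls into exactly one category:
#' \code{five_prime_most_exon} if it lies in the 5'-most exon of any
#' transcript of an overlapping same-strand gene, \code{other_exon} for any
#' other exonic overlap, \code{intron} if inside a same-strand gene span but
#' not exonic, and \code{intergenic} otherwise. Genes on the opposite strand
#' are ignored.
#'
#' @param pos a \code{GRanges} of width-1 positions (strand set), or an
#'   integer vector with \code{chrom}/\code{strandChar} given.
#' @param gm a [GeneModelSet-class].
#' @param chrom,strandChar used only when \code{pos} is an integer vector.
#' @return factor with levels \code{five_prime_most_exon}, \code{other_exon},
#'   \code{intron}, \code{intergenic}.
#' @export
classifyPosition <- function(pos, gm, chrom = NULL, strandChar = NULL) {
  if (!methods::is(pos, "GRanges")) {
    pos <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos),
                                  strand = strandChar)
  }
  lev <- c("five_prime_most_exon", "other_exon", "intron", "intergenic")
  inFirst <- IRanges::overlapsAny(pos, firstExons(gm), ignore.strand = FALSE)
  inExon <- IRanges::overlapsAny(pos, allExons(gm), ignore.strand = FALSE)
  inGene <- IRanges::overlapsAny(pos, gm@geneSpan, ignore.strand = FALSE)
  out <- rep("intergenic", length(pos))
  out[inGene] <- "intron"
  out[inExon] <- "other_exon"
  out[inFirst] <- "five_prime_most_exon"
  factor(out, levels = lev)
}

#' Read or write a TSS annotation as BED
#'
#' Annotated TSSs are single positions named by gene id. On disk BED is
#' 0-based half-open; in memory positions are 1-based.
#'
#' @param path a BED file of single-base features with gene ids in the
#'   \code{name} column.
#' @return \code{readTssAnnotation}: \code{GRanges} of width-1 positions
#'   with a \code{gene_id} metadata column.
#' @export
readTssAnnotation <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  out <- GenomicRanges::resize(GenomicRanges::granges(gr), width = 1L,
                               fix = "start")
  S4Vectors::mcols(out)$gene_id <- gr$name
  out
}

#' @rdname readTssAnnotation
#' @param tss \code{GRanges} of width-1 TSS positions with \code{gene_id}.
#' @export
writeTssAnnotation <- function(tss, path) {
  out <- GenomicRanges::granges(tss)
  S4Vectors::mcols(out)$name <- S4Vectors::mcols(tss)$gene_id
  rtracklayer::export(out, path, format = "bed")
  invisible(path)
}
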