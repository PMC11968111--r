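#' @include AllClasses.R
NULL

## Mapped-TSS tables: tab-separated chrom / pos / count / strand
## [/ barcode], the compact 5'-end evidence format used between alignment
## and clustering. Keeping tables instead of BAMs avoids holding whole
## alignment files in memory during clustering.

#' Read a mapped-TSS table
#'
#' A mapped-TSS table is a tab-separated file with columns chromosome,
#' position (1-based), read count, and strand, plus an optional fifth cell
#' barcode column (absence means a bulk-level table). An optional header
#' line is detected and skipped. Rows sharing (chrom, pos, strand, barcode)
#' are summed.
#'
#' @param path path to the table.
#' @return \code{GRanges} of width-1 positions with a \code{count} metadata
#'   column and, when present in the file, a \code{barcode} column.
#' @seealso [writeMappedTss()], [extractMappedTss()]
#' @export
readMappedTss <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(GenomicRanges::GRanges(count = integer()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 4L | ncol > 5L))
    stop("line ", which(ncol < 4L | ncol > 5L)[1L],
         ": expected 4 or 5 tab-separated columns")
  first <- fields[[1L]]
  skip <- is.na(suppressWarnings(as.integer(trimws(first[2L]))))
  if (skip) {
    fields <- fields[-1L]
    if (!length(fields)) return(GenomicRanges::GRanges(count = integer()))
  }
  off <- as.integer(skip)
  m <- matrix(trimws(unlist(fields)), nrow = length(fields), byrow = TRUE)
  pos <- suppressWarnings(as.integer(m[, 2L]))
  count <- suppressWarnings(as.integer(m[, 3L]))
  strand <- m[, 4L]
  bad <- which(is.na(pos) | is.na(count) | !(strand %in% c("+", "-")) |
                 pos < 1L | count < 0L)
  if (length(bad))
    stop("line ", bad[1L] + off,
         ": malformed row (need integer pos >= 1, integer count >= 0, ",
         "strand '+' or '-')")
  gr <- GenomicRanges::GRanges(m[, 1L], IRanges::IRanges(pos, pos),
                               strand = strand)
  S4Vectors::mcols(gr)$count <- count
  if (ncol(m) == 5L) S4Vectors::mcols(gr)$barcode <- m[, 5L]
  aggregateMappedTss(gr)
}

## Sum counts over identical (chrom, pos, strand[, barcode]) records.
aggregateMappedTss <- function(gr) {
  key <- paste(GenomeInfoDb::seqnames(gr), BiocGenerics::start(gr),
               BiocGenerics::strand(gr),
               if (!is.null(gr$barcode)) gr$barcode else "", sep = "\r")
  if (!anyDuplicated(key)) return(sortMappedTss(gr))
  idx <- which(!duplicated(key))
  out <- gr[idx]
  S4Vectors::mcols(out)$count <-
    as.integer(rowsum(as.numeric(gr$count), key)[match(key[idx], sort(unique(key))), ])
  sortMappedTss(out)
}

sortMappedTss <- function(gr) {
  gr[order(as.factor(GenomeInfoDb::seqnames(gr)),
           as.integer(BiocGenerics::strand(gr)),
           BiocGenerics::start(gr),
           if (!is.null(gr$barcode)) gr$barcode else
             rep("", length(gr)))]
}

#' Write a mapped-TSS table
#'
#' @param gr \code{GRanges} with \code{count} (and optionally
#'   \code{barcode}) metadata columns.
#' @param path output path; tab-separated, no header, LF line endings.
#' @return \code{path}, invisibly.
#' @export
writeMappedTss <- function(gr, path) {
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                   pos = BiocGenerics::start(gr),
                   count = gr$count,
                   strand = as.character(BiocGenerics::strand(gr)))
  if (!is.null(gr$barcode)) df$barcode <- gr$barcode
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, eol = "\n")
  invisible(path)
}

#' Extract mapped 5' ends from a BAM/SAM file
#'
#' For on-site (paired-end) data the genuine TSS is the 5' end of Read 1;
#' for near-site (single-end) data the evidence position is the 5' end of
#' Read 2. The 5' end of a \code{+} alignment is its leftmost aligned base
#' and of a \code{-} alignment its rightmost. Unmapped, secondary, and
#' supplementary alignments are skipped and tallied. When UB (UMI) tags are
#' present, reads are deduplicated to one count per UMI per position per
#' cell; CB tags populate the barcode column.
#'
#' @param file path to a BAM (or SAM, converted on the fly) file.
#' @param readEndPolicy \code{"read1_onsite"} keeps first-in-pair reads,
#'   \code{"read2_nearsite"} second-in-pair reads; unpaired alignments are
#'   kept under either policy.
#' @return \code{GRanges} of width-1 positions with \code{count} and (if CB
#'   tags were present) \code{barcode}; the skip tally is attached as
#'   \code{metadata(gr)$skipped} via attributes.
#' @export
extractMappedTss <- function(file,
                             readEndPolicy = c("read1_onsite",
                                               "read2_nearsite")) {
  readEndPolicy <- match.arg(readEndPolicy)
  if (grepl("\\.sam$", file, ignore.case = TRUE)) {
    file <- Rsamtools::asBam(file,
                             destination = tempfile(fileext = ""),
                             overwrite = TRUE, indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("flag", "rname", "pos", "strand", "cigar"),
    tag = c("CB", "UB"))
  res <- Rsamtools::scanBam(file, param = param)[[1L]]
  flag <- res$flag
  nTotal <- length(flag)
  unmapped <- bitwAnd(flag, 4L) != 0L
  secondary <- bitwAnd(flag, 256L) != 0L
  supplementary <- bitwAnd(flag, 2048L) != 0L
  keep <- !(unmapped | secondary | supplementary)
  paired <- bitwAnd(flag, 1L) != 0L
  isRead1 <- paired & bitwAnd(flag, 64L) != 0L
  isRead2 <- paired & bitwAnd(flag, 128L) != 0L
  keep <- keep & (!paired |
                    if (readEndPolicy == "read1_onsite") isRead1 else isRead2)
  skipped <- c(unmapped = sum(unmapped), secondary = sum(secondary),
               supplementary = sum(supplementary),
               other_read = sum(paired) - sum(keep & paired) -
                 sum((unmapped | secondary | supplementary) & paired))
  if (!any(keep)) {
    out <- GenomicRanges::GRanges()
    S4Vectors::mcols(out)$count <- integer()
    attr(out, "skipped") <- skipped
    return(out)
  }
  chrom <- as.character(res$rname)[keep]
  strand <- as.character(res$strand)[keep]
  start <- res$pos[keep]
  refWidth <- GenomicAlignments::cigarWidthAlongReferenceSpace(
    res$cigar[keep])
  fiveEnd <- ifelse(strand == "+", start, start + refWidth - 1L)
  cb <- res$tag$CB
  ub <- res$tag$UB
  hasCb <- !is.null(cb) && !all(is.na(cb))
  hasUb <- !is.null(ub) && !all(is.na(ub))
  if (hasCb) cb <- cb[keep]
  if (hasUb) ub <- ub[keep]
  if (hasUb) {
    ## one count per UMI per (position, strand, cell)
    key <- paste(chrom, fiveEnd, strand,
                 if (hasCb) cb else "", ub, sep = "\r")
    dedup <- !duplicated(key)
    chrom <- chrom[dedup]; fiveEnd <- fiveEnd[dedup]
    strand <- strand[dedup]
    if (hasCb) cb <- cb[dedup]
  }
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(fiveEnd, fiveEnd),
                               strand = strand)
  S4Vectors::mcols(gr)$count <- 1L
  if (hasCb) S4Vectors::mcols(gr)$barcode <- cb
  out <- aggregateMappedTss(gr)
  attr(out, "skipped") <- skipped
  out
}
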