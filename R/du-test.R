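#' @include AllClasses.R glmm.R quantify.R
NULL

#' Differential usage test at single-cell level
#'
#' Tests whether the usage of one TSS cluster differs between biological
#' conditions, modelling per-cell cluster counts as binomial draws out of
#' the cell's gene total with a sample-level logit-normal random intercept
#' (cells with zero gene count are dropped; they carry no likelihood
#' information).
#'
#' @param x per-cell counts of the TSS cluster of interest.
#' @param y per-cell gene totals (all clusters of the gene).
#' @param cellSample sample of each cell.
#' @param conditionOfSample named factor (names = sample levels) or factor
#'   aligned with \code{levels(factor(cellSample))}, giving each sample's
#'   condition.
#' @param covariates optional sample-level covariate matrix (rows in the
#'   order of \code{levels(factor(cellSample))}).
#' @return list as in [glmmLrtTest()], plus \code{level = "cell"}.
#' @seealso [fitDuBulk()], [testDifferentialUsage()]
#' @export
fitDuCell <- function(x, y, cellSample, conditionOfSample,
                      covariates = NULL) {
  cellSample <- factor(cellSample)
  cond <- sampleConditionPerObs(cellSample, conditionOfSample)
  cov <- if (!is.null(covariates))
    as.matrix(covariates)[as.integer(cellSample), , drop = FALSE] else NULL
  out <- glmmLrtTest(x, y, cellSample, cond, cov)
  out$level <- "cell"
  out
}

#' Differential usage test at pseudo-bulk level
#'
#' As [fitDuCell()] but on counts aggregated per sample. Because binomial
#' observations sharing the sample-level usage aggregate, the pseudo-bulk
#' likelihood equals the cell-level one up to a data constant, and the two
#' tests agree to numerical precision.
#'
#' @param x per-sample aggregated cluster counts.
#' @param y per-sample aggregated gene totals.
#' @param conditionOfSample condition of each sample.
#' @param covariates optional sample-level covariate matrix.
#' @return list as in [glmmLrtTest()], plus \code{level = "bulk"}.
#' @export
fitDuBulk <- function(x, y, conditionOfSample, covariates = NULL) {
  out <- glmmLrtTest(x, y, seq_along(x), factor(conditionOfSample),
                     covariates)
  out$level <- "bulk"
  out
}

sampleConditionPerObs <- function(cellSample, conditionOfSample) {
  lev <- levels(cellSample)
  if (!is.null(names(conditionOfSample))) {
    if (!all(lev %in% names(conditionOfSample)))
      stop("conditionOfSample lacks entries for some samples")
    conditionOfSample <- conditionOfSample[lev]
  } else if (length(conditionOfSample) != length(lev)) {
    stop("conditionOfSample must have one entry per sample")
  }
  factor(conditionOfSample)[as.integer(cellSample)]
}

#' Gene filters applied before differential usage testing
#'
#' A gene is kept if, in every sample, it is detected (gene total > 0,
#' pooling the compared cell groups) in at least \code{minDetect} of the
#' cells (boundary inclusive), and — when \code{requireMulticluster} — it
#' has at least two TSS clusters. Single-cluster genes have constant usage
#' 1 and are untestable.
#'
#' @param tcm a [TssCountMatrix-class] combining all samples.
#' @param minDetect minimum per-sample detection fraction.
#' @param requireMulticluster drop genes with a single cluster.
#' @return character vector of kept gene ids.
#' @export
filterGenes <- function(tcm, minDetect = 0.1, requireMulticluster = TRUE) {
  gt <- geneTotals(tcm)
  samp <- factor(tcm$sample_id)
  det <- vapply(levels(samp), function(sm) {
    cols <- which(samp == sm)
    Matrix::rowSums(gt[, cols, drop = FALSE] > 0) / length(cols)
  }, numeric(nrow(gt)))
  keep <- rownames(gt)[apply(det >= minDetect, 1L, all)]
  if (requireMulticluster) {
    tabs <- table(geneOf(tcm))
    keep <- keep[keep %in% names(tabs)[tabs >= 2L]]
  }
  keep
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; missing values are excluded
#' from the number of tests and returned as missing.
#'
#' @param p numeric vector of p-values in \code{[0, 1]} (NA allowed).
#' @return adjusted p-values, monotone and capped at 1.
#' @export
bhAdjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Wilcoxon rank-sum comparator test
#'
#' Applies the two-sided rank-sum test directly to TSS cluster usage: at
#' cell level to per-cell usage values (cells with zero gene total are
#' missing), at pseudo-bulk level to per-sample aggregated-count usage
#' ratios.
#'
#' @inheritParams fitDuCell
#' @param level \code{"cell"} or \code{"bulk"}.
#' @return two-sided p-value, or \code{NA} when a condition has no
#'   non-missing usage.
#' @export
wilcoxonDu <- function(x, y, cellSample, conditionOfSample,
                       level = c("cell", "bulk")) {
  level <- match.arg(level)
  cellSample <- factor(cellSample)
  if (level == "bulk") {
    xs <- as.vector(rowsum(as.numeric(x), cellSample))
    ys <- as.vector(rowsum(as.numeric(y), cellSample))
    usage <- ifelse(ys > 0, xs / ys, NA_real_)
    ## aggregated rows follow levels(cellSample); align conditions to it
    cond <- if (!is.null(names(conditionOfSample)))
      factor(conditionOfSample[levels(cellSample)]) else
        factor(conditionOfSample)
  } else {
    usage <- ifelse(y > 0, x / y, NA_real_)
    cond <- sampleConditionPerObs(cellSample, conditionOfSample)
  }
  ok <- !is.na(usage)
  if (length(unique(cond[ok])) < 2L) return(NA_real_)
  g <- split(usage[ok], droplevels(cond[ok]))
  if (any(lengths(g) == 0L)) return(NA_real_)
  if (length(unique(unlist(g))) == 1L) return(1)
  suppressWarnings(stats::wilcox.test(g[[1L]], g[[2L]],
                                      alternative = "two.sided")$p.value)
}

#' Wasserstein-1 distance between two empirical distributions
#'
#' @param a,b numeric samples.
#' @return the L1 distance between the two empirical CDFs.
#' @examples
#' wasserstein1(0.2, 0.7)  # 0.5
#' @export
wasserstein1 <- function(a, b) {
  breaks <- sort(unique(c(a, b)))
  if (length(breaks) < 2L) return(0)
  Fa <- stats::ecdf(a)(breaks)
  Fb <- stats::ecdf(b)(breaks)
  n <- length(breaks)
  sum(abs(Fa[-n] - Fb[-n]) * diff(breaks))
}

#' Distribution-based comparator test via Wasserstein permutation
#'
#' Nonparametric sample-level comparison: the test statistic is the mean
#' pairwise Wasserstein-1 distance between the per-sample usage
#' distributions of different conditions minus the mean distance within
#' conditions; significance comes from permuting sample condition labels.
#'
#' @param usageBySample list of per-cell usage vectors, one per sample
#'   (missing values removed internally).
#' @param conditionOfSample condition of each sample.
#' @param nPerm number of label permutations.
#' @return list with \code{statistic} and \code{pValue}
#'   (\code{(1 + #permuted >= observed) / (1 + nPerm)}), \code{NA} with a
#'   warning when the labels admit no permutation variety.
#' @export
ideasModifiedDu <- function(usageBySample, conditionOfSample,
                            nPerm = 2000L) {
  usageBySample <- lapply(usageBySample, function(u) u[!is.na(u)])
  keep <- lengths(usageBySample) > 0L
  usageBySample <- usageBySample[keep]
  cond <- droplevels(factor(conditionOfSample)[keep])
  J <- length(usageBySample)
  if (J < 3L || nlevels(cond) < 2L) {
    warning("too few samples for a permutation test")
    return(list(statistic = NA_real_, pValue = NA_real_))
  }
  D <- matrix(0, J, J)
  for (i in seq_len(J - 1L)) for (j in seq(i + 1L, J)) {
    D[i, j] <- D[j, i] <- wasserstein1(usageBySample[[i]],
                                       usageBySample[[j]])
  }
  stat <- function(labels) {
    between <- outer(labels, labels, `!=`)
    ut <- upper.tri(D)
    mean(D[ut & between]) - mean(D[ut & !between])
  }
  obs <- stat(cond)
  perm <- vapply(seq_len(nPerm), function(k) stat(sample(cond)), numeric(1))
  list(statistic = obs,
       pValue = (1 + sum(perm >= obs, na.rm = TRUE)) / (1 + nPerm))
}

#' Differential TSS usage testing across all clusters
#'
#' Applies the chosen test to every TSS cluster of every gene passing
#' [filterGenes()]: the cluster's counts are the binomial successes, the
#' gene totals the trials. P-values are Benjamini-Hochberg adjusted across
#' all tested clusters.
#'
#' @param tcm a [TssCountMatrix-class] combining all samples (see
#'   [combineSamples()]).
#' @param conditionOfSample named factor giving each sample's condition.
#' @param level model at single-cell (\code{"cell"}) or pseudo-bulk
#'   (\code{"bulk"}) resolution.
#' @param method \code{"glmm"} (binomial GLMM likelihood-ratio test),
#'   \code{"wilcoxon"}, or \code{"ideas"} (Wasserstein permutation,
#'   sample-level only).
#' @param minDetect,requireMulticluster passed to [filterGenes()].
#' @param covariates optional sample-level covariates for the GLMM.
#' @param nPerm permutations for \code{method = "ideas"}.
#' @return \code{DataFrame} with one row per tested cluster: \code{cluster},
#'   \code{gene}, \code{beta0}, \code{beta}, \code{sigma2}, \code{lrt},
#'   \code{df}, \code{pValue}, \code{pAdjusted}, \code{converged},
#'   \code{level}.
#' @export
testDifferentialUsage <- function(tcm, conditionOfSample,
                                  level = c("bulk", "cell"),
                                  method = c("glmm", "wilcoxon", "ideas"),
                                  minDetect = 0.1,
                                  requireMulticluster = TRUE,
                                  covariates = NULL,
                                  nPerm = 2000L) {
  level <- match.arg(level)
  method <- match.arg(method)
  genes <- filterGenes(tcm, minDetect, requireMulticluster)
  gene <- geneOf(tcm)
  rows <- which(gene %in% genes)
  counts <- SummarizedExperiment::assay(tcm, "counts")
  gt <- geneTotals(tcm)
  cellSample <- factor(tcm$sample_id)
  if (is.null(names(conditionOfSample))) {
    if (length(conditionOfSample) != nlevels(cellSample))
      stop("conditionOfSample must be named by sample or have one entry ",
           "per sample")
    names(conditionOfSample) <- levels(cellSample)
  }
  condS <- factor(conditionOfSample[levels(cellSample)])
  if (!length(rows)) {
    return(S4Vectors::DataFrame(
      cluster = character(), gene = character(), beta0 = numeric(),
      beta = numeric(), sigma2 = numeric(), lrt = numeric(),
      df = integer(), pValue = numeric(), converged = logical(),
      level = character(), pAdjusted = numeric()))
  }
  res <- vector("list", length(rows))
  for (k in seq_along(rows)) {
    r <- rows[k]
    g <- gene[r]
    x <- as.numeric(counts[r, ])
    y <- as.numeric(gt[g, ])
    rec <- list(cluster = rownames(tcm)[r], gene = g,
                beta0 = NA_real_, beta = NA_real_, sigma2 = NA_real_,
                lrt = NA_real_, df = NA_integer_, pValue = NA_real_,
                converged = NA, level = level)
    fit <- tryCatch(switch(method,
      glmm = {
        if (level == "bulk") {
          xs <- as.vector(rowsum(x, cellSample))
          ys <- as.vector(rowsum(y, cellSample))
          fitDuBulk(xs, ys, condS, covariates)
        } else {
          fitDuCell(x, y, cellSample, condS, covariates)
        }
      },
      wilcoxon = list(pValue = wilcoxonDu(x, y, cellSample, condS, level)),
      ideas = {
        usage <- split(ifelse(y > 0, x / y, NA_real_), cellSample)
        ideasModifiedDu(usage, condS, nPerm)
      }), error = function(e) list(pValue = NA_real_, error = TRUE))
    for (nm in intersect(names(rec), names(fit))) {
      if (nm == "beta") rec$beta <- fit$beta[1L] else rec[[nm]] <- fit[[nm]]
    }
    res[[k]] <- rec
  }
  out <- S4Vectors::DataFrame(
    cluster = vapply(res, `[[`, character(1), "cluster"),
    gene = vapply(res, `[[`, character(1), "gene"),
    beta0 = vapply(res, `[[`, numeric(1), "beta0"),
    beta = vapply(res, `[[`, numeric(1), "beta"),
    sigma2 = vapply(res, `[[`, numeric(1), "sigma2"),
    lrt = vapply(res, `[[`, numeric(1), "lrt"),
    df = vapply(res, function(r) as.integer(r$df), integer(1)),
    pValue = vapply(res, `[[`, numeric(1), "pValue"),
    converged = vapply(res, function(r) isTRUE(r$converged), logical(1)),
    level = level)
  out$pAdjusted <- bhAdjust(out$pValue)
  out
}
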