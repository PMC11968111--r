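#' @include AllClasses.R du-test.R
NULL

#' Construct a simulation scenario
#'
#' Defines one cell of the differential-usage benchmark: two biological
#' conditions with \code{J} samples each and \code{I} cells per sample,
#' two TSS clusters per gene, \code{nNull} genes with equal expected usage
#' in the two conditions and \code{nAlt} genes with a usage shift
#' \code{d ~ Uniform(0.1, 0.5)}. Sample-level usage offsets follow a
#' mixture of a narrow uniform and outlier components: a sample is an
#' outlier with probability \code{piOutlier}, deviating by between
#' \code{c1} and \code{c2}. Per-cell usage is drawn from a Beta
#' distribution with second shape parameter \code{betaShape} around the
#' sample-level mean.
#'
#' @param J samples per condition.
#' @param I cells per sample.
#' @param nNull,nAlt numbers of null / alternative genes.
#' @param piOutlier outlier probability per sample and gene.
#' @param c1,c2 outlier deviation bounds (0 < c1 < c2); (0.1, 0.2) is the
#'   small and (0.2, 0.3) the large deviation setting.
#' @param betaShape second Beta shape parameter for cell-level usage.
#' @param symmetricOutliers under the alternative, make the outlier
#'   component two-sided instead of one-sided positive.
#' @param seed RNG seed making the scenario fully reproducible.
#' @return a [SimScenario-class].
#' @export
simScenario <- function(J = 10L, I = 100L, nNull = 1000L, nAlt = 1000L,
                        piOutlier = 0.1, c1 = 0.1, c2 = 0.2,
                        betaShape = 5, symmetricOutliers = FALSE,
                        seed = 1L) {
  methods::new("SimScenario", J = as.integer(J), I = as.integer(I),
               nNull = as.integer(nNull), nAlt = as.integer(nAlt),
               piOutlier = piOutlier, c1 = c1, c2 = c2,
               betaShape = betaShape,
               symmetricOutliers = symmetricOutliers,
               seed = as.integer(seed))
}

#' Simulate per-gene negative-binomial read counts
#'
#' Generates independent negative-binomial gene-level counts per cell.
#' Per-gene means and dispersions can be supplied, estimated from a user
#' count matrix by method of moments via [estimateNbParams()], or drawn
#' from log-normal hyperpriors (means: meanlog log(2), sdlog 0.8;
#' sizes: meanlog log(2), sdlog 0.5) chosen to mimic the moderately-to-
#' well-detected genes retained by detection-rate filtering of 5'
#' single-cell data. An optional dropout probability zeroes entries
#' independently.
#'
#' @param nGenes,nCells dimensions of the output.
#' @param means,sizes optional per-gene NB mean and size (dispersion)
#'   vectors, recycled to \code{nGenes}.
#' @param dropout per-entry zero-inflation probability.
#' @return integer matrix, genes x cells, with \code{means}/\code{sizes}
#'   attached as attributes.
#' @export
simulateGeneCounts <- function(nGenes, nCells, means = NULL, sizes = NULL,
                               dropout = 0) {
  if (is.null(means))
    means <- stats::rlnorm(nGenes, meanlog = log(2), sdlog = 0.8)
  if (is.null(sizes))
    sizes <- stats::rlnorm(nGenes, meanlog = log(2), sdlog = 0.5)
  means <- rep_len(means, nGenes)
  sizes <- rep_len(sizes, nGenes)
  if (any(sizes <= 0)) stop("NB size (dispersion) must be positive")
  m <- matrix(stats::rnbinom(nGenes * nCells, mu = means, size = sizes),
              nrow = nGenes)
  if (dropout > 0)
    m[matrix(stats::runif(length(m)) < dropout, nrow = nGenes)] <- 0L
  attr(m, "means") <- means
  attr(m, "sizes") <- sizes
  m
}

#' Method-of-moments NB parameters from a count matrix
#'
#' @param counts genes x cells count matrix.
#' @return data.frame with per-gene \code{mean} and \code{size}
#'   (infinite-variance-consistent genes get a large size, i.e. near-
#'   Poisson).
#' @export
estimateNbParams <- function(counts) {
  mu <- Matrix::rowMeans(counts)
  v <- apply(counts, 1L, stats::var)
  size <- ifelse(v > mu, mu^2 / (v - mu), 1e6)
  data.frame(mean = mu, size = pmin(size, 1e6))
}

clip01 <- function(z) {
  z[z < 0] <- 0
  z[z > 1] <- 1
  z
}

## Sample-level usage offsets under the null: a three-part mixture of a
## narrow uniform and symmetric positive/negative outlier components.
drawTauNull <- function(n, piOutlier, c1, c2) {
  u <- stats::runif(n)
  tau <- stats::runif(n, -0.1, 0.1)
  pos <- u < piOutlier / 2
  neg <- u >= piOutlier / 2 & u < piOutlier
  tau[pos] <- stats::runif(sum(pos), c1, c2)
  tau[neg] <- stats::runif(sum(neg), -c2, -c1)
  tau
}

## Under the alternative the outlier component is one-sided positive
## (the symmetric variant is available as an option).
drawTauAlt <- function(n, piOutlier, c1, c2, symmetric = FALSE) {
  if (symmetric) return(drawTauNull(n, piOutlier, c1, c2))
  u <- stats::runif(n)
  tau <- stats::runif(n, -0.1, 0.1)
  out <- u < piOutlier
  tau[out] <- stats::runif(sum(out), c1, c2)
  tau
}

#' Draw expected per-sample usage for null genes
#'
#' For each gene a baseline usage \code{a ~ Uniform(0.1, 0.9)} is shared
#' by both conditions; each sample's expected usage is
#' \code{clip(a + tau)} with \code{tau} from the outlier mixture, clipped
#' to \code{[0, 1]}.
#'
#' @param nGenes number of genes.
#' @param scenario a [SimScenario-class].
#' @return list with \code{a} (length \code{nGenes}) and \code{mu}, an
#'   \code{nGenes x 2J} matrix of expected usages (columns: condition-1
#'   samples then condition-2 samples).
#' @export
drawNullUsage <- function(nGenes, scenario) {
  J <- scenario@J
  a <- stats::runif(nGenes, 0.1, 0.9)
  tau <- matrix(drawTauNull(nGenes * 2L * J, scenario@piOutlier,
                            scenario@c1, scenario@c2), nrow = nGenes)
  mu <- clip01(a + tau)
  list(a = a, d = rep(0, nGenes), mu = mu)
}

#' Draw expected per-sample usage for alternative genes
#'
#' Condition baselines are \code{a1 ~ Uniform(0.1, 0.4)} and
#' \code{a2 = a1 + d} with \code{d ~ Uniform(0.1, 0.5)}; per-sample
#' offsets come from the one-sided outlier mixture, and expected usages
#' are clipped to \code{[0, 1]}.
#'
#' @inheritParams drawNullUsage
#' @param dRange range of the usage shift; a degenerate range fixes
#'   \code{d} for power analyses at a single effect size.
#' @return list with \code{a} (condition-1 baseline), \code{d} (usage
#'   shift), and \code{mu} as in [drawNullUsage()].
#' @export
drawAltUsage <- function(nGenes, scenario, dRange = c(0.1, 0.5)) {
  J <- scenario@J
  a1 <- stats::runif(nGenes, 0.1, 0.4)
  d <- stats::runif(nGenes, dRange[1L], dRange[2L])
  tau <- matrix(drawTauAlt(nGenes * 2L * J, scenario@piOutlier,
                           scenario@c1, scenario@c2,
                           scenario@symmetricOutliers), nrow = nGenes)
  ak <- cbind(matrix(a1, nGenes, J), matrix(a1 + d, nGenes, J))
  mu <- clip01(ak + tau)
  list(a = a1, d = d, mu = mu)
}

#' Split gene counts into two TSS-cluster counts
#'
#' Per cell, the first cluster's usage is drawn from
#' \code{Beta(alpha, betaShape)} with \code{alpha = betaShape * mu / (1 -
#' mu)} so its mean equals the sample-level expected usage \code{mu}; a
#' clipped \code{mu} of 0 or 1 degenerates to a point mass. The first
#' cluster's count is binomial out of the cell's gene count; the second
#' cluster receives the complement.
#'
#' @param geneCounts vector of per-cell gene-level counts.
#' @param mu expected usage per cell (sample-level value expanded to
#'   cells).
#' @param betaShape second Beta shape parameter.
#' @return matrix with columns \code{x1}, \code{x2}; rows are cells.
#' @export
simulateTssCounts <- function(geneCounts, mu, betaShape = 5) {
  n <- length(geneCounts)
  mu <- rep_len(mu, n)
  gamma <- numeric(n)
  inner <- mu > 0 & mu < 1
  alpha <- betaShape * mu[inner] / (1 - mu[inner])
  gamma[inner] <- stats::rbeta(sum(inner), alpha, betaShape)
  gamma[!inner] <- mu[!inner]  # point mass at a clipped boundary
  x1 <- stats::rbinom(n, size = geneCounts, prob = gamma)
  cbind(x1 = x1, x2 = geneCounts - x1)
}

#' Simulate a full differential-usage dataset
#'
#' Generates, per the scenario, gene-level NB counts for \code{2J} samples
#' of \code{I} cells, expected usages for null and alternative genes, and
#' the two per-gene TSS cluster counts. Gene-level means may differ
#' between conditions (\code{dgeFraction} of genes get a condition-2
#' fold-change drawn log-normally) to emulate confounding differential
#' expression.
#'
#' @param scenario a [SimScenario-class].
#' @param dgeFraction fraction of genes with condition-specific gene-level
#'   means.
#' @param dgeSdLog log-scale SD of the condition-2 fold change.
#' @param dRange passed to [drawAltUsage()].
#' @return list: \code{x1}, \code{x2}, \code{y} (genes x cells matrices),
#'   \code{cellSample} (factor), \code{conditionOfSample} (named factor),
#'   \code{truth} (data.frame: gene, hypothesis, a, d), \code{mu}
#'   (genes x samples expected usage), \code{scenario}.
#' @export
simulateDuDataset <- function(scenario, dgeFraction = 0.2, dgeSdLog = 0.5,
                              dRange = c(0.1, 0.5)) {
  set.seed(scenario@seed)
  J <- scenario@J; I <- scenario@I
  nGenes <- scenario@nNull + scenario@nAlt
  nSamples <- 2L * J
  sampleIds <- sprintf("s%02d", seq_len(nSamples))
  condition <- stats::setNames(
    factor(rep(c("cond1", "cond2"), each = J)), sampleIds)
  cellSample <- factor(rep(sampleIds, each = I), levels = sampleIds)
  means <- stats::rlnorm(nGenes, meanlog = log(2), sdlog = 0.8)
  sizes <- stats::rlnorm(nGenes, meanlog = log(2), sdlog = 0.5)
  fc <- rep(1, nGenes)
  isDge <- stats::runif(nGenes) < dgeFraction
  fc[isDge] <- stats::rlnorm(sum(isDge), 0, dgeSdLog)
  nCells <- nSamples * I
  y <- matrix(0L, nGenes, nCells)
  cond2 <- as.integer(cellSample) > J
  y[, !cond2] <- stats::rnbinom(nGenes * sum(!cond2), mu = means,
                                size = sizes)
  y[, cond2] <- stats::rnbinom(nGenes * sum(cond2), mu = means * fc,
                               size = sizes)
  nullUsage <- drawNullUsage(scenario@nNull, scenario)
  altUsage <- drawAltUsage(scenario@nAlt, scenario, dRange)
  mu <- rbind(nullUsage$mu, altUsage$mu)
  x1 <- matrix(0L, nGenes, nCells)
  sIdx <- as.integer(cellSample)
  for (g in seq_len(nGenes)) {
    counts <- simulateTssCounts(y[g, ], mu[g, sIdx], scenario@betaShape)
    x1[g, ] <- counts[, "x1"]
  }
  geneIds <- sprintf("gene%04d", seq_len(nGenes))
  rownames(y) <- rownames(x1) <- geneIds
  colnames(mu) <- sampleIds
  rownames(mu) <- geneIds
  truth <- data.frame(
    gene = geneIds,
    hypothesis = rep(c("null", "alt"),
                     c(scenario@nNull, scenario@nAlt)),
    a = c(nullUsage$a, altUsage$a),
    d = c(nullUsage$d, altUsage$d))
  list(x1 = x1, x2 = y - x1, y = y,
       cellSample = cellSample, conditionOfSample = condition,
       truth = truth, mu = mu, scenario = scenario)
}

#' Run one DU method over all genes of a simulated dataset
#'
#' The test is applied to each gene's first TSS cluster (the second is its
#' complement and carries the mirrored signal).
#'
#' @param dataset output of [simulateDuDataset()].
#' @param method one of \code{"glmm_bulk"}, \code{"glmm_cell"},
#'   \code{"wilcoxon_bulk"}, \code{"wilcoxon_cell"}, \code{"ideas"}.
#' @param nPerm permutations for \code{"ideas"}.
#' @param genes optional subset of gene ids.
#' @return named numeric vector of p-values (NA where the method failed).
#' @export
runDuMethod <- function(dataset,
                        method = c("glmm_bulk", "glmm_cell",
                                   "wilcoxon_bulk", "wilcoxon_cell",
                                   "ideas"),
                        nPerm = 2000L, genes = NULL) {
  method <- match.arg(method)
  if (is.null(genes)) genes <- rownames(dataset$x1)
  cellSample <- dataset$cellSample
  cond <- dataset$conditionOfSample
  p <- stats::setNames(rep(NA_real_, length(genes)), genes)
  if (method %in% c("glmm_bulk", "wilcoxon_bulk")) {
    xs <- t(rowsum(t(dataset$x1[genes, , drop = FALSE]), cellSample))
    ys <- t(rowsum(t(dataset$y[genes, , drop = FALSE]), cellSample))
    condS <- cond[colnames(xs)]
  }
  for (g in genes) {
    p[g] <- tryCatch(switch(method,
      glmm_bulk = fitDuBulk(xs[g, ], ys[g, ], condS)$pValue,
      glmm_cell = fitDuCell(dataset$x1[g, ], dataset$y[g, ],
                            cellSample, cond)$pValue,
      wilcoxon_bulk = wilcoxonDu(dataset$x1[g, ], dataset$y[g, ],
                                 cellSample, cond, level = "bulk"),
      wilcoxon_cell = wilcoxonDu(dataset$x1[g, ], dataset$y[g, ],
                                 cellSample, cond, level = "cell"),
      ideas = {
        usage <- split(ifelse(dataset$y[g, ] > 0,
                              dataset$x1[g, ] / dataset$y[g, ], NA_real_),
                       cellSample)
        ideasModifiedDu(usage, cond[levels(cellSample)], nPerm)$pValue
      }), error = function(e) NA_real_)
  }
  p
}

#' Benchmark DU methods on simulated scenarios
#'
#' For each scenario and method, simulates a dataset, computes per-gene
#' p-values on the pooled null + alternative genes, BH-adjusts them
#' jointly, and reports the type I error (fraction of null genes
#' rejected) and power (fraction of alternative genes rejected) at the
#' \code{alpha} threshold. Failed fits count as non-rejections.
#'
#' @param scenarios list of [SimScenario-class] objects.
#' @param methods methods passed to [runDuMethod()].
#' @param alpha rejection threshold on BH-adjusted p-values.
#' @param nPerm permutations for the \code{"ideas"} method.
#' @return data.frame keyed by scenario x method with columns \code{J},
#'   \code{I}, \code{piOutlier}, \code{c1}, \code{c2}, \code{method},
#'   \code{typeIError}, \code{power}, \code{nFailed}.
#' @export
evaluateDuMethods <- function(scenarios, methods = "glmm_bulk",
                              alpha = 0.05, nPerm = 2000L) {
  if (methods::is(scenarios, "SimScenario")) scenarios <- list(scenarios)
  rows <- list()
  for (sc in scenarios) {
    dataset <- simulateDuDataset(sc)
    isNull <- dataset$truth$hypothesis == "null"
    for (m in methods) {
      p <- runDuMethod(dataset, m, nPerm = nPerm)
      padj <- bhAdjust(p)
      rej <- !is.na(padj) & padj < alpha
      rows[[length(rows) + 1L]] <- data.frame(
        J = sc@J, I = sc@I, piOutlier = sc@piOutlier,
        c1 = sc@c1, c2 = sc@c2, seed = sc@seed, method = m,
        typeIError = mean(rej[isNull]),
        power = mean(rej[!isNull]),
        nFailed = sum(is.na(p)))
    }
  }
  do.call(rbind, rows)
}
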