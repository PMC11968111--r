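#' @include AllClasses.R
NULL

## Binomial GLMM with a per-sample Gaussian random intercept,
## fitted by Laplace approximation of the marginal likelihood.
##
## Model, per observation i in sample j:
##   x_ij ~ Binomial(y_ij, theta_j),  logit(theta_j) = X_j beta + phi_j,
##   phi_j ~ N(0, sigma^2).
## The random-effect integral factorizes over samples; each factor is
## approximated by Laplace's method at the conditional mode phi_hat_j,
## found by a safeguarded Newton iteration (the conditional log-density is
## strictly concave in phi). The profile is maximized over (beta, log
## sigma) with nlminb. With sigma -> 0 the objective tends smoothly to the
## ordinary binomial GLM log-likelihood.

## numerically safe log(1 + exp(z))
log1pexp <- function(z) {
  out <- z
  small <- z < 35
  out[small] <- log1p(exp(z[small]))
  out
}

#' Fit a binomial GLMM with a per-sample random intercept
#'
#' Low-level fitter used by [fitDuCell()] and [fitDuBulk()]. Observations
#' are binomial successes \code{x} out of \code{y} trials with a logit-
#' linear predictor \code{X \%*\% beta + phi[sample]},
#' \code{phi_j ~ N(0, sigma^2)}. The marginal likelihood is maximized by
#' Laplace approximation over the per-sample random effects and
#' quasi-Newton optimization over \code{(beta, log sigma)}.
#'
#' @param x,y numeric vectors of successes and trials per observation
#'   (rows with \code{y = 0} are dropped: they carry no information).
#' @param sample factor (or coercible) assigning observations to samples.
#' @param X fixed-effect design matrix (including the intercept column).
#' @param startBeta optional starting coefficients; defaults to a plain
#'   binomial GLM fit.
#' @param logSigmaBounds box for \code{log sigma} in the outer
#'   optimization; the lower bound is the numerically-zero random effect.
#' @param sigma2Fixed if non-NULL, the random-effect variance is held at
#'   this value instead of being estimated; \code{0} drops the random
#'   effect entirely and yields an ordinary binomial GLM fit.
#' @param control passed to \code{stats::nlminb}.
#' @return list with \code{beta}, \code{sigma2}, \code{phi} (conditional
#'   modes), \code{loglik} (Laplace marginal log-likelihood including
#'   binomial constants), and \code{converged}.
#' @export
fitBinomGlmm <- function(x, y, sample, X,
                         startBeta = NULL,
                         logSigmaBounds = c(-7, 3),
                         sigma2Fixed = NULL,
                         control = list(rel.tol = 1e-12, iter.max = 500)) {
  keep <- y > 0
  x <- as.numeric(x[keep]); y <- as.numeric(y[keep])
  X <- X[keep, , drop = FALSE]
  s <- as.integer(factor(sample[keep]))
  J <- max(s)
  p <- ncol(X)
  if (any(x > y)) stop("x must not exceed y")
  const <- sum(lchoose(y, x))
  if (is.null(startBeta)) {
    fit0 <- suppressWarnings(stats::glm.fit(X, cbind(x, y - x),
                                            family = stats::binomial()))
    startBeta <- fit0$coefficients
    startBeta[is.na(startBeta)] <- 0
  }
  env <- new.env()
  env$phi <- numeric(J)
  tab <- function(v) as.vector(rowsum(v, s))
  ## inner: maximize the joint log density over phi at fixed (beta, sigma2)
  innerOpt <- function(etaFix, sigma2, phi) {
    pll <- function(phi) {
      eta <- etaFix + phi[s]
      sum(x * eta - y * log1pexp(eta)) - sum(phi^2) / (2 * sigma2)
    }
    f <- pll(phi)
    ok <- FALSE
    for (it in 1:80) {
      eta <- etaFix + phi[s]
      mu <- stats::plogis(eta)
      g <- tab(x - y * mu) - phi / sigma2
      if (max(abs(g)) < 1e-10 * max(1, abs(f))) { ok <- TRUE; break }
      h <- tab(y * mu * (1 - mu)) + 1 / sigma2
      step <- g / h
      for (half in 1:30) {
        cand <- phi + step
        fc <- pll(cand)
        if (fc >= f - 1e-12) break
        step <- step / 2
      }
      if (abs(fc - f) < 1e-13 * max(1, abs(f)) && max(abs(step)) < 1e-10) {
        phi <- cand; f <- fc; ok <- TRUE; break
      }
      phi <- cand; f <- fc
    }
    eta <- etaFix + phi[s]
    mu <- stats::plogis(eta)
    w <- tab(y * mu * (1 - mu)) + 1 / sigma2
    list(phi = phi, pll = f, w = w, ok = ok)
  }
  if (!is.null(sigma2Fixed) && sigma2Fixed == 0) {
    ## no random effect: ordinary binomial GLM likelihood
    negll0 <- function(beta) {
      eta <- drop(X %*% beta)
      -(sum(x * eta - y * log1pexp(eta)) + const)
    }
    opt <- stats::nlminb(startBeta, negll0,
                         control = list(rel.tol = 1e-14, iter.max = 500))
    return(list(beta = stats::setNames(opt$par, colnames(X)),
                sigma2 = 0, phi = numeric(J),
                loglik = -opt$objective,
                converged = opt$convergence == 0L,
                message = opt$message))
  }
  fixedSigma <- !is.null(sigma2Fixed)
  negll <- function(par) {
    beta <- par[seq_len(p)]
    sigma2 <- if (fixedSigma) sigma2Fixed else exp(2 * par[p + 1L])
    etaFix <- drop(X %*% beta)
    inner <- innerOpt(etaFix, sigma2, env$phi)
    env$phi <- inner$phi
    ll <- inner$pll - 0.5 * sum(log(sigma2 * inner$w))
    -(ll + const)
  }
  nPar <- if (fixedSigma) p else p + 1L
  start <- if (fixedSigma) startBeta else c(startBeta, log(0.3))
  lower <- c(rep(-50, p), if (!fixedSigma) logSigmaBounds[1L])
  upper <- c(rep(50, p), if (!fixedSigma) logSigmaBounds[2L])
  opt <- stats::nlminb(start, negll, lower = lower, upper = upper,
                       control = control)
  ## nlminb can report "false convergence" at a well-identified optimum
  ## (flat log-sigma direction); a restart from the solution that cannot
  ## improve the objective confirms convergence.
  converged <- opt$convergence == 0L
  if (!converged) {
    opt2 <- stats::nlminb(opt$par, negll, lower = lower, upper = upper,
                          control = control)
    if (opt2$objective <= opt$objective + 1e-6) {
      if (opt2$objective < opt$objective) opt <- opt2
      converged <- TRUE
    }
  }
  ## re-evaluate at the optimum so phi matches the returned parameters
  ll <- -negll(opt$par)
  list(beta = stats::setNames(opt$par[seq_len(p)], colnames(X)),
       sigma2 = if (fixedSigma) sigma2Fixed else
         unname(exp(2 * opt$par[p + 1L])),
       phi = env$phi,
       loglik = ll,
       converged = converged,
       message = opt$message)
}

#' Likelihood-ratio test for a condition effect in the binomial GLMM
#'
#' Fits the full model (intercept + condition dummies + covariates +
#' random intercept) and the null model without the condition dummies, and
#' compares twice the log-likelihood difference to a chi-squared
#' distribution with K - 1 degrees of freedom. The random-effect variance
#' is a nuisance parameter present under both hypotheses, so no boundary
#' correction is applied to the test of the condition coefficients.
#'
#' @param x,y successes and trials per observation.
#' @param sample sample of each observation.
#' @param condition factor of length \code{nlevels >= 2} giving each
#'   observation's biological condition; the first level is the baseline.
#' @param covariates optional numeric matrix of additional sample-level
#'   covariates (one row per observation), kept under both hypotheses.
#' @return list: \code{beta0}, \code{beta} (condition coefficients),
#'   \code{sigma2}, \code{loglikFull}, \code{loglikNull}, \code{lrt}
#'   (clamped at 0), \code{df}, \code{pValue}, \code{converged}.
#' @export
glmmLrtTest <- function(x, y, sample, condition, covariates = NULL) {
  condition <- droplevels(factor(condition))
  K <- nlevels(condition)
  keep <- y > 0
  if (length(unique(condition[keep])) < 2L)
    stop("need data in at least 2 conditions")
  Z <- stats::model.matrix(~condition)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    Z <- cbind(Z, covariates)
  }
  full <- fitBinomGlmm(x, y, sample, Z)
  Z0 <- Z[, -seq(2L, K), drop = FALSE]
  null <- fitBinomGlmm(x, y, sample, Z0,
                       startBeta = full$beta[-seq(2L, K)])
  lrt <- max(0, 2 * (full$loglik - null$loglik))
  conv <- full$converged && null$converged
  list(beta0 = unname(full$beta[1L]),
       beta = unname(full$beta[seq(2L, K)]),
       sigma2 = full$sigma2,
       loglikFull = full$loglik,
       loglikNull = null$loglik,
       lrt = lrt, df = K - 1L,
       pValue = if (conv) stats::pchisq(lrt, K - 1L, lower.tail = FALSE)
                else NA_real_,
       converged = conv)
}
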