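#' Hellinger standardization
#'
#' y_ij = sqrt(count_ij / column_total_j): square roots of relative
#' abundances, so that each sample's squared entries sum to 1 and
#' downstream dissimilarities are robust to total-count differences.
#'
#' @param x a [CommunityMatrix-class] or taxa-x-samples count matrix
#' @return matrix of the same shape.
#' @export
hellingerTransform <- function(x) {
  m <- if (is(x, "CommunityMatrix")) counts(x) else as.matrix(x)
  if (any(colSums(m) == 0)) stop("all-zero sample(s): ",
                                 paste(colnames(m)[colSums(m) == 0], collapse = ", "))
  t(vegan::decostand(t(m), method = "hellinger"))
}

#' Bray-Curtis and Sorensen dissimilarity matrices
#'
#' `brayCurtis()` computes BC(a, b) = 1 - 2 sum(min(a_i, b_i)) /
#' (sum a_i + sum b_i) between all sample pairs; `sorensen()` is its
#' presence-absence form 1 - 2|A n B| / (|A| + |B|). Pairs of empty
#' samples yield `NaN` (flagged by a warning).
#'
#' @param x a [CommunityMatrix-class], a taxa-x-samples matrix
#'   (e.g. [hellingerTransform()] output), or for `sorensen()` a
#'   presence-absence matrix/[CommunityMatrix-class]
#' @return square symmetric matrix with zero diagonal, sample ids as
#'   dimnames, entries in \[0, 1\].
#' @export
brayCurtis <- function(x) {
  m <- if (is(x, "CommunityMatrix")) counts(x) else as.matrix(x)
  if (ncol(m) < 2L) stop("need >= 2 samples")
  d <- as.matrix(vegan::vegdist(t(m), method = "bray"))
  if (any(is.na(d))) warning("undefined entries for empty-sample pairs")
  d
}

#' @rdname brayCurtis
#' @export
sorensen <- function(x) {
  m <- if (is(x, "CommunityMatrix")) counts(x) else as.matrix(x)
  if (ncol(m) < 2L) stop("need >= 2 samples")
  d <- as.matrix(vegan::vegdist(t(m), method = "bray", binary = TRUE))
  if (any(is.na(d))) warning("undefined entries for empty-sample pairs")
  d
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the off-diagonal entries with significance by
#' simultaneous row/column permutation of the second matrix;
#' p = (1 + #\{r_perm >= r\}) / (n_perm + 1), one-sided for positive
#' association (the standard ecological usage); a two-sided p on |r| is
#' reported alongside. A constant second matrix yields r = NA, p = 1.
#'
#' @param d1,d2 square symmetric dissimilarity matrices over the same samples
#' @param nPerm number of permutations
#' @param seed integer seed
#' @return list with `r`, `p`, `pTwoSided`, `nPerm`.
#' @export
mantelTest <- function(d1, d2, nPerm = 999, seed = 1) {
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  if (!all(dim(d1) == dim(d2))) stop("matrices must match")
  if (!is.null(dimnames(d1)) && !is.null(dimnames(d2)) &&
      !identical(colnames(d1), colnames(d2)))
    stop("sample sets differ between the two matrices")
  if (ncol(d1) < 4L) stop("need >= 4 samples for a meaningful permutation null")
  lo <- lower.tri(d2)
  if (stats::sd(d2[lo]) == 0 || stats::sd(d1[lo]) == 0)
    return(list(r = NA_real_, p = 1, pTwoSided = 1, nPerm = nPerm,
                degenerate = TRUE))
  mt <- withSeed(seed, vegan::mantel(stats::as.dist(d1), stats::as.dist(d2),
                                     method = "pearson", permutations = nPerm))
  perm <- mt$perm
  list(r = unname(mt$statistic),
       p = (1 + sum(perm >= mt$statistic)) / (nPerm + 1),
       pTwoSided = (1 + sum(abs(perm) >= abs(mt$statistic))) / (nPerm + 1),
       nPerm = nPerm)
}

## ---- CV equality: modified signed-likelihood ratio test ---------------------

# Profile log-likelihood of k normal samples under a common CV tau.
# For fixed tau, the ML group mean solves n tau^2 mu^2 + (sum x) mu -
# (sum x^2) = 0, giving a closed form; sd_i = tau mu_i.
.commonCVLogLik <- function(tau, stats) {
  ll <- 0
  for (g in stats) {
    mu <- (-g$sx + sqrt(g$sx^2 + 4 * g$n * tau^2 * g$sxx)) / (2 * g$n * tau^2)
    s2 <- tau^2 * mu^2
    ll <- ll + (-g$n / 2 * log(2 * pi * s2) -
                (g$sxx - 2 * mu * g$sx + g$n * mu^2) / (2 * s2))
  }
  ll
}

.cvSLRTStat <- function(groups) {
  stats <- lapply(groups, function(x)
    list(n = length(x), sx = sum(x), sxx = sum(x^2),
         mean = mean(x), sd = stats::sd(x)))
  # unconstrained ML: mu_i = xbar_i, sigma_i^2 = SS_i / n_i
  ll1 <- sum(vapply(stats, function(g) {
    s2 <- (g$sxx - g$sx^2 / g$n) / g$n
    -g$n / 2 * log(2 * pi * s2) - g$n / 2
  }, numeric(1)))
  opt <- stats::optimize(function(lt) -.commonCVLogLik(exp(lt), stats),
                         interval = c(log(1e-4), log(5)), tol = 1e-10)
  ll0 <- -opt$objective
  lrt <- max(2 * (ll1 - ll0), 0)
  cvs <- vapply(stats, function(g) g$sd / g$mean, numeric(1))
  mus <- vapply(stats, function(g) {
    tau <- exp(opt$minimum)
    (-g$sx + sqrt(g$sx^2 + 4 * g$n * tau^2 * g$sxx)) / (2 * g$n * tau^2)
  }, numeric(1))
  list(lrt = lrt, tau = exp(opt$minimum), cvs = cvs, mu0 = mus,
       n = vapply(stats, `[[`, numeric(1), "n"))
}

#' Modified signed-likelihood ratio test for equality of CVs
#'
#' Tests whether k normal samples share a common coefficient of variation.
#' The likelihood ratio compares the unconstrained fit with the common-CV
#' fit (profile likelihood over tau, with closed-form group means given
#' tau). For k = 2 the signed root r = sign(cv1 - cv2) sqrt(LRT) is
#' referred to the standard normal (two-sided); for k > 2 the LRT is
#' referred to chi-squared with k - 1 df. The small-sample modification is
#' delivered as a parametric bootstrap: `nSim` data sets are simulated
#' under the common-CV fit and p_sim = (1 + #\{stat_sim >= stat_obs\}) /
#' (n_sim + 1), the primary p-value.
#'
#' @param groups list of numeric vectors (>= 2 groups, each >= 3 values,
#'   positive means, nonzero variance)
#' @param nSim parametric-bootstrap simulation runs (0 skips the bootstrap
#'   and reports only the asymptotic p)
#' @param seed integer seed
#' @return list of class `SLRTResult`: `statistic` (signed root for k = 2,
#'   LRT otherwise), `pAsymptotic`, `pSim`, `cvs`, `tauHat`, `nSim`.
#' @export
cvSLRT <- function(groups, nSim = 1000, seed = 1) {
  if (!is.list(groups) || length(groups) < 2L) stop("need >= 2 groups")
  for (x in groups) {
    if (length(x) < 3L) stop("each group needs >= 3 observations")
    if (mean(x) <= 0) stop("group means must be positive")
    if (stats::sd(x) == 0) stop("a group has zero variance")
  }
  k <- length(groups)
  obs <- .cvSLRTStat(groups)
  if (k == 2L) {
    stat <- sign(obs$cvs[1] - obs$cvs[2]) * sqrt(obs$lrt)
    pAsym <- 2 * stats::pnorm(-abs(stat))
    ref <- abs(stat)
  } else {
    stat <- obs$lrt
    pAsym <- stats::pchisq(stat, df = k - 1, lower.tail = FALSE)
    ref <- stat
  }
  nSim <- assertCount(nSim, "nSim", positive = FALSE)
  if (nSim == 0L)
    return(structure(list(statistic = unname(stat),
                          pAsymptotic = unname(pAsym), pSim = NA_real_,
                          cvs = obs$cvs, tauHat = obs$tau, nSim = 0L),
                     class = "SLRTResult"))
  exceed <- withSeed(seed, {
    cnt <- 0L
    for (b in seq_len(nSim)) {
      sim <- lapply(seq_len(k), function(i)
        stats::rnorm(obs$n[i], obs$mu0[i], obs$tau * obs$mu0[i]))
      st <- try(.cvSLRTStat(sim)$lrt, silent = TRUE)
      if (!inherits(st, "try-error") &&
          (if (k == 2L) sqrt(st) else st) >= ref) cnt <- cnt + 1L
    }
    cnt
  })
  structure(list(statistic = unname(stat), pAsymptotic = unname(pAsym),
                 pSim = (1 + exceed) / (nSim + 1),
                 cvs = obs$cvs, tauHat = obs$tau, nSim = nSim),
            class = "SLRTResult")
}
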