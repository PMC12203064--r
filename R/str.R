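#' Cumulative richness over sliding time windows
#'
#' For every contiguous block of `window` consecutive samples (time order),
#' the number of taxa present in at least one sample of the block.
#'
#' @param pm presence-absence [CommunityMatrix-class] (single station)
#' @param window block length in sampling occasions, 1..n_samples
#' @return numeric vector of length `n_samples - window + 1`.
#' @export
cumulativeRichness <- function(pm, window) {
  m <- counts(pm)
  n <- ncol(m)
  window <- assertCount(window, "window")
  if (window > n) stop("window exceeds the number of samples")
  vapply(seq_len(n - window + 1L), function(j) {
    sum(rowSums(m[, j:(j + window - 1L), drop = FALSE]) > 0)
  }, numeric(1))
}

# all window lengths at once via per-taxon next-occurrence indices:
# a taxon is counted in block (j, w) iff its first occurrence >= j is
# <= j + w - 1.  O(taxa * n + n^2) instead of O(taxa * n^3).
.richnessAllWindows <- function(m) {
  n <- ncol(m)
  nt <- nrow(m)
  nxt <- matrix(Inf, nt, n)
  cur <- rep(Inf, nt)
  for (j in n:1) {
    cur[m[, j] > 0] <- j
    nxt[, j] <- cur
  }
  out <- matrix(NA_real_, n, n)  # [window, start]
  for (j in seq_len(n)) {
    d <- nxt[, j] - j
    maxw <- n - j + 1L
    tab <- tabulate(d[is.finite(d) & d < maxw] + 1L, nbins = maxw)
    out[seq_len(maxw), j] <- cumsum(tab)
  }
  out
}

#' Species-time relationship curve
#'
#' For each window length T = 1..n_samples, the geometric mean over all
#' contiguous windows of length T of the cumulative richness
#' ([cumulativeRichness()]). Windows with zero richness are excluded from
#' the geometric mean (with a warning) since log(0) is undefined.
#'
#' @param pm presence-absence [CommunityMatrix-class], time-ordered samples
#' @return data.frame of class `STRCurve` with columns `T`, `Sgeo`,
#'   `nWindows`, `nZero`.
#' @export
strCurve <- function(pm) {
  m <- counts(pm)
  if (ncol(m) < 3L) stop("at least 3 samples are required")
  if (all(m == 0)) stop("all-zero presence matrix")
  R <- .richnessAllWindows(m)
  n <- ncol(m)
  rows <- lapply(seq_len(n), function(w) {
    r <- R[w, seq_len(n - w + 1L)]
    pos <- r[r > 0]
    data.frame(T = w, Sgeo = if (length(pos)) geometricMean(pos) else NA_real_,
               nWindows = length(r), nZero = sum(r == 0))
  })
  out <- do.call(rbind, rows)
  if (any(out$nZero > 0))
    warning(sum(out$nZero), " zero-richness window(s) excluded from geometric means")
  class(out) <- c("STRCurve", "data.frame")
  out
}

#' Fit the power law S = c * T^w to an STR curve
#'
#' Nonlinear least squares on the untransformed scale, initialized from the
#' log-log ordinary regression; `se_w` from the Jacobian-based covariance;
#' adjusted R^2 on the untransformed scale (clamped to \[0, 1\]; defined as
#' 1 for an exactly constant curve, which the model fits perfectly).
#'
#' @param curve an [strCurve()] result (or data.frame with `T`, `Sgeo`)
#' @return An [STRFit-class].
#' @export
fitPowerLaw <- function(curve) {
  d <- curve[is.finite(curve$Sgeo) & curve$Sgeo > 0, c("T", "Sgeo")]
  if (nrow(d) < 3L) stop("need >= 3 window lengths with positive richness")
  ols <- stats::lm(log(Sgeo) ~ log(T), data = d)
  start <- list(cc = unname(exp(stats::coef(ols)[1])),
                w = unname(stats::coef(ols)[2]))
  ft <- try(minpack.lm::nlsLM(Sgeo ~ cc * T^w, data = d, start = start,
                              control = minpack.lm::nls.lm.control(maxiter = 200)),
            silent = TRUE)
  if (inherits(ft, "try-error")) {
    start <- list(cc = mean(d$Sgeo), w = 0)
    ft <- try(minpack.lm::nlsLM(Sgeo ~ cc * T^w, data = d, start = start,
                                control = minpack.lm::nls.lm.control(maxiter = 200)),
              silent = TRUE)
    if (inherits(ft, "try-error"))
      stop("power-law fit failed to converge: ", attr(ft, "condition")$message)
  }
  co <- summary(ft)$coefficients
  pred <- stats::predict(ft)
  ssRes <- sum((d$Sgeo - pred)^2)
  ssTot <- sum((d$Sgeo - mean(d$Sgeo))^2)
  n <- nrow(d)
  adj <- if (ssTot <= .Machine$double.eps * n) 1
         else 1 - (ssRes / ssTot) * (n - 1) / (n - 2 - 1)
  new("STRFit", cHat = unname(co["cc", 1]), wHat = unname(co["w", 1]),
      seC = unname(co["cc", 2]), seW = unname(co["w", 2]),
      adjR2 = min(max(adj, 0), 1), pPerm = NA_real_, pPermW = NA_real_,
      nPerm = 0L, curve = as.data.frame(curve))
}

#' Permutation significance of an STR fit
#'
#' Permutes the sample order uniformly, recomputes the full STR curve and
#' power-law fit per permutation, and reports
#' p = (1 + #\{adj R^2_perm >= adj R^2_obs\}) / (n_perm + 1). A w-based
#' null (same convention on the exponent) is reported alongside.
#' Permutations whose fit fails are counted as non-exceeding.
#'
#' @param pm presence-absence [CommunityMatrix-class] (single station)
#' @param nPerm number of permutations (>= 1)
#' @param seed integer seed
#' @return list with `pPerm`, `pPermW`, `obs` (the observed [STRFit-class]),
#'   `nPerm`.
#' @export
strPermutationTest <- function(pm, nPerm = 1000, seed = 1) {
  nPerm <- assertCount(nPerm, "nPerm")
  obs <- fitPowerLaw(strCurve(pm))
  n <- ncol(pm)
  stat <- withSeed(seed, {
    vapply(seq_len(nPerm), function(b) {
      perm <- pm
      ord <- sample.int(n)
      mp <- counts(pm)[, ord, drop = FALSE]
      colnames(mp) <- colnames(pm)   # relabel: times keep their order
      SummarizedExperiment::assay(perm, "counts") <- mp
      ftp <- try(suppressWarnings(fitPowerLaw(strCurve(perm))), silent = TRUE)
      if (inherits(ftp, "try-error")) c(-Inf, -Inf)
      else c(ftp@adjR2, ftp@wHat)
    }, numeric(2))
  })
  list(pPerm = (1 + sum(stat[1, ] >= obs@adjR2)) / (nPerm + 1),
       pPermW = (1 + sum(stat[2, ] >= obs@wHat)) / (nPerm + 1),
       obs = obs, nPerm = nPerm)
}

#' Species-time relationship analysis of one station
#'
#' Convenience wrapper: [strCurve()] + [fitPowerLaw()] +
#' (optionally) [strPermutationTest()].
#'
#' @inheritParams strPermutationTest
#' @param nPerm permutations (0 skips the test)
#' @return An [STRFit-class] with permutation p-values filled in.
#' @export
strAnalysis <- function(pm, nPerm = 1000, seed = 1) {
  if (nPerm == 0) return(fitPowerLaw(strCurve(pm)))
  pt <- strPermutationTest(pm, nPerm = nPerm, seed = seed)
  ft <- pt$obs
  ft@pPerm <- pt$pPerm
  ft@pPermW <- pt$pPermW
  ft@nPerm <- as.integer(nPerm)
  ft
}
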