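#' Construct a consumer-resource + neutral model
#'
#' Per-taxon parameters are recycled to `nTaxa`. The default community
#' spreads salinity optima across the estuarine range so that salinity
#' fluctuations re-rank competitors, which is the deterministic
#' (environmental-filtering) signal the determinism statistic detects.
#' Default kinetics are slow (net per-capita rates well below 1/30 per
#' day) so that monthly sampling resolves the dynamics; see the methods
#' vignette for the reasoning.
#'
#' @param nTaxa number of taxa
#' @param muMax maximal growth rate (/day)
#' @param K resource half-saturation (resource units)
#' @param sOpt salinity niche optimum (PSU); default evenly spread 12-34
#' @param sWidth niche width (PSU)
#' @param m loss rate (/day)
#' @param sigma demographic noise scale (per sqrt(abundance) per sqrt(day))
#' @param p metacommunity relative abundances (normalized to sum to 1)
#' @param q per-capita consumption coefficient
#' @param RSupply resource supply level
#' @param DR resource dilution rate (/day)
#' @param lambda immigration rate (/day)
#' @return A [CRNModel-class].
#' @export
crnModel <- function(nTaxa = 40, muMax = 0.12, K = 1,
                     sOpt = seq(12, 34, length.out = nTaxa), sWidth = 5,
                     m = 0.03, sigma = 0.05, p = rep(1, nTaxa), q = 0.05,
                     RSupply = 10, DR = 1, lambda = 0.01) {
  nTaxa <- assertCount(nTaxa, "nTaxa")
  p <- rep_len(p, nTaxa)
  new("CRNModel",
      muMax = rep_len(muMax, nTaxa), K = rep_len(K, nTaxa),
      sOpt = rep_len(sOpt, nTaxa), sWidth = rep_len(sWidth, nTaxa),
      m = rep_len(m, nTaxa), sigma = rep_len(sigma, nTaxa),
      p = p / sum(p), q = rep_len(q, nTaxa),
      RSupply = RSupply, DR = DR, lambda = lambda)
}

#' Deterministic drift of the consumer-resource + neutral model
#'
#' Per-taxon abundance drift
#' f_i = N_i (muMax_i R/(K_i+R) phi_i(s) - m_i) + lambda p_i with the
#' Gaussian salinity niche phi_i(s) = exp(-(s - sOpt_i)^2 / (2 sWidth_i^2)),
#' and resource drift
#' f_R = DR (RSupply - R) - sum_i q_i muMax_i R/(K_i+R) phi_i(s) N_i.
#'
#' @param model a [crnModel()]
#' @param N abundance vector (>= 0)
#' @param R resource level (>= 0)
#' @param s salinity (PSU)
#' @return list with `fN` (per-taxon drift) and `fR` (resource drift).
#' @export
crnDrift <- function(model, N, R, s) {
  phi <- exp(-(s - model@sOpt)^2 / (2 * model@sWidth^2))
  uptake <- model@muMax * R / (model@K + R) * phi
  list(fN = N * (uptake - model@m) + model@lambda * model@p,
       fR = model@DR * (model@RSupply - R) - sum(model@q * uptake * N))
}

#' Simulate the consumer-resource + neutral SDE
#'
#' Euler-Maruyama integration of
#' dN_i = f_i dt + sigma_i sqrt(max(N_i, 0)) dW_i and dR = f_R dt, with
#' negative excursions clipped to 0, salinity linearly interpolated
#' between sampling times, and a burn-in before the first sample so the
#' community starts near its stochastic attractor. Trajectories are
#' reported at the requested sampling times.
#'
#' @param model a [crnModel()]
#' @param times strictly increasing sampling days
#' @param env data.frame with `salinity` aligned to `times`
#' @param dtInt integration step (days); must not exceed the smallest
#'   sampling interval
#' @param seed integer seed
#' @param N0 initial abundances (default proportional to `p`)
#' @param R0 initial resource (default `RSupply`)
#' @param burnIn days integrated before the first sample (at its salinity)
#' @return list with `N` (taxa x times abundances), `R` (resource at the
#'   sampling times), `times`.
#' @export
simulateCRN <- function(model, times, env, dtInt = 0.1, seed = 1,
                        N0 = NULL, R0 = model@RSupply, burnIn = 365) {
  n <- length(times)
  if (n < 1L || (n > 1L && any(diff(times) <= 0)))
    stop("times must be strictly increasing")
  if (dtInt <= 0 || (n > 1L && dtInt > min(diff(times))))
    stop("dtInt must be positive and <= the smallest sampling interval")
  sal <- env$salinity
  if (length(sal) != n) stop("env must be aligned to times")
  salAt <- if (n == 1L) function(t) sal else
    stats::approxfun(times, sal, rule = 2)
  nt <- nTaxa(model)
  # default start near the carrying scale set by supply/consumption balance
  if (is.null(N0)) N0 <- model@p * 5000
  withSeed(seed, {
    N <- pmax(N0, 0); R <- max(R0, 0)
    noisy <- any(model@sigma > 0)
    stepTo <- function(t0, t1, N, R) {
      span <- t1 - t0
      nSteps <- max(1L, ceiling(span / dtInt))
      h <- span / nSteps
      sh <- sqrt(h)
      for (k in seq_len(nSteps)) {
        s <- salAt(t0 + (k - 1) * h)
        phi <- exp(-(s - model@sOpt)^2 / (2 * model@sWidth^2))
        uptake <- model@muMax * R / (model@K + R) * phi
        N <- N + (N * (uptake - model@m) + model@lambda * model@p) * h
        if (noisy) N <- N + model@sigma * sqrt(pmax(N, 0)) * stats::rnorm(nt) * sh
        N <- pmax(N, 0)
        # resource loss is stiff when consumers are abundant: semi-implicit
        # update (implicit in the linearized consumption + dilution)
        consPerR <- sum(model@q * model@muMax * phi * N / (model@K + R))
        R <- (R + h * model@DR * model@RSupply) /
          (1 + h * (model@DR + consPerR))
        if (any(!is.finite(N)) || !is.finite(R))
          stop(sprintf("non-finite state at t = %.2f (step %d); reduce dtInt",
                       t0 + k * h, k))
      }
      list(N = N, R = R)
    }
    if (burnIn > 0) {
      st <- stepTo(-burnIn, 0, N, R)
      N <- st$N; R <- st$R
    }
    out <- matrix(0, nt, n)
    Rout <- numeric(n)
    out[, 1] <- N; Rout[1] <- R
    if (n > 1L) for (j in seq_len(n - 1L)) {
      st <- stepTo(times[j], times[j + 1], out[, j], Rout[j])
      out[, j + 1] <- st$N; Rout[j + 1] <- st$R
    }
    rownames(out) <- sprintf("crn%04d", seq_len(nt))
    list(N = out, R = Rout, times = times)
  })
}

## ---- fitting ---------------------------------------------------------------

# quasi-steady-state resource under total (relative) abundance Xtot:
# DR (RSupply - R)(K + R) = q muRef R Xtot  ->  positive quadratic root
.qssResource <- function(RSupply, DR, K, q, muRef, Xtot) {
  a <- DR
  b <- DR * K - DR * RSupply + q * muRef * Xtot
  cc <- -DR * RSupply * K
  (-b + sqrt(b^2 - 4 * a * cc)) / (2 * a)
}

# Predicted increment of x over each interval under the fitted drift.
# theta = (A, sOpt, sWidth, m); the per-capita rate A*phi(s_k) - m - gbar_k
# is constant within an interval, so the linear drift ODE
# dx = (x * rate + lambda p) dt has the exact solution
# x(t+dt) = x e^(rate dt) + lambda p (e^(rate dt) - 1)/rate,
# used here (clipped to [0, 1]) instead of an unstable Euler step; it
# reduces to the plain Euler mean f dt as rate*dt -> 0.
.predictIncrement <- function(x, dtv, salK, gbar, cK, theta, lambdaP) {
  phi <- exp(-(salK - theta[2])^2 / (2 * theta[3]^2))
  rate <- theta[1] * cK * phi - theta[4] - gbar
  x0 <- x[seq_along(dtv)]
  er <- exp(pmin(rate * dtv, 30))
  grow <- ifelse(abs(rate) > 1e-12, (er - 1) / rate, dtv)
  pmin(pmax(x0 * er + lambdaP * grow, 0), 1) - x0
}

# increment prediction at one interval for all taxa, given rates
.predictAtInterval <- function(x0, rate, dt, lambdaP) {
  er <- exp(pmin(rate * dt, 30))
  grow <- ifelse(abs(rate) > 1e-12, (er - 1) / rate, dt)
  pmin(pmax(x0 * er + lambdaP * grow, 0), 1) - x0
}

.taxonNegLL <- function(theta, x, dtv, salK, gbar, cK, lambdaP) {
  if (any(!is.finite(theta))) return(1e10)
  pred <- .predictIncrement(x, dtv, salK, gbar, cK, theta, lambdaP)
  dx <- diff(x)
  keep <- x[seq_along(dtv)] > 0
  if (sum(keep) < 3L) return(1e10)
  v <- x[seq_along(dtv)][keep] * dtv[keep]
  s2 <- mean((dx[keep] - pred[keep])^2 / v)
  if (!is.finite(s2)) return(1e10)
  if (s2 <= 0) s2 <- 1e-20
  0.5 * sum(keep) * log(s2) + 0.5 * sum(log(v)) + 0.5 * sum(keep)
}

#' Fit the consumer-resource + neutral model to a community time series
#'
#' Counts are converted to relative abundances; the `topK` most abundant
#' taxa are fitted, each by maximizing the Euler pseudo-likelihood
#' Delta x_i(t_k) ~ Normal(f_i dt_k, sigma_i^2 x_i dt_k). In relative-
#' abundance space the resource coupling of the consumer-resource model
#' acts as a mean-field term: the per-capita drift is
#' A_i phi_i(s) - m_i - gbar(t), with A_i = muMax_i R/(K+R) the uptake
#' amplitude at the quasi-steady-state resource, phi_i the Gaussian
#' salinity niche, and gbar(t) the abundance-weighted community-mean
#' per-capita growth, which keeps the simplex dynamics bounded (the
#' replicator form of the model). gbar is unknown a priori and is
#' estimated jointly with the parameters by block coordinate descent,
#' alternating per-taxon fits with per-interval profiling of two shared
#' states -- gbar(t) and a relative uptake factor c(t) (the temporal
#' variation of the Monod factor R/(K+R) around its quasi-steady-state
#' value) -- over `nIter` passes. Immigration enters as
#' lambda p_i with p_i the taxon's mean relative abundance; sigma_i is
#' profiled out in closed form. Because the fitted drift is linear in x
#' within an interval, its within-interval integral has a closed form
#' (exponential solution), which is used as the pseudo-likelihood mean;
#' it reduces to the plain Euler mean f dt for slow rates and stays
#' numerically stable at monthly sampling intervals.
#'
#' @param object a [CommunityMatrix-class] (salinity in its column data;
#'   one station) or a taxa-x-times matrix of abundances
#' @param times,salinity required when `object` is a plain matrix
#' @param topK number of most-abundant taxa to fit
#' @param K,q,RSupply,DR,lambda shared model constants used during fitting
#' @param muRef reference uptake rate used in the resource closure
#' @param nIter mean-field self-consistency passes
#' @param estimateUptake also profile the per-interval uptake factor c(t)?
#'   Default: only when >= 10 taxa are fitted (with fewer taxa the shared
#'   factor is weakly identified against the per-taxon niches)
#' @param salinityAt evaluate the niche at the interval \code{"mid"}point
#'   salinity (default; matches the average within-interval forcing) or at
#'   the interval \code{"start"}
#' @return list of class `CRNFit`: `model` (fitted [CRNModel-class] for the
#'   fitted taxa), `sigma`, `driftIncrement` and `noiseVariance` (taxa x
#'   intervals), `gbar`, `x` (relative abundances), `times`, `skipped`
#'   (taxa with < 3 nonzero observations), `negLL`.
#' @export
fitCRN <- function(object, times = NULL, salinity = NULL, topK = 50,
                   K = 1, q = 0.05, RSupply = 10, DR = 1, lambda = 0.01,
                   muRef = 0.6, nIter = 3, estimateUptake = NULL,
                   salinityAt = c("mid", "start")) {
  salinityAt <- match.arg(salinityAt)
  # profiling the shared uptake factor needs enough taxa to be identified
  # against the per-taxon niches; default on only for richer fits
  if (is(object, "CommunityMatrix")) {
    if (length(unique(stations(object))) != 1L)
      stop("fit one station at a time (see stationSubset())")
    times <- sampleTimes(object)
    salinity <- environmentSeries(object)$salinity
    x <- sweep(counts(object), 2, colSums(counts(object)), "/")
  } else {
    x <- as.matrix(object)
    tot <- colSums(x)
    if (any(abs(tot - 1) > 1e-6)) x <- sweep(x, 2, tot, "/")
  }
  if (is.null(times) || is.null(salinity))
    stop("times and salinity are required")
  if (ncol(x) < 10L) stop("need >= 10 time points")
  if (is.null(rownames(x))) rownames(x) <- sprintf("taxon%04d", seq_len(nrow(x)))
  ord <- order(rowMeans(x), decreasing = TRUE)
  sel <- ord[seq_len(min(topK, nrow(x)))]
  x <- x[sel, , drop = FALSE]
  dtv <- diff(times)
  nInt <- length(dtv)
  salK <- if (salinityAt == "mid")
    (salinity[seq_len(nInt)] + salinity[-1]) / 2 else salinity[seq_len(nInt)]
  Rhat <- .qssResource(RSupply, DR, K, q, muRef, 1)
  g <- Rhat / (K + Rhat)
  lo <- c(0, min(salinity) - 10, 0.5, 0)
  hi <- c(2, max(salinity) + 10, 50, 2)
  fitOne <- function(xi, gbar, cK) {
    if (sum(xi > 0) < 3L) return(NULL)
    sBar <- sum(salK * xi[seq_len(nInt)]) / max(sum(xi[seq_len(nInt)]), 1e-12)
    lambdaP <- lambda * mean(xi)
    # the likelihood is multimodal in sOpt (a niche tail can mimic a
    # monotone response): start from a grid of optima across the observed
    # salinity range plus the abundance-weighted mean
    sQ <- stats::quantile(salK, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE)
    starts <- c(list(c(0.1, sBar, 4, 0.05),
                     c(0.3, sBar, 8, 0.1),
                     c(0.02, sBar, 10, 0.01)),
                lapply(sQ, function(s) c(0.1, s, 4, 0.03)),
                lapply(sQ[c(1, 3, 5)], function(s) c(0.2, s, 2, 0.05)))
    best <- NULL
    for (s0 in starts) {
      ft <- try(stats::optim(pmin(pmax(s0, lo), hi), .taxonNegLL, x = xi,
                             dtv = dtv, salK = salK, gbar = gbar, cK = cK,
                             lambdaP = lambdaP,
                             method = "L-BFGS-B", lower = lo, upper = hi,
                             control = list(maxit = 400)), silent = TRUE)
      if (inherits(ft, "try-error")) next
      if (is.null(best) || ft$value < best$value) best <- ft
    }
    if (is.null(best)) return(NULL)
    th <- best$par
    pred <- .predictIncrement(xi, dtv, salK, gbar, cK, th, lambdaP)
    keep <- xi[seq_len(nInt)] > 0
    v <- xi[seq_len(nInt)][keep] * dtv[keep]
    s2 <- mean((diff(xi)[keep] - pred[keep])^2 / v)
    list(theta = th, sigma = sqrt(max(s2, 0)), pred = pred, value = best$value)
  }
  # Block coordinate descent on the joint pseudo-likelihood: per-taxon
  # parameters given the shared per-interval states, then the shared states
  # profiled per interval given the parameters.  Two shared states per
  # interval: gbar_k (community-mean per-capita growth, the replicator
  # coupling) and cK_k (relative resource uptake factor g(t)/g0, which
  # enters multiplicatively with the niche).
  if (is.null(estimateUptake)) estimateUptake <- nrow(x) >= 10L
  gbar <- rep(0, nInt)
  cK <- rep(1, nInt)
  fits <- NULL
  dxAll <- t(diff(t(x)))
  for (it in seq_len(max(nIter, 1L))) {
    fits <- lapply(seq_len(nrow(x)), function(i) fitOne(x[i, ], gbar, cK))
    ok <- !vapply(fits, is.null, logical(1))
    if (!any(ok)) stop("no taxon could be fitted")
    if (it == nIter) break
    th <- do.call(rbind, lapply(fits[ok], `[[`, "theta"))
    sg2 <- pmax(vapply(fits[ok], `[[`, numeric(1), "sigma")^2, 1e-12)
    xo <- x[ok, , drop = FALSE]
    aPhi <- th[, 1] * exp(-outer(th[, 2], salK, "-")^2 / (2 * th[, 3]^2))
    lamP <- lambda * rowMeans(xo)
    for (k in seq_len(nInt)) {
      x0 <- xo[, k]
      keep <- x0 > 0
      if (sum(keep) < 3L) next
      dxk <- dxAll[ok, k][keep]
      wgt <- 1 / (sg2[keep] * x0[keep])
      obj2 <- function(par) {
        rate <- aPhi[keep, k] * par[2] - th[keep, 4] - par[1]
        pred <- .predictAtInterval(x0[keep], rate, dtv[k], lamP[keep])
        sum((dxk - pred)^2 * wgt)
      }
      if (estimateUptake) {
        ft <- try(stats::optim(c(gbar[k], cK[k]), obj2, method = "L-BFGS-B",
                               lower = c(-2, 0.05), upper = c(2, 5)),
                  silent = TRUE)
        if (!inherits(ft, "try-error")) {
          gbar[k] <- ft$par[1]; cK[k] <- ft$par[2]
        }
      } else {
        gbar[k] <- stats::optimize(function(g) obj2(c(g, 1)),
                                   c(-2, 2), tol = 1e-8)$minimum
      }
    }
  }
  ok <- !vapply(fits, is.null, logical(1))
  theta <- do.call(rbind, lapply(fits[ok], `[[`, "theta"))
  sigma <- vapply(fits[ok], `[[`, numeric(1), "sigma")
  xo <- x[ok, , drop = FALSE]
  drift <- do.call(rbind, lapply(fits[ok], `[[`, "pred"))
  noiseVar <- sweep(xo[, seq_len(nInt), drop = FALSE] * sigma^2, 2, dtv, "*")
  nFit <- sum(ok)
  model <- new("CRNModel",
               muMax = theta[, 1] / g, K = rep(K, nFit), sOpt = theta[, 2],
               sWidth = theta[, 3], m = theta[, 4], sigma = sigma,
               p = rep(1 / nFit, nFit), q = rep(q, nFit),
               RSupply = RSupply, DR = DR, lambda = lambda)
  dimnames(drift) <- list(rownames(xo), NULL)
  structure(list(model = model, sigma = stats::setNames(sigma, rownames(xo)),
                 driftIncrement = drift, noiseVariance = noiseVar,
                 gbar = gbar, cK = cK, x = xo, times = times, dt = dtv,
                 skipped = rownames(x)[!ok],
                 negLL = sum(vapply(fits[ok], `[[`, numeric(1), "value"))),
            class = "CRNFit")
}

#' Determinism of one taxon at one time
#'
#' The share (as a percentage) of the expected squared abundance increment
#' attributable to the fitted deterministic drift:
#' D_i(t_k) = 100 (f_i dt_k)^2 / ((f_i dt_k)^2 + sigma_i^2 x_i dt_k).
#' Equal to 100 when noise vanishes, 0 when drift vanishes, and 50 when
#' the two expected squared contributions match; defined as 0 (flagged by
#' attribute) when both vanish.
#'
#' @param fit a [fitCRN()] result
#' @param taxon taxon index or name among the fitted taxa
#' @param k sampling-interval index
#' @return percentage in \[0, 100\].
#' @export
taxonDeterminism <- function(fit, taxon, k) {
  stopifnot(inherits(fit, "CRNFit"))
  f2 <- fit$driftIncrement[taxon, k]^2
  v <- fit$noiseVariance[taxon, k]
  if (f2 == 0 && v == 0) return(structure(0, degenerate = TRUE))
  100 * f2 / (f2 + v)
}

#' Community-level determinism aggregates
#'
#' Per-interval unweighted mean over taxa present and abundance-weighted
#' mean (weights = relative abundances at the interval start), plus their
#' time averages. Intervals with an empty community are omitted.
#'
#' @param D taxa x intervals determinism matrix (0-100)
#' @param abundances taxa x intervals relative abundances (same axes)
#' @return A [DeterminismResult-class].
#' @export
communityDeterminism <- function(D, abundances) {
  if (!all(dim(D) == dim(abundances))) stop("D and abundances must share axes")
  nInt <- ncol(D)
  dw <- du <- rep(NA_real_, nInt)
  for (k in seq_len(nInt)) {
    xk <- abundances[, k]
    present <- xk > 0 & is.finite(D[, k])
    if (!any(present)) next
    du[k] <- mean(D[present, k])
    dw[k] <- sum(xk[present] * D[present, k]) / sum(xk[present])
  }
  new("DeterminismResult", D = D, DUnweighted = du, DWeighted = dw,
      meanUnweighted = mean(du, na.rm = TRUE),
      meanWeighted = mean(dw, na.rm = TRUE))
}

#' Fit the process model and compute determinism in one step
#'
#' @inheritParams fitCRN
#' @param ... passed to [fitCRN()]
#' @return A [DeterminismResult-class] with the fit attached as
#'   attribute `"fit"`.
#' @export
determinismAnalysis <- function(object, ...) {
  fit <- fitCRN(object, ...)
  f2 <- fit$driftIncrement^2
  D <- 100 * f2 / (f2 + fit$noiseVariance)
  D[f2 == 0 & fit$noiseVariance == 0] <- 0
  nInt <- length(fit$dt)
  res <- communityDeterminism(D, fit$x[, seq_len(nInt), drop = FALSE])
  attr(res, "fit") <- fit
  res
}
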