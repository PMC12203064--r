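#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData rowData
NULL

.ENV_COLS <- c("salinity", "temperature", "pH", "NOx", "PO4")

#' CommunityMatrix: a taxa-by-samples count table with temporal metadata
#'
#' `CommunityMatrix` extends [SummarizedExperiment::SummarizedExperiment]
#' with a single `counts` assay of non-negative integers (taxa in rows,
#' samples in columns). The column data carry, for every sample, the
#' sampling `station`, the sampling `time` in days since the first sample
#' of that station, and (optionally) environmental covariates such as
#' salinity (PSU), temperature (deg C), pH, NOx and PO4 (umol/L).
#'
#' `PresenceMatrix` is the presence-absence specialisation: the assay is
#' constrained to values in \{0, 1\}. It is the state variable of the
#' island-biogeography colonization-extinction model.
#'
#' @slot . see [SummarizedExperiment::SummarizedExperiment]
#' @aliases PresenceMatrix-class
#' @seealso [binarize()], [rarefy()], [readAsvTable()]
#' @exportClass CommunityMatrix
setClass("CommunityMatrix", contains = "SummarizedExperiment")

#' @exportClass PresenceMatrix
setClass("PresenceMatrix", contains = "CommunityMatrix")

.validCommunityMatrix <- function(object) {
  msg <- NULL
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is required")
  m <- SummarizedExperiment::assay(object, "counts")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    msg <- c(msg, "counts must have taxon row names and sample column names")
  else {
    if (anyDuplicated(rownames(m))) msg <- c(msg, "duplicate taxon_ids")
    if (anyDuplicated(colnames(m))) msg <- c(msg, "duplicate sample_ids")
  }
  if (any(!is.finite(m)) || any(m < 0) || any(m != round(m)))
    msg <- c(msg, "counts must be finite non-negative integers")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("station", "time") %in% colnames(cd)))
    msg <- c(msg, "colData must contain 'station' and 'time'")
  else {
    tm <- cd$time
    if (any(!is.finite(tm)) || any(tm < 0))
      msg <- c(msg, "'time' must be non-negative days since first sample")
    for (st in unique(cd$station)) {
      tt <- tm[cd$station == st]
      if (length(tt) > 1L && any(diff(tt) <= 0))
        msg <- c(msg, sprintf("times must strictly increase within station '%s'", st))
    }
  }
  if ("salinity" %in% colnames(cd) && any(cd$salinity < 0, na.rm = TRUE))
    msg <- c(msg, "salinity must be >= 0")
  if (is.null(msg)) TRUE else msg
}

setValidity("CommunityMatrix", .validCommunityMatrix)

setValidity("PresenceMatrix", function(object) {
  m <- SummarizedExperiment::assay(object, "counts")
  if (!all(m %in% c(0, 1))) "presence entries must be 0 or 1" else TRUE
})

#' Construct a CommunityMatrix
#'
#' @param counts integer matrix, taxa x samples, with dimnames.
#' @param station character vector of station labels, one per sample.
#' @param time numeric vector of days since the first sample of the
#'   sample's station; strictly increasing within each station.
#' @param env optional `data.frame` of environmental covariates
#'   (salinity, temperature, pH, NOx, PO4, date, ...), one row per sample.
#' @return A [CommunityMatrix-class] object.
#' @examples
#' m <- matrix(c(1L, 0L, 2L, 0L, 5L, 0L), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("t1", "t2"), c("s1", "s2", "s3")))
#' CommunityMatrix(m, station = "A", time = c(0, 30, 61))
#' @export
CommunityMatrix <- function(counts, station, time, env = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  station <- rep_len(as.character(station), ncol(counts))
  cd <- DataFrame(station = station, time = as.numeric(time),
                  row.names = colnames(counts))
  if (!is.null(env)) {
    env <- as.data.frame(env)
    keep <- setdiff(colnames(env), c("sample_id", "station", "time"))
    for (nm in keep) cd[[nm]] <- env[[nm]]
  }
  new("CommunityMatrix",
      SummarizedExperiment(assays = list(counts = counts), colData = cd))
}

#' @rdname CommunityMatrix
#' @param presence 0/1 matrix, taxa x samples, with dimnames.
#' @export
PresenceMatrix <- function(presence, station, time, env = NULL) {
  cm <- CommunityMatrix(presence, station = station, time = time, env = env)
  new("PresenceMatrix", cm)
}

## ---- accessors -------------------------------------------------------------

#' @importFrom BiocGenerics counts
#' @exportMethod counts
setMethod("counts", "CommunityMatrix", function(object, ...) {
  SummarizedExperiment::assay(object, "counts")
})

#' Accessors for CommunityMatrix metadata
#'
#' `sampleTimes()` returns days since each station's first sample;
#' `stations()` the per-sample station labels; `taxonIds()` and
#' `sampleIds()` the axis names; `environmentSeries()` a `data.frame`
#' of the per-sample environmental covariates present in the column data.
#'
#' @param object a [CommunityMatrix-class]
#' @return vectors / data.frame aligned to the samples.
#' @name accessors
#' @export
sampleTimes <- function(object) SummarizedExperiment::colData(object)$time

#' @rdname accessors
#' @export
stations <- function(object) as.character(SummarizedExperiment::colData(object)$station)

#' @rdname accessors
#' @export
taxonIds <- function(object) rownames(object)

#' @rdname accessors
#' @export
sampleIds <- function(object) colnames(object)

#' @rdname accessors
#' @export
environmentSeries <- function(object) {
  cd <- as.data.frame(SummarizedExperiment::colData(object))
  keep <- intersect(c(.ENV_COLS, "date"), colnames(cd))
  data.frame(sample_id = colnames(object), station = stations(object),
             time = cd$time, cd[, keep, drop = FALSE], row.names = NULL)
}

#' Subset a CommunityMatrix to one station
#' @param object a [CommunityMatrix-class]
#' @param station station label to keep
#' @return object restricted to that station's samples (time order kept).
#' @export
stationSubset <- function(object, station) {
  object[, stations(object) == station]
}

setMethod("show", "CommunityMatrix", function(object) {
  cat(sprintf("%s: %d taxa x %d samples, %d station(s)\n", class(object),
              nrow(object), ncol(object), length(unique(stations(object)))))
  tm <- sampleTimes(object)
  if (length(tm)) cat(sprintf("  time span: %g-%g days\n", min(tm), max(tm)))
  ev <- intersect(.ENV_COLS, colnames(SummarizedExperiment::colData(object)))
  if (length(ev)) cat("  covariates:", paste(ev, collapse = ", "), "\n")
})

## ---- result classes --------------------------------------------------------

#' STR power-law fit
#'
#' Result of fitting the species-time relationship S = c * T^w to a
#' geometric-mean richness curve. Slots hold the constant `c` and exponent
#' `w` with standard errors, the adjusted R^2 on the untransformed scale,
#' and (after [strPermutationTest()]) a permutation p-value.
#'
#' @slot cHat,wHat power-law constant and exponent
#' @slot seC,seW their standard errors
#' @slot adjR2 adjusted R^2 (untransformed scale, clamped to [0, 1])
#' @slot pPerm,pPermW permutation p-values (adj R^2 / w statistics); NA
#'   until a permutation test is run
#' @slot nPerm permutations used
#' @slot curve the fitted (T, Sgeo) curve
#' @exportClass STRFit
setClass("STRFit", representation(
  cHat = "numeric", wHat = "numeric", seC = "numeric", seW = "numeric",
  adjR2 = "numeric", pPerm = "numeric", pPermW = "numeric",
  nPerm = "integer", curve = "data.frame"))

setMethod("show", "STRFit", function(object) {
  cat(sprintf("STRFit: S = %.4g * T^%.4g  (se_w %.3g, adj R2 %.3f)\n",
              object@cHat, object@wHat, object@seW, object@adjR2))
  if (!is.na(object@pPerm))
    cat(sprintf("  permutation p = %.4g (n_perm = %d)\n",
                object@pPerm, object@nPerm))
})

#' @rdname STRFit-class
#' @param object an `STRFit`
#' @export
strExponent <- function(object) object@wHat

#' Colonization-extinction fit
#'
#' Maximum-likelihood estimates of per-day colonization (`c`) and
#' extinction (`e`) rates of the two-state island-biogeography model on
#' irregularly sampled presence-absence data, with asymptotic standard
#' errors, the maximized log-likelihood, the characteristic time
#' 1/(c+e) in days, the equilibrium occupancy c/(c+e) and the equilibrium
#' richness S_pool * c/(c+e).
#'
#' @slot c,e rates per day
#' @slot seC,seE asymptotic standard errors
#' @slot logLik maximized log-likelihood
#' @slot tChar characteristic time in days, 1/(c+e)
#' @slot occupancyEq equilibrium occupancy c/(c+e)
#' @slot SPool,SEq metacommunity richness used and equilibrium richness
#' @slot boundary TRUE when a rate sits at the likelihood boundary
#'   (no observed transitions of one kind); SEs are then infinite
#' @exportClass CEFit
setClass("CEFit", representation(
  c = "numeric", e = "numeric", seC = "numeric", seE = "numeric",
  logLik = "numeric", tChar = "numeric", occupancyEq = "numeric",
  SPool = "numeric", SEq = "numeric", boundary = "logical"))

setValidity("CEFit", function(object) {
  if (object@c < 0 || object@e < 0) return("rates must be non-negative")
  if (!object@boundary &&
      abs(object@tChar - 1 / (object@c + object@e)) >
        1e-8 * object@tChar) return("tChar must equal 1/(c+e)")
  TRUE
})

setMethod("show", "CEFit", function(object) {
  cat(sprintf("CEFit: c = %.5g/day (se %.3g), e = %.5g/day (se %.3g)\n",
              object@c, object@seC, object@e, object@seE))
  cat(sprintf("  characteristic time %.4g days, equilibrium occupancy %.3f, S_eq %.4g\n",
              object@tChar, object@occupancyEq, object@SEq))
  if (object@boundary) cat("  [boundary fit: a transition type was never observed]\n")
})

#' @rdname CEFit-class
#' @param object a `CEFit`
#' @export
colonizationRate <- function(object) object@c

#' @rdname CEFit-class
#' @export
extinctionRate <- function(object) object@e

#' Covariate-dependent colonization-extinction fit
#'
#' Log-link model c_k = exp(alpha_c + beta_c z_k), e_k = exp(alpha_e +
#' beta_e z_k) where z is the standardized covariate at the start of each
#' sampling interval. `contributionC`/`contributionE` are exp(beta) - 1,
#' the relative change in rate per +1 SD of the covariate; negative values
#' mean the covariate slows that process. A likelihood-ratio test against
#' the constant-rate model is included.
#'
#' @slot alphaC,betaC,alphaE,betaE log-link coefficients
#' @slot se named standard errors of the four coefficients
#' @slot covariate,covMean,covSD covariate name and the standardization used
#' @slot contributionC,contributionE exp(beta) - 1
#' @slot logLik maximized log-likelihood
#' @slot lrStat,lrP likelihood-ratio statistic and p-value (df = 2) against
#'   the constant-rate model
#' @exportClass CEFitEnv
setClass("CEFitEnv", representation(
  alphaC = "numeric", betaC = "numeric", alphaE = "numeric", betaE = "numeric",
  se = "numeric", covariate = "character", covMean = "numeric",
  covSD = "numeric", contributionC = "numeric", contributionE = "numeric",
  logLik = "numeric", lrStat = "numeric", lrP = "numeric"))

setMethod("show", "CEFitEnv", function(object) {
  cat(sprintf("CEFitEnv (%s): beta_c = %.4g (se %.3g), beta_e = %.4g (se %.3g)\n",
              object@covariate, object@betaC, object@se["betaC"],
              object@betaE, object@se["betaE"]))
  cat(sprintf("  contributions per +1 SD: colonization %+.3f, extinction %+.3f\n",
              object@contributionC, object@contributionE))
  cat(sprintf("  LR vs constant rates: %.3f (p = %.4g)\n", object@lrStat, object@lrP))
})

#' @rdname CEFitEnv-class
#' @param object a `CEFitEnv`
#' @export
salinityContributions <- function(object) {
  c(colonization = object@contributionC, extinction = object@contributionE)
}

#' Consumer-resource + neutral community model
#'
#' Parameters of the stochastic community model in which taxa compete for
#' one shared resource with Monod uptake kinetics modulated by a Gaussian
#' salinity niche, lose biomass at a constant rate, immigrate from a
#' metacommunity, and experience demographic noise through Wiener-process
#' increments. Per-taxon vectors: `muMax` (max growth, /day), `K`
#' (half-saturation, resource units), `sOpt` (salinity optimum, PSU),
#' `sWidth` (niche width, PSU), `m` (loss, /day), `sigma` (demographic
#' noise scale), `p` (metacommunity relative abundance, sums to 1), `q`
#' (per-capita consumption). Shared scalars: `RSupply` (supply level),
#' `DR` (resource dilution, /day), `lambda` (immigration, /day).
#'
#' @exportClass CRNModel
setClass("CRNModel", representation(
  muMax = "numeric", K = "numeric", sOpt = "numeric", sWidth = "numeric",
  m = "numeric", sigma = "numeric", p = "numeric", q = "numeric",
  RSupply = "numeric", DR = "numeric", lambda = "numeric"))

setValidity("CRNModel", function(object) {
  n <- length(object@muMax)
  per <- c("K", "sOpt", "sWidth", "m", "sigma", "p", "q")
  for (nm in per)
    if (length(slot(object, nm)) != n)
      return(sprintf("'%s' must have one value per taxon", nm))
  if (any(object@sWidth <= 0)) return("sWidth must be > 0")
  rates <- c(object@muMax, object@m, object@sigma, object@DR, object@lambda,
             object@K, object@q)
  if (any(rates < 0)) return("rates and scales must be >= 0")
  if (abs(sum(object@p) - 1) > 1e-8) return("p must sum to 1")
  TRUE
})

setMethod("show", "CRNModel", function(object) {
  cat(sprintf("CRNModel: %d taxa, R_supply %g, D_R %g/day, lambda %g/day\n",
              length(object@muMax), object@RSupply, object@DR, object@lambda))
  cat(sprintf("  salinity optima %.3g-%.3g PSU, niche widths %.3g-%.3g PSU\n",
              min(object@sOpt), max(object@sOpt),
              min(object@sWidth), max(object@sWidth)))
})

#' @rdname CRNModel-class
#' @param object a `CRNModel`
#' @export
nTaxa <- function(object) length(object@muMax)

#' Per-taxon, per-time determinism and community aggregates
#'
#' `D` holds, for each taxon and sampling interval, the percentage (0-100)
#' of the expected squared abundance increment attributable to the fitted
#' deterministic drift rather than to demographic noise. `DUnweighted` and
#' `DWeighted` are per-interval community means (the latter weighted by
#' relative abundance), and the `mean*` slots their time averages.
#'
#' @exportClass DeterminismResult
setClass("DeterminismResult", representation(
  D = "matrix", DUnweighted = "numeric", DWeighted = "numeric",
  meanUnweighted = "numeric", meanWeighted = "numeric"))

setValidity("DeterminismResult", function(object) {
  d <- object@D[is.finite(object@D)]
  if (length(d) && (min(d) < -1e-9 || max(d) > 100 + 1e-9))
    return("determinism must lie in [0, 100]")
  TRUE
})

setMethod("show", "DeterminismResult", function(object) {
  cat(sprintf("DeterminismResult: %d taxa x %d intervals\n",
              nrow(object@D), ncol(object@D)))
  cat(sprintf("  mean determinism: unweighted %.2f, weighted %.2f\n",
              object@meanUnweighted, object@meanWeighted))
})

#' @rdname DeterminismResult-class
#' @param object a `DeterminismResult`
#' @param weighted return the abundance-weighted mean?
#' @export
meanDeterminism <- function(object, weighted = FALSE) {
  if (weighted) object@meanWeighted else object@meanUnweighted
}
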