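#' Multi-station temporal sampling design
#'
#' Describes the synthetic estuarine survey: `nStations` stations sampled
#' monthly (February skipped by default, as in winter-holiday gaps common
#' to coastal monitoring series) for `years` years, along a salinity
#' gradient in which the river-influenced station has a high salinity SD
#' and the marine stations low SDs. Sampling days carry +/- 7 days of
#' jitter so the intervals are genuinely irregular.
#'
#' @param nStations number of stations
#' @param years years of monthly sampling
#' @param months calendar months sampled (default all but February)
#' @param salinityMean,salinitySD per-station salinity mean and SD (PSU)
#' @param seasonalAmplitude amplitude of the seasonal salinity sinusoid (PSU)
#' @param temperatureMean,temperatureAmplitude seasonal temperature profile (deg C)
#' @param dayJitter max day-of-month jitter (days)
#' @param startYear first calendar year
#' @param stationNames station labels
#' @return list of class `StationDesign`.
#' @export
stationDesign <- function(nStations = 3, years = 6, months = setdiff(1:12, 2),
                          salinityMean = c(20, 28, 30),
                          salinitySD = c(8, 2, 1.5),
                          seasonalAmplitude = 2,
                          temperatureMean = 24, temperatureAmplitude = 6,
                          dayJitter = 7, startYear = 2015,
                          stationNames = paste0("ST", seq_len(nStations))) {
  nStations <- assertCount(nStations, "nStations")
  years <- assertCount(years, "years")
  salinityMean <- rep_len(salinityMean, nStations)
  salinitySD <- rep_len(salinitySD, nStations)
  if (any(salinitySD < 0)) stop("salinitySD must be >= 0")
  structure(list(nStations = nStations, years = years, months = sort(months),
                 salinityMean = salinityMean, salinitySD = salinitySD,
                 seasonalAmplitude = seasonalAmplitude,
                 temperatureMean = temperatureMean,
                 temperatureAmplitude = temperatureAmplitude,
                 dayJitter = dayJitter, startYear = startYear,
                 stationNames = rep_len(stationNames, nStations)),
            class = "StationDesign")
}

#' True parameters of the presence-absence generator
#'
#' @param SPool metacommunity richness (number of independent taxa)
#' @param c0,e0 baseline colonization / extinction rates (per day)
#' @param betaC,betaE covariate effects on the log rates (per SD of salinity)
#' @return list of class `TrueCEParams`.
#' @export
trueCEParams <- function(SPool = 1000, c0 = 0.01, e0 = 0.02,
                         betaC = 0, betaE = 0) {
  SPool <- assertCount(SPool, "SPool")
  if (c0 <= 0 || e0 <= 0) stop("c0 and e0 must be > 0")
  structure(list(SPool = SPool, c0 = c0, e0 = e0,
                 betaC = betaC, betaE = betaE), class = "TrueCEParams")
}

#' Generate environmental series for a sampling design
#'
#' One sample per station per sampled month. Salinity is the station mean
#' plus a seasonal sinusoid plus Gaussian noise (truncated at 0);
#' temperature follows a shared seasonal profile; pH, NOx and PO4 are
#' generated with realistic magnitudes (nutrients increase toward fresher
#' water). Sampling days carry uniform +/- `dayJitter` day jitter.
#'
#' @param design a [stationDesign()]
#' @param seed integer seed
#' @return data.frame with columns `sample_id, station, date, time,
#'   salinity, temperature, pH, NOx, PO4`; `time` is days since the
#'   station's first sample.
#' @export
genEnvironment <- function(design, seed = 1) {
  stopifnot(inherits(design, "StationDesign"))
  withSeed(seed, {
    rows <- list()
    for (i in seq_len(design$nStations)) {
      grid <- expand.grid(month = design$months,
                          year = design$startYear + seq_len(design$years) - 1)
      grid <- grid[order(grid$year, grid$month), ]
      day <- 15 + round(stats::runif(nrow(grid), -design$dayJitter,
                                     design$dayJitter))
      date <- as.Date(sprintf("%d-%02d-%02d", grid$year, grid$month, day))
      doy <- as.numeric(format(date, "%j"))
      phase <- 2 * pi * doy / 365
      sal <- pmax(design$salinityMean[i] +
                    design$seasonalAmplitude * sin(phase) +
                    stats::rnorm(length(date), 0, design$salinitySD[i]), 0)
      temp <- design$temperatureMean -
        design$temperatureAmplitude * cos(phase - 0.5) +
        stats::rnorm(length(date), 0, 0.8)
      st <- design$stationNames[i]
      rows[[i]] <- data.frame(
        sample_id = sprintf("%s_%s", st, format(date, "%Y%m")),
        station = st, date = as.character(date),
        time = as.numeric(date - min(date)),
        salinity = round(sal, 3), temperature = round(temp, 3),
        pH = round(8.1 + stats::rnorm(length(date), 0, 0.05), 3),
        NOx = round(pmax(12 - 0.3 * sal + stats::rnorm(length(date), 0, 1), 0.05), 3),
        PO4 = round(pmax(1.1 - 0.025 * sal + stats::rnorm(length(date), 0, 0.08), 0.01), 3))
    }
    do.call(rbind, rows)
  })
}

#' Simulate presence-absence dynamics under the island model
#'
#' Each of `SPool` taxa evolves independently as a two-state Markov chain
#' observed at the given (irregular) times. State changes over each
#' interval are drawn from the exact interval transition probabilities
#' ([transitionProbability()]), with rates evaluated from the covariate at
#' the interval's start when `env` is supplied (log link,
#' c = exp(log c0 + betaC z), z = standardized salinity). The initial
#' state is Bernoulli with the stationary occupancy at the first sample.
#' Because sampling is exact (no time discretization) the generator is a
#' distributional oracle for [fitCE()] / [fitCEEnv()].
#'
#' @param params a [trueCEParams()]
#' @param times strictly increasing sampling days
#' @param env optional data.frame with a `salinity` column aligned to `times`
#' @param seed integer seed
#' @param station station label for the output
#' @return A presence-absence [CommunityMatrix-class].
#' @export
genPresenceMarkov <- function(params, times, env = NULL, seed = 1,
                              station = "ST1") {
  stopifnot(inherits(params, "TrueCEParams"))
  n <- length(times)
  if (n < 2L || any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (!is.null(env)) {
    if (nrow(env) != n) stop("env must be aligned to times")
    z <- (env$salinity - mean(env$salinity)) / stats::sd(env$salinity)
  } else z <- rep(0, n)
  cc <- params$c0 * exp(params$betaC * z)
  ee <- params$e0 * exp(params$betaE * z)
  S <- params$SPool
  withSeed(seed, {
    M <- matrix(0, S, n)
    M[, 1] <- stats::rbinom(S, 1, cc[1] / (cc[1] + ee[1]))
    for (k in seq_len(n - 1L)) {
      P <- transitionProbability(cc[k], ee[k], times[k + 1] - times[k])
      pUp <- ifelse(M[, k] == 1, P["present", "present"], P["absent", "present"])
      M[, k + 1] <- stats::rbinom(S, 1, pUp)
    }
    ids <- if (!is.null(env) && !is.null(env$sample_id)) env$sample_id else
      sprintf("%s_t%03d", station, seq_len(n))
    dimnames(M) <- list(sprintf("taxon%05d", seq_len(S)), ids)
    env2 <- if (is.null(env)) NULL else env
    PresenceMatrix(M, station = station, time = times - times[1], env = env2)
  })
}

#' Simulate a count table from the consumer-resource + neutral model
#'
#' Latent abundances come from [simulateCRN()]; at each sampling time the
#' observed counts are a multinomial draw of `depth` reads with
#' probabilities proportional to the latent abundances, emulating
#' fixed-depth amplicon sequencing.
#'
#' @param model a [crnModel()]
#' @param times strictly increasing sampling days
#' @param env data.frame with a `salinity` column aligned to `times`
#' @param depth reads per sample
#' @param seed integer seed
#' @param station station label
#' @return A [CommunityMatrix-class] whose columns each sum to `depth`.
#' @export
genCountsCRN <- function(model, times, env, depth = 2000, seed = 1,
                         station = "ST1") {
  depth <- assertCount(depth, "depth")
  sim <- simulateCRN(model, times, env, seed = seed)
  N <- sim$N
  counts <- withSeed(deriveSeed(seed, 10007L), {
    vapply(seq_along(times), function(k) {
      tot <- sum(N[, k])
      if (tot <= 0) stop("all latent abundances are zero at time ", times[k])
      stats::rmultinom(1, depth, N[, k] / tot)[, 1]
    }, numeric(nrow(N)))
  })
  counts <- matrix(counts, nrow = nrow(N))
  ids <- if (!is.null(env$sample_id)) env$sample_id else
    sprintf("%s_t%03d", station, seq_along(times))
  dimnames(counts) <- list(sprintf("crn%04d", seq_len(nrow(N))), ids)
  CommunityMatrix(counts, station = station, time = times - times[1], env = env)
}

#' Simulate a full multi-station survey
#'
#' Generates the environment for a [stationDesign()], then two count
#' tables per survey (the analogue of the two taxon groups of an amplicon
#' study): a `markov` group in which presence-absence follows the island
#' model with known (optionally salinity-dependent) rates and counts are
#' multinomial over lognormal taxon weights, and a `crn` group generated
#' by the consumer-resource + neutral process. Optionally writes the
#' ASV-table and metadata TSVs plus a JSON sidecar of true parameters.
#'
#' @param design a [stationDesign()]
#' @param ce a [trueCEParams()] for the markov group
#' @param crn a [crnModel()] for the crn group (default [crnModel()])
#' @param depth reads per sample
#' @param seed master seed
#' @param weightSD sdlog of the lognormal taxon weights in the markov group
#' @param outdir optional output directory for TSV/JSON artefacts
#' @return list with `groups` (named list of [CommunityMatrix-class]),
#'   `env` (the metadata data.frame) and `truth` (generator parameters).
#' @export
simulateCommunity <- function(design = stationDesign(),
                              ce = trueCEParams(SPool = 500, c0 = 0.01,
                                                e0 = 0.02, betaC = -0.3,
                                                betaE = -0.2),
                              crn = crnModel(), depth = 2000, seed = 1,
                              weightSD = 1.5, outdir = NULL) {
  env <- genEnvironment(design, seed = seed)
  mk <- list(); cr <- list()
  for (i in seq_len(design$nStations)) {
    st <- design$stationNames[i]
    e <- env[env$station == st, , drop = FALSE]
    pm <- genPresenceMarkov(ce, e$time, env = e, seed = deriveSeed(seed, 100 + i),
                            station = st)
    w <- withSeed(deriveSeed(seed, 200 + i),
                  stats::rlnorm(ce$SPool, 0, weightSD))
    cnt <- withSeed(deriveSeed(seed, 300 + i), {
      sapply(seq_len(ncol(pm)), function(k) {
        pr <- w * counts(pm)[, k]
        if (sum(pr) == 0) pr[sample.int(length(pr), 1)] <- 1
        stats::rmultinom(1, depth, pr / sum(pr))[, 1]
      })
    })
    dimnames(cnt) <- dimnames(counts(pm))
    mk[[st]] <- CommunityMatrix(cnt, station = st, time = e$time, env = e)
    cr[[st]] <- genCountsCRN(crn, e$time, e, depth = depth,
                             seed = deriveSeed(seed, 400 + i), station = st)
  }
  groups <- list(markov = do.call(.cbindStations, mk),
                 crn = do.call(.cbindStations, cr))
  truth <- list(design = unclass(design), ce = unclass(ce),
                crn = .crnAsList(crn), depth = depth, seed = seed)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (g in names(groups))
      writeAsvTable(groups[[g]], file.path(outdir, paste0("asv_", g, ".tsv")))
    utils::write.table(env, file.path(outdir, "metadata.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(groups = groups, env = env, truth = truth)
}

# column-bind per-station CommunityMatrix objects sharing a taxon axis
.cbindStations <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L) return(parts[[1]])
  out <- do.call(SummarizedExperiment::cbind, parts)
  new(class(parts[[1]]), out)
}

.crnAsList <- function(model) {
  nm <- slotNames(model)
  stats::setNames(lapply(nm, function(s) slot(model, s)), nm)
}
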