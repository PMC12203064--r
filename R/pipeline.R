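#' Pipeline run configuration
#'
#' @param design a [stationDesign()] used when no input files are given
#' @param ce,crnTruth generator parameters for the simulated groups
#' @param asvTables named list of ASV-table TSV paths (one per taxon group);
#'   `NULL` simulates instead
#' @param metadata metadata TSV path (required with `asvTables`)
#' @param depth rarefaction depth (`NULL`: minimum column sum per table)
#' @param nRarefactions rarefaction repetitions for dissimilarity averaging
#' @param nPerm permutations for STR significance
#' @param topK taxa fitted by the process model
#' @param covariate covariate for the colonization-extinction model
#' @param rarefiedOccupancy use the rarefied table (first repetition) for
#'   the presence-absence analyses instead of the raw table
#' @param seed master seed; fixes every downstream draw
#' @param outdir optional directory for TSV/JSON outputs
#' @return list of class `RunConfig`.
#' @export
runConfig <- function(design = stationDesign(),
                      ce = trueCEParams(SPool = 500, c0 = 0.01, e0 = 0.02,
                                        betaC = -0.3, betaE = -0.2),
                      crnTruth = crnModel(), asvTables = NULL, metadata = NULL,
                      depth = 2000, nRarefactions = 100, nPerm = 1000,
                      topK = 50, covariate = "salinity",
                      rarefiedOccupancy = FALSE, seed = 1, outdir = NULL) {
  stopifnot(nRarefactions >= 1, nPerm >= 0, topK >= 1)
  structure(list(design = design, ce = ce, crnTruth = crnTruth,
                 asvTables = asvTables, metadata = metadata, depth = depth,
                 nRarefactions = nRarefactions, nPerm = nPerm, topK = topK,
                 covariate = covariate, rarefiedOccupancy = rarefiedOccupancy,
                 seed = seed, outdir = outdir),
            class = "RunConfig")
}

.analyzeStation <- function(cm, config, fitDeterminism = TRUE) {
  pm <- binarize(cm)
  if (config$rarefiedOccupancy)
    pm <- binarize(rarefy(cm, seed = deriveSeed(config$seed, 900)))
  str <- strAnalysis(pm, nPerm = config$nPerm,
                     seed = deriveSeed(config$seed, 11))
  ceFit <- fitCE(pm)
  ceEnv <- try(fitCEEnv(pm, covariate = config$covariate), silent = TRUE)
  if (inherits(ceEnv, "try-error")) ceEnv <- NULL
  det <- NULL
  if (fitDeterminism) {
    det <- try(determinismAnalysis(cm, topK = config$topK), silent = TRUE)
    if (inherits(det, "try-error")) det <- NULL
  }
  depth <- if (is.null(config$depth)) min(colSums(counts(cm))) else
    min(config$depth, min(colSums(counts(cm))))
  reps <- repeatRarefy(cm, depth = depth, nRep = config$nRarefactions,
                       seed = deriveSeed(config$seed, 21))
  bc <- Reduce(`+`, lapply(reps, function(r)
    brayCurtis(hellingerTransform(r)))) / length(reps)
  list(str = str, ce = ceFit, ceEnv = ceEnv, determinism = det,
       brayCurtis = bc, depth = depth)
}

.fitSummaryRow <- function(station, group, res) {
  data.frame(
    station = station, group = group,
    w = res$str@wHat, se_w = res$str@seW, adj_R2 = res$str@adjR2,
    p_perm = res$str@pPerm,
    c = res$ce@c, e = res$ce@e, t_char = res$ce@tChar,
    occupancy_eq = res$ce@occupancyEq, S_eq = res$ce@SEq,
    contribution_c = if (is.null(res$ceEnv)) NA else res$ceEnv@contributionC,
    contribution_e = if (is.null(res$ceEnv)) NA else res$ceEnv@contributionE,
    lr_p = if (is.null(res$ceEnv)) NA else res$ceEnv@lrP,
    D_mean_unweighted = if (is.null(res$determinism)) NA else
      res$determinism@meanUnweighted,
    D_mean_weighted = if (is.null(res$determinism)) NA else
      res$determinism@meanWeighted,
    row.names = NULL)
}

#' Run the full temporal-assembly analysis
#'
#' Ingests (or simulates) per-group count tables, then per station and
#' group: binarizes, fits the species-time relationship with permutation
#' significance, infers colonization/extinction rates with and without the
#' salinity covariate, fits the process model and computes determinism,
#' and averages Hellinger/Bray-Curtis dissimilarities over repeated
#' rarefactions; Mantel tests against the salinity distance and the CV
#' equality test across stations complete the bundle. All randomness is
#' derived from the master seed, so reruns are bit-identical. Independent
#' stages that fail are recorded and skipped.
#'
#' @param config a [runConfig()]
#' @return list with `summary` (one row per station x group), `results`
#'   (nested per group/station), `mantel`, `cvTest`, `env`, `manifest`.
#' @export
runAll <- function(config = runConfig()) {
  stopifnot(inherits(config, "RunConfig"))
  if (is.null(config$asvTables)) {
    sim <- simulateCommunity(config$design, ce = config$ce,
                             crn = config$crnTruth,
                             depth = if (is.null(config$depth)) 2000 else config$depth,
                             seed = config$seed, outdir = config$outdir)
    groups <- sim$groups
    env <- sim$env
  } else {
    md <- readSampleMetadata(config$metadata)
    groups <- lapply(config$asvTables, readAsvTable, metadata = md)
    env <- md
  }
  results <- list(); rows <- list(); errors <- character()
  for (g in names(groups)) {
    cm <- groups[[g]]
    for (st in unique(stations(cm))) {
      res <- try(.analyzeStation(stationSubset(cm, st), config,
                                 fitDeterminism = (g == "crn" ||
                                                   length(groups) == 1L)),
                 silent = TRUE)
      if (inherits(res, "try-error")) {
        errors <- c(errors, sprintf("%s/%s: %s", g, st,
                                    attr(res, "condition")$message))
        next
      }
      results[[g]][[st]] <- res
      rows[[paste(g, st)]] <- .fitSummaryRow(st, g, res)
    }
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  # across-station statistics on the environment and communities
  salByStation <- split(env$salinity, env$station)
  cvTest <- try(cvSLRT(salByStation, nSim = 1000,
                       seed = deriveSeed(config$seed, 31)), silent = TRUE)
  if (inherits(cvTest, "try-error")) cvTest <- NULL
  mantel <- list()
  for (g in names(results)) {
    for (st in names(results[[g]])) {
      bc <- results[[g]][[st]]$brayCurtis
      ids <- colnames(bc)
      sal <- env$salinity[match(ids, env$sample_id)]
      dEnv <- as.matrix(stats::dist(sal))
      dimnames(dEnv) <- dimnames(bc)
      mantel[[paste(g, st, sep = "_")]] <-
        mantelTest(bc, dEnv, nPerm = min(config$nPerm, 999),
                   seed = deriveSeed(config$seed, 41))
    }
  }
  manifest <- list(seed = config$seed, depth = config$depth,
                   nRarefactions = config$nRarefactions, nPerm = config$nPerm,
                   topK = config$topK, covariate = config$covariate,
                   groups = names(groups),
                   stations = unique(env$station),
                   simulated = is.null(config$asvTables), errors = errors)
  out <- list(summary = summary, results = results, mantel = mantel,
              cvTest = cvTest, env = env, manifest = manifest)
  if (!is.null(config$outdir)) .writeRunOutputs(out, config$outdir)
  out
}

.writeRunOutputs <- function(out, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(out$summary, file.path(outdir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  js <- list(summary = out$summary,
             mantel = lapply(out$mantel, function(m) m[c("r", "p", "nPerm")]),
             cvTest = if (is.null(out$cvTest)) NULL else
               out$cvTest[c("statistic", "pAsymptotic", "pSim", "cvs")],
             manifest = out$manifest)
  jsonlite::write_json(js, file.path(outdir, "results.json"),
                       auto_unbox = TRUE, digits = 12, pretty = TRUE)
  for (g in names(out$results))
    for (st in names(out$results[[g]])) {
      bc <- out$results[[g]][[st]]$brayCurtis
      utils::write.table(
        data.frame(sample_id = rownames(bc), bc, check.names = FALSE),
        file.path(outdir, sprintf("braycurtis_%s_%s.tsv", g, st)),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
  invisible(outdir)
}
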