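test_that("environment generator matches the sampling design", {
  env <- genEnvironment(stationDesign(), seed = 1)
  expect_equal(nrow(env), 3 * 66)                      # 6 years x 11 months
  expect_setequal(unique(env$station), c("ST1", "ST2", "ST3"))
  for (st in unique(env$station))
    expect_true(all(diff(env$time[env$station == st]) > 0))
  expect_true(all(env$salinity >= 0))
  expect_false(any(format(as.Date(env$date), "%m") == "02"))  # February skipped
  # degenerate design: no noise, no season, no jitter -> constant salinity
  flat <- stationDesign(nStations = 1, salinityMean = 25, salinitySD = 0,
                        seasonalAmplitude = 0, dayJitter = 0)
  envF <- genEnvironment(flat, seed = 2)
  expect_true(all(abs(envF$salinity - 25) < 1e-9))
})

test_that("river-mouth salinity CV exceeds the marine station's", {
  des <- stationDesign()
  hits <- vapply(1:200, function(s) {
    env <- genEnvironment(des, seed = s)
    cv <- tapply(env$salinity, env$station, function(x) sd(x) / mean(x))
    cv["ST1"] > cv["ST3"]
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("presence generator honours degenerate rate limits", {
  tm <- monthlyTimes(20)
  offPM <- genPresenceMarkov(trueCEParams(SPool = 200, c0 = 1e-12, e0 = 0.5),
                             tm, seed = 1)
  expect_true(all(counts(offPM) == 0))
  onPM <- genPresenceMarkov(trueCEParams(SPool = 200, c0 = 0.5, e0 = 1e-12),
                            tm, seed = 1)
  expect_true(all(counts(onPM) == 1))
  expect_error(genPresenceMarkov(trueCEParams(), c(0, 10, 10)), "increasing")
})

test_that("presence generator reaches the stationary occupancy c/(c+e)", {
  tm <- monthlyTimes(66)
  pm <- genPresenceMarkov(trueCEParams(SPool = 10000, c0 = 0.01, e0 = 0.02),
                          tm, seed = 5)
  lateOcc <- mean(counts(pm)[, 60:66])
  se <- sqrt((1 / 3) * (2 / 3) / (10000 * 7))
  # serial dependence across the 7 pooled samples inflates the SE; allow 5x
  expect_lt(abs(lateOcc - 1 / 3), 5 * se * sqrt(7))
})

test_that("one-step transition frequencies match the exact probabilities", {
  cc <- 0.013; ee <- 0.031; dt <- 23
  pm <- genPresenceMarkov(trueCEParams(SPool = 100000, c0 = cc, e0 = ee),
                          c(0, dt), seed = 9)
  m <- counts(pm)
  P <- transitionProbability(cc, ee, dt)
  n0 <- sum(m[, 1] == 0)
  f01 <- sum(m[, 1] == 0 & m[, 2] == 1) / n0
  f10 <- sum(m[, 1] == 1 & m[, 2] == 0) / (nrow(m) - n0)
  expect_lt(abs(f01 - P["absent", "present"]),
            3 * sqrt(P[1, 2] * (1 - P[1, 2]) / n0))
  expect_lt(abs(f10 - P["present", "absent"]),
            3 * sqrt(P[2, 1] * (1 - P[2, 1]) / (nrow(m) - n0)))
})

test_that("count generator draws multinomially at fixed depth", {
  tm <- seq(0, 300, by = 30)
  env <- data.frame(salinity = rep(23, length(tm)))
  one <- crnModel(nTaxa = 1, sOpt = 23)
  cm1 <- genCountsCRN(one, tm, env, depth = 500, seed = 1)
  expect_true(all(counts(cm1) == 500))
  two <- crnModel(nTaxa = 2, sOpt = c(23, 23), sigma = 0)
  cm2 <- genCountsCRN(two, tm, env, depth = 400, seed = 2)
  expect_true(all(colSums(counts(cm2)) == 400))
  # identical parameters, no noise: pooled first-taxon fraction is 1/2
  fracs <- vapply(1:50, function(s) {
    cm <- genCountsCRN(two, c(0, 30), env[1:2, , drop = FALSE],
                       depth = 200, seed = s)
    counts(cm)[1, 2] / 200
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.5), 3 * sqrt(0.25 / (50 * 200)))
})

test_that("simulated surveys round-trip through the TSV interfaces", {
  sim <- simulateCommunity(stationDesign(years = 2),
                           ce = trueCEParams(SPool = 60),
                           crn = crnModel(nTaxa = 8), depth = 300, seed = 3,
                           outdir = withr::local_tempdir())
  expect_named(sim$groups, c("markov", "crn"))
  cm <- sim$groups$markov
  path <- withr::local_tempfile(fileext = ".tsv")
  mdPath <- withr::local_tempfile(fileext = ".tsv")
  writeAsvTable(cm, path)
  writeSampleMetadata(cm, mdPath)
  back <- readAsvTable(path, metadata = mdPath)
  expect_identical(counts(back), counts(cm))
  expect_equal(sampleTimes(back), sampleTimes(cm))
  expect_equal(stations(back), stations(cm))
})
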