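test_that("interval transition matrix follows the closed form", {
  P0 <- transitionProbability(0.3, 0.4, 0)
  expect_equal(unname(P0), diag(2))
  Pinf <- transitionProbability(0.3, 0.4, 1e9)
  expect_equal(unname(Pinf[1, ]), unname(Pinf[2, ]))
  expect_equal(unname(Pinf[1, ]), c(0.4, 0.3) / 0.7)
  P <- transitionProbability(0.2, 0.3, 2)
  expect_equal(P["absent", "present"], 0.25285, tolerance = 1e-4)
  expect_equal(P["present", "absent"], 0.37927, tolerance = 1e-4)
  expect_error(transitionProbability(0, 0, 5), "degenerate")
  expect_error(transitionProbability(-0.1, 0.2, 5), "non-negative")
  # rows always sum to one
  set.seed(1)
  for (i in 1:50) {
    P <- transitionProbability(runif(1, 0, 2), runif(1, 0, 2), runif(1, 0, 100))
    expect_equal(unname(rowSums(P)), c(1, 1))
  }
})

test_that("characteristic time is 1/(c+e) and scales accordingly", {
  expect_equal(characteristicTime(0.1, 0.3), 2.5)
  expect_equal(characteristicTime(0.2, 0.6), 1.25)
  expect_true(all(diff(vapply(c(0.1, 0.2, 0.4), characteristicTime,
                              numeric(1), c = 0.05)) < 0))
  expect_error(characteristicTime(0, 0))
})

test_that("transition tallies follow hand counts", {
  pm <- makePM(matrix(c(1, 1, 1, 0, 0, 1), 3, 2, byrow = TRUE),
               time = c(0, 30))
  tc <- countTransitions(pm)
  expect_equal(tc[, c("n00", "n01", "n10", "n11")],
               data.frame(n00 = 0, n01 = 1, n10 = 1, n11 = 1))
  expect_equal(tc$dt, 30)
  # identical consecutive samples -> no transitions
  pm2 <- makePM(matrix(c(1, 1, 0, 0, 1, 1), 3, 2, byrow = TRUE))
  tc2 <- countTransitions(pm2)
  expect_equal(tc2$n01 + tc2$n10, 0)
  # complete turnover of k taxa among n
  pm3 <- makePM(rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1), c(0, 0)))
  tc3 <- countTransitions(pm3)
  expect_equal(c(tc3$n01, tc3$n10), c(2, 2))
  expect_error(countTransitions(makePM(matrix(1, 2, 1))), "fewer than 2")
})

test_that("transition tallies never cross station boundaries", {
  m <- cbind(c(1, 0), c(0, 1), c(1, 1), c(0, 0))
  dimnames(m) <- list(c("a", "b"), c("s1", "s2", "s3", "s4"))
  pm <- PresenceMatrix(m, station = c("A", "A", "B", "B"),
                       time = c(0, 30, 0, 30))
  tc <- countTransitions(pm)
  expect_equal(nrow(tc), 2)           # one pair per station
  expect_equal(sum(tc$n00 + tc$n01 + tc$n10 + tc$n11), 2 * nrow(m))
})

test_that("symmetric transition counts give c = e and occupancy 1/2", {
  m <- cbind(rep(c(0, 0, 1, 1), c(50, 25, 25, 50)),
             rep(c(0, 1, 0, 1), c(50, 25, 25, 50)))
  dimnames(m) <- list(sprintf("t%03d", 1:150), c("s1", "s2"))
  pm <- PresenceMatrix(m, station = "A", time = c(0, 30))
  ft <- fitCE(pm)
  expect_equal(ft@c, ft@e, tolerance = 1e-4)
  expect_equal(ft@occupancyEq, 0.5, tolerance = 1e-4)
  # implied one-step transition probabilities are 1/3
  P <- transitionProbability(ft@c, ft@e, 30)
  expect_equal(P["absent", "present"], 1 / 3, tolerance = 1e-3)
})

test_that("maximum likelihood matches an independent grid search", {
  # independent likelihood (written from the closed form) + 2-pass grid
  gridOracle <- function(tc) {
    ll <- function(lc, le) {
      cc <- exp(lc); ee <- exp(le); rho <- cc + ee
      g <- 1 - exp(-rho * tc$dt)
      p01 <- cc / rho * g; p10 <- ee / rho * g
      sum(tc$n01 * log(p01) + tc$n00 * log(1 - p01) +
          tc$n10 * log(p10) + tc$n11 * log(1 - p10))
    }
    rng <- c(log(1e-4), log(0.5))
    ctr <- c(mean(rng), mean(rng)); hw <- diff(rng) / 2
    for (pass in 1:4) {
      lc <- seq(ctr[1] - hw, ctr[1] + hw, length.out = 41)
      le <- seq(ctr[2] - hw, ctr[2] + hw, length.out = 41)
      val <- outer(lc, le, Vectorize(ll))
      ix <- which(val == max(val), arr.ind = TRUE)[1, ]
      ctr <- c(lc[ix[1]], le[ix[2]]); hw <- hw / 10
    }
    exp(ctr)
  }
  set.seed(42)
  for (rep in 1:6) {
    nT <- sample(5:20, 1); nS <- sample(3:5, 1)
    pm <- genPresenceMarkov(trueCEParams(SPool = nT, c0 = 0.02, e0 = 0.03),
                            monthlyTimes(nS, seed = rep), seed = rep * 11)
    tc <- countTransitions(pm)
    if (sum(tc$n01) == 0 || sum(tc$n10) == 0) next
    ft <- fitCE(pm)
    or <- gridOracle(tc)
    expect_equal(ft@c, or[1], tolerance = 1e-3)
    expect_equal(ft@e, or[2], tolerance = 1e-3)
  }
})

test_that("likelihood is additive over taxon subsets", {
  pm <- genPresenceMarkov(trueCEParams(SPool = 200), monthlyTimes(20), seed = 3)
  ft <- fitCE(pm)
  par <- log(c(ft@c, ft@e))
  llAt <- function(p) -ecoTempo:::.ceNegLL(par, countTransitions(p))
  half1 <- pm[1:100, ]; half2 <- pm[101:200, ]
  expect_equal(llAt(pm), llAt(half1) + llAt(half2), tolerance = 1e-8)
})

test_that("boundary cases are flagged instead of fitted", {
  m <- cbind(c(1, 1, 0), c(1, 0, 0), c(0, 0, 0))
  dimnames(m) <- list(c("a", "b", "c"), c("s1", "s2", "s3"))
  pm <- PresenceMatrix(m, station = "A", time = c(0, 28, 61))  # no 0->1 moves
  ft <- fitCE(pm)
  expect_true(ft@boundary)
  expect_true(is.infinite(ft@seC) || is.infinite(ft@seE))
})

test_that("covariate effects carry the sign of beta into contributions", {
  env <- genEnvironment(stationDesign(nStations = 1, salinitySD = 6), seed = 2)
  pm <- genPresenceMarkov(trueCEParams(SPool = 6000, c0 = 0.01, e0 = 0.02,
                                       betaC = -0.5, betaE = 0.3),
                          env$time, env = env, seed = 4)
  ft <- fitCEEnv(pm)
  expect_lt(ft@betaC, 0); expect_gt(ft@betaE, 0)
  expect_lt(ft@contributionC, 0); expect_gt(ft@contributionE, 0)
  expect_equal(ft@contributionC, exp(ft@betaC) - 1)
  expect_lt(abs(ft@betaC - (-0.5)), 3 * ft@se["betaC"])
  expect_lt(abs(ft@betaE - 0.3), 3 * ft@se["betaE"])
  expect_lt(ft@lrP, 0.05)
  # constant covariate is rejected
  envC <- env; envC$salinity <- 25
  pmC <- genPresenceMarkov(trueCEParams(SPool = 100), env$time, seed = 1)
  SummarizedExperiment::colData(pmC)$salinity <- 25
  expect_error(fitCEEnv(pmC), "zero variance")
})

test_that("covariate model log-likelihood nests the constant-rate model", {
  env <- genEnvironment(stationDesign(nStations = 1), seed = 5)
  pm <- genPresenceMarkov(trueCEParams(SPool = 800), env$time, env = env,
                          seed = 6)
  base <- fitCE(pm)
  ft <- fitCEEnv(pm)
  expect_gte(ft@logLik, base@logLik - 1e-6)
  expect_gte(ft@lrStat, 0)
})
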