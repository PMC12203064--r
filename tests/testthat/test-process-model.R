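test_that("drift follows Monod growth, niche filtering, loss and immigration", {
  md <- crnModel(nTaxa = 1, muMax = 1, K = 1, sOpt = 20, sWidth = 4,
                 m = 0.2, lambda = 0)
  d <- crnDrift(md, N = 10, R = 1, s = 20)
  expect_equal(d$fN, 10 * (1 * 0.5 * 1 - 0.2))      # = 3.0 by hand
  # no growth without resource
  expect_equal(crnDrift(md, 10, 0, 20)$fN, -0.2 * 10)
  # Monod saturation: per-capita growth tends to muMax - m at the optimum
  dInf <- crnDrift(md, 1, 1e12, 20)
  expect_equal(dInf$fN, 1 - 0.2, tolerance = 1e-6)
  # immigration adds lambda * p even from emptiness
  md2 <- crnModel(nTaxa = 2, lambda = 0.4, p = c(0.25, 0.75))
  expect_equal(crnDrift(md2, c(0, 0), 5, 23)$fN, 0.4 * c(0.25, 0.75))
  # resource drift balances supply against weighted consumption
  d3 <- crnDrift(md, 10, 1, 20)
  expect_equal(d3$fR, 1 * (10 - 1) - 0.05 * 1 * 0.5 * 10)
})

test_that("noiseless simulation converges as the step shrinks", {
  tm <- seq(0, 120, by = 10)
  env <- data.frame(salinity = 23 + 3 * sin(2 * pi * tm / 120))
  md <- crnModel(nTaxa = 4, sOpt = c(18, 22, 26, 30), sigma = 0)
  s1 <- simulateCRN(md, tm, env, dtInt = 0.4, seed = 1, burnIn = 50)
  s2 <- simulateCRN(md, tm, env, dtInt = 0.2, seed = 1, burnIn = 50)
  nEnd1 <- s1$N[, ncol(s1$N)]; nEnd2 <- s2$N[, ncol(s2$N)]
  expect_lt(max(abs(nEnd1 - nEnd2) / pmax(nEnd2, 1e-6)), 0.01)
  # reproducible under a fixed seed even with noise
  mdN <- crnModel(nTaxa = 4, sigma = 0.1)
  a <- simulateCRN(mdN, tm, env, seed = 7)
  b <- simulateCRN(mdN, tm, env, seed = 7)
  expect_identical(a$N, b$N)
})

test_that("driftless diffusion is a martingale in the mean", {
  md <- crnModel(nTaxa = 1, muMax = 0, m = 0, lambda = 0, sigma = 0.4)
  env <- data.frame(salinity = c(23, 23))
  ends <- vapply(1:500, function(s)
    simulateCRN(md, c(0, 10), env, dtInt = 0.5, seed = s, N0 = 50,
                burnIn = 0)$N[1, 2], numeric(1))
  # Var(N_t) ~ sigma^2 * N0 * t for the sqrt-diffusion
  se <- sqrt(0.4^2 * 50 * 10 / 500)
  expect_lt(abs(mean(ends) - 50), 3 * se)
})

test_that("single-taxon equilibrium matches the root-found Monod balance", {
  md <- crnModel(nTaxa = 1, muMax = 0.4, K = 1, sOpt = 23, sWidth = 5,
                 m = 0.1, sigma = 0, lambda = 0, q = 0.05, RSupply = 10,
                 DR = 1)
  env <- data.frame(salinity = c(23, 23))
  sim <- simulateCRN(md, c(0, 4000), env, dtInt = 0.25, seed = 1, N0 = 100,
                     burnIn = 0)
  # independent oracle: R* solves mu R/(K+R) = m; N* from resource balance
  Rstar <- uniroot(function(R) 0.4 * R / (1 + R) - 0.1, c(1e-6, 10))$root
  Nstar <- 1 * (10 - Rstar) / (0.05 * 0.1)
  expect_equal(unname(sim$N[1, 2]), Nstar, tolerance = 1e-3)
  expect_equal(sim$R[2], Rstar, tolerance = 1e-3)
})

test_that("taxon determinism reduces correctly in both limits", {
  fakeFit <- structure(list(
    driftIncrement = matrix(c(0.2, 0, 0.1), 3, 1),
    noiseVariance = matrix(c(0, 0.3, 0.01), 3, 1)), class = "CRNFit")
  expect_equal(taxonDeterminism(fakeFit, 1, 1), 100)   # sigma = 0
  expect_equal(taxonDeterminism(fakeFit, 2, 1), 0)     # f = 0
  expect_equal(taxonDeterminism(fakeFit, 3, 1), 50)    # (f dt)^2 = sigma^2 x dt
  zero <- structure(list(driftIncrement = matrix(0, 1, 1),
                         noiseVariance = matrix(0, 1, 1)), class = "CRNFit")
  d0 <- taxonDeterminism(zero, 1, 1)
  expect_equal(as.numeric(d0), 0)
  expect_true(isTRUE(attr(d0, "degenerate")))
})

test_that("community determinism aggregates by hand arithmetic", {
  D <- matrix(c(80, 20), 2, 1)
  x <- matrix(c(0.75, 0.25), 2, 1)
  res <- communityDeterminism(D, x)
  expect_equal(res@DWeighted, 65)
  expect_equal(res@DUnweighted, 50)
  # constant determinism and equal abundances collapse both aggregates
  De <- matrix(40, 3, 4); xe <- matrix(1 / 3, 3, 4)
  rese <- communityDeterminism(De, xe)
  expect_equal(rese@meanUnweighted, 40)
  expect_equal(rese@meanWeighted, 40)
  # empty community at a time point is omitted from the averages
  x0 <- xe; x0[, 2] <- 0
  res0 <- communityDeterminism(De, x0)
  expect_true(is.na(res0@DUnweighted[2]))
  expect_equal(res0@meanUnweighted, 40)
})

test_that("fitted noise vanishes on noiseless trajectories", {
  tm <- seq(0, by = 2, length.out = 130)
  env <- seasonalEnv(tm, seed = 3)
  md <- crnModel(nTaxa = 12, sigma = 0, sOpt = seq(14, 30, length.out = 12),
                 lambda = 0)
  sim <- simulateCRN(md, tm, env, seed = 5, dtInt = 0.2, burnIn = 600,
                     N0 = rep(1000, 12))
  fit <- fitCRN(sim$N, times = tm, salinity = env$salinity, topK = 12,
                nIter = 4, lambda = 0)
  expect_lt(median(fit$sigma), 1e-3)
})

test_that("salinity optima are recovered to niche-scale accuracy", {
  # at monthly-scale series the optimum is identified to a few PSU (niche
  # width 5); we check rank agreement and absolute error well under a width
  tm <- seq(0, by = 5, length.out = 66)
  env <- seasonalEnv(tm, period = 330, seed = 3)
  truth <- c(16, 20, 24, 27, 30)
  md <- crnModel(nTaxa = 5, sOpt = truth, sigma = 0.02)
  sim <- simulateCRN(md, tm, env, seed = 7, dtInt = 0.2)
  fit <- fitCRN(sim$N, times = tm, salinity = env$salinity, topK = 5,
                nIter = 4)
  tr <- truth[match(rownames(fit$x), sprintf("crn%04d", 1:5))]
  expect_gt(cor(tr, fit$model@sOpt, method = "spearman"), 0.8)
  expect_lt(max(abs(tr - fit$model@sOpt)), 5)
})

test_that("temporal order carries the pseudo-likelihood signal", {
  tm <- seq(0, by = 5, length.out = 50)
  env <- seasonalEnv(tm, period = 330, seed = 11)
  md <- crnModel(nTaxa = 6, sOpt = seq(15, 30, length.out = 6), sigma = 0.02)
  wins <- vapply(1:30, function(s) {
    sim <- simulateCRN(md, tm, env, seed = s, dtInt = 0.25)
    x <- sim$N
    f1 <- fitCRN(x, times = tm, salinity = env$salinity, topK = 6, nIter = 2)
    ord <- withr::with_seed(s, sample.int(ncol(x)))
    f2 <- fitCRN(x[, ord], times = tm, salinity = env$salinity, topK = 6,
                 nIter = 2)
    f1$negLL < f2$negLL
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})
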