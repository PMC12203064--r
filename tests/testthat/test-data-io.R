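test_that("ASV tables round-trip losslessly through TSV", {
  m <- matrix(c(1, 0, 2, 0, 5, 0), nrow = 2, byrow = TRUE,
              dimnames = list(c("t1", "t2"), c("s1", "s2", "s3")))
  cm <- makeCM(m)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeAsvTable(cm, path)
  cm2 <- readAsvTable(path)
  expect_identical(counts(cm2), counts(cm))
  expect_identical(taxonIds(cm2), taxonIds(cm))

  # metadata round-trip, with time recomputed from ISO dates per station
  env <- data.frame(sample_id = colnames(m), station = "S1",
                    date = c("2015-01-15", "2015-02-12", "2015-03-20"),
                    salinity = c(20, 21, 19), temperature = c(18, 19, 21),
                    pH = 8.1, NOx = 5, PO4 = 0.5)
  mdPath <- withr::local_tempfile(fileext = ".tsv")
  write.table(env, mdPath, sep = "\t", quote = FALSE, row.names = FALSE)
  cm3 <- readAsvTable(path, metadata = mdPath)
  expect_equal(sampleTimes(cm3), c(0, 28, 64))
  expect_equal(environmentSeries(cm3)$salinity, env$salinity)
})

test_that("malformed ASV tables are rejected", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon_id\ts1\ts1", "a\t1\t2", "b\t0\t1"), path)
  expect_error(readAsvTable(path), "duplicate sample")
  writeLines(c("taxon_id\ts1\ts2", "a\t1.5\t2", "b\t0\t1"), path)
  expect_error(readAsvTable(path), "non-negative integers")
  writeLines(c("taxon_id\ts1\ts2", "a\t1\t2", "a\t0\t1"), path)
  expect_error(readAsvTable(path), "duplicate taxon")
})

test_that("binarize maps positive counts to 1 with no threshold", {
  cm <- makeCM(matrix(c(0, 3, 7, 0), 2, byrow = TRUE))
  expect_equal(unname(counts(binarize(cm))),
               matrix(c(0, 1, 1, 0), 2, byrow = TRUE))
  expect_true(all(counts(binarize(makeCM(matrix(0, 2, 3)))) == 0))
  expect_equal(unname(counts(binarize(makeCM(matrix(1, 1, 2))))[1, ]), c(1, 1))
  expect_s4_class(binarize(cm), "PresenceMatrix")
})

test_that("rarefaction subsamples without replacement to exact depth", {
  set.seed(10)
  m <- matrix(rpois(60, 40), 6, 10)
  cm <- makeCM(m)
  r <- rarefy(cm, depth = 100, seed = 1)
  expect_true(all(colSums(counts(r)) == 100))
  expect_true(all(counts(r) <= counts(cm)))
  # exhaustive draw leaves the column unchanged
  r2 <- rarefy(cm, depth = min(colSums(m)), seed = 2)
  jmin <- which.min(colSums(m))
  expect_equal(counts(r2)[, jmin], counts(cm)[, jmin])
  # reproducibility
  expect_identical(counts(rarefy(cm, 100, seed = 7)),
                   counts(rarefy(cm, 100, seed = 7)))
  # single-taxon sample gets exactly the depth
  cm1 <- makeCM(matrix(c(50, 0, 0, 50), 2))
  expect_equal(unname(counts(rarefy(cm1, 20, seed = 1))[, 1]), c(20, 0))
  # shallow samples are reported by name
  expect_error(rarefy(cm, depth = 1e6), "shallower")
})

test_that("rarefied counts match hypergeometric moments", {
  cm <- makeCM(matrix(c(5000, 5000), 2, 1))
  nRep <- 2000
  draws <- vapply(seq_len(nRep),
                  function(i) counts(rarefy(cm, 1000, seed = i))[1, 1],
                  numeric(1))
  # multivariate hypergeometric marginals: mean 500,
  # var = n * p * (1-p) * (N-n)/(N-1)
  sdHyper <- sqrt(1000 * 0.5 * 0.5 * (10000 - 1000) / (10000 - 1))
  expect_lt(abs(mean(draws) - 500), 3 * sdHyper / sqrt(nRep))
  expect_lt(abs(sd(draws) - sdHyper), 0.15 * sdHyper)
})

test_that("repeated rarefaction derives per-repetition seeds from the master", {
  set.seed(20)
  cm <- makeCM(matrix(rpois(40, 60), 4, 10))
  reps <- repeatRarefy(cm, depth = 150, nRep = 5, seed = 100)
  expect_length(reps, 5)
  expect_identical(counts(reps[[1]]), counts(rarefy(cm, 150, seed = 100)))
  expect_identical(counts(reps[[3]]), counts(rarefy(cm, 150, seed = 102)))
  # depth = column totals gives identical copies
  m2 <- matrix(50L, 3, 4)
  repsFull <- repeatRarefy(makeCM(m2), depth = 150, nRep = 3, seed = 1)
  expect_true(all(vapply(repsFull, function(r)
    identical(unname(counts(r)), matrix(50, 3, 4)), logical(1))))
  # repetitions are genuinely independent: block means of per-rep richness
  # scatter like sd/sqrt(block size)
  cmBig <- makeCM(matrix(rpois(600, 3), 30, 20))
  rich <- vapply(repeatRarefy(cmBig, depth = 20, nRep = 100, seed = 5),
                 function(r) mean(colSums(counts(r) > 0)), numeric(1))
  expect_gt(sd(rich), 0)
  blockMeans <- tapply(rich, rep(1:10, each = 10), mean)
  expect_lt(sd(blockMeans), sd(rich))
})

test_that("expected rarefied richness is monotone in depth", {
  set.seed(30)
  cm <- makeCM(matrix(rpois(200, 2), 20, 10))
  meanRich <- function(depth) {
    mean(vapply(1:30, function(i)
      mean(colSums(counts(rarefy(cm, depth, seed = i)) > 0)), numeric(1)))
  }
  depths <- c(3, 8, 15)
  rich <- vapply(depths, meanRich, numeric(1))
  expect_true(all(diff(rich) > 0))
})
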