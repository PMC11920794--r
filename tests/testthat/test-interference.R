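test_that("cis-DCO distances follow the transition-midpoint definition", {
  segs <- makeSegments(c(0, 3.5e6, 10.5e6), c(3e6, 10e6, 15e6),
                       c("P1", "H", "P1"))
  d <- extractCisDcos(segs)
  expect_identical(nrow(d), 1L)
  # transitions at (3 + 3.5)/2 = 3.25 Mb and (10 + 10.5)/2 = 10.25 Mb
  expect_identical(d$distance, 7e6)
  expect_identical(d$pattern, "P1-H-P1")
})

test_that("non-matching and inverted triples are not cis-DCOs", {
  expect_identical(nrow(extractCisDcos(
    makeSegments(c(0, 3.5e6, 10.5e6), c(3e6, 10e6, 15e6),
                 c("P1", "H", "P2")))), 0L)
  expect_identical(nrow(extractCisDcos(
    makeSegments(c(0, 3.5e6, 10.5e6), c(3e6, 10e6, 15e6),
                 c("H", "P1", "H")))), 0L)
  expect_identical(nrow(extractCisDcos(
    makeSegments(0, 3e6, "P1"))), 0L)
})

test_that("expected-distance null reproduces the random-pair closed form", {
  set.seed(23)
  L <- 2e7
  mids <- list(chr1 = runif(3000, 0, L))
  d <- replicate(100, sampleExpectedDistances(mids, 400))
  # |U1 - U2| on [0, L] has mean L/3
  expect_equal(mean(d), L / 3, tolerance = 0.02)
  set.seed(5); a <- sampleExpectedDistances(mids, 400)
  set.seed(5); b <- sampleExpectedDistances(mids, 400)
  expect_identical(a, b)
  expect_warning(z <- sampleExpectedDistances(list(chr1 = rep(5e6, 10))),
                 "fewer than 2 distinct")
  expect_length(z, 0L)
})

test_that("gamma fits recover known parameters by maximum likelihood", {
  set.seed(6)
  fe <- fitGammaDistances(rexp(10000, rate = 2))
  expect_equal(gammaShape(fe), 1, tolerance = 0.05)
  fg <- fitGammaDistances(rgamma(10000, shape = 4, rate = 2))
  expect_true(gammaShape(fg) > 3.8 && gammaShape(fg) < 4.2)
  expect_true(gammaRate(fg) > 1.9 && gammaRate(fg) < 2.1)
  expect_error(fitGammaDistances(rexp(5)), "insufficient")
  expect_warning(fc <- fitGammaDistances(rep(2, 50)), "capped")
  expect_identical(gammaShape(fc), 1e6)
  expect_message(fz <- fitGammaDistances(c(0, 0, rexp(98))), "zero distance")
  expect_gt(gammaShape(fz), 0)
})

test_that("gamma fits agree with fitdistrplus on the same data", {
  skip_if_not_installed("fitdistrplus")
  set.seed(8)
  x <- rgamma(2000, shape = 3.2, rate = 1.5)
  mine <- fitGammaDistances(x)
  ref <- fitdistrplus::fitdist(x, "gamma")
  expect_equal(gammaShape(mine), unname(ref$estimate["shape"]),
               tolerance = 1e-3)
  expect_equal(gammaRate(mine), unname(ref$estimate["rate"]),
               tolerance = 1e-3)
})

test_that("bootstrap shape distributions are reproducible and consistent", {
  set.seed(10)
  x <- rgamma(500, shape = 4, rate = 2)
  set.seed(1); a <- bootstrapShape(x, 200)
  set.seed(1); b <- bootstrapShape(x, 200)
  expect_identical(a, b)
  expect_length(bootstrapShape(x, 1), 1L)
  fit <- fitGammaDistances(x)
  expect_equal(mean(a), gammaShape(fit), tolerance = 0.1 * gammaShape(fit))
})

test_that("shape-distribution comparison separates interference from none", {
  set.seed(12)
  bootInterf <- bootstrapShape(rgamma(500, shape = 5, rate = 1), 300)
  bootExp <- bootstrapShape(rexp(500), 300)
  expect_lt(compareShapeDistributions(bootInterf, bootExp), 0.001)
  expect_equal(compareShapeDistributions(bootInterf, bootExp),
               compareShapeDistributions(bootExp, bootInterf))
  expect_warning(p1 <- compareShapeDistributions(rep(2, 10), rep(2, 10)),
                 "identical")
  expect_identical(p1, 1)
  expect_error(compareShapeDistributions(numeric(0), 1:3), "non-empty")
})

test_that("distance-set comparison behaves at the edges", {
  set.seed(14)
  x <- rgamma(100, 2, 1e-6)
  expect_gt(compareDistanceSets(x, x), 0.9)
  expect_lt(compareDistanceSets(x, x + 5e6), 0.01)
  expect_identical(compareDistanceSets(1.5, 2.5), 1)
  expect_error(compareDistanceSets(1:3, 1:4, paired = TRUE), "equal-length")
})

test_that("CoC is 1 for identical sets and 0 for empty observed bins", {
  set.seed(16)
  d <- runif(2000, 0, 2e7)
  prof <- computeCoc(d, d)
  expect_true(all(abs(prof$coc[prof$expected > 0] - 1) < 1e-12))
  obs <- runif(500, 4e6, 2e7)  # nothing below 3.5 Mb
  exp <- runif(2000, 0, 2e7)
  prof2 <- computeCoc(obs, exp)
  expect_identical(prof2$coc[1], 0)
  expect_error(computeCoc(numeric(0), d), "empty")
})

test_that("strong interference depresses short-distance CoC and rises with distance", {
  sim <- simulateF2Population(
    simConfig(seed = 61, nu = 10, class1Mean = 2, class2Mean = 0), 300)
  segs <- segmentGenotypes(sim$genotypes)
  res <- interferenceAnalysis(segs, bootstrapIters = 50, seed = 62)
  prof <- res$coc[res$coc$expected >= 10 & !is.na(res$coc$coc), ]
  expect_lt(prof$coc[1], 0.5)
  expect_gt(cor(seq_len(nrow(prof)), prof$coc, method = "spearman"), 0.5)
})
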