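# events GRanges straight from midpoints
midpointEvents <- function(chrom, mids, individual = "i1") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(round(mids), width = 1),
                         individual = individual, midpoint = mids,
                         type = "P1->H", flagged = FALSE)
}

test_that("window frequencies count midpoints and conserve totals", {
  gm <- tinyGenome()
  ev <- midpointEvents("chrA", c(1e5, 1.5e5, 2.9e5))
  prof <- windowFrequency(ev, 100, gm, window = 3e5)
  expect_identical(prof$freq[prof$chrom == "chrA"][1], 0.03)
  expect_identical(sum(prof$count), 3L)
  prof0 <- windowFrequency(ev[0], 100, gm, window = 3e5)
  expect_true(all(prof0$freq == 0))
  set.seed(18)
  ev2 <- midpointEvents("chrB", runif(57, 0, 1.5e6))
  prof2 <- windowFrequency(ev2, 50, gm, window = 3e5)
  expect_identical(sum(prof2$count), 57L)
  expect_error(windowFrequency(ev, 100, gm, window = 0), "positive")
})

test_that("scaled arm profiles map telomere to 0 and centromere to 1", {
  gm <- genomeModel("chr1", 2e6, 1e6)
  ev <- midpointEvents("chr1", c(2e4, 1.99e6))  # both chromosome ends
  prof <- windowFrequency(ev, 10, gm, window = 1e5)
  sc <- scaleArms(prof, gm, nBins = 10)
  withMass <- which(sc$meanFreq > 0)
  expect_identical(withMass, 1L)  # all crossover mass in the first bin
  expect_identical(nrow(sc), 10L)
  expect_identical(sum(sc$nWindows), nrow(prof))
})

test_that("mirror-symmetric landscapes give identical left and right scaled profiles", {
  gm <- genomeModel("chr1", 2e6, 1e6)  # metacentric
  set.seed(20)
  leftMids <- runif(400, 0, 1e6)
  mids <- c(leftMids, 2e6 - leftMids)  # exact mirror image
  prof <- windowFrequency(midpointEvents("chr1", mids), 100, gm,
                          window = 1e5)
  scLeft <- scaleArms(prof[prof$start <= 1e6, ], gm, nBins = 5)
  scRight <- scaleArms(prof[prof$start > 1e6, ], gm, nBins = 5)
  expect_equal(scLeft$meanFreq, scRight$meanFreq, tolerance = 1e-12)
})

test_that("correlation matrices are symmetric with unit diagonal", {
  gm <- tinyGenome()
  set.seed(22)
  p1 <- windowFrequency(midpointEvents("chrA", runif(300, 0, 2e6)), 100, gm)
  p2 <- windowFrequency(midpointEvents("chrA", runif(300, 0, 2e6)), 100, gm)
  m <- correlationMatrix(list(a = p1, b = p2, aAgain = p1))
  expect_identical(diag(m), c(a = 1, b = 1, aAgain = 1))
  expect_identical(m, t(m))
  expect_equal(m["a", "aAgain"], 1)
  rev1 <- p1; rev1$freq <- rev(rev1$freq)
  expect_lt(correlationMatrix(list(p1, rev1))[1, 2], 1)
  const <- p1; const$freq <- 0.5
  expect_true(is.na(correlationMatrix(list(p1, const))[1, 2]))
  short <- p1[-1, ]
  expect_error(correlationMatrix(list(p1, short)), "identical windows")
})

test_that("replicate populations correlate when and only when the landscape is shared", {
  gm <- syntheticGenomeModel()
  squeeze <- function(pos, L) ifelse(pos < L / 2, pos * 0.2,
                                     L - (L - pos) * 0.2)
  mkProf <- function(seed, transform = NULL) {
    sim <- simulateF2Population(
      simConfig(seed = seed, nu = 1, class1Mean = 2, class2Mean = 0), 300,
      positionTransform = transform)
    ev <- callCrossovers(segmentGenotypes(sim$genotypes))
    windowFrequency(ev, 300, gm, window = 3e5)
  }
  # a shared telomere-clustered landscape: replicates highly concordant
  m <- correlationMatrix(list(mkProf(71, squeeze), mkProf(72, squeeze)))
  expect_gt(m[1, 2], 0.4)
  # a homogeneous landscape carries no reproducible structure
  m0 <- correlationMatrix(list(mkProf(73), mkProf(74)))
  expect_lt(abs(m0[1, 2]), 0.25)
})

test_that("regional reduction separates pericentromeres from arms", {
  gm <- tinyGenome()
  set.seed(24)
  wt <- windowFrequency(midpointEvents("chrA", runif(2000, 0, 2e6)), 500,
                        gm, window = 1e5)
  mut <- wt
  expect_true(all(regionalReduction(mut, wt, gm)$perWindow$ratio == 1,
                  na.rm = TRUE))
  mut2 <- wt; mut2$freq <- wt$freq / 2
  rr2 <- regionalReduction(mut2, wt, gm)
  expect_equal(rr2$summary$median, c(0.5, 0.5))
  # remove crossovers only inside pericentromeres
  mut3 <- wt
  mid <- (mut3$start - 1 + mut3$end) / 2
  inPeri <- mut3$chrom == "chrA" & mid >= 1.0e6 & mid <= 1.4e6
  mut3$freq[inPeri] <- mut3$freq[inPeri] * 0.2
  rr3 <- regionalReduction(mut3, wt, gm, alternative = "less")
  med <- rr3$summary
  expect_lt(med$median[med$group == "pericentromere"],
            med$median[med$group == "arm"])
  expect_lt(rr3$testP, 0.01)
  noPeri <- genomeModel("chrA", 2e6, 1.2e6)
  expect_error(regionalReduction(mut3[mut3$chrom == "chrA", ],
                                 wt[wt$chrom == "chrA", ], noPeri),
               "pericentromere")
})
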