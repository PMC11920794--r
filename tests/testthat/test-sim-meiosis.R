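test_that("nu = 1 class I placement is a homogeneous Poisson process", {
  set.seed(42)
  L <- 2e7
  counts <- replicate(10000, length(placeClassICrossovers(L, 2, nu = 1)))
  expect_equal(mean(counts), 2, tolerance = 0.05)
  expect_lt(abs(var(counts) / mean(counts) - 1), 0.05)
  # inter-event distances indistinguishable from a Poisson-process oracle
  # (gaps on a finite window are truncation-biased, so compare like with
  # like by two-sample KS)
  gaps <- unlist(replicate(4000, diff(placeClassICrossovers(L, 5, nu = 1)),
                           simplify = FALSE))
  oracle <- unlist(replicate(4000, {
    p <- cumsum(rexp(30, rate = 5 / L))
    diff(p[p <= L])
  }, simplify = FALSE))
  expect_gt(length(gaps), 10000)
  ks <- suppressWarnings(ks.test(gaps, oracle))
  expect_gt(ks$p.value, 0.01)
})

test_that("interference (nu > 1) underdisperses counts and spaces events", {
  set.seed(7)
  L <- 2e7
  c1 <- replicate(10000, placeClassICrossovers(L, 2, nu = 1),
                  simplify = FALSE)
  c5 <- replicate(10000, placeClassICrossovers(L, 2, nu = 5),
                  simplify = FALSE)
  n1 <- lengths(c1); n5 <- lengths(c5)
  expect_lt(var(n5) / mean(n5), 1)
  nn <- function(lst) unlist(lapply(lst, function(p)
    if (length(p) >= 2) min(diff(p)) else numeric(0)))
  expect_gt(mean(nn(c5)), mean(nn(c1)))
})

test_that("variance/mean of class I counts strictly decreases with nu", {
  set.seed(11)
  vm <- vapply(c(1, 2, 5, 10), function(nu) {
    n <- replicate(3000, length(placeClassICrossovers(2e7, 2, nu)))
    var(n) / mean(n)
  }, numeric(1))
  expect_true(all(diff(vm) < 0))
})

test_that("degenerate class I inputs are handled", {
  expect_identical(placeClassICrossovers(2e7, 0, 5), numeric(0))
  expect_error(placeClassICrossovers(-1, 2, 5), "positive")
  expect_error(placeClassICrossovers(2e7, 2, 0), "nu")
  expect_error(placeClassICrossovers(2e7, -1, 5), ">= 0")
})

test_that("identical seed gives bit-identical simulated populations", {
  cfg <- simConfig(seed = 99, genoErrorP = 0.02)
  a <- simulateF2Population(cfg, 20)
  b <- simulateF2Population(cfg, 20)
  expect_identical(SummarizedExperiment::assay(a$genotypes, "geno"),
                   SummarizedExperiment::assay(b$genotypes, "geno"))
  expect_identical(a$truth@crossovers, b$truth@crossovers)
  expect_identical(a$truth@copyNumber, b$truth@copyNumber)
})

test_that("expected crossover count per individual and chromosome is 2 x mean x 1/2", {
  sim <- simulateF2Population(
    simConfig(seed = 5, nu = 1, class1Mean = 1.5, class2Mean = 0.5), 500)
  gm <- syntheticGenomeModel()
  perIC <- nrow(sim$truth@crossovers) / (500 * length(chromNames(gm)))
  # 2 gametes x (1.5 + 0.5) bivalent COs x 1/2 chromatid sampling = 2
  expect_equal(perIC, 2, tolerance = 0.1)
})

test_that("a single true crossover shows as a single genotype transition at its position", {
  sim <- simulateF2Population(simConfig(seed = 21, genoErrorP = 0), 30)
  tr <- sim$truth@crossovers
  cnt <- table(paste(tr$individual, tr$chrom))
  g <- SummarizedExperiment::assay(sim$genotypes, "geno")
  rr <- SummarizedExperiment::rowRanges(sim$genotypes)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  hits <- names(cnt)[cnt == 1]
  expect_gt(length(hits), 0)
  for (k in hits[1:min(5, length(hits))]) {
    id <- sub(" .*", "", k); ch <- sub(".* ", "", k)
    copy <- sim$truth@copyNumber
    if (copy$copy[copy$individual == id & copy$chrom == ch] != 2L) next
    col <- g[chrom == ch, id]
    p <- pos[chrom == ch]
    switches <- which(col[-1] != col[-length(col)])
    expect_length(switches, 1)
    truePos <- tr$pos[tr$individual == id & tr$chrom == ch]
    expect_lt(abs((p[switches] + p[switches + 1]) / 2 - truePos),
              diff(range(p)) / length(p) * 2)
  }
})

test_that("crossover-less bivalents missegregate when escape probability is 1", {
  sim <- simulateF2Population(
    simConfig(seed = 13, class1Mean = 0, class2Mean = 0, nu = 1,
              obligateEscapeP = 1), 40)
  expect_true(all(sim$truth@copyNumber$copy %in% c(1L, 3L)))
  sim2 <- simulateF2Population(
    simConfig(seed = 13, class1Mean = 0, class2Mean = 0, nu = 1,
              obligateEscapeP = 0), 40)
  expect_true(all(sim2$truth@copyNumber$copy == 2L))
})

test_that("simulated coverage reflects copy number", {
  gm <- tinyGenome()
  truth <- new("MeiosisTruth",
    crossovers = data.frame(individual = character(), chrom = character(),
                            gamete = integer(), pos = numeric()),
    copyNumber = data.frame(
      individual = rep(c("i1", "i2", "i3"), each = 2),
      chrom = rep(c("chrA", "chrB"), 3),
      copy = c(3L, 2L, 1L, 2L, 2L, 2L)))
  cov <- simulateCoverage(truth, gm, windowBp = 1e5, baseDepth = 20,
                          noiseSd = 0)
  d <- SummarizedExperiment::assay(cov, "depth")
  ch <- as.character(GenomicRanges::seqnames(
    SummarizedExperiment::rowRanges(cov)))
  expect_true(all(d[ch == "chrA", "i1"] == 30))
  expect_true(all(d[ch == "chrA", "i2"] == 10))
  expect_true(all(d[ch == "chrB", "i1"] == 20))
  expect_error(simulateCoverage(truth, gm, windowBp = 0), "positive")
})

test_that("noisy disomic coverage concentrates around ratio 1", {
  set.seed(3)
  gm <- genomeModel("chr1", 1.5e7, 7e6)  # 150 windows of 100 kb
  truth <- new("MeiosisTruth",
    crossovers = data.frame(individual = character(), chrom = character(),
                            gamete = integer(), pos = numeric()),
    copyNumber = data.frame(individual = sprintf("i%03d", 1:300),
                            chrom = "chr1", copy = 2L))
  cov <- simulateCoverage(truth, gm, baseDepth = 20, noiseSd = 1)
  m <- colMeans(SummarizedExperiment::assay(cov, "depth")) / 20
  expect_gte(mean(m >= 0.95 & m <= 1.05), 0.99)
})

test_that("seed-count simulation inverts the closed-form estimator", {
  set.seed(17)
  z <- simulateSeedCounts(0, 500)
  expect_identical(z@nGreen + z@nRed, 0L)
  rf <- replicate(40, recombinationFrequency(simulateSeedCounts(21.8, 4000)))
  expect_lt(abs(mean(rf) - 21.8), 1)
  big <- simulateSeedCounts(50, 4e6)
  expect_equal((big@nGreen + big@nRed) / big@nTotal, 0.375, tolerance = 0.01)
  expect_error(simulateSeedCounts(100, 100), "rfCm")
})
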