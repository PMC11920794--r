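test_that("SNP filter applies the strict quality/coverage thresholds", {
  ge <- makeGeno(matrix(c("P1", "H", "P2", "H"), 4, 1))
  q <- matrix(c(100, 250, 101, 150), 4, 1)
  cv <- matrix(c(3.0, 2.5, 2.6, 5.0), 4, 1)
  SummarizedExperiment::assay(ge, "qual", withDimnames = FALSE) <- q
  SummarizedExperiment::assay(ge, "cov", withDimnames = FALSE) <- cv
  out <- suppressMessages(filterSnps(ge))
  g <- SummarizedExperiment::assay(out, "geno")
  expect_true(is.na(g[1, 1]))  # qual exactly 100: removed (strict >)
  expect_true(is.na(g[2, 1]))  # cov exactly 2.5: removed (strict >)
  expect_identical(unname(g[3, 1]), "P2")  # 101 / 2.6: kept
  expect_identical(unname(g[4, 1]), "H")
})

test_that("SNP filtering is idempotent", {
  set.seed(1)
  ge <- makeGeno(matrix(sample(c("P1", "H", "P2"), 60, TRUE), 30, 2))
  SummarizedExperiment::assay(ge, "qual", withDimnames = FALSE) <-
    matrix(runif(60, 50, 300), 30, 2)
  SummarizedExperiment::assay(ge, "cov", withDimnames = FALSE) <- matrix(runif(60, 0, 6), 30, 2)
  once <- suppressMessages(filterSnps(ge))
  twice <- suppressMessages(filterSnps(once))
  expect_identical(SummarizedExperiment::assay(once, "geno"),
                   SummarizedExperiment::assay(twice, "geno"))
  expect_error(suppressMessages(
    filterSnps(makeGeno(matrix(character(0), 0, 0)))), "empty")
})

test_that("library filter drops strictly sub-threshold read counts", {
  ge <- makeGeno(matrix("H", 20, 3))
  SummarizedExperiment::colData(ge)$informativeReads <-
    c(49999, 50000, 120000)
  out <- filterLibraries(ge)
  expect_identical(ncol(out), 2L)
  expect_identical(unname(informativeReads(out)), c(50000, 120000))
  expect_warning(filterLibraries(ge, minReads = 1e9), "all libraries")
})

test_that("genotype tables round-trip through TSV", {
  set.seed(2)
  calls <- matrix(sample(c("P1", "H", "P2", NA), 40, TRUE), 20, 2,
                  dimnames = list(NULL, c("a", "b")))
  ge <- makeGeno(calls)
  SummarizedExperiment::assay(ge, "cov", withDimnames = FALSE) <-
    matrix(round(runif(40, 0, 9), 3), 20, 2)
  path <- tempfile(fileext = ".tsv")
  writeGenotypeTable(ge, path)
  back <- readGenotypeTable(path)
  expect_identical(SummarizedExperiment::assay(back, "geno"),
                   SummarizedExperiment::assay(ge, "geno"))
  expect_equal(SummarizedExperiment::assay(back, "cov"),
               SummarizedExperiment::assay(ge, "cov"), tolerance = 1e-6)
  expect_equal(unname(informativeReads(back)),
               unname(informativeReads(ge)))
  expect_identical(
    GenomicRanges::start(SummarizedExperiment::rowRanges(back)),
    GenomicRanges::start(SummarizedExperiment::rowRanges(ge)))
})

test_that("malformed genotype rows fail with a line number", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("individual\tchrom\tpos\tgenotype\tqual\tcov\tlib_reads",
               "i1\tchr1\t100\tP1\t200\t5\t60000",
               "i1\tchr1\t200\tXX\t200\t5\t60000"), path)
  expect_error(readGenotypeTable(path), "line 3")
  writeLines(c("individual\tchrom\tpos\tgenotype\tqual\tcov\tlib_reads",
               "i1\tchr1\toops\tP1\t200\t5\t60000"), path)
  expect_error(readGenotypeTable(path), "line 2")
})

test_that("marker maps round-trip and reject unsorted positions", {
  mk <- GenomicRanges::GRanges("chr2", IRanges::IRanges(c(10, 40, 90), width = 1),
                               allele_p1 = c("A", "C", "G"),
                               allele_p2 = c("T", "G", "A"))
  path <- tempfile(fileext = ".tsv")
  writeMarkerMap(mk, path)
  back <- readMarkerMap(path)
  expect_identical(GenomicRanges::start(back), GenomicRanges::start(mk))
  expect_identical(S4Vectors::mcols(back)$allele_p1, c("A", "C", "G"))
  bad <- data.frame(chrom = "chr1", pos = c(100, 50),
                    allele_p1 = "A", allele_p2 = "T")
  write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readMarkerMap(path), "strictly increasing")
})

test_that("crossover BED round-trips with 0-based half-open coordinates", {
  segs <- makeSegments(c(1e5, 5e5, 9e5), c(4.5e5, 8.5e5, 1.2e6),
                       c("P1", "H", "P1"))
  ev <- callCrossovers(segs)
  path <- tempfile(fileext = ".bed")
  writeCrossoverBed(ev, path)
  raw <- read.table(path, sep = "\t")
  # internal 1-based start maps to BED start - 1
  expect_identical(raw$V2, GenomicRanges::start(ev) - 1L)
  expect_identical(raw$V3, GenomicRanges::end(ev))
  back <- readCrossoverBed(path)
  expect_identical(GenomicRanges::start(back), GenomicRanges::start(ev))
  expect_equal(S4Vectors::mcols(back)$midpoint,
               S4Vectors::mcols(ev)$midpoint)
  writeLines("chr1\t500\t100\ti1\t300\tP1->H\t0", path)
  expect_error(readCrossoverBed(path), "end < start")
})

test_that("coverage tracks round-trip through TSV", {
  gm <- tinyGenome()
  cov <- makeCoverage(matrix(c(2, 3, 2, 2), 2, 2,
                             dimnames = list(NULL, c("i1", "i2"))), gm)
  path <- tempfile(fileext = ".tsv")
  writeCoverageTrack(cov, path)
  back <- readCoverageTrack(path)
  expect_equal(SummarizedExperiment::assay(back, "depth"),
               SummarizedExperiment::assay(cov, "depth"), tolerance = 1e-6)
  expect_identical(
    GenomicRanges::start(SummarizedExperiment::rowRanges(back)),
    GenomicRanges::start(SummarizedExperiment::rowRanges(cov)))
})
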