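# small in-code fixtures shared across test files

# two small chromosomes with centromeres and pericentromere intervals
tinyGenome <- function() {
  genomeModel(
    c("chrA", "chrB"), c(2e6, 1.5e6), c(1.2e6, 0.5e6),
    pericentromere = GenomicRanges::GRanges(
      c("chrA", "chrB"),
      IRanges::IRanges(start = c(1.0e6, 0.3e6), end = c(1.4e6, 0.7e6))
    )
  )
}

# GenotypeExperiment from a character matrix (markers x individuals) on one
# chromosome with evenly spaced markers and clean qual/cov
makeGeno <- function(calls, chrom = "chr1", spacing = 5e4,
                     qual = 200, cov = 5, reads = 1e5) {
  calls <- as.matrix(calls)
  n <- nrow(calls)
  markers <- GenomicRanges::GRanges(
    rep(chrom, n), IRanges::IRanges(start = seq_len(n) * spacing,
                                    width = 1L))
  genotypeExperiment(
    geno = calls,
    qual = matrix(qual, n, ncol(calls)),
    cov = matrix(cov, n, ncol(calls)),
    markers = markers,
    informativeReads = rep(reads, ncol(calls))
  )
}

# segments table from vectors (single individual/chromosome by default)
makeSegments <- function(starts, ends, states, individual = "ind1",
                         chrom = "chr1") {
  data.frame(individual = individual, chrom = chrom,
             start = starts, end = ends, state = states,
             nMarkers = 10L, nSupporting = 10L, stringsAsFactors = FALSE)
}

# CoverageExperiment with given per-chromosome copy ratios (columns =
# individuals), constant depth, optional Gaussian noise
makeCoverage <- function(copies, genome, windowBp = 1e5, baseDepth = 20,
                         noiseSd = 0) {
  cn <- chromNames(genome)
  lens <- unname(chromLengths(genome))
  starts <- lapply(lens, function(L) seq(1, L, by = windowBp))
  nWin <- vapply(starts, length, integer(1))
  windows <- GenomicRanges::GRanges(
    rep(cn, nWin),
    IRanges::IRanges(unlist(starts),
                     end = pmin(unlist(starts) + windowBp - 1,
                                rep(lens, nWin))))
  winChrom <- rep(cn, nWin)
  copies <- as.matrix(copies)
  depth <- apply(copies, 2, function(cp)
    pmax(0, baseDepth * cp[match(winChrom, cn)] / 2 +
           stats::rnorm(length(winChrom), 0, noiseSd)))
  colnames(depth) <- colnames(copies)
  coverageExperiment(depth, windows)
}

# greedy truth-vs-called crossover matching within `tol` bp
matchCrossovers <- function(truth, events, tol = 1e5) {
  evd <- data.frame(
    ind = S4Vectors::mcols(events)$individual,
    chrom = as.character(GenomicRanges::seqnames(events)),
    mid = S4Vectors::mcols(events)$midpoint
  )
  rec <- 0L; fp <- 0L; errs <- numeric(0)
  keys <- unique(paste(truth$individual, truth$chrom))
  evKey <- paste(evd$ind, evd$chrom)
  trKey <- paste(truth$individual, truth$chrom)
  for (k in keys) {
    t <- truth$pos[trKey == k]
    e <- evd$mid[evKey == k]
    for (tt in t) {
      if (length(e)) {
        d <- abs(e - tt)
        if (min(d) < tol) {
          rec <- rec + 1L
          errs <- c(errs, min(d))
          e <- e[-which.min(d)]
        }
      }
    }
    fp <- fp + length(e)
  }
  fp <- fp + sum(!(evKey %in% trKey))
  list(nTrue = nrow(truth), nRecovered = rec, nFalse = fp, errors = errs)
}
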