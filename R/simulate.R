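#' Construct a simulation configuration
#'
#' Default intensities describe a wild-type-like plant F2 cross: ~1.8
#' interfering class I crossovers per bivalent with strong interference
#' (`nu = 5`), a small Poisson class II contribution, 2% genotyping error,
#' 50 kb mean marker spacing and libraries of ~200,000 informative reads.
#'
#' @param genome a [GenomeModel-class]; defaults to [syntheticGenomeModel()].
#' @param class1Mean expected class I (interfering) crossovers per bivalent
#'   per chromosome.
#' @param nu gamma shape of class I inter-crossover distances; `nu = 1` is a
#'   homogeneous Poisson process (no interference).
#' @param class2Mean expected class II (non-interfering, Poisson) crossovers
#'   per bivalent per chromosome.
#' @param obligateEscapeP probability that a bivalent without any crossover
#'   missegregates, producing a monosomic or trisomic individual.
#' @param genoErrorP per-marker probability of a genotype mis-call.
#' @param markerSpacing mean distance between SNP markers (bp).
#' @param meanLibReads mean informative (SNP-associated) reads per library.
#' @param meanMarkerCov mean per-marker coverage.
#' @param seed integer RNG seed (mandatory; every simulation is fully
#'   reproducible from it).
#' @return a [SimConfig-class].
#' @export
simConfig <- function(genome = syntheticGenomeModel(),
                      class1Mean = 1.8, nu = 5, class2Mean = 0.3,
                      obligateEscapeP = 0, genoErrorP = 0.02,
                      markerSpacing = 5e4, meanLibReads = 2e5,
                      meanMarkerCov = 5, seed) {
  if (missing(seed)) stop("seed is mandatory")
  new("SimConfig",
    genome = genome, class1Mean = class1Mean, nu = nu,
    class2Mean = class2Mean, obligateEscapeP = obligateEscapeP,
    genoErrorP = genoErrorP, markerSpacing = markerSpacing,
    meanLibReads = meanLibReads, meanMarkerCov = meanMarkerCov,
    seed = as.integer(seed)
  )
}

#' Place class I crossovers by a stationary gamma renewal process
#'
#' Inter-crossover distances are gamma(shape = `nu`, rate = `nu * class1Mean
#' / chromLength`), so the expected number of crossovers on the chromosome is
#' `class1Mean`. The first event uses the equilibrium (forward-recurrence)
#' delay — a uniform fraction of a length-biased gamma(`nu + 1`) interval —
#' so the process is stationary and no artificial interference appears near
#' position 0. With `nu = 1` this reduces exactly to a homogeneous Poisson
#' process.
#'
#' Uses the session RNG; call `set.seed()` (or go through
#' [simulateF2Population()], which seeds from its [SimConfig-class]) for
#' reproducibility.
#'
#' @param chromLength chromosome length in bp (> 0).
#' @param class1Mean expected number of crossovers on the chromosome (>= 0).
#' @param nu gamma shape (> 0); larger values space crossovers more evenly.
#' @return sorted numeric vector of crossover positions in `[0, chromLength]`.
#' @examples
#' set.seed(1)
#' placeClassICrossovers(3e7, 2, nu = 5)
#' @export
placeClassICrossovers <- function(chromLength, class1Mean, nu) {
  if (length(chromLength) != 1 || !is.finite(chromLength) || chromLength <= 0)
    stop("chromLength must be a single positive number")
  if (class1Mean < 0) stop("class1Mean must be >= 0")
  if (nu <= 0) stop("nu must be > 0")
  if (class1Mean == 0) return(numeric(0))
  rate <- nu * class1Mean / chromLength
  pos <- stats::runif(1) * stats::rgamma(1, shape = nu + 1, rate = rate)
  if (pos > chromLength) return(numeric(0))
  out <- pos
  k <- as.integer(ceiling(class1Mean + 6 * sqrt(class1Mean + 1) + 4))
  repeat {
    cs <- pos + cumsum(stats::rgamma(k, shape = nu, rate = rate))
    out <- c(out, cs[cs <= chromLength])
    if (cs[k] > chromLength) break
    pos <- cs[k]
  }
  out
}

# Poisson class II placement: count ~ Poisson(mean), positions uniform
.placeClass2 <- function(chromLength, class2Mean) {
  if (class2Mean == 0) return(numeric(0))
  sort(stats::runif(stats::rpois(1, class2Mean), 0, chromLength))
}

# haplotype parent (1 or 2) at each marker, given crossover breakpoints
.haplotypeAt <- function(markerPos, breaks, startParent) {
  odd <- findInterval(markerPos, breaks) %% 2L
  startParent + odd * (3L - 2L * startParent)
}

#' Simulate an F2 population
#'
#' Each individual is the union of two independent gametes. Per meiosis and
#' chromosome, bivalent crossovers are the union of class I (gamma renewal,
#' [placeClassICrossovers()]) and class II (Poisson) events; each crossover
#' is assigned to a random chromatid pair with no chromatid interference, so
#' the single sampled chromatid carries each bivalent crossover
#' independently with probability 1/2. Bivalents with zero crossovers
#' missegregate with probability `obligateEscapeP`, making the chromosome
#' monosomic or trisomic with equal odds (at most one missegregation per
#' individual and chromosome, so copy number stays in 1..3; a trisomic
#' chromosome carries the missegregated chromatid twice). Genotype calls are
#' then flipped to a random wrong state with probability `genoErrorP`.
#'
#' @param config a [SimConfig-class]; its `seed` fully determines the output.
#' @param nIndividuals number of F2 individuals (>= 1).
#' @param positionTransform optional `function(pos, chromLength)` applied to
#'   bivalent crossover positions before chromatid assignment; used to build
#'   non-uniform crossover landscapes (e.g. telomere-clustered scenarios)
#'   on top of the homogeneous placement model.
#' @return a list with elements `genotypes` (a [GenotypeExperiment-class])
#'   and `truth` (a [MeiosisTruth-class]).
#' @examples
#' sim <- simulateF2Population(simConfig(seed = 1, genoErrorP = 0), 5)
#' sim$genotypes
#' @export
simulateF2Population <- function(config, nIndividuals,
                                 positionTransform = NULL) {
  stopifnot(is(config, "SimConfig"))
  if (nIndividuals < 1) stop("nIndividuals must be >= 1")
  gm <- config@genome
  chroms <- chromNames(gm)
  if (length(chroms) == 0) stop("empty genome: no chromosomes")
  set.seed(config@seed)
  lens <- unname(chromLengths(gm))

  # fixed marker map: jittered regular grid with mean gap = markerSpacing
  # (bounded gaps mimic a curated, evenly informative SNP set)
  markerPos <- lapply(seq_along(chroms), function(ci) {
    sp <- config@markerSpacing
    centers <- seq(sp / 2, lens[ci], by = sp)
    pos <- round(centers + stats::runif(length(centers), -0.2, 0.2) * sp)
    unique(pmin(pmax(pos, 1), as.integer(lens[ci])))
  })
  nMark <- vapply(markerPos, length, integer(1))
  ids <- sprintf("ind%04d", seq_len(nIndividuals))

  geno <- matrix(NA_character_, nrow = sum(nMark), ncol = nIndividuals,
                 dimnames = list(NULL, ids))
  rowOff <- c(0L, cumsum(nMark))
  copyMat <- matrix(2L, nrow = nIndividuals, ncol = length(chroms),
                    dimnames = list(ids, chroms))
  truthBr <- vector("list", 2L * nIndividuals * length(chroms))
  truthMeta <- matrix(0L, nrow = length(truthBr), ncol = 4L)  # i, ci, m, len
  ti <- 0L

  for (i in seq_len(nIndividuals)) {
    for (ci in seq_along(chroms)) {
      L <- lens[ci]
      gametes <- vector("list", 2L)
      zeroCO <- logical(2L)
      for (m in 1:2) {
        biv <- sort(c(
          placeClassICrossovers(L, config@class1Mean, config@nu),
          .placeClass2(L, config@class2Mean)
        ))
        if (!is.null(positionTransform) && length(biv))
          biv <- sort(pmin(pmax(positionTransform(biv, L), 0), L))
        zeroCO[m] <- length(biv) == 0L
        kept <- biv[stats::runif(length(biv)) < 0.5]
        gametes[[m]] <- list(breaks = kept,
                             startParent = sample(1:2, 1L))
      }
      copy <- 2L
      haps <- gametes
      if (config@obligateEscapeP > 0) {
        mis <- which(zeroCO)[which(stats::runif(sum(zeroCO)) <
                                     config@obligateEscapeP)]
        if (length(mis)) {
          m <- mis[1L]  # at most one missegregation per chromosome
          copy <- sample(c(1L, 3L), 1L)
          haps <- if (copy == 1L) gametes[-m] else
            c(gametes, gametes[m])
        }
      }
      mp <- markerPos[[ci]]
      a1 <- .haplotypeAt(mp, haps[[1L]]$breaks, haps[[1L]]$startParent)
      nP1 <- (a1 == 1L)
      for (h in haps[-1L])
        nP1 <- nP1 + (.haplotypeAt(mp, h$breaks, h$startParent) == 1L)
      g <- rep("H", length(mp))
      g[nP1 == length(haps)] <- "P1"
      g[nP1 == 0L] <- "P2"
      geno[(rowOff[ci] + 1L):rowOff[ci + 1L], i] <- g

      copyMat[i, ci] <- copy
      for (m in 1:2) {
        br <- gametes[[m]]$breaks
        if (length(br)) {
          ti <- ti + 1L
          truthBr[[ti]] <- br
          truthMeta[ti, ] <- c(i, ci, m, length(br))
        }
      }
    }
  }
  truthMeta <- truthMeta[seq_len(ti), , drop = FALSE]

  # i.i.d. per-marker genotype noise: flip to one of the two wrong states
  if (config@genoErrorP > 0) {
    flip <- which(stats::runif(length(geno)) < config@genoErrorP)
    if (length(flip)) {
      code <- match(geno[flip], .GENO_STATES)
      shift <- sample(1:2, length(flip), replace = TRUE)
      geno[flip] <- .GENO_STATES[(code - 1L + shift) %% 3L + 1L]
    }
  }

  qual <- matrix(stats::runif(length(geno), 150, 250), nrow = nrow(geno))
  cov <- matrix(stats::rgamma(length(geno), shape = 4,
                              rate = 4 / config@meanMarkerCov),
                nrow = nrow(geno))
  markers <- GenomicRanges::GRanges(
    rep(chroms, nMark),
    IRanges::IRanges(start = unlist(markerPos), width = 1L)
  )
  reads <- pmax(0, round(stats::rnorm(nIndividuals, config@meanLibReads,
                                      0.1 * config@meanLibReads)))
  ge <- genotypeExperiment(geno, qual, cov, markers, reads)
  co <- data.frame(
    individual = rep(ids[truthMeta[, 1L]], truthMeta[, 4L]),
    chrom = rep(chroms[truthMeta[, 2L]], truthMeta[, 4L]),
    gamete = rep(truthMeta[, 3L], truthMeta[, 4L]),
    pos = if (ti > 0) unlist(truthBr[seq_len(ti)]) else numeric(0),
    stringsAsFactors = FALSE
  )
  copyTab <- data.frame(
    individual = rep(ids, each = length(chroms)),
    chrom = rep(chroms, nIndividuals),
    copy = as.integer(t(copyMat)),
    stringsAsFactors = FALSE
  )
  truth <- new("MeiosisTruth", crossovers = co, copyNumber = copyTab)
  list(genotypes = ge, truth = truth)
}

#' Simulate windowed sequencing coverage reflecting chromosome copy number
#'
#' Window depth is `baseDepth * copy / 2` plus Gaussian noise, truncated at
#' zero, emulating mosdepth-style fixed windows.
#'
#' @param truth a [MeiosisTruth-class] (copy numbers are taken from it).
#' @param genome a [GenomeModel-class].
#' @param windowBp window size in bp (> 0); default 100 kb.
#' @param baseDepth expected depth of a disomic chromosome (> 0).
#' @param noiseSd standard deviation of per-window Gaussian noise.
#' @return a [CoverageExperiment-class].
#' @export
simulateCoverage <- function(truth, genome, windowBp = 1e5, baseDepth = 20,
                             noiseSd = 2) {
  stopifnot(is(truth, "MeiosisTruth"))
  if (windowBp <= 0) stop("windowBp must be positive")
  if (baseDepth <= 0) stop("baseDepth must be positive")
  chroms <- chromNames(genome)
  lens <- unname(chromLengths(genome))
  starts <- lapply(seq_along(chroms), function(ci)
    seq(1, lens[ci], by = windowBp))
  nWin <- vapply(starts, length, integer(1))
  windows <- GenomicRanges::GRanges(
    rep(chroms, nWin),
    IRanges::IRanges(
      start = unlist(starts),
      end = pmin(unlist(starts) + windowBp - 1, rep(lens, nWin))
    )
  )
  ids <- unique(truth@copyNumber$individual)
  depth <- matrix(0, nrow = length(windows), ncol = length(ids),
                  dimnames = list(NULL, ids))
  winChrom <- rep(chroms, nWin)
  cpKey <- paste(truth@copyNumber$individual, truth@copyNumber$chrom)
  for (j in seq_along(ids)) {
    cp <- truth@copyNumber$copy[match(paste(ids[j], winChrom), cpKey)]
    mu <- baseDepth * cp / 2
    depth[, j] <- pmax(0, mu + stats::rnorm(length(windows), 0, noiseSd))
  }
  coverageExperiment(depth, windows)
}

#' Simulate fluorescent-seed counts for a reporter interval
#'
#' Inverse of the closed-form recombination-frequency estimator: with map
#' distance `rfCm`, the probability that a seed is single-fluorescent
#' (green-only plus red-only) is `(1 - (1 - rfCm/100)^2) / 2`, split equally
#' between the two colours; counts are multinomial.
#'
#' @param rfCm map distance in centimorgans, in `[0, 100)`.
#' @param nTotal total seeds scored.
#' @return a [SeedCounts-class].
#' @seealso [recombinationFrequency()]
#' @export
simulateSeedCounts <- function(rfCm, nTotal) {
  if (rfCm < 0 || rfCm >= 100)
    stop("rfCm must be in [0, 100)")
  if (nTotal < 1) stop("nTotal must be >= 1")
  r <- rfCm / 100
  pSingle <- (1 - (1 - r)^2) / 2
  cnt <- stats::rmultinom(1, nTotal, c(pSingle / 2, pSingle / 2, 1 - pSingle))
  seedCounts(nGreen = cnt[1], nRed = cnt[2], nTotal = nTotal)
}
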