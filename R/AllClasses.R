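#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start end width mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowRanges colData
NULL

#' Chromosome set with centromeres and pericentromere annotation
#'
#' A `GenomeModel` describes the chromosomes an analysis runs on: their
#' lengths, centromere midpoints, and (optionally) pericentromere intervals.
#' Pericentromeres are an external annotation (typically derived from DNA
#' methylation); they are required only by [regionalReduction()].
#'
#' @slot chromNames character vector of chromosome names.
#' @slot chromLengths numeric vector of chromosome lengths (bp).
#' @slot centromereMids numeric vector of centromere midpoints (bp).
#' @slot pericentromere [GenomicRanges::GRanges] of pericentromere intervals
#'   (may be empty).
#' @seealso [genomeModel()], [syntheticGenomeModel()]
#' @export
setClass("GenomeModel",
  slots = c(
    chromNames = "character",
    chromLengths = "numeric",
    centromereMids = "numeric",
    pericentromere = "GRanges"
  )
)

setValidity("GenomeModel", function(object) {
  msg <- character()
  n <- length(object@chromNames)
  if (length(object@chromLengths) != n || length(object@centromereMids) != n)
    msg <- c(msg, "chromNames, chromLengths and centromereMids must have equal length")
  if (anyDuplicated(object@chromNames))
    msg <- c(msg, "chromosome names must be unique")
  if (any(object@chromLengths <= 0))
    msg <- c(msg, "chromosome lengths must be positive")
  if (length(object@chromLengths) == n &&
      (any(object@centromereMids <= 0) || any(object@centromereMids >= object@chromLengths)))
    msg <- c(msg, "centromere midpoints must lie strictly inside (0, length)")
  if (length(object@pericentromere) > 0) {
    pc <- object@pericentromere
    idx <- match(as.character(seqnames(pc)), object@chromNames)
    if (anyNA(idx))
      msg <- c(msg, "pericentromere intervals on unknown chromosomes")
    else if (any(start(pc) < 0) || any(end(pc) > object@chromLengths[idx]))
      msg <- c(msg, "pericentromere intervals outside chromosome bounds")
  }
  if (length(msg)) msg else TRUE
})

#' Simulation configuration for F2 meiosis
#'
#' Holds the generative parameters of the meiosis simulator: the genome,
#' the class I (interfering) and class II (non-interfering) crossover
#' intensities, the interference shape `nu`, the nondisjunction escape
#' probability for crossover-less bivalents, the per-marker genotyping
#' error rate, and marker/library/sequencing nuisance parameters.
#'
#' `nu = 1` makes class I placement a homogeneous Poisson process
#' (no interference); larger `nu` spaces class I crossovers more evenly.
#'
#' @slot genome a [GenomeModel].
#' @slot class1Mean expected class I crossovers per bivalent per chromosome.
#' @slot nu gamma shape of class I inter-crossover distances (> 0).
#' @slot class2Mean expected class II crossovers per bivalent per chromosome.
#' @slot obligateEscapeP probability a crossover-less bivalent missegregates.
#' @slot genoErrorP per-marker genotype mis-call probability.
#' @slot markerSpacing mean distance between markers (bp).
#' @slot meanLibReads mean informative reads per library.
#' @slot meanMarkerCov mean per-marker sequencing coverage.
#' @slot seed integer RNG seed (mandatory).
#' @seealso [simConfig()], [simulateF2Population()]
#' @export
setClass("SimConfig",
  slots = c(
    genome = "GenomeModel",
    class1Mean = "numeric",
    nu = "numeric",
    class2Mean = "numeric",
    obligateEscapeP = "numeric",
    genoErrorP = "numeric",
    markerSpacing = "numeric",
    meanLibReads = "numeric",
    meanMarkerCov = "numeric",
    seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  prob_in_01 <- function(p) length(p) == 1 && is.finite(p) && p >= 0 && p <= 1
  if (!(length(object@class1Mean) == 1 && object@class1Mean >= 0))
    msg <- c(msg, "class1Mean must be a single value >= 0")
  if (!(length(object@nu) == 1 && object@nu > 0))
    msg <- c(msg, "nu must be a single value > 0")
  if (!(length(object@class2Mean) == 1 && object@class2Mean >= 0))
    msg <- c(msg, "class2Mean must be a single value >= 0")
  if (!prob_in_01(object@obligateEscapeP))
    msg <- c(msg, "obligateEscapeP must be a probability in [0, 1]")
  if (!prob_in_01(object@genoErrorP))
    msg <- c(msg, "genoErrorP must be a probability in [0, 1]")
  if (!(object@markerSpacing > 0))
    msg <- c(msg, "markerSpacing must be positive")
  if (length(object@seed) != 1 || is.na(object@seed))
    msg <- c(msg, "seed is mandatory")
  if (length(msg)) msg else TRUE
})

#' Per-marker genotype calls for an F2 population
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] subclass holding one
#' row per SNP marker (as width-1 `GRanges`) and one column per F2
#' individual, with three assays:
#' \describe{
#'   \item{`geno`}{character calls in `"P1"`, `"H"`, `"P2"` or `NA` (missing).}
#'   \item{`qual`}{per-call mapping quality.}
#'   \item{`cov`}{per-call sequencing coverage.}
#' }
#' `colData` carries `informativeReads`, the number of SNP-associated reads
#' per library, used by [filterLibraries()].
#'
#' @seealso [genotypeExperiment()], [filterSnps()], [segmentGenotypes()]
#' @export
setClass("GenotypeExperiment", contains = "RangedSummarizedExperiment")

.GENO_STATES <- c("P1", "H", "P2")

setValidity("GenotypeExperiment", function(object) {
  msg <- character()
  need <- c("geno", "qual", "cov")
  if (!all(need %in% SummarizedExperiment::assayNames(object)))
    msg <- c(msg, "assays 'geno', 'qual' and 'cov' are required")
  else {
    g <- assay(object, "geno")
    if (!all(g[!is.na(g)] %in% .GENO_STATES))
      msg <- c(msg, "genotype calls must be 'P1', 'H', 'P2' or NA")
    cv <- assay(object, "cov")
    if (any(cv[!is.na(cv)] < 0))
      msg <- c(msg, "coverage must be >= 0")
  }
  if (!"informativeReads" %in% colnames(colData(object)))
    msg <- c(msg, "colData must contain 'informativeReads'")
  if (length(msg)) msg else TRUE
})

#' Windowed sequencing-depth tracks for a population
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] subclass with one row
#' per fixed-size genomic window (`GRanges`) and one column per individual,
#' and a single `depth` assay of mean per-window sequencing depth.
#'
#' @seealso [coverageExperiment()], [callPloidy()]
#' @export
setClass("CoverageExperiment", contains = "RangedSummarizedExperiment")

setValidity("CoverageExperiment", function(object) {
  msg <- character()
  if (!"depth" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'depth' is required")
  else if (any(assay(object, "depth") < 0, na.rm = TRUE))
    msg <- c(msg, "depth must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a simulated F2 population
#'
#' Records, for every simulated individual, the true crossover midpoints on
#' each inherited chromatid and the per-chromosome copy number. Used to
#' benchmark the crossover caller and the ploidy caller against truth.
#'
#' @slot crossovers data.frame with columns `individual`, `chrom`, `gamete`
#'   (1 or 2) and `pos` (bp), one row per true crossover on an inherited
#'   chromatid.
#' @slot copyNumber data.frame with columns `individual`, `chrom`, `copy`
#'   (1, 2 or 3).
#' @seealso [simulateF2Population()]
#' @export
setClass("MeiosisTruth",
  slots = c(crossovers = "data.frame", copyNumber = "data.frame")
)

setValidity("MeiosisTruth", function(object) {
  msg <- character()
  if (!all(c("individual", "chrom", "gamete", "pos") %in% names(object@crossovers)))
    msg <- c(msg, "crossovers needs columns individual, chrom, gamete, pos")
  if (!all(c("individual", "chrom", "copy") %in% names(object@copyNumber)))
    msg <- c(msg, "copyNumber needs columns individual, chrom, copy")
  else if (!all(object@copyNumber$copy %in% c(1L, 2L, 3L)))
    msg <- c(msg, "copy number must be 1, 2 or 3")
  if (length(msg)) msg else TRUE
})

#' Maximum-likelihood gamma fit with bootstrap shape distribution
#'
#' Result of fitting a two-parameter gamma distribution to inter-crossover
#' distances by maximum likelihood, optionally with a bootstrap distribution
#' of the shape parameter attached by [bootstrapShape()].
#'
#' @slot shape fitted gamma shape (the interference parameter `v`).
#' @slot rate fitted gamma rate (1/bp).
#' @slot logLik maximised log-likelihood.
#' @slot n sample size.
#' @slot bootstrapShapes numeric vector of bootstrap shape estimates
#'   (length 0 until [bootstrapShape()] is run).
#' @seealso [fitGammaDistances()], [bootstrapShape()]
#' @export
setClass("GammaFit",
  slots = c(
    shape = "numeric",
    rate = "numeric",
    logLik = "numeric",
    n = "integer",
    bootstrapShapes = "numeric"
  )
)

setValidity("GammaFit", function(object) {
  msg <- character()
  if (!(is.finite(object@shape) && object@shape > 0))
    msg <- c(msg, "shape must be finite and positive")
  if (!(is.finite(object@rate) && object@rate > 0))
    msg <- c(msg, "rate must be finite and positive")
  if (length(msg)) msg else TRUE
})

#' Fluorescent-seed counts for one scored interval
#'
#' Counts of green-only and red-only fluorescent seeds among all seeds of a
#' fluorescent-reporter line, the input of the closed-form recombination
#' frequency estimator.
#'
#' @slot nGreen integer, green-only fluorescent seeds.
#' @slot nRed integer, red-only fluorescent seeds.
#' @slot nTotal integer, total seeds scored.
#' @seealso [seedCounts()], [recombinationFrequency()]
#' @export
setClass("SeedCounts",
  slots = c(nGreen = "integer", nRed = "integer", nTotal = "integer")
)

setValidity("SeedCounts", function(object) {
  msg <- character()
  if (object@nTotal <= 0L) msg <- c(msg, "nTotal must be positive")
  if (object@nGreen < 0L || object@nRed < 0L)
    msg <- c(msg, "seed counts must be non-negative")
  if (object@nGreen + object@nRed > object@nTotal)
    msg <- c(msg, "nGreen + nRed cannot exceed nTotal")
  if (length(msg)) msg else TRUE
})
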