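#' Extract cis-double-crossover distances
#'
#' Scans each individual-chromosome's alternating genotype segments for
#' maximal parental–heterozygous–parental triples with *matching* parental
#' states (P1–H–P1 or P2–H–P2) and returns the distance between the
#' midpoints of the two flanking transitions. Heterozygous–parental–
#' heterozygous triples and P1–H–P2 triples (parental states differ) are not
#' counted.
#'
#' @param segments data.frame from [segmentGenotypes()].
#' @return data.frame with columns `individual`, `chrom`, `pattern`
#'   (`"P1-H-P1"` or `"P2-H-P2"`) and `distance` (bp).
#' @export
extractCisDcos <- function(segments) {
  req <- c("individual", "chrom", "start", "end", "state")
  stopifnot(all(req %in% names(segments)))
  empty <- data.frame(individual = character(), chrom = character(),
                      pattern = character(), distance = numeric())
  if (nrow(segments) < 3) return(empty)
  segments <- segments[order(segments$individual, segments$chrom,
                             segments$start), ]
  n <- nrow(segments)
  grp <- paste(segments$individual, segments$chrom)
  i <- 2:(n - 1)
  mid <- i[grp[i - 1] == grp[i] & grp[i] == grp[i + 1] &
             segments$state[i] == "H" &
             segments$state[i - 1] == segments$state[i + 1] &
             segments$state[i - 1] %in% c("P1", "P2")]
  if (!length(mid)) return(empty)
  t1 <- (segments$end[mid - 1] + segments$start[mid]) / 2
  t2 <- (segments$end[mid] + segments$start[mid + 1]) / 2
  data.frame(
    individual = segments$individual[mid],
    chrom = segments$chrom[mid],
    pattern = paste0(segments$state[mid - 1], "-H-", segments$state[mid - 1]),
    distance = t2 - t1,
    stringsAsFactors = FALSE
  )
}

#' Crossover midpoints grouped by chromosome
#'
#' @param events crossover `GRanges` from [callCrossovers()].
#' @param excludeFlagged drop flagged (direct parental-to-parental) events.
#' @return named list of numeric midpoint vectors, one per chromosome.
#' @export
midpointsByChrom <- function(events, excludeFlagged = TRUE) {
  if (excludeFlagged && length(events))
    events <- events[!mcols(events)$flagged]
  split(mcols(events)$midpoint, as.character(seqnames(events)))
}

#' Randomised expected inter-crossover distances
#'
#' Builds the no-interference null: per chromosome, two sets of `nSample`
#' crossover midpoints are drawn with replacement from all identified
#' crossovers of that chromosome; each midpoint of the first set is paired
#' with one uniformly drawn midpoint of the second set and the absolute
#' distance recorded. Zero distances (self-pairing of identical midpoints)
#' are retained. Chromosomes with fewer than two distinct midpoints are
#' skipped with a warning. Distances are pooled across chromosomes.
#'
#' @param midpoints named list of per-chromosome midpoint vectors
#'   ([midpointsByChrom()]), or a single numeric vector (one chromosome).
#' @param nSample midpoints per set and chromosome (default 400).
#' @return numeric vector of expected distances (bp),
#'   `nSample` per usable chromosome.
#' @export
sampleExpectedDistances <- function(midpoints, nSample = 400) {
  if (is.numeric(midpoints)) midpoints <- list(midpoints)
  out <- lapply(names(midpoints) %||% seq_along(midpoints), function(ch) {
    mp <- midpoints[[ch]]
    if (length(unique(mp)) < 2) {
      warning("chromosome ", ch,
              " has fewer than 2 distinct midpoints; skipped")
      return(numeric(0))
    }
    s1 <- sample(mp, nSample, replace = TRUE)
    s2 <- sample(mp, nSample, replace = TRUE)
    abs(s1 - s2[sample.int(nSample, nSample, replace = TRUE)])
  })
  unlist(out, use.names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Maximum-likelihood gamma fit to inter-crossover distances
#'
#' Two-parameter gamma fit by maximum likelihood. The shape equation
#' `log(k) - digamma(k) = log(mean(x)) - mean(log(x))` is solved by Newton
#' iteration from Minka's closed-form initialiser; the rate is
#' `shape / mean(x)`. Zero distances are replaced by half the smallest
#' positive distance (reported via `message()`). Near-constant samples whose
#' shape diverges are capped at 1e6 with a warning.
#'
#' @param x numeric vector of distances (bp), `length(x) >= 10`.
#' @return a [GammaFit-class].
#' @examples
#' set.seed(1)
#' fitGammaDistances(rgamma(1000, shape = 4, rate = 2))
#' @export
fitGammaDistances <- function(x) {
  if (length(x) < 10) stop("insufficient data: need at least 10 distances")
  if (any(x < 0)) stop("distances must be non-negative")
  if (any(x == 0)) {
    pos <- x[x > 0]
    if (!length(pos)) stop("all distances are zero")
    message(sum(x == 0), " zero distance(s) replaced by half the smallest ",
            "positive distance")
    x[x == 0] <- min(pos) / 2
  }
  k <- .gammaShapeMLE(x)
  capped <- FALSE
  if (!is.finite(k) || k > 1e6) {
    warning("gamma shape diverged (near-constant sample); capped at 1e6")
    k <- 1e6
    capped <- TRUE
  }
  rate <- k / mean(x)
  ll <- sum(stats::dgamma(x, shape = k, rate = rate, log = TRUE))
  if (capped && !is.finite(ll)) ll <- -Inf
  new("GammaFit", shape = k, rate = rate, logLik = ll,
      n = length(x), bootstrapShapes = numeric(0))
}

# Newton solve of log(k) - digamma(k) = s with Minka's initialiser
.gammaShapeMLE <- function(x) {
  s <- log(mean(x)) - mean(log(x))
  if (s <= 0 || !is.finite(s)) return(Inf)
  k <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  for (i in 1:50) {
    delta <- (log(k) - digamma(k) - s) / (1 / k - trigamma(k))
    kNew <- k - delta
    if (kNew <= 0) kNew <- k / 2
    if (abs(kNew - k) < 1e-10 * k) return(kNew)
    k <- kNew
  }
  k
}

#' @rdname GammaFit-class
#' @param object a `GammaFit`.
#' @export
setMethod("show", "GammaFit", function(object) {
  cat(sprintf("GammaFit: shape = %.4g, rate = %.4g (n = %d, logLik = %.2f)\n",
              object@shape, object@rate, object@n, object@logLik))
  if (length(object@bootstrapShapes))
    cat(sprintf("  bootstrap shapes: %d draws, 2.5%%/50%%/97.5%% = %.3g/%.3g/%.3g\n",
                length(object@bootstrapShapes),
                stats::quantile(object@bootstrapShapes, 0.025),
                stats::median(object@bootstrapShapes),
                stats::quantile(object@bootstrapShapes, 0.975)))
  invisible(NULL)
})

#' @rdname GammaFit-class
#' @param x a `GammaFit`.
#' @export
gammaShape <- function(x) x@shape

#' @rdname GammaFit-class
#' @export
gammaRate <- function(x) x@rate

#' @rdname GammaFit-class
#' @export
bootstrapShapes <- function(x) x@bootstrapShapes

#' Bootstrap distribution of the gamma shape parameter
#'
#' Resamples the distances with replacement `iters` times (default 1000) and
#' refits the gamma by maximum likelihood, recording the shape of each
#' resample. Errors if more than 10% of refits fail.
#'
#' @param x numeric vector of distances.
#' @param iters bootstrap iterations.
#' @return numeric vector of bootstrap shape estimates (failed refits
#'   removed).
#' @export
bootstrapShape <- function(x, iters = 1000) {
  if (iters < 1) stop("iters must be >= 1")
  if (length(x) < 10) stop("insufficient data: need at least 10 distances")
  pos <- x[x > 0]
  if (!length(pos)) stop("all distances are zero")
  x[x == 0] <- min(pos) / 2  # same zero handling as fitGammaDistances
  shapes <- vapply(seq_len(iters), function(i) {
    xs <- sample(x, replace = TRUE)
    k <- .gammaShapeMLE(xs)
    if (!is.finite(k)) NA_real_ else min(k, 1e6)
  }, numeric(1))
  if (mean(is.na(shapes)) > 0.1)
    stop("more than 10% of bootstrap refits failed")
  shapes[!is.na(shapes)]
}

#' Compare two bootstrap shape distributions
#'
#' Two-sided Mann–Whitney U test between the bootstrap shape estimates of
#' the observed and expected distance distributions.
#'
#' @param bootObs,bootExp numeric vectors of bootstrap shape estimates.
#' @return the two-sided p-value.
#' @export
compareShapeDistributions <- function(bootObs, bootExp) {
  if (!length(bootObs) || !length(bootExp))
    stop("both bootstrap vectors must be non-empty")
  if (length(unique(c(bootObs, bootExp))) == 1L) {
    warning("identical constant shape distributions; p = 1")
    return(1)
  }
  stats::wilcox.test(bootObs, bootExp, exact = FALSE)$p.value
}

#' Rank-based comparison of two distance sets
#'
#' Two-sided rank test between two sets of inter-crossover distances:
#' unpaired Mann–Whitney by default, or Wilcoxon signed-rank on paired
#' (equal-length) values with `paired = TRUE`.
#'
#' @param distA,distB numeric distance vectors.
#' @param paired use the signed-rank test on paired values.
#' @return the two-sided p-value.
#' @export
compareDistanceSets <- function(distA, distB, paired = FALSE) {
  if (!length(distA) || !length(distB))
    stop("distance sets must be non-empty")
  if (paired && length(distA) != length(distB))
    stop("paired comparison requires equal-length sets")
  if (length(distA) == 1 && length(distB) == 1 && !paired)
    return(1)  # no power
  if (identical(sort(distA), sort(distB)) && !paired)
    if (length(unique(distA)) == 1L) return(1)
  stats::wilcox.test(distA, distB, paired = paired, exact = FALSE)$p.value
}

#' Coefficient-of-coincidence profile
#'
#' Bins observed and expected inter-crossover distances (default 3.5 Mb
#' bins from 0), rescales the expected counts so their total matches the
#' observed total, and reports the per-bin ratio CoC = observed/expected.
#' CoC 1 means independent crossover occurrence, below 1 positive
#' interference, above 1 clustering (negative interference). Bins with zero
#' expected counts have undefined CoC (`NA`).
#'
#' @param observed numeric vector of observed cis-DCO distances (bp).
#' @param expected numeric vector of expected (randomised) distances (bp).
#' @param binWidth bin width in bp (default 3.5e6).
#' @return data.frame with columns `binStart`, `binEnd`, `observed`,
#'   `expected` (rescaled), `coc`.
#' @export
computeCoc <- function(observed, expected, binWidth = 3.5e6) {
  if (!length(observed)) stop("empty observed distance set")
  if (!length(expected)) stop("empty expected distance set")
  if (binWidth <= 0) stop("binWidth must be positive")
  top <- max(observed, expected)
  breaks <- seq(0, binWidth * ceiling(top / binWidth + 1e-9), by = binWidth)
  if (length(breaks) < 2) breaks <- c(0, binWidth)
  binOf <- function(d) {
    b <- findInterval(d, breaks, left.open = TRUE, rightmost.closed = FALSE)
    b[d == 0] <- 1L  # zero distances belong to the first bin
    tabulate(b, nbins = length(breaks) - 1L)
  }
  obs <- binOf(observed)
  expRaw <- binOf(expected)
  expScaled <- expRaw * sum(obs) / sum(expRaw)
  data.frame(
    binStart = breaks[-length(breaks)],
    binEnd = breaks[-1],
    observed = obs,
    expected = expScaled,
    coc = ifelse(expScaled == 0, NA_real_, obs / expScaled)
  )
}

#' Full cis-DCO interference analysis
#'
#' Runs the complete interference procedure on segmented genotypes: extract
#' cis-DCO distances, build the randomised expected-distance null from
#' crossover midpoints, fit gamma distributions to both sets, bootstrap the
#' shape parameter, compare the bootstrap shape distributions by
#' Mann–Whitney, and compute the coefficient-of-coincidence profile.
#'
#' @param segments data.frame from [segmentGenotypes()].
#' @param events optional crossover `GRanges`; computed with
#'   [callCrossovers()] if `NULL`.
#' @param nullN midpoints per set and chromosome for the null (default 400).
#' @param bootstrapIters bootstrap iterations (default 1000).
#' @param binWidth CoC bin width (default 3.5e6 bp).
#' @param seed optional RNG seed for the randomised null and bootstraps.
#' @return a list with elements `observed`, `expected` (distance vectors),
#'   `fitObserved`, `fitExpected` ([GammaFit-class] with bootstrap shapes),
#'   `shapeP` (Mann–Whitney p-value on bootstrap shapes), `coc`
#'   (the [computeCoc()] profile), `medianObserved`, `medianExpected`.
#' @export
interferenceAnalysis <- function(segments, events = NULL, nullN = 400,
                                 bootstrapIters = 1000, binWidth = 3.5e6,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(events)) events <- callCrossovers(segments)
  dcos <- extractCisDcos(segments)
  observed <- dcos$distance
  expected <- sampleExpectedDistances(midpointsByChrom(events), nullN)
  fitObs <- suppressMessages(fitGammaDistances(observed))
  fitExp <- suppressMessages(fitGammaDistances(expected))
  fitObs@bootstrapShapes <- bootstrapShape(observed, bootstrapIters)
  fitExp@bootstrapShapes <- bootstrapShape(expected, bootstrapIters)
  shapeP <- compareShapeDistributions(fitObs@bootstrapShapes,
                                      fitExp@bootstrapShapes)
  list(
    observed = observed,
    expected = expected,
    fitObserved = fitObs,
    fitExpected = fitExp,
    shapeP = shapeP,
    coc = computeCoc(observed, expected, binWidth),
    medianObserved = stats::median(observed),
    medianExpected = stats::median(expected)
  )
}
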