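#' Normalize windowed depth to per-chromosome copy ratios
#'
#' For each individual, the disomic baseline `D` is the length-weighted mean
#' depth over chromosomes, re-estimated iteratively with chromosomes whose
#' provisional ratio falls outside `[monoThreshold, triThreshold]` excluded
#' (at most `maxIter` rounds or until the included set stabilises), so an
#' aneuploid chromosome does not inflate its own baseline. The ratio of
#' chromosome `c` is its mean window depth divided by `D`. Ratios are
#' invariant to rescaling all depths by a constant.
#'
#' @param x a [CoverageExperiment-class].
#' @param genome a [GenomeModel-class].
#' @param triThreshold,monoThreshold thresholds used for provisional
#'   exclusion during baseline estimation (and by [classifyPloidy()]).
#' @param maxIter maximum re-estimation rounds.
#' @return data.frame with columns `individual`, `chrom`, `ratio`.
#' @export
normalizePloidy <- function(x, genome, triThreshold = 1.2,
                            monoThreshold = 0.8, maxIter = 5) {
  stopifnot(is(x, "CoverageExperiment"))
  rr <- rowRanges(x)
  winChrom <- as.character(seqnames(rr))
  chroms <- chromNames(genome)
  if (!all(chroms %in% winChrom))
    stop("chromosome(s) without coverage windows: ",
         paste(setdiff(chroms, winChrom), collapse = ", "))
  lens <- unname(chromLengths(genome))
  depth <- assay(x, "depth")
  # per-chromosome mean depth, chromosomes x individuals
  chromMean <- do.call(rbind, lapply(chroms, function(ch)
    colMeans(depth[winChrom == ch, , drop = FALSE], na.rm = TRUE)))
  res <- vector("list", ncol(depth))
  for (j in seq_len(ncol(depth))) {
    d <- chromMean[, j]
    include <- rep(TRUE, length(chroms))
    for (it in seq_len(maxIter)) {
      if (!any(include)) break
      D <- sum(d[include] * lens[include]) / sum(lens[include])
      ratio <- d / D
      newInclude <- ratio >= monoThreshold & ratio <= triThreshold
      if (identical(newInclude, include)) break
      include <- newInclude
    }
    if (!any(include)) {
      warning("all chromosomes excluded during baseline estimation for ",
              colnames(depth)[j], "; falling back to plain mean")
      D <- sum(d * lens) / sum(lens)
      ratio <- d / D
    }
    res[[j]] <- data.frame(individual = colnames(depth)[j], chrom = chroms,
                           ratio = ratio, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Classify a copy ratio into monosomy/disomy/trisomy
#'
#' Strict thresholds exactly as printed: a ratio above `triThreshold`
#' (default 1.2) indicates trisomy, below `monoThreshold` (default 0.8)
#' monosomy; everything else (boundaries included) is disomy.
#'
#' @param ratio numeric vector of copy ratios (>= 0).
#' @param triThreshold,monoThreshold classification thresholds.
#' @return character vector in `c("monosomy", "disomy", "trisomy")`.
#' @examples
#' classifyPloidy(c(0.5, 1.0, 1.2, 1.5))
#' @export
classifyPloidy <- function(ratio, triThreshold = 1.2, monoThreshold = 0.8) {
  if (any(is.na(ratio)))
    stop("NA/NaN copy ratio")
  if (any(ratio < 0))
    stop("copy ratios must be >= 0")
  ifelse(ratio > triThreshold, "trisomy",
         ifelse(ratio < monoThreshold, "monosomy", "disomy"))
}

#' Arm-level copy ratios and partial-trisomy detection
#'
#' Splits each chromosome at its centromere midpoint (windows are assigned
#' to the arm containing their midpoint), computes per-arm ratios against
#' the same individual baseline used by [normalizePloidy()], classifies arms
#' with the same thresholds, and reports partial trisomy when exactly one
#' arm is trisomic.
#'
#' @inheritParams normalizePloidy
#' @return data.frame with columns `individual`, `chrom`, `leftArmRatio`,
#'   `rightArmRatio`, `leftArmClass`, `rightArmClass`, `partialTrisomy`.
#' @export
detectPartialTrisomy <- function(x, genome, triThreshold = 1.2,
                                 monoThreshold = 0.8, maxIter = 5) {
  stopifnot(is(x, "CoverageExperiment"))
  rr <- rowRanges(x)
  winChrom <- as.character(seqnames(rr))
  winMid <- (start(rr) + end(rr)) / 2
  chroms <- chromNames(genome)
  cen <- unname(centromereMids(genome))
  lens <- unname(chromLengths(genome))
  depth <- assay(x, "depth")
  whole <- normalizePloidy(x, genome, triThreshold, monoThreshold, maxIter)
  # recover each individual's baseline D from whole-chromosome ratios
  chromMean <- do.call(rbind, lapply(chroms, function(ch)
    colMeans(depth[winChrom == ch, , drop = FALSE], na.rm = TRUE)))
  res <- vector("list", 0L)
  for (j in seq_len(ncol(depth))) {
    id <- colnames(depth)[j]
    rj <- whole$ratio[whole$individual == id]
    D <- stats::median(chromMean[, j] / rj)  # constant across chromosomes
    for (ci in seq_along(chroms)) {
      onChrom <- winChrom == chroms[ci]
      leftSel <- onChrom & winMid <= cen[ci]
      rightSel <- onChrom & winMid > cen[ci]
      armRatio <- function(sel) {
        if (!any(sel)) return(NA_real_)
        mean(depth[sel, j], na.rm = TRUE) / D
      }
      lr <- armRatio(leftSel)
      rr2 <- armRatio(rightSel)
      if (is.na(lr) || is.na(rr2))
        warning("arm with no windows on ", chroms[ci], " for ", id,
                "; arm class undefined")
      cls <- function(r) if (is.na(r)) NA_character_ else
        classifyPloidy(r, triThreshold, monoThreshold)
      lc <- cls(lr)
      rc <- cls(rr2)
      res[[length(res) + 1L]] <- data.frame(
        individual = id, chrom = chroms[ci],
        leftArmRatio = lr, rightArmRatio = rr2,
        leftArmClass = lc, rightArmClass = rc,
        partialTrisomy = isTRUE(sum(c(lc, rc) == "trisomy", na.rm = TRUE) == 1L &&
                                  !anyNA(c(lc, rc))),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Call per-chromosome ploidy from windowed coverage
#'
#' Combines [normalizePloidy()], [classifyPloidy()] and
#' [detectPartialTrisomy()] into one per-individual per-chromosome table.
#' The `call` column equals `class` except that a disomic chromosome with
#' exactly one trisomic arm is reported as `"partial_trisomy"`.
#'
#' @inheritParams normalizePloidy
#' @return data.frame with columns `individual`, `chrom`, `ratio`, `class`,
#'   `leftArmRatio`, `rightArmRatio`, `leftArmClass`, `rightArmClass`,
#'   `call`.
#' @export
callPloidy <- function(x, genome, triThreshold = 1.2, monoThreshold = 0.8,
                       maxIter = 5) {
  whole <- normalizePloidy(x, genome, triThreshold, monoThreshold, maxIter)
  whole$class <- classifyPloidy(whole$ratio, triThreshold, monoThreshold)
  arms <- detectPartialTrisomy(x, genome, triThreshold, monoThreshold,
                               maxIter)
  out <- merge(whole, arms, by = c("individual", "chrom"), sort = FALSE)
  out$call <- ifelse(out$class == "disomy" & out$partialTrisomy,
                     "partial_trisomy", out$class)
  out$partialTrisomy <- NULL
  out[order(out$individual, out$chrom), ]
}
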