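#' Windowed crossover-frequency landscape
#'
#' Bins crossover midpoints into fixed-origin windows (default 300 kb,
#' last partial window retained) and reports per-window crossover frequency
#' per F2 individual, so that `sum(count) == length(events)` and
#' `freq = count / nIndividuals`.
#'
#' @param events crossover `GRanges` from [callCrossovers()].
#' @param nIndividuals number of individuals the events were called in.
#' @param genome a [GenomeModel-class].
#' @param window window size in bp (default 3e5).
#' @return data.frame with columns `chrom`, `start` (1-based), `end`,
#'   `count`, `freq`; the number of individuals is attached as attribute
#'   `nIndividuals`.
#' @export
windowFrequency <- function(events, nIndividuals, genome, window = 3e5) {
  if (window <= 0) stop("window must be positive")
  if (nIndividuals < 1) stop("nIndividuals must be >= 1")
  chroms <- chromNames(genome)
  lens <- unname(chromLengths(genome))
  evChrom <- as.character(seqnames(events))
  evMid <- mcols(events)$midpoint
  res <- lapply(seq_along(chroms), function(ci) {
    starts <- seq(0, by = window,
                  length.out = max(1, ceiling(lens[ci] / window)))
    ends <- pmin(starts + window, lens[ci])
    mids <- evMid[evChrom == chroms[ci]]
    idx <- pmin(findInterval(mids, starts), length(starts))
    cnt <- tabulate(idx, nbins = length(starts))
    data.frame(chrom = chroms[ci], start = starts + 1, end = ends,
               count = cnt, freq = cnt / nIndividuals,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "nIndividuals") <- nIndividuals
  out
}

#' Proportionally scaled telomere-to-centromere arm profile
#'
#' Maps every chromosome arm onto [0, 1] with 0 at the telomere and 1 at
#' the centromere, assigns windows by their midpoint, and averages window
#' frequencies within `nBins` equal bins across all arms of all
#' chromosomes.
#'
#' @param profile a windowed profile from [windowFrequency()].
#' @param genome a [GenomeModel-class].
#' @param nBins number of proportional-coordinate bins (default 20).
#' @return data.frame with columns `binStart`, `binEnd` (in [0, 1]),
#'   `meanFreq`, `nWindows`.
#' @export
scaleArms <- function(profile, genome, nBins = 20) {
  cen <- centromereMids(genome)
  lens <- chromLengths(genome)
  mid <- (profile$start - 1 + profile$end) / 2
  cenC <- unname(cen[profile$chrom])
  lenC <- unname(lens[profile$chrom])
  coord <- ifelse(mid <= cenC, mid / cenC, (lenC - mid) / (lenC - cenC))
  bin <- pmin(pmax(ceiling(coord * nBins), 1L), nBins)
  agg <- tapply(profile$freq, factor(bin, levels = seq_len(nBins)),
                mean)
  cnt <- tapply(rep(1, nrow(profile)), factor(bin, levels = seq_len(nBins)),
                sum)
  data.frame(
    binStart = (seq_len(nBins) - 1) / nBins,
    binEnd = seq_len(nBins) / nBins,
    meanFreq = as.numeric(agg),
    nWindows = as.integer(ifelse(is.na(cnt), 0L, cnt))
  )
}

#' Rank-correlation matrix between crossover landscapes
#'
#' Spearman rank correlation between every pair of windowed profiles
#' computed on identical windows. Constant profiles yield `NA` (undefined)
#' entries.
#'
#' @param profiles named list of profiles from [windowFrequency()], all on
#'   identical windows.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlationMatrix <- function(profiles) {
  if (length(profiles) < 2) stop("need at least 2 profiles")
  key <- lapply(profiles, function(p) paste(p$chrom, p$start, p$end))
  if (!all(vapply(key[-1], identical, logical(1), key[[1]])))
    stop("profiles must be computed on identical windows")
  nm <- names(profiles) %||% paste0("profile", seq_along(profiles))
  m <- diag(1, length(profiles))
  dimnames(m) <- list(nm, nm)
  for (i in seq_along(profiles)) for (j in seq_along(profiles)) {
    if (i < j) {
      fi <- profiles[[i]]$freq
      fj <- profiles[[j]]$freq
      r <- if (stats::sd(fi) == 0 || stats::sd(fj) == 0) NA_real_ else
        suppressWarnings(stats::cor(fi, fj, method = "spearman"))
      m[i, j] <- m[j, i] <- r
    }
  }
  m
}

#' Arm versus pericentromere crossover reduction
#'
#' Per-window ratio of mutant to wild-type crossover frequency, grouped by
#' whether the window midpoint falls in a pericentromere interval. Windows
#' with zero wild-type frequency are reported as `NA`. Group medians/means
#' and a two-sample rank test between the groups summarise the comparison.
#'
#' @param profileMut,profileWt windowed profiles from [windowFrequency()] on
#'   identical windows.
#' @param genome a [GenomeModel-class]; pericentromere intervals required.
#' @param alternative alternative hypothesis for the rank test comparing
#'   pericentromere vs arm ratios (default `"two.sided"`; use `"less"` to
#'   test for a stronger pericentromeric reduction).
#' @return list with `perWindow` (data.frame: `chrom`, `start`, `end`,
#'   `ratio`, `group`), `summary` (per-group n, median, mean) and `testP`
#'   (rank-test p-value, pericentromere vs arm).
#' @export
regionalReduction <- function(profileMut, profileWt, genome,
                              alternative = "two.sided") {
  if (!identical(paste(profileMut$chrom, profileMut$start),
                 paste(profileWt$chrom, profileWt$start)))
    stop("profiles must be computed on identical windows")
  peri <- pericentromere(genome)
  if (length(peri) == 0)
    stop("genome has no pericentromere annotation")
  ratio <- ifelse(profileWt$freq == 0, NA_real_,
                  profileMut$freq / profileWt$freq)
  mid <- (profileMut$start - 1 + profileMut$end) / 2
  winGr <- GenomicRanges::GRanges(profileMut$chrom,
                                  IRanges::IRanges(round(mid), width = 1L))
  inPeri <- IRanges::overlapsAny(winGr, peri)
  group <- ifelse(inPeri, "pericentromere", "arm")
  perWindow <- data.frame(chrom = profileMut$chrom, start = profileMut$start,
                          end = profileMut$end, ratio = ratio, group = group,
                          stringsAsFactors = FALSE)
  ok <- !is.na(ratio)
  summary <- do.call(rbind, lapply(c("arm", "pericentromere"), function(g) {
    r <- ratio[ok & group == g]
    data.frame(group = g, n = length(r),
               median = stats::median(r), mean = mean(r))
  }))
  testP <- if (all(c("arm", "pericentromere") %in% group[ok]) &&
                 min(table(group[ok])) >= 2)
    stats::wilcox.test(ratio[ok & group == "pericentromere"],
                       ratio[ok & group == "arm"],
                       alternative = alternative, exact = FALSE)$p.value
  else NA_real_
  list(perWindow = perWindow, summary = summary, testP = testP)
}
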