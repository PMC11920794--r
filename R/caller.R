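#' Segment per-marker genotypes into parental/heterozygous blocks
#'
#' A deterministic sliding-window segmentation: each marker receives a
#' provisional state by plurality vote over the `windowMarkers` markers
#' centred on it (missing calls do not vote; all-missing windows and ties
#' inherit the previous marker's state). Runs of provisional states shorter
#' than `minSegmentMarkers` are absorbed into the flanking run with more
#' markers (ties to the left), shortest run first, until stable; runs whose
#' fraction of supporting raw calls falls below `purity` are absorbed the
#' same way. Two local passes then sharpen the result: each segment
#' boundary is re-placed at the raw-call maximum-likelihood changepoint
#' between its two segments (ties resolved towards the provisional
#' boundary), and uninterrupted raw runs of a different state of at least
#' `max(3, minSegmentMarkers - 2)` markers — essentially impossible under
#' independent mis-calls at realistic error rates — are restored as
#' segments, so short double-crossover tracts and near-telomeric segments
#' survive the vote. The result is an alternating sequence of genotype
#' segments per individual and chromosome.
#'
#' This caller is a defined, deterministic stand-in for HMM-based crossover
#' callers used on real genotyping-by-sequencing data; it is adequate at
#' simulated per-marker error rates up to ~5%.
#'
#' @param x a [GenotypeExperiment-class].
#' @param windowMarkers voting window size in markers (odd values centre
#'   cleanly; default 15).
#' @param purity minimum fraction of supporting raw calls per segment, in
#'   (0.5, 1].
#' @param minSegmentMarkers minimum run length in markers.
#' @return data.frame with columns `individual`, `chrom`, `start`, `end`
#'   (first/last marker position of the segment, bp), `state`, `nMarkers`,
#'   `nSupporting`.
#' @export
segmentGenotypes <- function(x, windowMarkers = 15, purity = 0.8,
                             minSegmentMarkers = 5) {
  stopifnot(is(x, "GenotypeExperiment"))
  if (windowMarkers < 1 || minSegmentMarkers < 1)
    stop("window and segment sizes must be positive")
  if (purity <= 0.5 || purity > 1)
    stop("purity must be in (0.5, 1]")
  rr <- rowRanges(x)
  chrom <- as.character(seqnames(rr))
  posAll <- start(rr)
  g <- assay(x, "geno")
  cn <- colnames(x)
  out <- vector("list", 0L)
  shortChroms <- character()
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    sel <- sel[order(posAll[sel])]
    pos <- posAll[sel]
    if (length(sel) < windowMarkers) {
      shortChroms <- c(shortChroms, ch)
      next
    }
    codes <- matrix(match(g[sel, , drop = FALSE], .GENO_STATES),
                    nrow = length(sel))
    for (j in seq_len(ncol(codes))) {
      segs <- .segmentOne(codes[, j], pos, windowMarkers, purity,
                          minSegmentMarkers)
      if (!is.null(segs)) {
        segs$individual <- cn[j]
        segs$chrom <- ch
        out[[length(out) + 1L]] <- segs
      }
    }
  }
  if (length(shortChroms))
    warning("chromosome(s) with fewer than ", windowMarkers,
            " markers skipped: ", paste(shortChroms, collapse = ", "))
  if (!length(out))
    return(data.frame(individual = character(), chrom = character(),
                      start = numeric(), end = numeric(), state = character(),
                      nMarkers = integer(), nSupporting = integer()))
  nSeg <- vapply(out, function(s) length(s$start), integer(1))
  data.frame(
    individual = rep(vapply(out, `[[`, "", "individual"), nSeg),
    chrom = rep(vapply(out, `[[`, "", "chrom"), nSeg),
    start = unlist(lapply(out, `[[`, "start")),
    end = unlist(lapply(out, `[[`, "end")),
    state = .GENO_STATES[unlist(lapply(out, `[[`, "state"))],
    nMarkers = unlist(lapply(out, `[[`, "nMarkers")),
    nSupporting = unlist(lapply(out, `[[`, "nSupporting")),
    stringsAsFactors = FALSE
  )
}

# segment one individual-chromosome; code: integer 1..3 / NA per marker
.segmentOne <- function(code, pos, window, purity, minSeg) {
  n <- length(code)
  half <- (window - 1L) %/% 2L
  counts <- matrix(0L, n, 3L)
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  for (s in 1:3) {
    cs <- c(0L, cumsum(!is.na(code) & code == s))
    counts[, s] <- cs[hi + 1L] - cs[lo]
  }
  mx <- max.col(counts, ties.method = "first")
  maxv <- counts[cbind(seq_len(n), mx)]
  prov <- mx
  prov[maxv == 0L] <- NA_integer_
  unresolved <- which(maxv == 0L |
                        rowSums(counts == maxv) > 1L & maxv > 0L)
  for (i in unresolved) {
    if (i > 1L && !is.na(prov[i - 1L]) &&
        (maxv[i] == 0L || counts[i, prov[i - 1L]] == maxv[i]))
      prov[i] <- prov[i - 1L]
    # else keep vectorized plurality (or NA for all-missing leading window)
  }
  if (anyNA(prov)) {
    nz <- which(!is.na(prov))
    if (!length(nz)) return(NULL)
    prov[seq_len(nz[1L] - 1L)] <- prov[nz[1L]]  # backfill leading
    for (i in which(is.na(prov))) prov[i] <- prov[i - 1L]
  }

  absorb <- function(r, bad) {
    k <- bad[1L]
    nr <- length(r$lengths)
    into <- if (k == 1L) 2L
      else if (k == nr) k - 1L
      else if (r$lengths[k + 1L] > r$lengths[k - 1L]) k + 1L
      else k - 1L  # ties -> left
    r$values[k] <- r$values[into]
    rle(inverse.rle(r))
  }
  r <- rle(prov)
  repeat {
    short <- which(r$lengths < minSeg)
    if (!length(short) || length(r$lengths) == 1L) break
    short <- short[order(r$lengths[short])][1L]  # shortest first, ties left
    r <- absorb(r, short)
  }
  # purity pass: fraction of raw calls supporting the run state
  repeat {
    if (length(r$lengths) == 1L) break
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    support <- vapply(seq_along(r$lengths), function(k) {
      cc <- code[starts[k]:ends[k]]
      c(sum(!is.na(cc) & cc == r$values[k]), sum(!is.na(cc)))
    }, integer(2L))
    frac <- ifelse(support[2L, ] == 0L, 1, support[1L, ] / support[2L, ])
    bad <- which(frac < purity)
    if (!length(bad)) break
    r <- absorb(r, bad)
  }
  # maximum-likelihood boundary refinement: place each cut where the raw
  # calls best split into left-state then right-state
  if (length(r$lengths) > 1L) {
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    newEnds <- ends
    for (k in seq_len(length(r$lengths) - 1L)) {
      lo <- starts[k]
      hi <- ends[k + 1L]
      cc <- code[lo:hi]
      isA <- cumsum(!is.na(cc) & cc == r$values[k])
      isB <- cumsum(!is.na(cc) & cc == r$values[k + 1L])
      cand <- seq_len(hi - lo)  # cut after lo+cand-1
      score <- isA[cand] + (isB[length(cc)] - isB[cand])
      best <- cand[score == max(score)]
      cur <- ends[k] - lo + 1L
      newEnds[k] <- lo + best[which.min(abs(best - cur))] - 1L
    }
    newEnds[-length(newEnds)] <- pmin(cummax(newEnds[-length(newEnds)]),
                                      n - 1L)
    lens <- diff(c(0L, newEnds[-length(newEnds)], n))
    r <- list(lengths = lens[lens > 0L],
              values = r$values[lens > 0L])
    r <- rle(inverse.rle(r))
  }
  # rescue pass: clean raw runs of a different state long enough to be
  # near-impossible under i.i.d. mis-calls are restored as segments
  rescueLen <- max(3L, minSeg - 2L)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segIdx <- list()
  for (k in seq_along(r$lengths)) {
    s <- starts[k]; e <- ends[k]; S <- r$values[k]
    rr <- rle(code[s:e])
    re <- cumsum(rr$lengths) + s - 1L
    rs <- re - rr$lengths + 1L
    keep <- !is.na(rr$values) & rr$values != S & rr$lengths >= rescueLen &
      (rs > s | s == 1L) & (re < e | e == n)
    pieces <- list()
    cursor <- s
    for (q in which(keep)) {
      if (rs[q] > cursor)
        pieces[[length(pieces) + 1L]] <- c(cursor, rs[q] - 1L, S)
      pieces[[length(pieces) + 1L]] <- c(rs[q], re[q], rr$values[q])
      cursor <- re[q] + 1L
    }
    if (cursor <= e)
      pieces[[length(pieces) + 1L]] <- c(cursor, e, S)
    segIdx <- c(segIdx, pieces)
  }
  m <- do.call(rbind, segIdx)
  # merge any adjacent pieces that ended up with the same state
  keepRow <- c(TRUE, m[-1L, 3L] != m[-nrow(m), 3L])
  starts <- m[keepRow, 1L]
  ends <- c(starts[-1L] - 1L, n)
  vals <- m[keepRow, 3L]
  r <- list(lengths = ends - starts + 1L, values = vals)
  nSupp <- vapply(seq_along(r$lengths), function(k) {
    cc <- code[starts[k]:ends[k]]
    sum(!is.na(cc) & cc == r$values[k])
  }, integer(1L))
  list(start = pos[starts], end = pos[ends], state = r$values,
       nMarkers = r$lengths, nSupporting = nSupp)
}

#' Call crossover events at segment boundaries
#'
#' Emits one crossover event per adjacent segment pair: the event interval
#' runs from the last marker of the left segment to the first marker of the
#' right segment, and the crossover position is the midpoint of that
#' interval. Direct parental-to-parental transitions (two crossovers inside
#' one marker gap) are flagged (`flagged = TRUE`), never silently emitted.
#'
#' @param segments data.frame from [segmentGenotypes()].
#' @return a [GenomicRanges::GRanges] of events with metadata columns
#'   `individual`, `midpoint`, `type`, `flagged`.
#' @export
callCrossovers <- function(segments) {
  req <- c("individual", "chrom", "start", "end", "state")
  stopifnot(all(req %in% names(segments)))
  if (nrow(segments) == 0)
    return(.emptyEvents())
  segments <- segments[order(segments$individual, segments$chrom,
                             segments$start), ]
  grp <- paste(segments$individual, segments$chrom)
  left <- which(grp[-nrow(segments)] == grp[-1])
  if (!length(left))
    return(.emptyEvents())
  right <- left + 1L
  sL <- segments$state[left]
  sR <- segments$state[right]
  if (any(sL == sR))
    stop("adjacent segments with identical state: segments are invalid")
  flagged <- sL != "H" & sR != "H"
  GenomicRanges::GRanges(
    segments$chrom[left],
    IRanges::IRanges(start = segments$end[left], end = segments$start[right]),
    individual = segments$individual[left],
    midpoint = (segments$end[left] + segments$start[right]) / 2,
    type = paste0(sL, "->", sR),
    flagged = flagged
  )
}

.emptyEvents <- function() {
  gr <- GenomicRanges::GRanges()
  mcols(gr) <- S4Vectors::DataFrame(
    individual = character(0), midpoint = numeric(0),
    type = character(0), flagged = logical(0)
  )
  gr
}

#' Remove all events of individuals with any ploidy change
#'
#' Crossover analyses include only individuals with no evidence of ploidy
#' change on any chromosome: a single monosomic, trisomic or arm-trisomic
#' call removes the individual's events genome-wide.
#'
#' @param events crossover `GRanges` from [callCrossovers()].
#' @param ploidyCalls data.frame from [callPloidy()]; must cover every
#'   individual present in `events`.
#' @return the filtered events `GRanges`.
#' @export
excludeAneuploids <- function(events, ploidyCalls) {
  stopifnot(all(c("individual", "chrom", "class") %in% names(ploidyCalls)))
  ids <- unique(mcols(events)$individual)
  missing <- setdiff(ids, unique(ploidyCalls$individual))
  if (length(missing))
    stop("no ploidy call for individual(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  bad <- ploidyCalls$class != "disomy"
  if ("call" %in% names(ploidyCalls))
    bad <- bad | ploidyCalls$call != "disomy"
  badIds <- unique(ploidyCalls$individual[bad])
  events[!(mcols(events)$individual %in% badIds)]
}
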