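#' Filter SNP genotype calls on quality and coverage
#'
#' Retains calls with mapping quality strictly above `minQual` and coverage
#' strictly above `minCov` (defaults ">100" and ">2.5x"); all other calls are
#' set to missing. The number of masked calls is reported with `message()`.
#' Filtering is idempotent.
#'
#' @param x a [GenotypeExperiment-class].
#' @param minQual minimum mapping quality (strict inequality).
#' @param minCov minimum coverage (strict inequality).
#' @return the filtered [GenotypeExperiment-class].
#' @export
filterSnps <- function(x, minQual = 100, minCov = 2.5) {
  stopifnot(is(x, "GenotypeExperiment"))
  if (nrow(x) == 0 || ncol(x) == 0) stop("empty genotype matrix")
  if (!is.finite(minQual) || !is.finite(minCov))
    stop("thresholds must be finite")
  g <- assay(x, "geno")
  keep <- assay(x, "qual") > minQual & assay(x, "cov") > minCov
  nMasked <- sum(!keep & !is.na(g))
  g[!keep] <- NA_character_
  SummarizedExperiment::assay(x, "geno") <- g
  message(nMasked, " genotype calls masked by quality/coverage filter")
  x
}

#' Exclude under-sequenced libraries
#'
#' Drops individuals whose number of SNP-associated reads is strictly below
#' `minReads` (default "<50,000 reads"). Retained individuals are unchanged.
#'
#' @param x a [GenotypeExperiment-class].
#' @param minReads minimum informative read count per library.
#' @return the filtered [GenotypeExperiment-class]; may have zero columns
#'   (with a warning).
#' @export
filterLibraries <- function(x, minReads = 5e4) {
  stopifnot(is(x, "GenotypeExperiment"))
  keep <- colData(x)$informativeReads >= minReads
  if (!any(keep))
    warning("all libraries below ", minReads, " informative reads")
  x[, keep]
}

# ---- genotype table TSV ----------------------------------------------------

.MISSING_TOKEN <- "."

#' Read and write genotype tables
#'
#' The on-disk format is a headered TSV with one row per individual-marker
#' pair: `individual`, `chrom`, `pos` (1-based), `genotype` (`P1`/`H`/`P2`,
#' `.` for missing), `qual`, `cov`, `lib_reads` (per-library informative read
#' count, repeated on every row of the library). Write-then-read round-trips
#' the object.
#'
#' @param path file path.
#' @return `readGenotypeTable` returns a [GenotypeExperiment-class].
#' @export
readGenotypeTable <- function(path) {
  df <- .read_tsv_checked(path, c("individual", "chrom", "pos", "genotype",
                                  "qual", "cov", "lib_reads"))
  for (col in c("pos", "qual", "cov", "lib_reads")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop("malformed ", col, " in ", path, " at line ", bad[1] + 1L)
    df[[col]] <- v
  }
  bad <- which(!(df$genotype %in% c(.GENO_STATES, .MISSING_TOKEN)))
  if (length(bad))
    stop("malformed genotype in ", path, " at line ", bad[1] + 1L)
  df$genotype[df$genotype == .MISSING_TOKEN] <- NA_character_

  mk <- unique(df[, c("chrom", "pos")])
  mk <- mk[order(mk$chrom, mk$pos), ]
  ids <- unique(df$individual)
  ri <- match(paste(df$chrom, df$pos), paste(mk$chrom, mk$pos))
  ci <- match(df$individual, ids)
  shape <- function(v, default) {
    m <- matrix(default, nrow = nrow(mk), ncol = length(ids),
                dimnames = list(NULL, ids))
    m[cbind(ri, ci)] <- v
    m
  }
  reads <- df$lib_reads[match(ids, df$individual)]
  genotypeExperiment(
    geno = shape(df$genotype, NA_character_),
    qual = shape(df$qual, NA_real_),
    cov = shape(df$cov, NA_real_),
    markers = GenomicRanges::GRanges(mk$chrom,
                                     IRanges::IRanges(mk$pos, width = 1L)),
    informativeReads = reads
  )
}

#' @rdname readGenotypeTable
#' @param x a [GenotypeExperiment-class].
#' @export
writeGenotypeTable <- function(x, path) {
  stopifnot(is(x, "GenotypeExperiment"))
  rr <- rowRanges(x)
  nM <- nrow(x); nI <- ncol(x)
  g <- assay(x, "geno")
  g[is.na(g)] <- .MISSING_TOKEN
  df <- data.frame(
    individual = rep(colnames(x), each = nM),
    chrom = rep(as.character(seqnames(rr)), nI),
    pos = rep(start(rr), nI),
    genotype = as.vector(g),
    qual = signif(as.vector(assay(x, "qual")), 6),
    cov = signif(as.vector(assay(x, "cov")), 6),
    lib_reads = rep(colData(x)$informativeReads, each = nM)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- marker map TSV --------------------------------------------------------

#' Read and write marker maps
#'
#' A marker map is a TSV with columns `chrom`, `pos` (1-based) and the two
#' parental alleles `allele_p1`, `allele_p2`. Positions must be strictly
#' increasing within a chromosome.
#'
#' @param path file path.
#' @return `readMarkerMap` returns a width-1 [GenomicRanges::GRanges] with
#'   `allele_p1`/`allele_p2` metadata columns.
#' @export
readMarkerMap <- function(path) {
  df <- .read_tsv_checked(path, c("chrom", "pos", "allele_p1", "allele_p2"))
  if (any(unlist(tapply(df$pos, df$chrom, function(p) diff(p) <= 0))))
    stop("marker positions must be strictly increasing within chromosomes")
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$pos, width = 1L),
                         allele_p1 = df$allele_p1, allele_p2 = df$allele_p2)
}

#' @rdname readMarkerMap
#' @param markers a width-1 `GRanges` with `allele_p1`/`allele_p2` columns.
#' @export
writeMarkerMap <- function(markers, path) {
  df <- data.frame(
    chrom = as.character(seqnames(markers)),
    pos = start(markers),
    allele_p1 = mcols(markers)$allele_p1,
    allele_p2 = mcols(markers)$allele_p2
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- crossover events BED --------------------------------------------------

#' Read and write crossover events as BED
#'
#' Crossover events are exported as BED3+ (0-based half-open): `chrom`,
#' `start`, `end` delimit the flanking-marker interval, followed by
#' `individual`, `midpoint` (bp), `type` (e.g. `P1->H`) and `flagged`
#' (0/1, direct parental-to-parental transitions). Internal coordinates are
#' 1-based inclusive, so internal position `p` becomes BED start `p - 1`.
#'
#' @param path file path.
#' @return `readCrossoverBed` returns a [GenomicRanges::GRanges] with
#'   `individual`, `midpoint`, `type`, `flagged` metadata columns.
#' @export
readCrossoverBed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "individual",
                                        "midpoint", "type", "flagged"))
  bad <- which(df$end < df$start)
  if (length(bad))
    stop("BED interval end < start at line ", bad[1])
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start + 1L, df$end),
                         individual = df$individual,
                         midpoint = df$midpoint,
                         type = df$type,
                         flagged = df$flagged == 1L)
}

#' @rdname readCrossoverBed
#' @param events a crossover `GRanges` as produced by [callCrossovers()].
#' @export
writeCrossoverBed <- function(events, path) {
  df <- data.frame(
    chrom = as.character(seqnames(events)),
    start = start(events) - 1L,
    end = end(events),
    individual = mcols(events)$individual,
    midpoint = signif(mcols(events)$midpoint, 10),
    type = mcols(events)$type,
    flagged = as.integer(mcols(events)$flagged)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- coverage track TSV ----------------------------------------------------

#' Read and write coverage tracks
#'
#' bedGraph-like headered TSV with columns `individual`, `chrom`, `start`
#' (0-based), `end`, `depth`; one row per window per individual.
#'
#' @param path file path.
#' @return `readCoverageTrack` returns a [CoverageExperiment-class].
#' @export
readCoverageTrack <- function(path) {
  df <- .read_tsv_checked(path, c("individual", "chrom", "start", "end",
                                  "depth"))
  bad <- which(df$end < df$start)
  if (length(bad))
    stop("coverage window end < start at line ", bad[1] + 1L)
  win <- unique(df[, c("chrom", "start", "end")])
  win <- win[order(win$chrom, win$start), ]
  ids <- unique(df$individual)
  ri <- match(paste(df$chrom, df$start), paste(win$chrom, win$start))
  ci <- match(df$individual, ids)
  depth <- matrix(NA_real_, nrow = nrow(win), ncol = length(ids),
                  dimnames = list(NULL, ids))
  depth[cbind(ri, ci)] <- df$depth
  coverageExperiment(depth,
    GenomicRanges::GRanges(win$chrom,
                           IRanges::IRanges(win$start + 1L, win$end)))
}

#' @rdname readCoverageTrack
#' @param x a [CoverageExperiment-class].
#' @export
writeCoverageTrack <- function(x, path) {
  stopifnot(is(x, "CoverageExperiment"))
  rr <- rowRanges(x)
  nW <- nrow(x); nI <- ncol(x)
  df <- data.frame(
    individual = rep(colnames(x), each = nW),
    chrom = rep(as.character(seqnames(rr)), nI),
    start = rep(start(rr) - 1L, nI),
    end = rep(end(rr), nI),
    depth = signif(as.vector(assay(x, "depth")), 6)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
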