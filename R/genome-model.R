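#' Construct a GenomeModel
#'
#' @param chromNames character vector of chromosome names.
#' @param chromLengths numeric vector of chromosome lengths in bp.
#' @param centromereMids numeric vector of centromere midpoints in bp.
#' @param pericentromere optional [GenomicRanges::GRanges] of pericentromere
#'   intervals (0-based start is not assumed; supply 1-based inclusive
#'   coordinates as for any `GRanges`).
#' @return a [GenomeModel-class] object.
#' @examples
#' gm <- genomeModel("chr1", 3e7, 1.5e7)
#' chromLengths(gm)
#' @export
genomeModel <- function(chromNames, chromLengths, centromereMids,
                        pericentromere = GenomicRanges::GRanges()) {
  new("GenomeModel",
    chromNames = as.character(chromNames),
    chromLengths = as.numeric(chromLengths),
    centromereMids = as.numeric(centromereMids),
    pericentromere = pericentromere
  )
}

#' @describeIn genomeModel A five-chromosome synthetic genome (20-30 Mb
#'   chromosomes with asymmetric centromeres and +/- 2 Mb pericentromere
#'   intervals), used as the default simulation genome. The proportions
#'   mimic a small plant genome; the coordinates are synthetic.
#' @export
syntheticGenomeModel <- function() {
  nm <- paste0("chr", 1:5)
  len <- c(30e6, 20e6, 23.5e6, 21e6, 27e6)
  cen <- c(15e6, 3.6e6, 13.8e6, 4e6, 11.2e6)
  peri <- GenomicRanges::GRanges(
    seqnames = nm,
    ranges = IRanges::IRanges(
      start = pmax(1, cen - 2e6),
      end = pmin(len, cen + 2e6)
    )
  )
  genomeModel(nm, len, cen, peri)
}

#' @rdname GenomeModel-class
#' @param x,object a `GenomeModel`.
#' @export
chromNames <- function(x) x@chromNames

#' @rdname GenomeModel-class
#' @export
chromLengths <- function(x) stats::setNames(x@chromLengths, x@chromNames)

#' @rdname GenomeModel-class
#' @export
centromereMids <- function(x) stats::setNames(x@centromereMids, x@chromNames)

#' @rdname GenomeModel-class
#' @export
pericentromere <- function(x) x@pericentromere

#' @rdname GenomeModel-class
#' @export
setMethod("show", "GenomeModel", function(object) {
  cat("GenomeModel with", length(object@chromNames), "chromosomes\n")
  cat("  total length:", sprintf("%.1f Mb", sum(object@chromLengths) / 1e6), "\n")
  cat("  pericentromere intervals:", length(object@pericentromere), "\n")
  invisible(NULL)
})

#' Read and write genome model tables
#'
#' The genome model is serialized as a TSV with columns `chrom`, `length`,
#' `centromere_mid`; pericentromere intervals travel in a separate BED3 file
#' (0-based half-open, as for every exported BED).
#'
#' @param path TSV path.
#' @param pericentromereBed optional BED3 path of pericentromere intervals.
#' @return `readGenomeModel` returns a [GenomeModel-class];
#'   `writeGenomeModel` returns `path` invisibly.
#' @export
readGenomeModel <- function(path, pericentromereBed = NULL) {
  df <- .read_tsv_checked(path, c("chrom", "length", "centromere_mid"))
  peri <- GenomicRanges::GRanges()
  if (!is.null(pericentromereBed)) {
    bed <- utils::read.table(pericentromereBed, sep = "\t", header = FALSE,
                             col.names = c("chrom", "start", "end"),
                             stringsAsFactors = FALSE)
    if (any(bed$end < bed$start))
      stop("pericentromere BED has end < start")
    peri <- GenomicRanges::GRanges(bed$chrom,
                                   IRanges::IRanges(bed$start + 1L, bed$end))
  }
  genomeModel(df$chrom, df$length, df$centromere_mid, peri)
}

#' @rdname readGenomeModel
#' @param genome a [GenomeModel-class].
#' @export
writeGenomeModel <- function(genome, path, pericentromereBed = NULL) {
  df <- data.frame(
    chrom = chromNames(genome),
    length = unname(chromLengths(genome)),
    centromere_mid = unname(centromereMids(genome))
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(pericentromereBed)) {
    pc <- pericentromere(genome)
    bed <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(pc)),
      start = GenomicRanges::start(pc) - 1L,
      end = GenomicRanges::end(pc)
    )
    utils::write.table(bed, pericentromereBed, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

# read a TSV and fail with a clear message if required columns are absent
.read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("file ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "))
  df
}
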