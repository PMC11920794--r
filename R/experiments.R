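#' Construct a GenotypeExperiment
#'
#' @param geno character matrix of calls (`"P1"`, `"H"`, `"P2"`, `NA`),
#'   markers in rows, individuals in columns.
#' @param qual,cov numeric matrices with the same dimensions as `geno`.
#' @param markers width-1 [GenomicRanges::GRanges] of marker positions, one
#'   per row of `geno`.
#' @param informativeReads numeric vector of SNP-associated read counts, one
#'   per individual (column).
#' @return a [GenotypeExperiment-class].
#' @examples
#' mk <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(100, 200), width = 1))
#' g <- matrix(c("P1", "H", "H", "P2"), nrow = 2,
#'             dimnames = list(NULL, c("ind1", "ind2")))
#' ge <- genotypeExperiment(g, qual = matrix(200, 2, 2), cov = matrix(5, 2, 2),
#'                          markers = mk, informativeReads = c(1e5, 1e5))
#' @export
genotypeExperiment <- function(geno, qual, cov, markers, informativeReads) {
  stopifnot(nrow(geno) == length(markers))
  if (is.null(colnames(geno)) && ncol(geno) > 0)
    colnames(geno) <- paste0("ind", seq_len(ncol(geno)))
  cd <- S4Vectors::DataFrame(informativeReads = as.numeric(informativeReads),
                             row.names = colnames(geno))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(geno = geno, qual = qual, cov = cov),
    rowRanges = markers, colData = cd
  )
  new("GenotypeExperiment", se)
}

#' Construct a CoverageExperiment
#'
#' @param depth numeric matrix of mean window depths, windows in rows,
#'   individuals in columns.
#' @param windows [GenomicRanges::GRanges] tiling the genome, one per row.
#' @return a [CoverageExperiment-class].
#' @export
coverageExperiment <- function(depth, windows) {
  stopifnot(nrow(depth) == length(windows))
  if (is.null(colnames(depth)))
    colnames(depth) <- paste0("ind", seq_len(ncol(depth)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(depth = depth), rowRanges = windows
  )
  new("CoverageExperiment", se)
}

#' @rdname GenotypeExperiment-class
#' @param object a `GenotypeExperiment`.
#' @export
setMethod("show", "GenotypeExperiment", function(object) {
  g <- assay(object, "geno")
  cat("GenotypeExperiment:", nrow(object), "markers x", ncol(object),
      "individuals\n")
  cat("  chromosomes:",
      paste(unique(as.character(seqnames(rowRanges(object)))), collapse = ", "),
      "\n")
  cat(sprintf("  missing calls: %.1f%%\n", 100 * mean(is.na(g))))
  invisible(NULL)
})

#' @rdname CoverageExperiment-class
#' @param object a `CoverageExperiment`.
#' @export
setMethod("show", "CoverageExperiment", function(object) {
  cat("CoverageExperiment:", nrow(object), "windows x", ncol(object),
      "individuals\n")
  invisible(NULL)
})

#' @rdname GenotypeExperiment-class
#' @param x a `GenotypeExperiment`.
#' @return `genoCalls` returns the character call matrix; `informativeReads`
#'   the per-library SNP-associated read counts.
#' @export
genoCalls <- function(x) assay(x, "geno")

#' @rdname GenotypeExperiment-class
#' @export
informativeReads <- function(x)
  stats::setNames(colData(x)$informativeReads, colnames(x))
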