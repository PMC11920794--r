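#' Construct fluorescent-seed counts
#'
#' @param nGreen green-only fluorescent seeds.
#' @param nRed red-only fluorescent seeds.
#' @param nTotal total seeds scored.
#' @return a [SeedCounts-class].
#' @examples
#' seedCounts(30, 30, 400)
#' @export
seedCounts <- function(nGreen, nRed, nTotal) {
  new("SeedCounts", nGreen = as.integer(nGreen), nRed = as.integer(nRed),
      nTotal = as.integer(nTotal))
}

#' @rdname SeedCounts-class
#' @param object a `SeedCounts`.
#' @export
setMethod("show", "SeedCounts", function(object) {
  cat(sprintf("SeedCounts: %d green-only + %d red-only of %d seeds\n",
              object@nGreen, object@nRed, object@nTotal))
  invisible(NULL)
})

#' Recombination frequency from fluorescent-seed counts
#'
#' Closed-form map-distance estimator for a seed-based fluorescent reporter
#' interval:
#' \deqn{RF = 100 (1 - \sqrt{1 - 2 (N_G + N_R) / N_T})}
#' where \eqn{N_G} and \eqn{N_R} are green-only and red-only seed counts and
#' \eqn{N_T} the total. Double-fluorescent and non-fluorescent seeds enter
#' only through \eqn{N_T}. The estimator is undefined when the
#' single-fluorescent fraction exceeds 1/2 (RF would exceed 50 cM), which is
#' an error, not a clamp.
#'
#' @param counts a [SeedCounts-class], or `nGreen` when the three counts are
#'   given separately.
#' @param nRed,nTotal optional scalar counts (with `counts` = nGreen).
#' @return map distance in centimorgans.
#' @examples
#' recombinationFrequency(seedCounts(30, 30, 400))  # 16.334 cM
#' @export
recombinationFrequency <- function(counts, nRed = NULL, nTotal = NULL) {
  if (!is(counts, "SeedCounts"))
    counts <- seedCounts(counts, nRed, nTotal)
  s <- 2 * (counts@nGreen + counts@nRed) / counts@nTotal
  if (s > 1)
    stop("estimator undefined (single-fluorescent fraction > 1/2)")
  100 * (1 - sqrt(1 - s))
}

#' Bootstrap confidence interval for the recombination frequency
#'
#' Percentile interval from multinomial resampling of the three seed
#' classes (green-only, red-only, remainder). Resamples whose
#' single-fluorescent fraction exceeds 1/2 are dropped.
#'
#' @param counts a [SeedCounts-class].
#' @param iters bootstrap iterations (values below 100 warn).
#' @param level confidence level (default 0.95).
#' @return numeric vector `c(low, high)` in centimorgans.
#' @export
rfBootstrapCi <- function(counts, iters = 1000, level = 0.95) {
  stopifnot(is(counts, "SeedCounts"))
  if (iters < 100) warning("fewer than 100 bootstrap iterations")
  p <- c(counts@nGreen, counts@nRed,
         counts@nTotal - counts@nGreen - counts@nRed) / counts@nTotal
  draws <- stats::rmultinom(iters, counts@nTotal, p)
  s <- 2 * (draws[1, ] + draws[2, ]) / counts@nTotal
  rf <- 100 * (1 - sqrt(1 - s[s <= 1]))
  a <- (1 - level) / 2
  stats::setNames(stats::quantile(rf, c(a, 1 - a), names = FALSE),
                  c("low", "high"))
}
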