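#' Fragment-length profile: histogram, median and modal peaks
#'
#' Summarizes a set of integer fragment lengths into the per-allele profile
#' reported for each sample: the raw histogram, the median, and the modal
#' peak(s). The median follows the usual order-statistic convention — for an
#' even count it is the mean of the two central values, so half-integer
#' medians such as 169.5 are possible. Peaks are all local maxima of the raw
#' histogram (over the filled integer support) whose count is at least
#' `peak_fraction` times the global maximum, reported in ascending length
#' order; this multi-peak rule lets dual-peak profiles such as 158/191 be
#' reported as two peaks rather than one arbitrary winner.
#'
#' No smoothing is applied by default; `smooth_window` (odd, in bp) applies a
#' moving average to the histogram before peak calling for noisy profiles.
#' The median is always computed on the raw lengths.
#'
#' @param lengths integer fragment lengths in bp (non-empty).
#' @param peak_fraction minimum peak height as a fraction of the tallest bin
#'   (default 0.8).
#' @param smooth_window moving-average window (odd integer >= 1; 1 = none).
#' @return A `length_profile` object: list with `histogram` (data.frame of
#'   `length`, `count` over observed lengths), `n`, `median`, `modes`.
#' @examples
#' p <- length_profile(c(rep(158, 100), rep(191, 100), 150, 170))
#' p$modes
#' @export
length_profile <- function(lengths, peak_fraction = 0.8, smooth_window = 1L) {
  lengths <- as.integer(lengths)
  lengths <- lengths[!is.na(lengths)]
  if (length(lengths) == 0L) stop("no fragments")
  stopifnot(peak_fraction > 0, peak_fraction <= 1,
            smooth_window >= 1L, smooth_window %% 2L == 1L)
  support <- seq(min(lengths), max(lengths))
  counts <- tabulate(lengths - min(lengths) + 1L, nbins = length(support))
  prof <- structure(list(
    histogram = data.frame(length = support[counts > 0L],
                           count = counts[counts > 0L]),
    n = length(lengths),
    median = stats::median(lengths),
    modes = find_modes(support, counts, peak_fraction, smooth_window)
  ), class = "length_profile")
  prof
}

# local maxima of the (optionally smoothed) histogram at >= frac * max;
# boundaries compare against an implicit zero bin outside the support
find_modes <- function(support, counts, frac, window) {
  x <- as.numeric(counts)
  if (window > 1L) {
    half <- (window - 1L) %/% 2L
    padded <- c(numeric(half), x, numeric(half))
    x <- vapply(seq_along(counts),
                function(i) mean(padded[i:(i + window - 1L)]), numeric(1))
  }
  left <- c(0, x[-length(x)])
  right <- c(x[-1L], 0)
  is_peak <- x > 0 & x >= left & x >= right & x >= frac * max(x)
  support[is_peak]
}

#' @export
print.length_profile <- function(x, ...) {
  cat("length_profile: n =", x$n,
      " median =", x$median,
      " modes =", paste(x$modes, collapse = "/"), "\n")
  invisible(x)
}

#' Mutant allele frequency from typed fragment counts
#'
#' `maf = n_mut / (n_mut + n_wt)`. Unresolved fragments are excluded from
#' both numerator and denominator.
#'
#' @param n_mut,n_wt mutant / wild typed fragment counts (non-negative).
#' @return The mutant allele fraction in \[0, 1\].
#' @examples
#' compute_maf(7475, 2525)  # 0.7475
#' @export
compute_maf <- function(n_mut, n_wt) {
  stopifnot(n_mut >= 0, n_wt >= 0)
  if (n_mut + n_wt == 0) stop("no typed fragments")
  n_mut / (n_mut + n_wt)
}

#' Bin a mutant allele frequency into the reporting strata
#'
#' Frequencies are stratified as low (0.1-1%), medium (1-10%) and high
#' (10-100%); anything below 0.1% is below the limit of detection. Bins are
#' half-open below and the top bin is closed at 1: the boundaries 0.001,
#' 0.01 and 0.10 map to low, medium and high respectively.
#'
#' @param maf numeric vector of fractions in \[0, 1\].
#' @return Factor with levels `below_lod`, `low`, `medium`, `high`.
#' @examples
#' bin_frequency(c(0.0005, 0.0022, 0.0457, 0.7475))
#' @export
bin_frequency <- function(maf) {
  stopifnot(all(maf >= 0 & maf <= 1))
  # half-open below; include.lowest closes the top bin at 1.0
  cut(maf, breaks = c(-Inf, 0.001, 0.01, 0.10, 1),
      labels = c("below_lod", "low", "medium", "high"),
      right = FALSE, include.lowest = TRUE)
}

#' Classify a sample's mutant fragment profile against its wild profile
#'
#' Compares the mutant and wild-type fragment-length profiles of one sample
#' and describes the mutant (ctDNA) population as `Short`, `Long`, `Normal`
#' or `Other`; samples with fewer than `min_support` mutant fragments are
#' `Insufficient`. With `d` the difference mutant median - wild median:
#' `d <= -delta` is Short, `d >= +delta` is Long; within `delta` of zero the
#' sample is Normal when the mutant profile has a single mode, and Other when
#' multiple mutant modes straddle the wild median (a bimodal mutant
#' population rather than a shifted one).
#'
#' The `delta` threshold (default 3 bp) and the rule itself are a pragmatic
#' reconstruction of the descriptive Short/Long/Normal/Other labels used for
#' patient samples; no formal definition exists, so the threshold is exposed.
#'
#' @param mut_profile,wt_profile `length_profile`s of mutant / wild
#'   fragments.
#' @param min_support minimum mutant fragment count (default 5).
#' @param delta median-difference threshold in bp (default 3).
#' @return One of `"Short"`, `"Long"`, `"Normal"`, `"Other"`,
#'   `"Insufficient"`.
#' @export
classify_sample <- function(mut_profile, wt_profile, min_support = 5L,
                            delta = 3) {
  stopifnot(inherits(mut_profile, "length_profile"),
            inherits(wt_profile, "length_profile"))
  if (mut_profile$n < min_support) return("Insufficient")
  d <- mut_profile$median - wt_profile$median
  if (d <= -delta) return("Short")
  if (d >= delta) return("Long")
  straddle <- length(mut_profile$modes) > 1L &&
    min(mut_profile$modes) < wt_profile$median &&
    max(mut_profile$modes) > wt_profile$median
  if (straddle) "Other" else "Normal"
}
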