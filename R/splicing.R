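#' Percent-spliced-in from junction count, coverage and intron size
#'
#' `PSI = ucount / (depth / size) = ucount * size / depth`: the junction
#' read count normalized by the average per-base read coverage of the
#' intron. Missing (NA) exactly when `depth` is zero. Scale-invariant in
#' (ucount, depth) and, by construction, not capped at 1.
#'
#' @param ucount uniquely mapped junction read count(s), >= 0.
#' @param depth summed per-base read depth over the intron, >= 0.
#' @param size intron length in bp, >= 1.
#' @return numeric PSI value(s); `NA` where depth is zero.
#' @examples
#' computePsi(10, 1000, 100)  # 1.0
#' computePsi(5, 0, 80)       # NA: no coverage, PSI undefined
#' @export
computePsi <- function(ucount, depth, size) {
  if (any(ucount < 0, na.rm = TRUE) || any(depth < 0, na.rm = TRUE))
    stop("ucount and depth must be nonnegative")
  if (any(size < 1, na.rm = TRUE)) stop("size must be >= 1")
  out <- ucount * size / depth
  out[depth == 0] <- NA_real_
  out
}

#' Select analyzable splicing traits
#'
#' An intron is retained as an s-trait when (a) it has at least
#' `min_junction` junction reads in at least `ceiling(min_sample_frac * n)`
#' samples, and (b) the standard error of its PSI across samples (sample
#' standard deviation over the square root of the non-missing count) is at
#' least `min_se`, so that invariant splicing events are dropped.
#'
#' @param splice a [SpliceQuant-class].
#' @param min_junction junction-read support threshold (default 5).
#' @param min_sample_frac required fraction of supported samples (default
#'   0.05).
#' @param min_se minimum PSI standard error (default 0.01).
#' @return character vector of retained intron ids.
#' @export
filterSTraits <- function(splice, min_junction = 5, min_sample_frac = 0.05,
                          min_se = 0.01) {
  uc <- ucounts(splice)
  p <- psi(splice)
  need <- ceiling(min_sample_frac * nrow(uc))
  supp <- colSums(uc >= min_junction) >= need
  se <- apply(p, 2, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) return(0)
    sd(x) / sqrt(length(x))
  })
  intronInfo(splice)$intron[supp & se >= min_se]
}
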