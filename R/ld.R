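#' Pairwise linkage disequilibrium r-squared
#'
#' Squared Pearson correlation of dosages over pairwise-complete samples.
#' Symmetric in its arguments and invariant to swapping the ref/alt coding
#' of either marker. A zero-variance marker yields `NA` with a warning.
#'
#' @param genotypes a [GenotypeData-class].
#' @param marker_a,marker_b marker ids (or column indices).
#' @return squared correlation in `[0, 1]`, or `NA`.
#' @export
ldR2 <- function(genotypes, marker_a, marker_b) {
  d <- dosages(genotypes)
  a <- d[, marker_a]; b <- d[, marker_b]
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2) stop("need at least 2 samples with complete data")
  if (sd(a[ok]) == 0 || sd(b[ok]) == 0) {
    warning("zero-variance marker: LD r2 undefined")
    return(NA_real_)
  }
  cor(a[ok], b[ok])^2
}

#' Greedy LD pruning within sliding windows
#'
#' Left-to-right scan per chromosome: a marker is retained unless its
#' squared correlation with an already-retained marker inside the trailing
#' window exceeds `r2_max`. Guarantees that no retained pair within a window
#' exceeds the threshold.
#'
#' @param genotypes a [GenotypeData-class].
#' @param r2_max LD ceiling for retained pairs (default 0.2).
#' @param window_bp window span in bp within which pairs are checked.
#' @return character vector of retained marker ids.
#' @export
ldPrune <- function(genotypes, r2_max = 0.2, window_bp = 1e6) {
  mk <- markerInfo(genotypes)
  d <- dosages(genotypes)
  keep <- logical(nrow(mk))
  for (cc in unique(mk$chrom)) {
    idx <- which(mk$chrom == cc)
    kept <- integer(0)
    for (j in idx) {
      inwin <- kept[mk$pos[kept] > mk$pos[j] - window_bp]
      ok <- TRUE
      x <- d[, j]
      if (sd(x, na.rm = TRUE) == 0) next
      for (k in inwin) {
        cc2 <- suppressWarnings(cor(x, d[, k], use = "pairwise.complete.obs"))
        if (!is.na(cc2) && cc2^2 > r2_max) { ok <- FALSE; break }
      }
      if (ok) kept <- c(kept, j)
    }
    keep[kept] <- TRUE
  }
  mk$id[keep]
}
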