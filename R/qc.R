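#' Marker-level quality filters
#'
#' Retains markers with minor-allele frequency at least `maf_min` and
#' heterozygous-call fraction at most `het_max`, both computed over
#' non-missing calls. The defaults reproduce the standard panel filters for
#' dense inbred-line SNP sets (MAF >= 0.05, het <= 0.02).
#'
#' @param genotypes a [GenotypeData-class].
#' @param maf_min minimum minor-allele frequency.
#' @param het_max maximum heterozygous call fraction.
#' @return A filtered [GenotypeData-class].
#' @export
filterMarkers <- function(genotypes, maf_min = 0.05, het_max = 0.02) {
  d <- dosages(genotypes)
  f <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  het <- colMeans(d == 1, na.rm = TRUE)
  het[is.nan(het)] <- 0
  keep <- !is.na(maf) & maf >= maf_min & het <= het_max
  if (!any(keep)) stop("all markers removed by filters")
  genotypes[, which(keep)]
}

#' Drop samples with excess heterozygous calls
#'
#' Samples whose heterozygous-call fraction (over non-missing calls) exceeds
#' `het_sample_max` are removed; their ids are reported in a message. In a
#' fully inbred panel heterozygosity beyond a few percent indicates
#' contamination.
#'
#' @param genotypes a [GenotypeData-class].
#' @param het_sample_max maximum tolerated per-sample heterozygosity.
#' @return A filtered [GenotypeData-class].
#' @export
filterHeterozygousSamples <- function(genotypes, het_sample_max = 0.20) {
  d <- dosages(genotypes)
  het <- rowMeans(d == 1, na.rm = TRUE)
  het[is.nan(het)] <- 0
  drop <- het > het_sample_max
  if (all(drop)) stop("all samples exceed the heterozygosity threshold")
  if (any(drop))
    message("dropping ", sum(drop), " sample(s) with > ",
            100 * het_sample_max, "% heterozygous calls: ",
            paste(rownames(d)[drop], collapse = ", "))
  genotypes[which(!drop), ]
}

#' Select robustly expressed genes
#'
#' Keeps genes with FPKM at least `fpkm_min` in at least
#' `ceiling(frac * n_samples)` samples; e.g. with 572 samples and
#' `frac = 0.80` the required count is 458.
#'
#' @param expression an [ExpressionData-class] or samples x genes matrix.
#' @param fpkm_min expression floor (FPKM units).
#' @param frac required fraction of samples at or above the floor.
#' @return character vector of retained gene ids.
#' @export
filterExpressedGenes <- function(expression, fpkm_min = 1, frac = 0.80) {
  x <- if (is(expression, "ExpressionData")) fpkm(expression) else expression
  need <- ceiling(frac * nrow(x))
  keep <- colSums(x >= fpkm_min) >= need
  colnames(x)[keep]
}
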