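## Mean-impute missing dosages per marker and drop zero-variance columns.
.imputedCentered <- function(d) {
  mu <- colMeans(d, na.rm = TRUE)
  for (j in which(colSums(is.na(d)) > 0)) d[is.na(d[, j]), j] <- mu[j]
  z <- sweep(d, 2, colMeans(d))
  v <- apply(z, 2, function(x) sum(x^2))
  z[, v > 0, drop = FALSE]
}

#' Centered-cross-product kinship matrix
#'
#' VanRaden-style centered relationship: dosages are mean-imputed per marker
#' (missing calls only), centered, and the kinship is `Z Z' / m` over the
#' `m` markers with nonzero variance. Symmetric and positive semi-definite
#' by construction. Typically computed on an LD-pruned marker set.
#'
#' @param genotypes a [GenotypeData-class].
#' @param markers optional marker ids to restrict to (e.g. from [ldPrune()]).
#' @return genotype x genotype numeric matrix.
#' @export
computeKinship <- function(genotypes, markers = NULL) {
  d <- dosages(genotypes)
  if (!is.null(markers)) d <- d[, markers, drop = FALSE]
  if (ncol(d) < 2) stop("need at least 2 markers")
  z <- .imputedCentered(d)
  K <- tcrossprod(z) / ncol(z)
  dimnames(K) <- list(rownames(d), rownames(d))
  K
}

#' Principal components of genetic variation
#'
#' Top-`k` eigenvectors of the centered-genotype covariance (via SVD of the
#' mean-imputed, centered dosage matrix), optionally on a random marker
#' subsample. Sign convention: each score column is flipped so its
#' largest-magnitude entry is positive.
#'
#' @param genotypes a [GenotypeData-class].
#' @param k number of components (default 5).
#' @param n_subsample optional number of randomly subsampled markers
#'   (seeded by `seed`); default uses all markers.
#' @param seed seed for the marker subsample.
#' @return samples x k matrix of PC scores with attribute `"varprop"`
#'   (variance proportions).
#' @export
computePCs <- function(genotypes, k = 5, n_subsample = NULL, seed = 1L) {
  d <- dosages(genotypes)
  if (!is.null(n_subsample) && n_subsample < ncol(d)) {
    set.seed(seed)
    d <- d[, sort(sample.int(ncol(d), n_subsample)), drop = FALSE]
  }
  z <- .imputedCentered(d)
  if (k >= min(dim(z))) stop("k must be smaller than the matrix rank")
  sv <- svd(z, nu = k, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k)
  for (j in seq_len(k)) {
    i <- which.max(abs(scores[, j]))
    if (scores[i, j] < 0) scores[, j] <- -scores[, j]
  }
  dimnames(scores) <- list(rownames(d), paste0("PC", seq_len(k)))
  attr(scores, "varprop") <- sv$d[seq_len(k)]^2 / sum(sv$d^2)
  scores
}
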