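#' Sample excess-free kurtosis (fourth standardized moment)
#'
#' Standard definition: `E[(x - mu)^4] / sd^4`, so a Gaussian has kurtosis 3.
#' @param x numeric vector.
#' @return kurtosis value.
#' @export
kurtosis <- function(x) {
  x <- x[!is.na(x)]
  m <- mean(x); s2 <- mean((x - m)^2)
  mean((x - m)^4) / s2^2
}

#' Select genes for ICA module discovery
#'
#' Keeps genes whose broad-sense heritability exceeds `h2_min` and whose
#' cross-sample expression standard deviation exceeds `sd_min` (FPKM scale
#' by default), removing unheritable and invariant genes before latent
#' component extraction.
#'
#' @param expression an [ExpressionData-class] (or samples x genes matrix).
#' @param h2 named per-gene H-squared vector.
#' @param h2_min heritability floor (default 0.05).
#' @param sd_min expression sd floor (default 1).
#' @return character vector of retained gene ids.
#' @export
selectIcaGenes <- function(expression, h2, h2_min = 0.05, sd_min = 1.0) {
  x <- if (is(expression, "ExpressionData")) fpkm(expression) else expression
  sds <- apply(x, 2, sd)
  keep <- colnames(x)[!is.na(h2[colnames(x)]) & h2[colnames(x)] > h2_min &
                        sds > sd_min]
  if (!length(keep)) stop("no genes pass the ICA selection filters")
  keep
}

#' Number of components explaining a variance target
#'
#' Smallest `k` such that the top-`k` squared singular values of the
#' per-gene-centered matrix account for at least `target` of the total.
#'
#' @param x genes x samples matrix (centered per gene internally).
#' @param target variance fraction (default 0.80).
#' @return integer component count.
#' @export
nComponentsForVariance <- function(x, target = 0.80) {
  xc <- x - rowMeans(x)
  d2 <- svd(xc, nu = 0, nv = 0)$d^2
  unname(which(cumsum(d2) / sum(d2) >= target)[1])
}

#' Fixed-point (FastICA) independent component analysis
#'
#' Whitened symmetric fixed-point ICA with the logcosh contrast
#' (`g = tanh`). Rows of `x` are observations (genes), columns variables
#' (samples): the decomposition is `x_centered ~ sources %*% t(mixing)`,
#' with `sources` the genes x components loading matrix and `mixing` the
#' samples x components coefficient matrix. Deterministic under `seed`;
#' each component's sign is fixed so its largest-magnitude gene loading is
#' positive. Per-component kurtosis of the sample coefficients is reported,
#' and non-convergence of the fixed-point iteration is flagged.
#'
#' @param x genes x samples numeric matrix.
#' @param n_components number of components (must not exceed the rank).
#' @param max_iter fixed-point iteration cap (default 500).
#' @param tol convergence tolerance on the rotation update (default 1e-4,
#'   the conventional fixed-point setting).
#' @param nonlinearity contrast function; only `"logcosh"` is implemented.
#' @param seed integer seed for the random initial rotation.
#' @return object of class `"ICADecomposition"`: list with `sources`
#'   (genes x k), `mixing` (samples x k), `kurtosis` (length k, of the
#'   sample coefficients), `converged` (logical), `iterations`.
#' @export
runIca <- function(x, n_components, max_iter = 500, tol = 1e-4,
                   nonlinearity = "logcosh", seed = 1L) {
  stopifnot(nonlinearity == "logcosh")
  x <- as.matrix(x)
  n <- nrow(x)
  xc <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(xc)
  rank <- sum(sv$d > sv$d[1] * 1e-10)
  if (n_components > rank) stop("n_components exceeds the matrix rank")
  k <- n_components
  Z <- sqrt(n) * sv$u[, seq_len(k), drop = FALSE]  # whitened, unit cov

  set.seed(seed)
  W <- matrix(rnorm(k * k), k, k)
  orth <- function(M) {
    e <- eigen(crossprod(M), symmetric = TRUE)
    M %*% (e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)), k) %*%
             t(e$vectors))
  }
  W <- orth(W)
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    S <- Z %*% W
    G <- tanh(S)
    Wn <- crossprod(Z, G) / n -
      sweep(W, 2, colMeans(1 - G^2), `*`)
    Wn <- orth(Wn)
    dv <- max(abs(abs(diag(crossprod(Wn, W))) - 1))
    W <- Wn
    if (dv < tol) { converged <- TRUE; break }
  }
  S <- Z %*% W                                   # genes x k loadings
  A <- t(W) %*% diag(sv$d[seq_len(k)], k) %*%
    t(sv$v[, seq_len(k), drop = FALSE]) / sqrt(n)  # k x samples
  mixing <- t(A)
  for (j in seq_len(k)) {
    i <- which.max(abs(S[, j]))
    if (S[i, j] < 0) { S[, j] <- -S[, j]; mixing[, j] <- -mixing[, j] }
  }
  rownames(S) <- rownames(x)
  rownames(mixing) <- colnames(x)
  colnames(S) <- colnames(mixing) <- paste0("IC", seq_len(k))
  structure(list(sources = S, mixing = mixing,
                 kurtosis = apply(mixing, 2, kurtosis),
                 converged = converged, iterations = it),
            class = "ICADecomposition")
}

#' @export
print.ICADecomposition <- function(x, ...) {
  cat("ICADecomposition:", ncol(x$sources), "components,",
      nrow(x$sources), "genes x", nrow(x$mixing), "samples\n")
  cat("  converged:", x$converged, "after", x$iterations, "iterations\n")
  cat(sprintf("  coefficient kurtosis: median %.2f, max %.2f\n",
              median(x$kurtosis), max(x$kurtosis)))
  invisible(x)
}

#' Filter independent components by cluster support and kurtosis
#'
#' Per component, the per-sample coefficients are split by 2-means
#' clustering; the component is retained only when both clusters hold more
#' than `cluster_min` samples (guards against components driven by a
#' handful of outlier samples) and the coefficient kurtosis exceeds
#' `kurtosis_min` (standard fourth-moment definition, Gaussian = 3, so the
#' default 6 is a strong non-Gaussianity requirement).
#'
#' @param decomp an `"ICADecomposition"` from [runIca()].
#' @param kurtosis_min kurtosis threshold (default 6).
#' @param cluster_min minimum samples per 2-means cluster (default 10).
#' @param seed seed for the k-means starts.
#' @return data.frame with `component`, `kurtosis`, `min_cluster`,
#'   `retained`, `reason`.
#' @export
filterComponents <- function(decomp, kurtosis_min = 6, cluster_min = 10,
                             seed = 1L) {
  set.seed(seed)
  M <- decomp$mixing
  rows <- lapply(seq_len(ncol(M)), function(j) {
    x <- M[, j]
    km <- kmeans(x, centers = 2, nstart = 5)
    mc <- min(table(km$cluster))
    kk <- decomp$kurtosis[j]
    reason <- if (mc <= cluster_min) "small-cluster"
      else if (kk <= kurtosis_min) "low-kurtosis" else "retained"
    data.frame(component = colnames(M)[j], kurtosis = kk,
               min_cluster = mc, retained = reason == "retained",
               reason = reason, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Assign gene module membership under each retained component
#'
#' Gene loadings of each component are robust-standardized
#' (`(x - median) / mad`), given two-sided normal p-values and
#' Benjamini-Hochberg corrected within the component; members are genes
#' with FDR at or below `fdr_max`.
#'
#' @param decomp an `"ICADecomposition"`.
#' @param components components to assign (default all); typically the
#'   retained set from [filterComponents()].
#' @param fdr_max membership FDR (default 0.01; 0.001 gives core members).
#' @return named list of character vectors of member genes.
#' @export
assignModuleMembership <- function(decomp, components = NULL,
                                   fdr_max = 0.01) {
  S <- decomp$sources
  if (is.null(components)) components <- colnames(S)
  out <- lapply(components, function(j) {
    s <- S[, j]
    md <- mad(s)
    if (md == 0) stop("MAD of loadings is zero for ", j)
    z <- (s - median(s)) / md
    p <- 2 * pnorm(-abs(z))
    fdr <- p.adjust(p, "BH")
    rownames(S)[fdr <= fdr_max]
  })
  names(out) <- components
  out
}

#' Genotype BLUPs and heritability of component coefficients
#'
#' One-way random-intercept fit of the per-sample coefficients on genotype;
#' returns the shrunken genotype means
#' \eqn{\hat\mu + \frac{\sigma^2_G}{\sigma^2_G + \sigma^2_E/n_i}(\bar y_i - \hat\mu)}
#' for every genotype (including unreplicated ones) and the component
#' H-squared from the same fit. With no replication at all, raw genotype
#' means are returned with a flag.
#'
#' @param coefficients named numeric vector (one value per sample).
#' @param replicate_map named character vector sample -> genotype.
#' @return list with `blup` (named by genotype), `H2`, `sigma_g2`,
#'   `sigma_e2`, `unreplicated` flag.
#' @export
blupIcCoefficients <- function(coefficients, replicate_map) {
  rmap <- replicate_map[names(coefficients)]
  ni <- table(rmap)
  ybar <- tapply(coefficients, rmap, mean)
  if (!any(ni >= 2) || length(ni[ni >= 2]) < 2) {
    return(list(blup = setNames(as.numeric(ybar), names(ybar)),
                H2 = NA_real_, sigma_g2 = NA_real_, sigma_e2 = NA_real_,
                unreplicated = TRUE))
  }
  sel <- rmap %in% names(ni)[ni >= 2]
  fit <- .remlOneWay(coefficients[sel], rmap[sel])
  shrink <- fit$sigma_g2 / (fit$sigma_g2 + fit$sigma_e2 / as.numeric(ni))
  if (fit$sigma_g2 + fit$sigma_e2 == 0) shrink <- rep(0, length(ni))
  blup <- fit$mu + shrink * (as.numeric(ybar) - fit$mu)
  list(blup = setNames(blup, names(ybar)), H2 = fit$H2,
       sigma_g2 = fit$sigma_g2, sigma_e2 = fit$sigma_e2,
       unreplicated = FALSE)
}

## p-values for one marker against every column of a trait matrix
.scanMarkerAllTraits <- function(g, Y, covariates = NULL) {
  ok <- !is.na(g)
  g <- g[ok]; Y <- Y[ok, , drop = FALSE]
  X <- cbind(rep(1, length(g)),
             if (!is.null(covariates)) covariates[ok, , drop = FALSE])
  qx <- qr(X)
  rg <- qr.resid(qx, g)
  ss <- sum(rg^2)
  if (ss <= 1e-12) return(rep(NA_real_, ncol(Y)))
  RY <- qr.resid(qx, Y)
  b <- colSums(RY * rg) / ss
  df <- length(g) - ncol(X) - 1
  rss <- colSums(RY^2) - b^2 * ss
  tt <- b / sqrt(rss / df / ss)
  2 * pt(-abs(tt), df)
}

#' e-trait enrichment of a component's GWAS peak
#'
#' Every SNP of the peak is tested against all genes at a relaxed threshold
#' (`relaxed_p`, default 1e-5) to define the peak's e-traits; a 2x2 Fisher
#' exact test then asks whether the component's member genes are enriched
#' among those e-traits. Significant enrichment (p <= 0.01 conventionally)
#' indicates the peak tends to regulate the genes of the module.
#'
#' @param module_genes character vector of module member genes (non-empty).
#' @param peak_markers marker ids of the peak's significant SNPs.
#' @param traits genotype x genes matrix of (transformed) expression.
#' @param genotypes a [GenotypeData-class].
#' @param covariates optional covariate matrix (rows = genotypes).
#' @param relaxed_p relaxed e-trait threshold (default 1e-5).
#' @return list with `p`, `odds_ratio`, `table` (2x2), `etraits`.
#' @export
icPeakEnrichment <- function(module_genes, peak_markers, traits, genotypes,
                             covariates = NULL, relaxed_p = 1e-5) {
  if (!length(module_genes)) stop("empty module")
  d <- dosages(genotypes)[rownames(traits), , drop = FALSE]
  pmin_all <- rep(Inf, ncol(traits))
  for (mm in peak_markers) {
    p <- .scanMarkerAllTraits(d[, mm], traits, covariates)
    pmin_all <- pmin(pmin_all, p, na.rm = TRUE)
  }
  etrait <- pmin_all <= relaxed_p
  inmod <- colnames(traits) %in% module_genes
  tab <- matrix(c(sum(inmod & etrait), sum(inmod & !etrait),
                  sum(!inmod & etrait), sum(!inmod & !etrait)), 2, 2,
                dimnames = list(c("etrait", "not_etrait"),
                                c("in_module", "not_in_module")))
  ft <- fisher.test(t(tab), alternative = "greater")
  list(p = ft$p.value, odds_ratio = unname(ft$estimate), table = tab,
       etraits = colnames(traits)[etrait])
}
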