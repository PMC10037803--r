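#' Genome-wide single-marker linear-model scan
#'
#' Per marker, ordinary least squares of the trait on alt-allele dosage plus
#' covariates (typically population-structure PCs), with a two-sided t-test
#' on the dosage coefficient. Computed by the Frisch-Waugh residualization
#' identity, so all markers without missing data are handled in one pass of
#' matrix algebra; markers with missing calls fall back to a per-marker fit
#' on pairwise-complete observations. P-values are invariant under affine
#' transformation of the trait.
#'
#' @param trait named numeric vector (names matching genotype sample ids);
#'   expression traits should be Box-Cox transformed upstream.
#' @param genotypes a [GenotypeData-class].
#' @param covariates optional samples x k numeric matrix (no intercept
#'   column; one is added).
#' @param min_obs minimum complete observations per marker (default 20).
#' @return data.frame with `marker`, `chrom`, `pos`, `beta`, `se`, `p`,
#'   `maf`, `n`. Zero-variance markers carry `NA` results.
#' @export
lmScan <- function(trait, genotypes, covariates = NULL, min_obs = 20) {
  d <- dosages(genotypes)
  if (!is.null(names(trait))) {
    keep <- intersect(rownames(d), names(trait)[!is.na(trait)])
    d <- d[keep, , drop = FALSE]
    y <- trait[keep]
    if (!is.null(covariates)) covariates <- covariates[keep, , drop = FALSE]
  } else y <- trait
  n <- length(y)
  X <- cbind(`(Intercept)` = rep(1, n), covariates)
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("collinear covariates")
  kc <- ncol(X)
  ry <- qr.resid(qx, y)
  syy <- sum(ry^2)

  m <- ncol(d)
  beta <- se <- p <- rep(NA_real_, m)
  nn <- rep(n, m)
  hasNA <- colSums(is.na(d)) > 0
  fr <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(fr, 1 - fr)

  if (any(!hasNA)) {
    G <- d[, !hasNA, drop = FALSE]
    RG <- qr.resid(qx, G)
    ss <- colSums(RG^2)
    ok <- ss > 1e-12
    bg <- rep(NA_real_, ncol(G))
    bg[ok] <- colSums(RG[, ok, drop = FALSE] * ry) / ss[ok]
    df <- n - kc - 1
    rss <- syy - bg^2 * ss
    s2 <- rss / df
    seg <- sqrt(s2 / ss)
    tt <- bg / seg
    idx <- which(!hasNA)
    beta[idx] <- bg
    se[idx] <- seg
    p[idx][ok] <- 2 * pt(-abs(tt[ok]), df)
  }
  for (j in which(hasNA)) {
    g <- d[, j]
    okr <- !is.na(g)
    if (sum(okr) < min_obs) next
    Xs <- X[okr, , drop = FALSE]
    qs <- qr(Xs)
    rg <- qr.resid(qs, g[okr])
    ssj <- sum(rg^2)
    if (ssj <= 1e-12) next
    ryj <- qr.resid(qs, y[okr])
    b <- sum(rg * ryj) / ssj
    dfj <- sum(okr) - kc - 1
    s2j <- (sum(ryj^2) - b^2 * ssj) / dfj
    beta[j] <- b
    se[j] <- sqrt(s2j / ssj)
    p[j] <- 2 * pt(-abs(b / se[j]), dfj)
    nn[j] <- sum(okr)
  }
  mk <- markerInfo(genotypes)
  data.frame(marker = mk$id, chrom = mk$chrom, pos = mk$pos,
             beta = beta, se = se, p = p, maf = maf, n = nn,
             stringsAsFactors = FALSE)
}

#' Kinship-aware mixed-model scan
#'
#' Single-random-effect linear mixed model \eqn{y = X\beta + g\gamma + u + e}
#' with \eqn{u \sim N(0, \sigma^2_g K)}. The variance ratio is estimated once
#' per trait under the null (no marker) by maximum likelihood on the spectral
#' decomposition of the kinship matrix; each marker is then tested by a
#' generalized-least-squares Wald test in the whitened coordinates.
#'
#' @param trait named numeric vector (e.g. log-transformed phenotype).
#' @param genotypes a [GenotypeData-class].
#' @param kinship genotype x genotype PSD matrix (see [computeKinship()]).
#' @param covariates optional samples x k matrix.
#' @param delta optional fixed variance ratio \eqn{\sigma^2_e/\sigma^2_g};
#'   estimated by maximum likelihood when `NULL`.
#' @return data.frame as in [lmScan()], plus attribute `"delta"` (the fitted
#'   ratio \eqn{\sigma^2_e/\sigma^2_g}).
#' @export
lmmScan <- function(trait, genotypes, kinship, covariates = NULL,
                    delta = NULL) {
  d <- dosages(genotypes)
  keep <- if (!is.null(names(trait)))
    intersect(rownames(d), names(trait)[!is.na(trait)]) else rownames(d)
  d <- d[keep, , drop = FALSE]
  y <- trait[keep]
  K <- kinship[keep, keep]
  if (!is.null(covariates)) covariates <- covariates[keep, , drop = FALSE]
  n <- length(y)
  ee <- eigen(K, symmetric = TRUE)
  if (min(ee$values) < -1e-6 * max(abs(ee$values)))
    stop("kinship matrix is not positive semi-definite")
  lam <- pmax(ee$values, 0)
  U <- ee$vectors
  ys <- drop(crossprod(U, y))
  X <- cbind(`(Intercept)` = rep(1, n), covariates)
  Xs <- crossprod(U, X)

  negll <- function(logdelta) {
    v <- lam + exp(logdelta)
    w <- 1 / v
    Xw <- Xs * sqrt(w); yw <- ys * sqrt(w)
    fit <- qr(Xw)
    r <- qr.resid(fit, yw)
    s2 <- sum(r^2) / n
    0.5 * (n * log(s2) + sum(log(v)) + n)
  }
  if (is.null(delta)) {
    opt <- optimize(negll, c(-12, 12))
    delta <- exp(opt$minimum)
  }

  v <- lam + delta
  sw <- 1 / sqrt(v)
  Xw <- Xs * sw; yw <- ys * sw
  qx <- qr(Xw)
  kc <- ncol(Xw)
  ryw <- qr.resid(qx, yw)
  syy <- sum(ryw^2)
  Gw <- (crossprod(U, d)) * sw
  RG <- qr.resid(qx, Gw)
  ss <- colSums(RG^2)
  ok <- ss > 1e-12
  beta <- se <- p <- rep(NA_real_, ncol(d))
  bg <- colSums(RG * ryw) / ifelse(ok, ss, NA)
  df <- n - kc - 1
  s2 <- (syy - bg^2 * ss) / df
  seg <- sqrt(s2 / ss)
  beta[ok] <- bg[ok]; se[ok] <- seg[ok]
  p[ok] <- 2 * pt(-abs(bg[ok] / seg[ok]), df)
  fr <- colMeans(d) / 2
  mk <- markerInfo(genotypes)
  out <- data.frame(marker = mk$id, chrom = mk$chrom, pos = mk$pos,
                    beta = beta, se = se, p = p, maf = pmin(fr, 1 - fr),
                    n = n, stringsAsFactors = FALSE)
  attr(out, "delta") <- delta
  out
}

#' Bonferroni-corrected per-test significance threshold
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param n_tests number of tests (e.g. number of markers).
#' @return list with `p` (= alpha / n_tests) and `neglog10`.
#' @examples
#' bonferroniThreshold(0.05, 12191984)  # p ~ 4.1e-9, -log10 ~ 8.39
#' @export
bonferroniThreshold <- function(alpha = 0.05, n_tests) {
  stopifnot(n_tests >= 1)
  p <- alpha / n_tests
  list(p = p, neglog10 = -log10(p))
}

#' Consolidate significant markers into QTL peaks
#'
#' Per chromosome, consecutive significant markers separated by less than
#' `gap_max` bp merge into one peak; peaks with fewer than `min_snps`
#' members are discarded. The lead marker is the member with the smallest
#' p-value (ties broken by smaller position). Idempotent: re-grouping the
#' leads leaves the peaks unchanged, and retained peaks are pairwise
#' separated by at least `gap_max`.
#'
#' @param sig data.frame of significant markers with columns `marker`,
#'   `chrom`, `pos`, `p` (and optionally `beta`, `maf`).
#' @param gap_max merge distance in bp (default 1 Mb).
#' @param min_snps minimum member support (default 3).
#' @return data.frame with `chrom`, `start`, `end`, `lead_id`, `lead_pos`,
#'   `lead_p`, `n_snps` (plus `lead_beta`, `lead_maf` when available) and a
#'   `members` list-column of member marker ids.
#' @export
groupPeaks <- function(sig, gap_max = 1e6, min_snps = 3) {
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), lead_id = character(),
                      lead_pos = integer(), lead_p = numeric(),
                      n_snps = integer(), stringsAsFactors = FALSE)
  if (is.null(sig) || !nrow(sig)) return(empty)
  sig <- sig[order(sig$chrom, sig$pos), , drop = FALSE]
  out <- list()
  for (cc in unique(sig$chrom)) {
    s <- sig[sig$chrom == cc, , drop = FALSE]
    grp <- cumsum(c(1, diff(s$pos) >= gap_max))
    for (gg in unique(grp)) {
      ss <- s[grp == gg, , drop = FALSE]
      if (nrow(ss) < min_snps) next
      lead <- ss[order(ss$p, ss$pos), ][1, ]
      row <- data.frame(chrom = cc, start = min(ss$pos), end = max(ss$pos),
                        lead_id = lead$marker, lead_pos = lead$pos,
                        lead_p = lead$p, n_snps = nrow(ss),
                        stringsAsFactors = FALSE)
      if (!is.null(ss$beta)) row$lead_beta <- lead$beta
      if (!is.null(ss$maf)) row$lead_maf <- lead$maf
      row$members <- I(list(ss$marker))
      out[[length(out) + 1]] <- row
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify peaks of one e-trait as cis or trans
#'
#' A peak is cis when its lead marker lies within `window` bp of the gene
#' span (from `min(TSS, TES) - window` to `max(TSS, TES) + window`) on the
#' gene's chromosome, otherwise trans. When several peaks of one trait fall
#' in the cis window, only the one with the smallest lead p-value keeps the
#' cis label (at most one cis-QTL per trait by construction); the others are
#' relabeled trans.
#'
#' @param peaks data.frame from [groupPeaks()] for one trait.
#' @param gene one row of a gene-model data.frame (`gene`, `chrom`, `start`,
#'   `end`, `strand`).
#' @param window cis window in bp (default 1 Mb).
#' @return `peaks` with a `class` column (`"cis"`/`"trans"`).
#' @export
classifyCisTrans <- function(peaks, gene, window = 1e6) {
  if (is.null(gene) || !nrow(gene)) stop("unknown gene")
  if (!nrow(peaks)) { peaks$class <- character(0); return(peaks) }
  lo <- min(gene$start, gene$end) - window
  hi <- max(gene$start, gene$end) + window
  cis <- peaks$chrom == gene$chrom & peaks$lead_pos >= lo &
    peaks$lead_pos <= hi
  peaks$class <- ifelse(cis, "cis", "trans")
  ci <- which(cis)
  if (length(ci) > 1) {
    best <- ci[order(peaks$lead_p[ci], peaks$lead_pos[ci])][1]
    peaks$class[setdiff(ci, best)] <- "trans"
  }
  peaks
}

#' Variance explained by detected QTL peaks
#'
#' Joint OLS of the (transformed) trait on all lead-SNP dosages gives the
#' cumulative PVE (model R-squared); each peak's own PVE is the marginal
#' R-squared of its lead alone. Being computed in-sample, these values are
#' upwardly biased relative to what the same QTL would explain in
#' independent data. Collinear leads are dropped to an independent subset
#' and flagged.
#'
#' @param trait named numeric vector.
#' @param genotypes a [GenotypeData-class].
#' @param peaks data.frame with a `lead_id` column (>= 1 row).
#' @return list with `cumulative` (R-squared of the joint fit), `per_peak`
#'   (named marginal R-squared per lead), `dropped` (collinear leads
#'   removed from the joint fit).
#' @export
computePve <- function(trait, genotypes, peaks) {
  stopifnot(nrow(peaks) >= 1)
  d <- dosages(genotypes)
  keep <- if (!is.null(names(trait))) intersect(rownames(d), names(trait))
    else rownames(d)
  y <- trait[keep]
  G <- d[keep, peaks$lead_id, drop = FALSE]
  marg <- apply(G, 2, function(g) {
    ok <- !is.na(g) & !is.na(y)
    if (sd(g[ok]) == 0) return(0)
    cor(g[ok], y[ok])^2
  })
  X <- cbind(1, G)
  X[is.na(X)] <- 0
  qx <- qr(X)
  dropped <- character(0)
  if (qx$rank < ncol(X)) {
    used <- qx$pivot[seq_len(qx$rank)]
    dropped <- colnames(X)[setdiff(seq_len(ncol(X))[-1], used)]
    X <- X[, used, drop = FALSE]
    qx <- qr(X)
  }
  r <- qr.resid(qx, y)
  r2 <- 1 - sum(r^2) / sum((y - mean(y))^2)
  list(cumulative = r2, per_peak = marg, dropped = dropped)
}

#' Permutation-based genome-wide significance threshold
#'
#' For each permutation, the sample labels of the genotype matrix are
#' shuffled while trait and covariate labels stay fixed, the full scan is
#' re-run, and the per-trait minimum p-value is recorded. The threshold is
#' the `quantile` (default 95th) percentile of the pooled
#' `-log10(min p)` distribution over traits and permutations.
#'
#' @param traits genotype x traits matrix of (transformed) trait values.
#' @param genotypes a [GenotypeData-class].
#' @param covariates optional covariate matrix (rows = genotypes).
#' @param n_perm number of permutations (default 100).
#' @param quantile_level percentile of the null distribution (default 0.95).
#' @param seed integer seed for the label shuffles.
#' @return list with `min_p` (traits x permutations matrix),
#'   `threshold_neglog10` and `threshold_p`.
#' @export
permutationThreshold <- function(traits, genotypes, covariates = NULL,
                                 n_perm = 100, quantile_level = 0.95,
                                 seed = 1L) {
  stopifnot(n_perm >= 1)
  set.seed(seed)
  d0 <- dosages(genotypes)
  mk <- markerInfo(genotypes)
  n <- nrow(d0)
  traits <- as.matrix(traits)
  minp <- matrix(NA_real_, ncol(traits), n_perm,
                 dimnames = list(colnames(traits), NULL))
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n)
    dp <- d0[perm, , drop = FALSE]
    rownames(dp) <- rownames(d0)
    gp <- GenotypeData(dp, mk)
    for (j in seq_len(ncol(traits))) {
      y <- setNames(traits[, j], rownames(traits))
      sc <- lmScan(y, gp, covariates = covariates)
      minp[j, b] <- min(sc$p, na.rm = TRUE)
    }
  }
  thr <- as.numeric(quantile(-log10(minp), quantile_level, na.rm = TRUE))
  list(min_p = minp, threshold_neglog10 = thr, threshold_p = 10^(-thr))
}

#' Map QTL for a matrix of traits
#'
#' Drives the full per-trait pipeline: linear scan ([lmScan()] or
#' [lmmScan()]), significance thresholding, optional effect-size filter
#' (sQTL mode: `|beta| >= min_beta`), peak consolidation ([groupPeaks()])
#' and cis/trans classification ([classifyCisTrans()]) when the trait maps
#' to a gene model. Traits yielding more than `max_peaks` peaks are excluded
#' (reported in attribute `"excluded"`). Per-peak and cumulative PVE are
#' attached.
#'
#' @param traits genotype x traits matrix (pre-transformed: Box-Cox for
#'   expression, PSI as-is).
#' @param genotypes a [GenotypeData-class].
#' @param covariates optional covariate matrix.
#' @param threshold significance threshold on the p scale.
#' @param geneModels optional gene-model data.frame; traits whose name
#'   matches a `gene` (or whose host gene is given via `trait_gene`) get
#'   cis/trans labels.
#' @param trait_gene optional named character vector trait -> gene id (for
#'   s-traits hosted in a gene).
#' @param max_peaks per-trait peak cap (default 10).
#' @param min_beta optional absolute effect-size floor (sQTL mode uses 0.05).
#' @param gap_max,min_snps passed to [groupPeaks()].
#' @param cis_window passed to [classifyCisTrans()].
#' @param model `"lm"` or `"lmm"`.
#' @param kinship required when `model = "lmm"`.
#' @return data.frame of peaks (`trait`, `chrom`, `start`, `end`, `lead_id`,
#'   `lead_pos`, `lead_p`, `n_snps`, `class`, `pve`, `cum_pve`, `lead_beta`,
#'   `lead_maf`), with attribute `"excluded"` naming dropped traits.
#' @export
mapQtl <- function(traits, genotypes, covariates = NULL, threshold,
                   geneModels = NULL, trait_gene = NULL, max_peaks = 10,
                   min_beta = NULL, gap_max = 1e6, min_snps = 3,
                   cis_window = 1e6, model = c("lm", "lmm"),
                   kinship = NULL) {
  model <- match.arg(model)
  traits <- as.matrix(traits)
  excluded <- character(0)
  res <- list()
  for (tn in colnames(traits)) {
    y <- setNames(traits[, tn], rownames(traits))
    if (all(is.na(y))) next
    scan <- if (model == "lm") lmScan(y, genotypes, covariates)
      else lmmScan(y, genotypes, kinship, covariates)
    sig <- scan[!is.na(scan$p) & scan$p <= threshold, , drop = FALSE]
    if (!is.null(min_beta))
      sig <- sig[abs(sig$beta) >= min_beta, , drop = FALSE]
    pk <- groupPeaks(sig, gap_max = gap_max, min_snps = min_snps)
    if (!nrow(pk)) next
    if (nrow(pk) > max_peaks) { excluded <- c(excluded, tn); next }
    gid <- if (!is.null(trait_gene)) trait_gene[tn] else tn
    if (!is.null(geneModels) && !is.na(gid) && gid %in% geneModels$gene) {
      pk <- classifyCisTrans(pk, geneModels[geneModels$gene == gid, ],
                             window = cis_window)
    } else pk$class <- NA_character_
    pv <- computePve(y, genotypes, pk)
    pk$pve <- unname(pv$per_peak[pk$lead_id])
    pk$cum_pve <- pv$cumulative
    pk$trait <- tn
    res[[tn]] <- pk
  }
  if (!length(res)) {
    out <- data.frame(trait = character(), chrom = character(),
                      start = integer(), end = integer(),
                      lead_id = character(), lead_pos = integer(),
                      lead_p = numeric(), n_snps = integer(),
                      class = character(), pve = numeric(),
                      cum_pve = numeric())
    attr(out, "excluded") <- excluded
    return(out)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  first <- c("trait", "chrom", "start", "end", "lead_id", "lead_pos",
             "lead_p", "n_snps", "class", "pve", "cum_pve")
  out <- out[, c(first, setdiff(names(out), first))]
  attr(out, "excluded") <- excluded
  out
}

#' Candidate genes for an organismal trait
#'
#' A gene is a candidate when (a) a trait-associated SNP, or any SNP in LD
#' `r2 > ld_min` with one, lies within `dist` bp of the gene span
#' (evidence `"proximity"` / `"LD"`), or (b) an eQTL lead SNP for the gene
#' is itself in the trait-associated set or in LD `r2 > ld_min` with a
#' trait-associated SNP (evidence `"eQTL-overlap"`).
#'
#' @param trait_snps data.frame of trait-associated SNPs (`marker`, `chrom`,
#'   `pos`).
#' @param geneModels gene-model data.frame.
#' @param eqtl optional eQTL peak table from [mapQtl()] (uses `trait` as the
#'   gene id and `lead_id`).
#' @param genotypes a [GenotypeData-class] (for LD lookups).
#' @param dist proximity window in bp (default 50 kb).
#' @param ld_min LD proxy threshold (default 0.8).
#' @param ld_search_bp how far from a trait SNP LD proxies are sought
#'   (default 1 Mb).
#' @return data.frame `gene`, `evidence`.
#' @export
candidateGenesForTrait <- function(trait_snps, geneModels, eqtl = NULL,
                                   genotypes, dist = 5e4, ld_min = 0.8,
                                   ld_search_bp = 1e6) {
  if (is.null(trait_snps) || !nrow(trait_snps))
    return(data.frame(gene = character(), evidence = character()))
  d <- dosages(genotypes)
  mk <- markerInfo(genotypes)
  ## expand the trait-associated set with LD proxies in a local window
  proxy <- character(0)
  for (i in seq_len(nrow(trait_snps))) {
    cand <- which(mk$chrom == trait_snps$chrom[i] &
                    abs(mk$pos - trait_snps$pos[i]) <= ld_search_bp)
    x <- d[, trait_snps$marker[i]]
    for (j in cand) {
      if (mk$id[j] %in% trait_snps$marker) next
      r2 <- suppressWarnings(cor(x, d[, j], use = "pairwise.complete.obs"))^2
      if (!is.na(r2) && r2 > ld_min) proxy <- c(proxy, mk$id[j])
    }
  }
  hit <- function(ids) {
    pos <- mk[match(ids, mk$id), ]
    vapply(seq_len(nrow(geneModels)), function(gi) {
      gm <- geneModels[gi, ]
      any(pos$chrom == gm$chrom & pos$pos >= gm$start - dist &
            pos$pos <= gm$end + dist)
    }, logical(1))
  }
  prox <- hit(trait_snps$marker)
  ldh <- if (length(proxy)) hit(proxy) else rep(FALSE, nrow(geneModels))
  out <- data.frame(gene = geneModels$gene,
                    evidence = ifelse(prox, "proximity",
                                      ifelse(ldh, "LD", NA_character_)),
                    stringsAsFactors = FALSE)
  if (!is.null(eqtl) && nrow(eqtl)) {
    tset <- union(trait_snps$marker, proxy)
    for (gi in unique(eqtl$trait)) {
      leads <- eqtl$lead_id[eqtl$trait == gi]
      if (any(leads %in% tset)) {
        row <- match(gi, out$gene)
        if (!is.na(row) && is.na(out$evidence[row]))
          out$evidence[row] <- "eQTL-overlap"
      }
    }
  }
  out[!is.na(out$evidence), , drop = FALSE]
}
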