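#' Interpolate genetic-map position
#'
#' Piecewise-linear interpolation of centimorgan position between flanking
#' anchors, assuming a uniform recombination rate between mapped markers.
#' Queries outside the anchor range are extrapolated with the nearest
#' interval's rate and flagged via the `"extrapolated"` attribute.
#'
#' @param map data.frame with columns `chrom`, `bp`, `cM` (cM nondecreasing
#'   in bp within each chromosome).
#' @param chrom chromosome.
#' @param bp query position(s) in bp.
#' @return numeric cM position(s), attribute `"extrapolated"` logical.
#' @export
interpolateGeneticMap <- function(map, chrom, bp) {
  m <- map[map$chrom == chrom, ]
  if (!nrow(m)) stop("chromosome absent from genetic map: ", chrom)
  m <- m[order(m$bp), ]
  if (is.unsorted(m$cM)) stop("cM must be nondecreasing within chromosome")
  out <- numeric(length(bp))
  extra <- bp < min(m$bp) | bp > max(m$bp)
  if (nrow(m) == 1) {
    out[] <- m$cM
  } else {
    inside <- !extra
    out[inside] <- approx(m$bp, m$cM, xout = bp[inside], ties = "ordered")$y
    rate_lo <- (m$cM[2] - m$cM[1]) / (m$bp[2] - m$bp[1])
    k <- nrow(m)
    rate_hi <- (m$cM[k] - m$cM[k - 1]) / (m$bp[k] - m$bp[k - 1])
    lo <- bp < m$bp[1]; hi <- bp > m$bp[k]
    out[lo] <- m$cM[1] + rate_lo * (bp[lo] - m$bp[1])
    out[hi] <- m$cM[k] + rate_hi * (bp[hi] - m$bp[k])
  }
  attr(out, "extrapolated") <- extra
  out
}

## Haploid allele frequencies and counts per population; het calls excluded.
.popFreqs <- function(genotypes, labels = NULL) {
  d <- dosages(genotypes)
  if (is.null(labels)) labels <- subpopLabels(genotypes)
  labels <- labels[rownames(d)]
  pops <- unique(labels)  # first-appearance order: first label = reference
  if (length(pops) < 2) stop("need two populations")
  al <- d / 2
  al[d == 1] <- NA  # residual heterozygotes carry no haploid allele
  lapply(setNames(pops, pops), function(pp) {
    a <- al[labels == pp, , drop = FALSE]
    list(n = colSums(!is.na(a)), p = colMeans(a, na.rm = TRUE))
  })
}

## Weir-Cockerham per-site variance components for two haploid samples.
## Returns a (among) and b (within); theta = a / (a + b).
.wcComponents <- function(n1, p1, n2, p2) {
  r <- 2
  nT <- n1 + n2
  nc <- (nT - (n1^2 + n2^2) / nT) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / nT
  msp <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / (r - 1)
  msg <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (nT - r)
  list(a = (msp - msg) / nc, b = msg)
}

## 100-kb/10-kb sliding window grid over the observed marker range.
.slidingWindows <- function(mk, window_bp, step_bp) {
  out <- list()
  for (cc in unique(mk$chrom)) {
    pos <- mk$pos[mk$chrom == cc]
    starts <- seq(1, max(pos), by = step_bp)
    out[[cc]] <- data.frame(chrom = cc, start = starts,
                            end = starts + window_bp - 1,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Sliding-window Weir-Cockerham Fst between two populations
#'
#' Per-site Weir-Cockerham variance components with inbred lines treated as
#' haploid allele samples; the window value is the weighted
#' (ratio-of-sums) estimator `sum(a) / sum(a + b)` over member SNPs.
#' Windows containing no SNPs are omitted. Invariant under sample
#' reordering and ref/alt allele flips.
#'
#' @param genotypes a [GenotypeData-class] with two subpopulation labels
#'   (or `labels` supplied).
#' @param labels optional named sample -> population vector.
#' @param window_bp,step_bp window geometry (defaults 100 kb / 10 kb).
#' @return data.frame `chrom`, `start`, `end`, `n_snps`, `fst`.
#' @export
windowedFst <- function(genotypes, labels = NULL, window_bp = 1e5,
                        step_bp = 1e4) {
  pf <- .popFreqs(genotypes, labels)
  if (length(pf) != 2) stop("windowedFst requires exactly two populations")
  if (any(pf[[1]]$n < 2) || any(pf[[2]]$n < 2))
    stop("both populations need >= 2 called lines per site")
  wc <- .wcComponents(pf[[1]]$n, pf[[1]]$p, pf[[2]]$n, pf[[2]]$p)
  mk <- markerInfo(genotypes)
  win <- .slidingWindows(mk, window_bp, step_bp)
  rows <- lapply(seq_len(nrow(win)), function(i) {
    sel <- mk$chrom == win$chrom[i] & mk$pos >= win$start[i] &
      mk$pos <= win$end[i]
    if (!any(sel)) return(NULL)
    A <- sum(wc$a[sel]); B <- sum(wc$a[sel] + wc$b[sel])
    data.frame(chrom = win$chrom[i], start = win$start[i],
               end = win$end[i], n_snps = sum(sel),
               fst = if (B > 0) A / B else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Windowed nucleotide diversity per population
#'
#' Per SNP site, the unbiased expected heterozygosity
#' `2 p (1 - p) n / (n - 1)` over the population's haploid allele sample;
#' the window value is the sum over member SNPs divided by the window
#' length in bp. Monomorphic (unascertained) sites contribute zero, so
#' absolute levels underestimate sequence diversity; ratios between
#' populations computed under the same convention are unaffected.
#'
#' @inheritParams windowedFst
#' @return data.frame `chrom`, `start`, `end`, `n_snps`, and one `pi_<pop>`
#'   column per population.
#' @export
windowPi <- function(genotypes, labels = NULL, window_bp = 1e5,
                     step_bp = 1e4) {
  pf <- .popFreqs(genotypes, labels)
  mk <- markerInfo(genotypes)
  win <- .slidingWindows(mk, window_bp, step_bp)
  persite <- lapply(pf, function(z) {
    h <- 2 * z$p * (1 - z$p) * z$n / pmax(z$n - 1, 1)
    h[z$n < 2] <- 0
    h
  })
  rows <- lapply(seq_len(nrow(win)), function(i) {
    sel <- mk$chrom == win$chrom[i] & mk$pos >= win$start[i] &
      mk$pos <= win$end[i]
    row <- data.frame(chrom = win$chrom[i], start = win$start[i],
                      end = win$end[i], n_snps = sum(sel))
    for (pp in names(persite))
      row[[paste0("pi_", pp)]] <- sum(persite[[pp]][sel]) / window_bp
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Single-site XP-CLR likelihood
#'
#' Log-likelihood of the object-population allele count under the drift
#' model: the object frequency `p2` is Gaussian around the observed
#' reference frequency `p1` with variance `omega * p1 * (1 - p1) / c`,
#' where `c` is the probability that the site escapes hitchhiking
#' (`c = 1` neutral; under selection `c = 1 - exp(-log2N * r / s)`).
#' Gaussian mass outside `(0, 1)` collapses to point masses at the
#' boundaries where the binomial likelihood is evaluated exactly; the
#' interior integral uses composite Simpson quadrature with `n_quad`
#' intervals.
#'
#' @param x2 object-population alt-allele count at the site.
#' @param n2 object-population allele sample size.
#' @param p1 reference-population allele frequency.
#' @param omega genome-wide neutral drift scale.
#' @param c_escape escape probability in (0, 1]; 1 recovers neutrality.
#' @param n_quad even number of Simpson intervals (default 1200).
#' @return log-likelihood value.
#' @export
xpclrSiteLoglik <- function(x2, n2, p1, omega, c_escape = 1,
                            n_quad = 1200) {
  v <- omega * p1 * (1 - p1) / c_escape
  s <- sqrt(v)
  qs <- seq(0, 1, length.out = n_quad + 1)
  w <- c(1, rep(c(4, 2), length.out = n_quad - 1), 1) / 3 / n_quad
  dens <- dnorm(qs, p1, s)
  lik <- dbinom(x2, n2, qs)
  m0 <- pnorm(0, p1, s)
  m1 <- pnorm(1, p1, s, lower.tail = FALSE)
  L <- sum(w * dens * lik) + m0 * (x2 == 0) + m1 * (x2 == n2)
  log(max(L, 1e-300))
}

## Correlation-based site weights: greedy grouping of sites whose dosage
## correlation exceeds the cutoff; each site weighted 1/group size.
.corrWeights <- function(d, cutoff) {
  m <- ncol(d)
  if (m == 1) return(1)
  grp <- integer(m); g <- 0
  for (j in seq_len(m)) {
    if (grp[j] > 0) next
    g <- g + 1; grp[j] <- g
    if (j < m) for (k in (j + 1):m) {
      if (grp[k] > 0) next
      r <- suppressWarnings(cor(d[, j], d[, k]))
      if (!is.na(r) && abs(r) > cutoff) grp[k] <- g
    }
  }
  1 / table(grp)[grp]
}

#' Cross-population composite likelihood ratio (XP-CLR) scan
#'
#' At each grid point along a chromosome, up to `max_snps` nearest SNPs
#' within `window_cM` Morgans are scored: the composite log-likelihood of
#' the object population's allele counts is maximized over a log-spaced
#' grid of selection coefficients (with the neutral model included as the
#' `s = 0` grid member, so the CLR is nonnegative by construction) and
#' compared with the neutral composite likelihood,
#' `CLR = 2 (max_s l_sel - l_neutral)`. The neutral drift scale `omega` is
#' estimated genome-wide by method of moments from the (p1, p2) frequency
#' pairs unless supplied. Sites in pairwise dosage correlation above
#' `corr_cutoff` are down-weighted (weight 1 over group size).
#'
#' @param genotypes a [GenotypeData-class] with two subpopulations.
#' @param labels optional named sample -> population vector.
#' @param map genetic map data.frame (`chrom`, `bp`, `cM`).
#' @param ref_pop reference (non-swept) population label; default the
#'   first sorted label.
#' @param grid_spacing_bp spacing of scan grid points (default 10 kb).
#' @param window_cM half-window in Morgans around each grid point
#'   (default 0.0005).
#' @param max_snps maximum SNPs per grid point (default 100).
#' @param s_grid_size number of selection-coefficient grid values
#'   (default 100, log-spaced in `[1e-5, 0.5]`; the neutral member is
#'   added).
#' @param corr_cutoff correlated-site down-weighting threshold
#'   (default 0.95).
#' @param omega optional fixed drift scale.
#' @param log2N sweep time-scale constant `log(2 Ne)` in the escape
#'   probability (default `log(2000)`).
#' @param n_quad Simpson intervals for the site likelihood.
#' @return data.frame `chrom`, `pos`, `n_snps`, `clr`, `s_hat`, with
#'   attribute `"omega"`.
#' @export
xpclrScan <- function(genotypes, labels = NULL, map, ref_pop = NULL,
                      grid_spacing_bp = 1e4, window_cM = 5e-4,
                      max_snps = 100, s_grid_size = 100,
                      corr_cutoff = 0.95, omega = NULL,
                      log2N = log(2000), n_quad = 600) {
  pf <- .popFreqs(genotypes, labels)
  if (length(pf) != 2) stop("xpclrScan requires exactly two populations")
  if (is.null(ref_pop)) ref_pop <- names(pf)[1]
  obj_pop <- setdiff(names(pf), ref_pop)
  p1 <- pf[[ref_pop]]$p
  p2 <- pf[[obj_pop]]$p
  n2 <- pf[[obj_pop]]$n
  x2 <- round(p2 * n2)
  mk <- markerInfo(genotypes)
  d <- dosages(genotypes)

  poly <- p1 > 0 & p1 < 1
  if (is.null(omega))
    omega <- sum((p2[poly] - p1[poly])^2) / sum(p1[poly] * (1 - p1[poly]))
  omega <- max(omega, 1e-4)  # guard against degenerate identical populations

  s_grid <- exp(seq(log(1e-5), log(0.5), length.out = s_grid_size))
  qs <- seq(0, 1, length.out = n_quad + 1)
  wq <- c(1, rep(c(4, 2), length.out = n_quad - 1), 1) / 3 / n_quad

  out <- list()
  for (cc in unique(mk$chrom)) {
    idx <- which(mk$chrom == cc & poly)
    if (!length(idx)) next
    cm <- interpolateGeneticMap(map, cc, mk$pos[idx])
    grid <- seq(min(mk$pos[idx]), max(mk$pos[idx]), by = grid_spacing_bp)
    gcm <- interpolateGeneticMap(map, cc, grid)
    for (gi in seq_along(grid)) {
      r <- abs(cm - gcm[gi]) / 100  # Morgans
      near <- which(r <= window_cM)
      if (!length(near)) {
        out[[length(out) + 1]] <- data.frame(
          chrom = cc, pos = grid[gi], n_snps = 0L, clr = NA_real_,
          s_hat = NA_real_)
        next
      }
      if (length(near) > max_snps)
        near <- near[order(r[near])[seq_len(max_snps)]]
      sites <- idx[near]
      rr <- pmax(r[near], 1e-8)
      wts <- as.numeric(.corrWeights(d[, sites, drop = FALSE], corr_cutoff))

      nq <- length(qs)
      ns <- length(sites)
      ## binomial likelihood of each site on the quadrature grid, once
      B <- matrix(dbinom(rep(x2[sites], each = nq), rep(n2[sites], each = nq),
                         qs), nq, ns)
      p1s <- p1[sites]
      at0 <- as.numeric(x2[sites] == 0)
      at1 <- as.numeric(x2[sites] == n2[sites])
      ll_for_c <- function(cv) {
        sdv <- sqrt(omega * p1s * (1 - p1s) / cv)
        dens <- matrix(dnorm(qs, rep(p1s, each = nq), rep(sdv, each = nq)),
                       nq, ns)
        L <- colSums(wq * dens * B) +
          pnorm(0, p1s, sdv) * at0 +
          pnorm(1, p1s, sdv, lower.tail = FALSE) * at1
        sum(wts * log(pmax(L, 1e-300)))
      }
      ll_neu <- ll_for_c(rep(1, ns))
      best <- ll_neu; s_hat <- 0
      for (s in s_grid) {
        cv <- pmin(pmax(1 - exp(-log2N * rr / s), 1e-4), 1)
        ll <- ll_for_c(cv)
        if (ll > best) { best <- ll; s_hat <- s }
      }
      out[[length(out) + 1]] <- data.frame(
        chrom = cc, pos = grid[gi], n_snps = length(sites),
        clr = 2 * (best - ll_neu), s_hat = s_hat)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "omega") <- omega
  res
}

#' Combine window statistics and flag highly differentiated windows
#'
#' Averages grid-point XP-CLR scores within each Fst window, joins the
#' per-population diversity columns, flags the top `1 - decile` fraction
#' of windows per statistic (by rank, so exactly `ceiling((1-decile) * n)`
#' windows carry each flag), and applies the diversity-ratio QC: windows
#' whose `pi_ratio = pi_ref / pi_obj` falls below the genome-wide mean are
#' removed from both highly-differentiated sets.
#'
#' @param fst_windows output of [windowedFst()].
#' @param xpclr output of [xpclrScan()].
#' @param pi_windows output of [windowPi()].
#' @param ref_pop,obj_pop population labels forming the pi ratio
#'   (reference on top); defaults to the column order of `pi_windows`.
#' @param decile flag quantile (default 0.90: top 10%).
#' @return data.frame with `fst`, `xpclr_mean`, `pi_*`, `pi_ratio`,
#'   `top_fst`, `top_xpclr`, `qc_pass`, `hd_fst`, `hd_xpclr`.
#' @export
combineWindowStats <- function(fst_windows, xpclr, pi_windows,
                               ref_pop = NULL, obj_pop = NULL,
                               decile = 0.90) {
  out <- fst_windows
  key <- paste(out$chrom, out$start)
  picol <- grep("^pi_", names(pi_windows), value = TRUE)
  if (is.null(ref_pop)) ref_pop <- sub("^pi_", "", picol[1])
  if (is.null(obj_pop)) obj_pop <- sub("^pi_", "", picol[2])
  pk <- paste(pi_windows$chrom, pi_windows$start)
  for (cc in picol) out[[cc]] <- pi_windows[[cc]][match(key, pk)]
  out$pi_ratio <- out[[paste0("pi_", ref_pop)]] /
    out[[paste0("pi_", obj_pop)]]
  out$pi_ratio[!is.finite(out$pi_ratio)] <- NA

  out$xpclr_mean <- vapply(seq_len(nrow(out)), function(i) {
    sel <- xpclr$chrom == out$chrom[i] & xpclr$pos >= out$start[i] &
      xpclr$pos <= out$end[i]
    if (!any(sel)) return(NA_real_)
    mean(xpclr$clr[sel], na.rm = TRUE)
  }, numeric(1))

  topFlag <- function(x) {
    n_ok <- sum(!is.na(x))
    k <- ceiling((1 - decile) * n_ok)
    flag <- rep(FALSE, length(x))
    flag[order(x, decreasing = TRUE, na.last = NA)[seq_len(k)]] <- TRUE
    flag
  }
  out$top_fst <- topFlag(out$fst)
  out$top_xpclr <- topFlag(out$xpclr_mean)
  out$qc_pass <- !is.na(out$pi_ratio) &
    out$pi_ratio >= mean(out$pi_ratio, na.rm = TRUE)
  out$hd_fst <- out$top_fst & out$qc_pass
  out$hd_xpclr <- out$top_xpclr & out$qc_pass
  out
}

#' Sweep candidate genes from doubly flagged windows
#'
#' A gene is a candidate target of selection when its full span lies
#' within the union of QC-passing windows flagged by Fst AND within the
#' union flagged by XP-CLR.
#'
#' @param window_table output of [combineWindowStats()].
#' @param geneModels gene-model data.frame.
#' @return character vector of candidate gene ids.
#' @export
sweepCandidateGenes <- function(window_table, geneModels) {
  mkGR <- function(df) GenomicRanges::reduce(GenomicRanges::GRanges(
    df$chrom, IRanges::IRanges(df$start, df$end)))
  fstU <- mkGR(window_table[window_table$hd_fst, , drop = FALSE])
  xpU <- mkGR(window_table[window_table$hd_xpclr, , drop = FALSE])
  genes <- GenomicRanges::GRanges(geneModels$chrom,
                                  IRanges::IRanges(geneModels$start,
                                                   geneModels$end))
  inFst <- GenomicRanges::countOverlaps(genes, fstU, type = "within") > 0
  inXp <- GenomicRanges::countOverlaps(genes, xpU, type = "within") > 0
  geneModels$gene[inFst & inXp]
}
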