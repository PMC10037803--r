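#' Colocalization of cis-eQTL and cis-sQTL lead SNPs by LD
#'
#' For every gene with both a cis-eQTL peak and a cis-sQTL peak, the LD
#' r-squared between the two lead SNPs is computed; the pair is flagged
#' colocalized when `r2 >= r2_min` (default 0.6). Output is symmetric in
#' the order of the two peak tables.
#'
#' @param eqtl_peaks peak table from [mapQtl()] for e-traits (gene ids in
#'   `trait`); only rows with `class == "cis"` are used.
#' @param sqtl_peaks peak table for s-traits; `gene` column (or
#'   `trait_gene` mapping applied upstream) identifies the host gene.
#' @param genotypes a [GenotypeData-class].
#' @param r2_min colocalization threshold (default 0.6).
#' @return data.frame `gene`, `eqtl_lead`, `sqtl_lead`, `r2`, `colocalized`.
#' @export
colocLeadSnps <- function(eqtl_peaks, sqtl_peaks, genotypes, r2_min = 0.6) {
  e <- eqtl_peaks[!is.na(eqtl_peaks$class) & eqtl_peaks$class == "cis", ]
  s <- sqtl_peaks[!is.na(sqtl_peaks$class) & sqtl_peaks$class == "cis", ]
  sgene <- if (!is.null(s$gene)) s$gene else s$trait
  egene <- if (!is.null(e$gene)) e$gene else e$trait
  shared <- intersect(egene, sgene)
  d <- dosages(genotypes)
  rows <- list()
  for (gg in shared) {
    el <- e$lead_id[egene == gg][1]
    for (sl in s$lead_id[sgene == gg]) {
      if (!(el %in% colnames(d)) || !(sl %in% colnames(d))) {
        warning("missing genotypes for lead SNP; pair skipped for ", gg)
        next
      }
      r2 <- if (el == sl) 1 else
        suppressWarnings(cor(d[, el], d[, sl],
                             use = "pairwise.complete.obs"))^2
      rows[[length(rows) + 1]] <-
        data.frame(gene = gg, eqtl_lead = el, sqtl_lead = sl, r2 = r2,
                   colocalized = !is.na(r2) && r2 >= r2_min,
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(gene = character(), eqtl_lead = character(),
                      sqtl_lead = character(), r2 = numeric(),
                      colocalized = logical()))
  do.call(rbind, rows)
}

#' Correlation between gene expression and intron PSI
#'
#' Spearman rank correlation per gene-intron pair, computed across
#' per-genotype means (the same substrate as the QTL scans), with
#' Benjamini-Hochberg FDR across pairs. Pairs with fewer than `min_obs`
#' genotypes carrying both values are skipped. Rank correlation is used
#' because PSI is a bounded-below ratio prone to outliers; `method` is
#' configurable.
#'
#' @param expr_means genotype x genes matrix of expression means (log or
#'   FPKM scale; Spearman is invariant to monotone rescaling).
#' @param psi_means genotype x introns matrix of PSI means.
#' @param pairs data.frame with columns `gene`, `intron`.
#' @param fdr_max significance threshold on the FDR (default 0.05).
#' @param min_obs minimum paired observations (default 20).
#' @param method correlation method (default `"spearman"`).
#' @return data.frame `gene`, `intron`, `correlation`, `p`, `fdr`, `sign`,
#'   `significant`.
#' @export
exprPsiCorrelation <- function(expr_means, psi_means, pairs, fdr_max = 0.05,
                               min_obs = 20, method = "spearman") {
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    gg <- pairs$gene[i]; ii <- pairs$intron[i]
    if (!(gg %in% colnames(expr_means)) || !(ii %in% colnames(psi_means)))
      next
    x <- expr_means[, gg]; y <- psi_means[rownames(expr_means), ii]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < min_obs) next
    ct <- suppressWarnings(
      cor.test(x[ok], y[ok], method = method, exact = FALSE))
    rows[[length(rows) + 1]] <-
      data.frame(gene = gg, intron = ii,
                 correlation = unname(ct$estimate), p = ct$p.value,
                 stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(gene = character(), intron = character(),
                      correlation = numeric(), p = numeric(),
                      fdr = numeric(), sign = character(),
                      significant = logical()))
  out <- do.call(rbind, rows)
  out$fdr <- p.adjust(out$p, "BH")
  out$sign <- ifelse(out$correlation >= 0, "positive", "negative")
  out$significant <- out$fdr < fdr_max
  out
}

#' @importFrom stats cor.test chisq.test
NULL

#' Chi-square test for imbalance between positive and negative correlations
#'
#' One-degree-of-freedom goodness-of-fit of the observed (positive,
#' negative) counts against equal proportions; two-sided p-value, invariant
#' under swapping the two counts.
#'
#' @param n_positive,n_negative nonnegative counts, not both zero.
#' @return list with `statistic`, `p`.
#' @examples
#' directionImbalanceTest(226, 132)$p  # ~ 6.76e-7
#' @export
directionImbalanceTest <- function(n_positive, n_negative) {
  stopifnot(n_positive >= 0, n_negative >= 0)
  if (n_positive + n_negative < 1) stop("both counts are zero")
  tot <- n_positive + n_negative
  e <- tot / 2
  stat <- (n_positive - e)^2 / e + (n_negative - e)^2 / e
  list(statistic = stat, p = pchisq(stat, df = 1, lower.tail = FALSE))
}
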