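## Profile REML for the one-way random-intercept model.
## For gamma = sigma_g2/sigma_e2 the REML criterion has sigma_e2 and the mean
## profiled out in closed form; only gamma is optimized numerically.
.remlOneWay <- function(y, group) {
  group <- as.character(group)
  ybar <- tapply(y, group, mean)
  ni <- tapply(y, group, length)
  N <- length(y)
  ssw <- sum((y - ybar[group])^2)

  crit <- function(loggamma) {
    g <- exp(loggamma)
    w <- ni / (1 + g * ni)
    mu <- sum(w * ybar) / sum(w)
    Q <- ssw + sum(w * (ybar - mu)^2)
    s2e <- Q / (N - 1)
    0.5 * ((N - 1) * log(s2e) + sum(log(1 + g * ni)) + log(sum(w)) +
             Q / s2e)
  }
  opt <- optimize(crit, c(-14, 14))
  ## compare against the gamma -> 0 boundary
  if (crit(-30) <= opt$objective + 1e-10) {
    gamma <- 0
  } else gamma <- exp(opt$minimum)
  w <- ni / (1 + gamma * ni)
  mu <- sum(w * ybar) / sum(w)
  Q <- ssw + sum(w * (ybar - mu)^2)
  s2e <- Q / (N - 1)
  s2g <- gamma * s2e
  list(sigma_g2 = s2g, sigma_e2 = s2e, mu = mu,
       H2 = if (s2g + s2e > 0) s2g / (s2g + s2e) else 0,
       n_genotypes = length(ni), n_samples = N, ni = ni, ybar = ybar)
}

#' Broad-sense heritability of one expression trait
#'
#' Fits the one-way random-intercept model (genotype as random effect) by
#' restricted maximum likelihood and returns the variance components and
#' \eqn{H^2 = \sigma^2_G / (\sigma^2_G + \sigma^2_E)}. Only genotypes with at
#' least two replicates contribute; negative component estimates are clamped
#' to zero by the boundary of the profile search. H-squared is invariant
#' under affine transformation of the input values.
#'
#' @param values numeric vector of expression values (one per sample); for
#'   FPKM data a log-scale transform upstream is recommended.
#' @param replicate_map named character vector sample -> genotype covering
#'   `names(values)` (or positional if `values` is unnamed and the map is in
#'   the same order).
#' @return list with `sigma_g2`, `sigma_e2`, `H2`, `n_genotypes`,
#'   `n_samples`, and logical `constant` flag.
#' @export
estimateH2 <- function(values, replicate_map) {
  if (!is.null(names(values))) replicate_map <- replicate_map[names(values)]
  stopifnot(length(values) == length(replicate_map))
  tab <- table(replicate_map)
  keepg <- names(tab)[tab >= 2]
  if (length(keepg) < 2)
    stop("need at least 2 genotypes with at least 2 replicates")
  sel <- replicate_map %in% keepg
  y <- values[sel]; grp <- replicate_map[sel]
  if (sd(y) == 0)
    return(list(sigma_g2 = 0, sigma_e2 = 0, H2 = 0,
                n_genotypes = length(keepg), n_samples = length(y),
                constant = TRUE))
  fit <- .remlOneWay(y, grp)
  list(sigma_g2 = fit$sigma_g2, sigma_e2 = fit$sigma_e2, H2 = fit$H2,
       n_genotypes = fit$n_genotypes, n_samples = fit$n_samples,
       constant = FALSE)
}

#' Heritability for every gene of an expression matrix
#'
#' @param expression an [ExpressionData-class].
#' @param transform `"log"` (default; `log(FPKM + 1e-8)`) or `"none"`.
#' @param genes optional subset of gene ids.
#' @return data.frame with `gene`, `sigma_g2`, `sigma_e2`, `H2`,
#'   `n_genotypes`, `n_samples`.
#' @export
estimateH2Matrix <- function(expression, transform = c("log", "none"),
                             genes = NULL) {
  transform <- match.arg(transform)
  x <- fpkm(expression)
  if (!is.null(genes)) x <- x[, genes, drop = FALSE]
  if (transform == "log") x <- log(x + 1e-8)
  rmap <- replicateMap(expression)
  res <- lapply(colnames(x), function(g) {
    fit <- estimateH2(setNames(x[, g], rownames(x)), rmap)
    data.frame(gene = g, sigma_g2 = fit$sigma_g2, sigma_e2 = fit$sigma_e2,
               H2 = fit$H2, n_genotypes = fit$n_genotypes,
               n_samples = fit$n_samples)
  })
  do.call(rbind, res)
}

#' Compare per-gene heritability between two subpopulations
#'
#' H-squared is estimated separately within each subpopulation. A gene is
#' flagged `reduced` when the second subpopulation's estimate falls below
#' `(1 - reduction_fraction)` times the first's (default: reduced by over
#' 80%); a softer flag at `secondary_fraction` (default 20% reduction) is
#' also reported. Flags are `NA` when the reference estimate is zero or a
#' subpopulation lacks replicated genotypes.
#'
#' @param expression an [ExpressionData-class].
#' @param genotype_labels named character vector genotype -> subpopulation
#'   (two levels).
#' @param pops character of length 2: reference subpopulation first.
#' @param reduction_fraction main flag threshold (default 0.80).
#' @param secondary_fraction secondary flag threshold (default 0.20).
#' @param transform passed to [estimateH2Matrix()].
#' @return data.frame with per-gene `H2_<pop1>`, `H2_<pop2>`, `reduced`,
#'   `reduced_secondary`.
#' @export
compareSubpopH2 <- function(expression, genotype_labels, pops = NULL,
                            reduction_fraction = 0.80,
                            secondary_fraction = 0.20,
                            transform = "log") {
  rmap <- replicateMap(expression)
  if (is.null(pops)) pops <- unique(genotype_labels)[1:2]
  h2pop <- lapply(pops, function(pp) {
    gset <- names(genotype_labels)[genotype_labels == pp]
    sel <- names(rmap)[rmap %in% gset]
    sub <- ExpressionData(fpkm(expression)[sel, , drop = FALSE], rmap[sel])
    ok <- tryCatch({
      estimateH2Matrix(sub, transform = transform)$H2
    }, error = function(e) rep(NA_real_, ncol(fpkm(expression))))
    ok
  })
  h1 <- h2pop[[1]]; h2 <- h2pop[[2]]
  reduced <- ifelse(is.na(h1) | is.na(h2) | h1 == 0, NA,
                    h2 < (1 - reduction_fraction) * h1)
  reduced2 <- ifelse(is.na(h1) | is.na(h2) | h1 == 0, NA,
                     h2 < (1 - secondary_fraction) * h1)
  out <- data.frame(gene = colnames(fpkm(expression)), h1, h2,
                    reduced = reduced, reduced_secondary = reduced2)
  names(out)[2:3] <- paste0("H2_", pops)
  out
}

#' Heritability-distribution shift per GO term
#'
#' For every annotation term with between `size_min` and `size_max` member
#' genes among the tested set, a two-sample Kolmogorov-Smirnov test compares
#' the members' H-squared values against all remaining tested genes.
#' P-values are Benjamini-Hochberg corrected across terms; a term is called
#' significant when FDR <= `fdr_max` and the relative median shift
#' `|median_term - median_background| / median_background` is at least
#' `median_shift_min`.
#'
#' @param h2 named numeric vector of per-gene H-squared (the tested set is
#'   `names(h2)`).
#' @param annotations data.frame with columns `gene`, `term`.
#' @param size_min,size_max term size bounds (defaults 25 and 499).
#' @param fdr_max FDR threshold (default 0.05).
#' @param median_shift_min relative median-shift threshold (default 0.20).
#' @return data.frame with one row per eligible term: `term`, `n_genes`,
#'   `median_term`, `median_background`, `ks_statistic`, `p`, `fdr`,
#'   `direction`, `significant`.
#' @export
goHeritabilityShift <- function(h2, annotations, size_min = 25,
                                size_max = 499, fdr_max = 0.05,
                                median_shift_min = 0.20) {
  ann <- annotations[annotations$gene %in% names(h2), ]
  sizes <- table(ann$term)
  terms <- names(sizes)[sizes >= size_min & sizes <= size_max]
  nexcl <- sum(!(names(sizes) %in% terms))
  if (nexcl) message(nexcl, " term(s) outside size bounds excluded")
  if (!length(terms)) return(data.frame())
  rows <- lapply(terms, function(tt) {
    gset <- unique(ann$gene[ann$term == tt])
    a <- h2[names(h2) %in% gset]
    b <- h2[!(names(h2) %in% gset)]
    ks <- suppressWarnings(ks.test(a, b))
    data.frame(term = tt, n_genes = length(a),
               median_term = median(a), median_background = median(b),
               ks_statistic = unname(ks$statistic), p = ks$p.value)
  })
  out <- do.call(rbind, rows)
  out$fdr <- p.adjust(out$p, "BH")
  out$direction <- ifelse(out$median_term >= out$median_background,
                          "higher", "lower")
  shift <- abs(out$median_term - out$median_background) /
    out$median_background
  out$significant <- out$fdr <= fdr_max & shift >= median_shift_min
  out[order(out$p), ]
}

#' GO-term enrichment of a study gene set (hypergeometric test)
#'
#' One-sided hypergeometric (Fisher) test per term of overlap between the
#' study set and the term's genes, against the background set, with
#' Benjamini-Hochberg correction across terms.
#'
#' @param study character vector of study genes (subset of `background`).
#' @param background character vector of background genes (e.g. all
#'   expressed genes).
#' @param annotations data.frame with columns `gene`, `term`.
#' @return data.frame with `term`, `n_term`, `n_overlap`, `fold`, `p`, `fdr`.
#' @export
goEnrichment <- function(study, background, annotations) {
  if (!length(study)) stop("empty study set")
  if (!all(study %in% background)) stop("study genes must be in background")
  ann <- annotations[annotations$gene %in% background, ]
  N <- length(unique(background))
  k <- length(unique(study))
  terms <- unique(ann$term)
  rows <- lapply(terms, function(tt) {
    gset <- unique(ann$gene[ann$term == tt])
    m <- length(gset)
    q <- length(intersect(study, gset))
    p <- phyper(q - 1, m, N - m, k, lower.tail = FALSE)
    data.frame(term = tt, n_term = m, n_overlap = q,
               fold = (q / k) / (m / N), p = p)
  })
  out <- do.call(rbind, rows)
  out$fdr <- p.adjust(out$p, "BH")
  out[order(out$p), ]
}
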