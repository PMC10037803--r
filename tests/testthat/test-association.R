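test_that("lmScan recovers exact effects and matches the normal-equations oracle", {
  g <- fix_geno()
  d <- dosages(g)
  ## noiseless trait: beta recovered exactly, p underflows
  y <- setNames(0.5 * d[, 10], rownames(d))
  sc <- lmScan(y, g)
  expect_equal(sc$beta[10], 0.5, tolerance = 1e-10)
  expect_lt(sc$p[10], 1e-100)
  ## oracle: direct solve of the normal equations, 20 random markers
  set.seed(31)
  pcs <- computePCs(g, 3)
  yr <- setNames(rnorm(nrow(d)) + 0.3 * d[, 5], rownames(d))
  sc2 <- lmScan(yr, g, covariates = pcs)
  for (j in sample(ncol(d), 20)) {
    X <- cbind(1, d[, j], pcs)
    fit <- lm.fit(X, yr)
    bj <- fit$coefficients[2]
    rss <- sum(fit$residuals^2)
    sej <- sqrt(rss / fit$df.residual * solve(crossprod(X))[2, 2])
    if (sd(d[, j]) == 0) { expect_true(is.na(sc2$beta[j])); next }
    expect_equal(sc2$beta[j], unname(bj), tolerance = 1e-10)
    expect_equal(sc2$se[j], sej, tolerance = 1e-10)
  }
  ## p-values invariant under affine trait transform
  sc3 <- lmScan(5 * yr - 2, g, covariates = pcs)
  expect_equal(sc2$p, sc3$p, tolerance = 1e-9)
  expect_error(lmScan(yr, g, covariates = cbind(pcs, pcs[, 1])),
               "collinear")
})

test_that("lmScan null calibration gives the nominal false-positive rate", {
  g <- fix_geno_indep()
  set.seed(32)
  fp <- vapply(1:10, function(i) {
    y <- setNames(rnorm(nSamples(g)), sampleIDs(g))
    mean(lmScan(y, g)$p < 0.05, na.rm = TRUE)
  }, numeric(1))
  expect_lt(abs(mean(fp) - 0.05), 0.015)
})

test_that("lmmScan degenerates to lmScan under identity kinship and matches GLS", {
  g <- fix_geno()[, 1:200]
  set.seed(33)
  y <- setNames(rnorm(nSamples(g)), sampleIDs(g))
  K <- diag(nSamples(g))
  dimnames(K) <- list(sampleIDs(g), sampleIDs(g))
  a <- lmScan(y, g)
  b <- lmmScan(y, g, K)
  expect_equal(a$p, b$p, tolerance = 1e-6)
  ## fixed variance ratio: explicit GLS oracle
  Kr <- computeKinship(g)
  delta <- 2.5
  sc <- lmmScan(y, g, Kr, delta = delta)
  V <- Kr + delta * diag(nSamples(g))
  Vi <- solve(V)
  d <- dosages(g)
  for (j in c(3, 50, 150)) {
    X <- cbind(1, d[, j])
    XtVi <- crossprod(X, Vi)
    bhat <- solve(XtVi %*% X, XtVi %*% y)
    r <- y - X %*% bhat
    s2 <- drop(crossprod(r, Vi %*% r)) / (length(y) - 2)
    seb <- sqrt(s2 * solve(XtVi %*% X)[2, 2])
    expect_equal(sc$beta[j], bhat[2], tolerance = 1e-8)
    expect_equal(sc$se[j], seb, tolerance = 1e-8)
  }
  Kbad <- Kr; Kbad[1, 2] <- Kbad[1, 2] + 10  # asymmetric/non-PSD
  expect_error(lmmScan(y, g, (Kbad + t(Kbad)) / 2 -
                         diag(20, nSamples(g))), "positive semi-definite")
})

test_that("mixed model deflates structure-driven inflation relative to OLS", {
  g <- fix_geno()
  labs <- subpopLabels(g)
  set.seed(34)
  ## confounded null: trait depends on subpopulation, not on any marker
  y <- setNames(2 * (labs == "tropical") + rnorm(nSamples(g)), sampleIDs(g))
  K <- computeKinship(g)
  gif <- function(p) median(qchisq(p, 1, lower.tail = FALSE),
                            na.rm = TRUE) / qchisq(0.5, 1)
  l_lm <- gif(lmScan(y, g)$p)
  l_mm <- gif(lmmScan(y, g, K)$p)
  expect_lt(abs(l_mm - 1), abs(l_lm - 1))
})

test_that("Bonferroni threshold reproduces the genome-wide constants", {
  thr <- bonferroniThreshold(0.05, 12191984)
  expect_equal(thr$p, 4.1e-9, tolerance = 0.05)
  expect_equal(thr$neglog10, 8.39, tolerance = 0.001)
  expect_equal(bonferroniThreshold(0.05, 1)$p, 0.05)
})

test_that("peak grouping follows the distance rule and matches the merge oracle", {
  ## forced example: {1.0, 1.5, 1.9, 4.0} Mb
  sig <- data.frame(marker = paste0("m", 1:4), chrom = "chr1",
                    pos = c(1e6, 1.5e6, 1.9e6, 4e6),
                    p = c(1e-10, 1e-12, 1e-9, 1e-15))
  pk <- groupPeaks(sig)
  expect_equal(nrow(pk), 1L)  # the singleton at 4 Mb is dropped
  expect_equal(pk$start, 1e6); expect_equal(pk$end, 1.9e6)
  expect_equal(pk$lead_id, "m2"); expect_equal(pk$n_snps, 3L)
  expect_equal(nrow(groupPeaks(sig[0, ])), 0L)

  ## brute-force O(n^2) merge oracle: repeatedly fuse any two clusters
  ## whose closest members are < gap apart, until a fixpoint
  oracle_groups <- function(pos, gap) {
    grp <- seq_along(pos)
    repeat {
      changed <- FALSE
      for (i in seq_along(pos)) for (j in seq_along(pos)) {
        if (grp[i] != grp[j] && abs(pos[i] - pos[j]) < gap) {
          grp[grp == grp[j]] <- grp[i]
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    grp
  }
  set.seed(35)
  for (rep_i in 1:40) {
    n <- sample(3:25, 1)
    pos <- sort(sample.int(2e7, n))
    sig <- data.frame(marker = paste0("m", 1:n), chrom = "chr1",
                      pos = pos, p = runif(n))
    pk <- groupPeaks(sig, gap_max = 1e6, min_snps = 1)
    grp <- oracle_groups(pos, 1e6)
    expect_equal(nrow(pk), length(unique(grp)))
    for (gg in unique(grp)) {
      memb <- pos[grp == gg]
      expect_true(any(pk$start == min(memb) & pk$end == max(memb)))
    }
  }
  ## idempotence & separation: re-grouping lead markers changes nothing
  set.seed(36)
  pos <- sort(sample.int(2e7, 50))
  sig <- data.frame(marker = paste0("m", 1:50), chrom = "chr1", pos = pos,
                    p = runif(50))
  pk <- groupPeaks(sig, min_snps = 1)
  if (nrow(pk) > 1) expect_true(all(diff(pk$start) >= 1e6))
  again <- groupPeaks(data.frame(marker = pk$lead_id, chrom = pk$chrom,
                                 pos = pk$lead_pos, p = pk$lead_p),
                      min_snps = 1)
  expect_equal(nrow(again), nrow(pk))
})

test_that("cis/trans classification keeps at most one cis peak per trait", {
  gene <- data.frame(gene = "gX", chrom = "chr1", start = 5e6, end = 5.1e6,
                     strand = "+")
  pk <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                   start = c(4.4e6, 5.6e6, 1e6), end = c(4.6e6, 5.8e6, 1.2e6),
                   lead_id = c("a", "b", "c"),
                   lead_pos = c(4.5e6, 5.6e6, 1.1e6),
                   lead_p = c(1e-9, 1e-12, 1e-20), n_snps = 3L)
  out <- classifyCisTrans(pk, gene)
  ## both chr1 peaks are in the window; only the smaller-p one stays cis
  expect_equal(out$class, c("trans", "cis", "trans"))
  ## 0.5 Mb downstream of the span end is cis
  one <- classifyCisTrans(pk[2, ], gene)
  expect_equal(one$class, "cis")
  expect_error(classifyCisTrans(pk, gene[0, ]), "unknown gene")
})

test_that("PVE recovers planted variance and stays below H2 on average", {
  study <- fix_study()
  g <- study$genotypes
  Y <- study_etraits(study, study$truth$planted_cis$gene)
  h2tab <- estimateH2Matrix(study$expression,
                            genes = study$truth$planted_cis$gene)
  pves <- h2s <- numeric(0)
  for (i in seq_len(nrow(study$truth$planted_cis))) {
    gg <- study$truth$planted_cis$gene[i]
    pk <- data.frame(lead_id = study$truth$planted_cis$marker[i])
    pv <- computePve(setNames(Y[, gg], rownames(Y)), g, pk)
    pves <- c(pves, pv$cumulative)
    h2s <- c(h2s, h2tab$H2[h2tab$gene == gg])
  }
  expect_equal(mean(pves), 0.4, tolerance = 0.1)
  expect_lt(mean(pves), mean(h2s) + 0.05)
  ## a null singleton peak explains only ~1/n of the variance
  set.seed(37)
  yn <- setNames(rnorm(nSamples(g)), sampleIDs(g))
  pvn <- computePve(yn, g, data.frame(lead_id = markerInfo(g)$id[1]))
  expect_lt(pvn$cumulative, 0.1)
  ## collinear leads are dropped and flagged
  dup <- data.frame(lead_id = rep(markerInfo(g)$id[1], 2))
  pvd <- computePve(yn, g, dup)
  expect_length(pvd$dropped, 1L)
})

test_that("permutation threshold matches the independent-markers closed form", {
  g <- fix_geno_indep()  # 400 independent markers
  M <- nMarkers(g)
  set.seed(38)
  Y <- matrix(rnorm(nSamples(g) * 60), nSamples(g), 60,
              dimnames = list(sampleIDs(g), paste0("t", 1:60)))
  pt <- permutationThreshold(Y, g, n_perm = 15, seed = 2)
  closed <- -log10(1 - 0.95^(1 / M))
  expect_lt(abs(pt$threshold_neglog10 - closed), 0.25)
  ## duplicated markers: one effective test, threshold ~ -log10 of the
  ## 5th percentile of a uniform
  d1 <- dosages(g)[, rep(1, 30)]
  colnames(d1) <- paste0("d", 1:30)
  gd <- GenotypeData(d1, data.frame(id = colnames(d1), chrom = "chr1",
                                    pos = 1000L * (1:30), ref = "A",
                                    alt = "T"))
  ptd <- permutationThreshold(Y, gd, n_perm = 15, seed = 2)
  expect_lt(abs(ptd$threshold_neglog10 - (-log10(0.05))), 0.35)
  ## monotone nonincreasing in M on nested marker sets
  g_half <- g[, 1:(M / 2)]
  pth <- permutationThreshold(Y, g_half, n_perm = 15, seed = 2)
  expect_lte(pth$threshold_neglog10, pt$threshold_neglog10 + 0.05)
})

test_that("mapQtl applies the max-peak and effect-size exclusion rules", {
  ## large panel so that each of 12 competing planted effects is powered
  g <- simulateGenotypes(simConfig(n_genotypes = 300, n_markers = 2500,
                                   n_chromosomes = 3,
                                   chromosome_length_bp = 6e6, seed = 77))
  pcs <- computePCs(g, 5)
  d <- dosages(g)
  mk <- markerInfo(g)
  set.seed(39)
  ## 12 planted effects, 4 per chromosome, >= 1.4 Mb apart
  picks <- vapply(split(seq_len(nrow(mk)), mk$chrom), function(ii) {
    vapply(c(0.8e6, 2.2e6, 3.6e6, 5e6),
           function(q) ii[which.min(abs(mk$pos[ii] - q))], 1L)
  }, integer(4))
  picks <- as.integer(picks)
  y12 <- setNames(rowSums(scale(d[, picks])) * 2 + rnorm(nrow(d), 0, 0.5),
                  rownames(d))
  ## sparse threshold: the per-trait peak cap is what is under test
  out <- mapQtl(cbind(crazy = y12), g, covariates = pcs,
                threshold = 1e-4, max_peaks = 10, min_snps = 1)
  expect_true("crazy" %in% attr(out, "excluded"))
  expect_false("crazy" %in% out$trait)
  ## sQTL mode: a small planted shift is removed by the beta filter
  j <- picks[1]
  ysmall <- setNames(0.01 * d[, j] + rnorm(nrow(d), 0, 0.005), rownames(d))
  outs <- mapQtl(cbind(tiny = ysmall), g, threshold = 1e-4,
                 min_beta = 0.05, min_snps = 1)
  expect_equal(nrow(outs), 0L)
  outs2 <- mapQtl(cbind(tiny = ysmall), g, threshold = 1e-4,
                  min_beta = NULL, min_snps = 1)
  expect_gt(nrow(outs2), 0L)
})

test_that("candidate genes are called by proximity, LD proxy and eQTL overlap", {
  study <- fix_study()
  g <- study$genotypes
  mk <- markerInfo(g)
  gm <- study$geneModels
  ## proximity: a trait SNP 30 kb from a gene
  g1 <- gm[1, ]
  near <- mk[mk$chrom == g1$chrom &
               abs(mk$pos - (g1$start - 3e4)) < 5e3, ][1, ]
  ts <- data.frame(marker = near$id, chrom = near$chrom, pos = near$pos)
  cand <- candidateGenesForTrait(ts, gm, genotypes = g, ld_search_bp = 0)
  expect_true(g1$gene %in% cand$gene)
  expect_equal(cand$evidence[cand$gene == g1$gene], "proximity")
  ## a SNP 200 kb away from every gene on an empty stretch: no candidates
  far_gm <- gm[abs(gm$start - near$pos) > 2e5 | gm$chrom != near$chrom, ]
  cand2 <- candidateGenesForTrait(ts, far_gm, genotypes = g,
                                  ld_search_bp = 0)
  expect_equal(nrow(cand2[cand2$evidence == "proximity" &
                            cand2$gene %in% far_gm$gene[
                              far_gm$chrom == near$chrom &
                                abs(far_gm$start - near$pos) < 2.5e5], ]), 0L)
  ## eQTL overlap: phenotype driven through a planted cis marker
  cis1 <- study$truth$planted_cis[1, ]
  cm <- mk[mk$id == cis1$marker, ]
  ts3 <- data.frame(marker = cm$id, chrom = cm$chrom, pos = cm$pos)
  eq <- data.frame(trait = cis1$gene, lead_id = cis1$marker)
  gm_far <- gm[gm$gene == cis1$gene, ]
  gm_far$start <- gm_far$start + 5e5  # push out of the proximity window
  gm_far$end <- gm_far$end + 5e5
  cand3 <- candidateGenesForTrait(ts3, gm_far, eqtl = eq, genotypes = g,
                                  dist = 1e4, ld_search_bp = 0)
  expect_true(cis1$gene %in% cand3$gene)
  expect_equal(cand3$evidence[cand3$gene == cis1$gene], "eQTL-overlap")
})
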