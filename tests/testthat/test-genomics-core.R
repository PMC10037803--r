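mk3 <- function(doses, ids = paste0("m", seq_len(ncol(doses)))) {
  GenotypeData(doses,
               data.frame(id = ids, chrom = "chr1",
                          pos = seq_len(ncol(doses)) * 1000L,
                          ref = "A", alt = "T"))
}

test_that("marker filters apply MAF and heterozygosity rules", {
  n <- 50
  d <- cbind(rep(c(0, 2), length.out = n),       # MAF 0.5: kept
             c(rep(2, 2), rep(0, n - 2)),        # MAF 0.04: removed
             c(rep(1, 2), rep(c(0, 2), length.out = n - 2)))  # 4% het: removed
  rownames(d) <- paste0("s", 1:n)
  g <- mk3(d)
  kept <- markerInfo(filterMarkers(g))$id
  expect_identical(kept, "m1")
  # inbred fixture: het filter removes nothing
  gi <- fix_geno()
  expect_equal(nMarkers(filterMarkers(gi, maf_min = 0)), nMarkers(gi))
  expect_error(filterMarkers(g, maf_min = 0.6), "all markers")
})

test_that("heterozygous-sample filter drops contaminated lines only", {
  d <- rbind(s1 = rep(1, 40),                       # 100% het: dropped
             s2 = rep(c(0, 2), 20),                 # 0% het: kept
             s3 = c(rep(1, 10), rep(0, 30)))        # 25% het: dropped
  g <- mk3(d)
  expect_message(out <- filterHeterozygousSamples(g), "s1, s3")
  expect_identical(sampleIDs(out), "s2")
  # threshold 1 is the identity
  expect_identical(sampleIDs(filterHeterozygousSamples(g, 1.0)),
                   sampleIDs(g))
})

test_that("ldR2 matches the direct correlation oracle and is symmetric", {
  g <- fix_geno()
  d <- dosages(g)
  ids <- markerInfo(g)$id
  set.seed(1)
  for (k in 1:100) {
    pair <- sample(ids, 2)
    r2 <- suppressWarnings(ldR2(g, pair[1], pair[2]))
    oracle <- suppressWarnings(cor(d[, pair[1]], d[, pair[2]]))^2
    if (is.na(oracle)) expect_true(is.na(r2))
    else expect_equal(r2, oracle, tolerance = 1e-12)
  }
  expect_equal(suppressWarnings(ldR2(g, ids[1], ids[2])),
               suppressWarnings(ldR2(g, ids[2], ids[1])))
  # ref/alt flip invariance
  d2 <- d; d2[, 1] <- 2 - d2[, 1]
  g2 <- GenotypeData(d2, markerInfo(g))
  expect_equal(suppressWarnings(ldR2(g, ids[1], ids[2])),
               suppressWarnings(ldR2(g2, ids[1], ids[2])))
  # identical columns give exactly 1
  d3 <- cbind(d[, 1], d[, 1]); rownames(d3) <- rownames(d)
  expect_equal(ldR2(mk3(d3), "m1", "m2"), 1.0)
  # zero-variance marker: NA with warning
  d4 <- cbind(d[, 1], 0); rownames(d4) <- rownames(d)
  expect_warning(r <- ldR2(mk3(d4), "m1", "m2"), "zero-variance")
  expect_true(is.na(r))
})

test_that("independent markers show near-zero LD", {
  g <- fix_geno_indep()
  ids <- markerInfo(g)$id
  set.seed(2)
  r2s <- replicate(50, {
    p <- sample(ids, 2)
    suppressWarnings(ldR2(g, p[1], p[2]))
  })
  expect_lt(mean(r2s, na.rm = TRUE), 0.03)
})

test_that("ldPrune output verified by exhaustive pairwise oracle", {
  g <- fix_geno()[, 1:300]
  kept <- ldPrune(g, r2_max = 0.2, window_bp = 1e6)
  # duplicates collapse: no retained pair within the window exceeds r2_max
  d <- dosages(g)
  mk <- markerInfo(g)
  pos <- mk$pos[match(kept, mk$id)]
  for (i in seq_along(kept)) {
    for (j in seq_len(i - 1)) {
      if (abs(pos[i] - pos[j]) < 1e6) {
        r2 <- suppressWarnings(cor(d[, kept[i]], d[, kept[j]]))^2
        expect_lte(r2, 0.2 + 1e-12)
      }
    }
  }
  # exact duplicates: exactly one survives
  dd <- cbind(a = d[, 1], b = d[, 1])
  rownames(dd) <- rownames(d)
  expect_length(ldPrune(mk3(dd), r2_max = 0.2, window_bp = 1e6), 1L)
  # independent markers: everything survives
  gi <- fix_geno_indep()[, 1:100]
  expect_gte(length(ldPrune(gi, r2_max = 0.5, window_bp = 1e6)), 95)
})

test_that("kinship equals the ZZ'/m oracle and behaves for relatives", {
  set.seed(3)
  d <- matrix(sample(c(0, 2), 50, replace = TRUE), 5, 10,
              dimnames = list(paste0("s", 1:5), NULL))
  g <- mk3(d)
  K <- computeKinship(g)
  z <- sweep(d, 2, colMeans(d))
  keepc <- apply(z, 2, function(x) any(x != 0))
  oracle <- tcrossprod(z[, keepc]) / sum(keepc)
  expect_equal(unname(K), unname(oracle), tolerance = 1e-12)
  expect_identical(K, t(K))
  # identical samples: equal rows, mutual entry = diagonal entry
  d2 <- d; d2[2, ] <- d2[1, ]
  K2 <- computeKinship(mk3(d2))
  expect_equal(K2[1, ], K2[2, ])
  expect_equal(K2[1, 2], K2[1, 1])
  # unrelated equal-frequency panel: off-diagonal mean near zero
  gi <- fix_geno_indep()
  Ki <- computeKinship(gi)
  expect_lt(abs(mean(Ki[upper.tri(Ki)])), 0.05 * mean(diag(Ki)))
})

test_that("PCs separate subpopulations and have orthogonal scores", {
  g <- fix_geno()
  pcs <- computePCs(g, k = 5)
  labs <- subpopLabels(g)
  ## PC1 separates the two subpopulations with AUC ~ 1
  x <- pcs[, 1]
  pos <- x[labs == "tropical"]; neg <- x[labs == "temperate"]
  auc <- mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
  expect_gt(max(auc, 1 - auc), 0.95)
  cp <- crossprod(pcs)
  expect_lt(max(abs(cp[upper.tri(cp)])) / max(diag(cp)), 1e-8)
  expect_error(computePCs(g, k = nSamples(g)), "rank")
  # rank-1 matrix: one component explains all variance
  v <- rep(c(0, 2), 10)
  d1 <- outer(c(rep(1, 10), rep(0, 10)), v)
  rownames(d1) <- paste0("s", 1:20)
  p1 <- computePCs(mk3(d1), k = 1)
  expect_equal(attr(p1, "varprop")[1], 1, tolerance = 1e-10)
})

test_that("Box-Cox selects sensible lambdas and standardizes output", {
  set.seed(4)
  x <- exp(rnorm(500))
  fit <- boxcoxTransform(x)
  expect_lt(abs(fit$lambda), 0.15)        # lognormal: log branch
  expect_equal(mean(fit$transformed), 0, tolerance = 1e-10)
  expect_equal(sd(fit$transformed), 1, tolerance = 1e-10)
  y <- rnorm(500, 50, 5)
  expect_lt(abs(boxcoxTransform(y)$lambda - 1), 0.6)  # near-linear
  ## monotone: lambda = 1 is an affine (rank-preserving) map
  expect_equal(rank(boxcoxTransform(x)$transformed), rank(x))
  ## shift handles nonpositive input
  fs <- boxcoxTransform(c(-5, rnorm(99)))
  expect_gte(fs$shift, 5)
  expect_error(boxcoxTransform(rep(1, 20)), "constant")
  expect_error(boxcoxTransform(1:5), "10 observations")
})

test_that("expressed-gene filter reproduces the 80%-of-samples count rule", {
  ## 572 samples at frac 0.80 -> 458 required
  expect_equal(ceiling(0.80 * 572), 458)
  n <- 50
  x <- cbind(all = rep(2, n),
             low = rep(0.99, n),
             some = c(rep(2, 39), rep(0, 11)))
  rownames(x) <- paste0("s", 1:n)
  kept <- filterExpressedGenes(x, fpkm_min = 1, frac = 0.80)
  expect_identical(kept, "all")  # "some" fails: 39 < ceiling(0.8*50) = 40
  kept2 <- filterExpressedGenes(x, fpkm_min = 1, frac = 0.78)
  expect_setequal(kept2, c("all", "some"))
})
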