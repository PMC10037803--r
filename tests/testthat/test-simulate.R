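test_that("simConfig rejects degenerate parameters", {
  expect_error(simConfig(n_markers = 3, n_chromosomes = 5), "n_chromosomes")
  expect_error(simConfig(maf_floor = 0.5), "maf_floor")
  expect_error(simConfig(divergence_F = 0), "divergence_F")
  expect_error(simConfig(subpop_split = c(a = 0.5, b = 0.4)), "sum to 1")
})

test_that("simulated genotypes are inbred, deterministic and respect the MAF floor", {
  g <- fix_geno()
  d <- dosages(g)
  expect_true(all(d %in% c(0, 2)))  # no heterozygous calls in inbred mode
  g2 <- simulateGenotypes(simConfig(n_genotypes = 100, n_markers = 1000,
                                    n_chromosomes = 2,
                                    chromosome_length_bp = 5e6, seed = 42))
  expect_identical(dosages(g), dosages(g2))
  f <- colMeans(d) / 2
  expect_gte(mean(pmin(f, 1 - f) >= 0.05), 0.99)
  mk <- markerInfo(g)
  expect_false(is.unsorted(mk$pos[mk$chrom == "chr1"]))
})

test_that("subpopulation frequency gap shrinks in the no-divergence limit", {
  gap_for_F <- function(F) {
    g <- simulateGenotypes(simConfig(n_genotypes = 200, n_markers = 400,
                                     n_chromosomes = 1, divergence_F = F,
                                     ld_block_bp = 0, seed = 5))
    labs <- subpopLabels(g)
    d <- dosages(g) / 2
    mean(abs(colMeans(d[labs == "tropical", ]) -
               colMeans(d[labs == "temperate", ])))
  }
  g_small <- gap_for_F(0.005)
  g_large <- gap_for_F(0.3)
  expect_lt(g_small, 0.06)     # dominated by binomial sampling noise
  expect_gt(g_large, 2 * g_small)
})

test_that("Balding-Nichols F is recovered by the per-site Weir-Cockerham oracle", {
  g <- simulateGenotypes(simConfig(n_genotypes = 200, n_markers = 6000,
                                   n_chromosomes = 2, divergence_F = 0.1,
                                   seed = 17))
  labs <- subpopLabels(g)
  al <- dosages(g) / 2
  comps <- vapply(seq_len(ncol(al)), function(j)
    wc_fst_oracle(al[labs == "tropical", j], al[labs == "temperate", j]),
    numeric(2))
  fst <- sum(comps["a", ]) / sum(comps["a", ] + comps["b", ])
  expect_lt(abs(fst - 0.1), 0.02)  # within sampling tolerance
})

test_that("plantSweep honours target gap, no-ops and boosts in-window Fst", {
  g <- fix_geno()
  region <- list(chrom = "chr1", start = 2e6, end = 2e6 + 99999)
  expect_identical(plantSweep(g, region, 0), g)
  empty <- list(chrom = "chr1", start = 4.99e6, end = 4.999e6)
  mkpos <- markerInfo(g)
  if (!any(mkpos$chrom == "chr1" & mkpos$pos >= empty$start &
             mkpos$pos <= empty$end)) {
    expect_warning(plantSweep(g, empty, 0.5), "no markers")
  }
  gs <- plantSweep(g, region, 0.9)
  labs <- subpopLabels(gs)
  d <- dosages(gs) / 2
  mk <- markerInfo(gs)
  inwin <- mk$chrom == "chr1" & mk$pos >= region$start & mk$pos <= region$end
  gapw <- abs(colMeans(d[labs == "tropical", inwin, drop = FALSE]) -
                colMeans(d[labs == "temperate", inwin, drop = FALSE]))
  expect_true(all(gapw >= 0.9))
  # outside untouched
  expect_identical(dosages(g)[, !inwin], dosages(gs)[, !inwin])
  # per-site Fst inside the window exceeds the genome background
  al <- d
  persite <- function(j) {
    cc <- wc_fst_oracle(al[labs == "tropical", j], al[labs == "temperate", j])
    cc["a"] / (cc["a"] + cc["b"])
  }
  fin <- vapply(which(inwin), persite, numeric(1))
  fout <- vapply(sample(which(!inwin), 200), persite, numeric(1))
  expect_gt(min(fin), quantile(fout, 0.99))
})

test_that("expression simulator hits target H2 and planted cis PVE", {
  g <- simulateGenotypes(simConfig(n_genotypes = 200,
                                   replicates_per_genotype = 3,
                                   n_markers = 200, n_chromosomes = 1,
                                   seed = 3))
  ## null gene: H2 = 0 means shuffling replicate labels changes nothing
  h2 <- setNames(c(0, 0.6), c("gnull", "gcis"))
  mk <- markerInfo(g)
  f <- colMeans(dosages(g)) / 2
  cm <- mk$id[which(pmin(f, 1 - f) > 0.3)[1]]
  tt <- truthTable(planted_cis = data.frame(gene = "gcis", marker = cm,
                                            pve = 0.4),
                   per_gene_target_h2 = h2)
  e <- simulateExpression(g, tt, replicates = 3, seed = 4)
  x <- log(fpkm(e))
  fit0 <- estimateH2(setNames(x[, "gnull"], rownames(x)), replicateMap(e))
  expect_lt(fit0$H2, 0.1)
  ## planted cis: OLS of genotype means on the causal marker recovers R2
  rmap <- replicateMap(e)
  gm <- tapply(x[, "gcis"], rmap, mean)[sampleIDs(g)]
  r2 <- summary(lm(gm ~ dosages(g)[, cm]))$r.squared
  expect_lt(abs(r2 - 0.4), 0.15)
  expect_error(truthTable(per_gene_target_h2 = c(g1 = 1.2)), "H2")
})

test_that("mean realized H2 tracks the target across many genes", {
  g <- simulateGenotypes(simConfig(n_genotypes = 150,
                                   replicates_per_genotype = 3,
                                   n_markers = 50, n_chromosomes = 1,
                                   seed = 9))
  h2 <- setNames(rep(0.5, 200), paste0("g", 1:200))
  e <- simulateExpression(g, truthTable(per_gene_target_h2 = h2),
                          replicates = 3, seed = 10)
  est <- estimateH2Matrix(e)$H2
  expect_lt(abs(mean(est) - 0.5), 0.07)
})

test_that("splicing counts give unbiased PSI, respond to planted sQTL, and propagate missingness", {
  g <- fix_geno()
  introns <- data.frame(intron = c("i1", "i2", "i3"), gene = "g1",
                        chrom = "chr1", start = 1000L,
                        end = 1000L + c(99L, 199L, 149L))
  rmap <- setNames(sampleIDs(g), sampleIDs(g))
  f <- colMeans(dosages(g)) / 2
  qm <- markerInfo(g)$id[which(pmin(f, 1 - f) > 0.3)[1]]
  tt <- truthTable(per_gene_target_h2 = c(g1 = 0.5),
                   planted_splice_qtl = data.frame(intron = "i2",
                                                   marker = qm, shift = 0.4))
  sq <- simulateSplicingCounts(g, introns, tt, rmap, base_psi = 0.95,
                               mean_coverage = 400, seed = 6)
  p <- psi(sq)
  ## large depth: mean PSI converges on the target
  expect_equal(mean(p[, "i1"], na.rm = TRUE), 0.95, tolerance = 0.03)
  ## planted shift separates the homozygous dosage classes
  dd <- dosages(g)[, qm]
  shift <- mean(p[dd == 2, "i2"], na.rm = TRUE) -
    mean(p[dd == 0, "i2"], na.rm = TRUE)
  expect_lt(abs(shift - 0.4), 0.12)
  ## no planted effect: PSI distributions equal across dosage classes
  ksp <- suppressWarnings(
    ks.test(p[dd == 2, "i1"], p[dd == 0, "i1"]))$p.value
  expect_gt(ksp, 0.01)
  ## zero coverage -> depth 0 -> missing PSI downstream
  sq0 <- simulateSplicingCounts(g, introns[1, ], tt, rmap,
                                coverage_rates = matrix(0, nSamples(g), 1),
                                seed = 1)
  expect_true(all(depths(sq0) == 0))
  expect_true(all(is.na(psi(sq0))))
  expect_error(simulateSplicingCounts(g, introns, tt, rmap,
                                      base_psi = -0.1), "negative")
})

test_that("organismal trait is positive, seeded, and null traits stay null in GWAS", {
  g <- fix_geno_indep()
  t1 <- simulateOrganismalTrait(g, seed = 5)
  t2 <- simulateOrganismalTrait(g, seed = 5)
  expect_identical(t1, t2)
  expect_true(all(t1 > 0))
  ## null trait: no marker passes Bonferroni
  sc <- lmScan(setNames(log(t1), names(t1)), g)
  expect_gt(min(sc$p, na.rm = TRUE), 0.05 / nMarkers(g))
  ## one large effect: the causal marker is the lead of the only peak
  f <- colMeans(dosages(g)) / 2
  cm <- markerInfo(g)$id[which(pmin(f, 1 - f) > 0.3)[1]]
  tb <- simulateOrganismalTrait(g, effects = data.frame(marker = cm,
                                                        beta = 2),
                                noise_sd = 0.5, seed = 8)
  scb <- lmScan(setNames(log(tb), names(tb)), g)
  expect_equal(scb$marker[which.min(scb$p)], cm)
})
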