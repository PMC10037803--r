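## Shared fixtures, built once per test run and cached.
.fix_cache <- new.env(parent = emptyenv())

fix_cached <- function(name, builder) {
  if (!exists(name, envir = .fix_cache)) {
    assign(name, builder(), envir = .fix_cache)
  }
  get(name, envir = .fix_cache)
}

## structured two-subpopulation panel, moderate size
fix_geno <- function() fix_cached("geno", function()
  simulateGenotypes(simConfig(n_genotypes = 100, n_markers = 1000,
                              n_chromosomes = 2,
                              chromosome_length_bp = 5e6, seed = 42)))

## independent markers (no LD blocks), for null-calibration checks
fix_geno_indep <- function() fix_cached("geno_indep", function()
  simulateGenotypes(simConfig(n_genotypes = 100, n_markers = 400,
                              n_chromosomes = 2,
                              chromosome_length_bp = 5e6,
                              ld_block_bp = 0, seed = 43)))

## small full study with planted truth
fix_study <- function() fix_cached("study", function()
  simulateStudy(simConfig(n_genotypes = 120, n_markers = 2500,
                          n_chromosomes = 3, chromosome_length_bp = 6e6,
                          replicates_per_genotype = 2, seed = 7),
                n_genes = 300, n_introns = 80, n_cis = 12,
                n_modules = 1, module_size = 15, n_splice_qtl = 6))

## genotype-level trait means on the Box-Cox scale for a study
study_etraits <- function(study, genes = NULL) {
  e <- study$expression
  rmap <- replicateMap(e)
  gm <- rowsum(fpkm(e), rmap) / as.vector(table(rmap))
  gm <- gm[sampleIDs(study$genotypes), , drop = FALSE]
  if (!is.null(genes)) gm <- gm[, genes, drop = FALSE]
  Y <- apply(log(gm + 1e-8), 2, function(y) boxcoxTransform(y)$transformed)
  rownames(Y) <- rownames(gm)
  Y
}

## independent per-site Weir-Cockerham oracle (haploid samples), direct
## transcription of the ANOVA component formulas
wc_fst_oracle <- function(alleles1, alleles2) {
  n1 <- sum(!is.na(alleles1)); n2 <- sum(!is.na(alleles2))
  p1 <- mean(alleles1, na.rm = TRUE); p2 <- mean(alleles2, na.rm = TRUE)
  r <- 2; nT <- n1 + n2
  nc <- (nT - (n1^2 + n2^2) / nT) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / nT
  msp <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / (r - 1)
  msg <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (nT - r)
  a <- (msp - msg) / nc
  c(a = a, b = msg)
}
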