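#' Simulation configuration for a structured inbred panel
#'
#' Bundles and validates the parameters of the synthetic genotype generator.
#' Two diverged subpopulations are simulated under the Balding-Nichols model:
#' each marker has an ancestral allele frequency and per-subpopulation
#' frequencies drawn from a Beta distribution with divergence parameter `F`.
#'
#' @param n_genotypes number of inbred lines.
#' @param replicates_per_genotype RNA-seq replicates per line (>= 1).
#' @param n_markers number of biallelic SNPs.
#' @param n_chromosomes number of chromosomes.
#' @param chromosome_length_bp length of each chromosome in bp.
#' @param subpop_split named fractions per subpopulation (must sum to 1).
#' @param divergence_F Balding-Nichols F, in (0, 1).
#' @param maf_floor minimum ancestral minor-allele frequency (< 0.5).
#' @param ld_block_bp haplotype-block length in bp: markers within a block
#'   share a latent block haplotype and are in strong mutual LD
#'   (r-squared around `(1 - 2*ld_flip)^2`); 0 makes all markers
#'   independent.
#' @param ld_flip per-marker allele-copy error rate within a block
#'   (default 0.015).
#' @param seed integer seed controlling the whole fixture.
#' @return A validated list of class `"simConfig"`.
#' @export
simConfig <- function(n_genotypes = 200, replicates_per_genotype = 2,
                      n_markers = 5000, n_chromosomes = 5,
                      chromosome_length_bp = 1e7,
                      subpop_split = c(tropical = 0.5, temperate = 0.5),
                      divergence_F = 0.1, maf_floor = 0.05,
                      ld_block_bp = 5e4, ld_flip = 0.015, seed = 1L) {
  stopifnot(n_genotypes >= 2, replicates_per_genotype >= 1,
            n_markers >= 1, n_chromosomes >= 1, chromosome_length_bp >= 1)
  if (n_markers < n_chromosomes)
    stop("n_markers must be at least n_chromosomes")
  if (!(divergence_F > 0 && divergence_F < 1))
    stop("divergence_F must lie in the open interval (0, 1)")
  if (maf_floor >= 0.5)
    stop("maf_floor must be < 0.5")
  if (abs(sum(subpop_split) - 1) > 1e-8)
    stop("subpop_split fractions must sum to 1")
  if (is.null(names(subpop_split)))
    names(subpop_split) <- paste0("pop", seq_along(subpop_split))
  structure(list(n_genotypes = as.integer(n_genotypes),
                 replicates_per_genotype = as.integer(replicates_per_genotype),
                 n_markers = as.integer(n_markers),
                 n_chromosomes = as.integer(n_chromosomes),
                 chromosome_length_bp = as.integer(chromosome_length_bp),
                 subpop_split = subpop_split,
                 divergence_F = divergence_F,
                 maf_floor = maf_floor,
                 ld_block_bp = ld_block_bp, ld_flip = ld_flip,
                 seed = as.integer(seed)),
            class = "simConfig")
}

## Draw Balding-Nichols subpopulation frequencies around ancestral p.
.bnFreq <- function(p, F) {
  a <- p * (1 - F) / F
  b <- (1 - p) * (1 - F) / F
  rbeta(length(p), a, b)
}

#' Simulate inbred genotypes under two-subpopulation Balding-Nichols structure
#'
#' Lines are fully inbred: dosages are homozygous, in \{0, 2\}, with no
#' heterozygous calls. Markers are organised into haplotype blocks of
#' `ld_block_bp` bp: each block has one ancestral allele frequency,
#' per-subpopulation frequencies drawn Balding-Nichols with parameter
#' `divergence_F`, and one latent block allele per line; the block's
#' markers copy that allele with a small error rate `ld_flip`, creating
#' the strong local LD of real inbred panels while leaving blocks mutually
#' independent. Blocks whose realized minor-allele frequency falls below
#' `maf_floor` are redrawn (bounded number of rounds), so in practice
#' >= 99% of markers respect the floor.
#'
#' @param config a [simConfig()] object.
#' @return A [GenotypeData-class] with subpopulation labels attached.
#' @examples
#' g <- simulateGenotypes(simConfig(n_genotypes = 20, n_markers = 50, seed = 1))
#' table(dosages(g))  # only 0 and 2: inbred lines
#' @export
simulateGenotypes <- function(config) {
  stopifnot(inherits(config, "simConfig"))
  set.seed(config$seed)
  n <- config$n_genotypes
  m <- config$n_markers
  F <- config$divergence_F

  ## subpopulation assignment (deterministic blocks, not random)
  sizes <- round(config$subpop_split * n)
  sizes[length(sizes)] <- n - sum(sizes[-length(sizes)])
  pops <- rep(names(config$subpop_split), times = sizes)
  ids <- sprintf("line%03d", seq_len(n))
  labels <- setNames(pops, ids)

  ## marker map: roughly even split across chromosomes, unique sorted positions
  chrom_of <- sort(rep_len(seq_len(config$n_chromosomes), m))
  pos <- integer(m)
  for (cc in seq_len(config$n_chromosomes)) {
    k <- sum(chrom_of == cc)
    pos[chrom_of == cc] <- sort(sample.int(config$chromosome_length_bp, k))
  }
  chrom <- paste0("chr", chrom_of)
  markers <- data.frame(id = sprintf("snp_%s_%d", chrom, pos),
                        chrom = chrom, pos = pos,
                        ref = "A", alt = "T", stringsAsFactors = FALSE)

  popidx <- split(seq_len(n), pops)
  ## haplotype blocks: one latent BN-frequency allele per line per block,
  ## copied to each member marker with error rate ld_flip
  block <- if (config$ld_block_bp > 0)
    paste(chrom, (pos - 1) %/% config$ld_block_bp) else as.character(seq_len(m))
  blk <- split(seq_len(m), block)
  eps <- config$ld_flip
  lo <- max(0.5 * config$maf_floor + 0.1, config$maf_floor + 0.05)

  drawBlocks <- function(blocks) {
    d <- matrix(0, n, sum(lengths(blocks)))
    colidx <- split(seq_len(ncol(d)), rep(seq_along(blocks), lengths(blocks)))
    for (bi in seq_along(blocks)) {
      p_anc <- runif(1, lo, 1 - lo)
      h <- integer(n)
      for (pp in names(popidx)) {
        q <- .bnFreq(p_anc, F)
        h[popidx[[pp]]] <- rbinom(length(popidx[[pp]]), 1, q)
      }
      k <- length(blocks[[bi]])
      flip <- matrix(rbinom(n * k, 1, eps), n, k)
      d[, colidx[[bi]]] <- 2 * abs(h - flip)  # XOR: copy with error
    }
    d
  }

  dos <- matrix(0, n, m)
  dos[, unlist(blk)] <- drawBlocks(blk)
  for (round in 1:25) {
    f <- colMeans(dos) / 2
    badm <- pmin(f, 1 - f) < config$maf_floor
    if (sum(badm) <= max(0, floor(0.005 * m))) break
    badblk <- blk[vapply(blk, function(ii) any(badm[ii]), TRUE)]
    dos[, unlist(badblk)] <- drawBlocks(badblk)
  }
  rownames(dos) <- ids
  GenotypeData(dos, markers, labels = labels)
}

#' Plant a selective-sweep signal into a genomic window
#'
#' Resamples alleles for all markers inside `region` so that the
#' between-subpopulation allele-frequency difference is at least
#' `target_gap`, with the second subpopulation driven toward fixation
#' (emulating a completed sweep there, which also depresses its nucleotide
#' diversity). Markers outside the region are untouched.
#'
#' @param genotypes a [GenotypeData-class] with two subpopulation labels.
#' @param region list or vector with `chrom`, `start`, `end` (1-based bp).
#' @param target_gap required allele-frequency difference in `[0, 1]`.
#' @param swept_pop label of the subpopulation that experienced the sweep;
#'   default the second label.
#' @return A [GenotypeData-class] with the region's markers resampled.
#' @export
plantSweep <- function(genotypes, region, target_gap, swept_pop = NULL) {
  stopifnot(target_gap >= 0, target_gap <= 1)
  if (target_gap == 0) return(genotypes)
  mk <- markerInfo(genotypes)
  sel <- which(mk$chrom == region$chrom & mk$pos >= region$start &
                 mk$pos <= region$end)
  if (!length(sel)) {
    warning("no markers in sweep region; genotypes unchanged")
    return(genotypes)
  }
  labs <- subpopLabels(genotypes)
  pops <- unique(labs)
  stopifnot(length(pops) == 2)
  if (is.null(swept_pop)) swept_pop <- pops[2]
  other <- setdiff(pops, swept_pop)
  d <- dosages(genotypes)
  i_sw <- which(labs == swept_pop)
  i_ot <- which(labs == other)
  gap2 <- min(target_gap + 0.05, 0.99)  # margin absorbs binomial sampling noise
  for (j in sel) {
    for (try in 1:80) {
      up <- runif(1) < 0.5
      q_sw <- if (up) runif(1, 0.995, 1) else runif(1, 0, 0.005)
      q_ot <- if (up) q_sw - gap2 else q_sw + gap2
      a_sw <- rbinom(length(i_sw), 1, q_sw)
      a_ot <- rbinom(length(i_ot), 1, q_ot)
      if (abs(mean(a_sw) - mean(a_ot)) >= target_gap) break
    }
    d[i_sw, j] <- 2 * a_sw
    d[i_ot, j] <- 2 * a_ot
  }
  GenotypeData(d, mk, labels = genotypes@labels)
}

#' Assemble a ground-truth table for the expression simulator
#'
#' @param planted_cis data.frame with columns `gene`, `marker`, `pve`
#'   (target fraction of genotype-mean expression variance explained).
#' @param planted_trans data.frame with columns `gene`, `marker`, `effect`
#'   (effect per standardized dosage unit, genotype-level sd units).
#' @param planted_modules list of lists with fields `id`, `genes`, `driver`
#'   (marker id), and optional `share` (genotype-level variance share of the
#'   module factor in member genes, default 0.5).
#' @param per_gene_target_h2 named numeric vector of target broad-sense
#'   heritabilities in `[0, 1)`, one entry per simulated gene.
#' @param planted_sweeps data.frame with `chrom`, `start`, `end`, `gap`.
#' @param planted_splice_qtl data.frame with `intron`, `marker`, `shift`
#'   (PSI difference between the two homozygous dosage classes).
#' @return list of class `"truthTable"`.
#' @export
truthTable <- function(planted_cis = NULL, planted_trans = NULL,
                       planted_modules = list(), per_gene_target_h2,
                       planted_sweeps = NULL, planted_splice_qtl = NULL) {
  if (any(per_gene_target_h2 < 0 | per_gene_target_h2 >= 1))
    stop("target H2 values must lie in [0, 1)")
  structure(list(planted_cis = planted_cis, planted_trans = planted_trans,
                 planted_modules = planted_modules,
                 per_gene_target_h2 = per_gene_target_h2,
                 planted_sweeps = planted_sweeps,
                 planted_splice_qtl = planted_splice_qtl),
            class = "truthTable")
}

.stdDosage <- function(x) {
  s <- sd(x)
  if (s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Simulate replicated FPKM expression with planted regulatory architecture
#'
#' Per gene, a genotype-level genetic value (planted cis/trans marker effects,
#' an optional shared module factor driven by a module's driver marker, and a
#' polygenic residual) and replicate-level Gaussian noise are combined on the
#' log scale so that the genotype-level variance fraction equals the gene's
#' target broad-sense heritability, then exponentiated onto a nonnegative
#' FPKM-like scale (lognormal noise: FPKM is right-skewed and nonnegative).
#'
#' Planted cis effects are calibrated so that an OLS regression of
#' log genotype-mean expression on the causal marker has expected R-squared
#' equal to the stated `pve` (accounting for replicate averaging).
#'
#' @param genotypes a [GenotypeData-class]; one row per line.
#' @param truth a [truthTable()]; `per_gene_target_h2` names define the genes.
#' @param replicates replicates per genotype.
#' @param baseline_log mean log-FPKM (default `log(10)`).
#' @param scale_log sd of log-FPKM at the sample level (default 0.6).
#' @param seed optional integer seed.
#' @return An [ExpressionData-class] object; samples are named
#'   `<line>_r<rep>`.
#' @export
simulateExpression <- function(genotypes, truth, replicates = 2,
                               baseline_log = log(10), scale_log = 0.6,
                               seed = NULL) {
  stopifnot(inherits(truth, "truthTable"))
  if (!is.null(seed)) set.seed(seed)
  h2 <- truth$per_gene_target_h2
  if (any(h2 < 0 | h2 >= 1)) stop("target H2 values must lie in [0, 1)")
  genes <- names(h2)
  d <- dosages(genotypes)
  lines <- rownames(d)
  n <- length(lines)
  r <- replicates

  cisTab <- truth$planted_cis
  transTab <- truth$planted_trans
  .checkMarkers <- function(mm) {
    miss <- setdiff(mm, colnames(d))
    if (length(miss)) stop("truth references unknown markers: ",
                           paste(head(miss, 3), collapse = ", "))
  }
  if (!is.null(cisTab)) .checkMarkers(cisTab$marker)
  if (!is.null(transTab)) .checkMarkers(transTab$marker)

  ## shared module factors, standardized to genotype-level variance 1
  modFac <- list()
  for (mod in truth$planted_modules) {
    .checkMarkers(mod$driver)
    x <- d[, mod$driver]
    f <- mean(x) / 2
    minor <- if (f <= 0.5) x > 0 else x == 0
    raw <- as.numeric(minor) + 0.1 * rnorm(n)
    modFac[[mod$id]] <- (raw - mean(raw)) / sd(raw)
  }

  samples <- paste0(rep(lines, each = r), "_r", rep(seq_len(r), times = n))
  repmap <- setNames(rep(lines, each = r), samples)
  X <- matrix(0, length(samples), length(genes),
              dimnames = list(samples, genes))

  for (k in seq_along(genes)) {
    gname <- genes[k]
    h <- h2[k]
    var_fixed <- 0
    gval <- numeric(n)
    if (!is.null(cisTab)) {
      rows <- which(cisTab$gene == gname)
      for (ri in rows) {
        pve <- cisTab$pve[ri]
        ## expected genotype-mean variance, in genotype-level units of 1
        vbar <- if (h > 0) 1 + (1 - h) / (h * r) else Inf
        vb <- pve * vbar
        if (vb >= 1) stop("planted cis PVE ", pve, " infeasible for H2 ", h)
        gval <- gval + sqrt(vb) * .stdDosage(d[, cisTab$marker[ri]])
        var_fixed <- var_fixed + vb
      }
    }
    if (!is.null(transTab)) {
      rows <- which(transTab$gene == gname)
      for (ri in rows) {
        b <- transTab$effect[ri]
        gval <- gval + b * .stdDosage(d[, transTab$marker[ri]])
        var_fixed <- var_fixed + b^2
      }
    }
    for (mod in truth$planted_modules) {
      if (gname %in% mod$genes) {
        share <- if (is.null(mod$share)) 0.5 else mod$share
        sgn <- sample(c(-1, 1), 1)
        gval <- gval + sgn * sqrt(share) * modFac[[mod$id]]
        var_fixed <- var_fixed + share
      }
    }
    if (var_fixed > 1) stop("planted variance shares exceed 1 for gene ", gname)
    gval <- gval + sqrt(1 - var_fixed) * rnorm(n)
    z <- sqrt(h) * rep(gval, each = r) + sqrt(1 - h) * rnorm(n * r)
    X[, k] <- exp(baseline_log + scale_log * z)
  }
  ExpressionData(X, repmap)
}

#' Simulate intron junction counts and coverage with genotype-dependent PSI
#'
#' Counts are Poisson given latent per-base coverage rates: for intron `j`
#' and sample `s`, `depth ~ Pois(size_j * lambda_s)` and
#' `ucount ~ Pois(psi_target * lambda_s)`, so the expected percent-spliced-in
#' `ucount / (depth / size)` equals the genotype-dependent target. Planted
#' splicing QTLs shift the PSI target by `shift` between the two homozygous
#' dosage classes. Genes with zero coverage rate produce depth 0 and hence
#' missing PSI downstream.
#'
#' @param genotypes a [GenotypeData-class].
#' @param introns data.frame with `intron`, `gene`, `chrom`, `start`, `end`
#'   (sizes must be positive).
#' @param truth a [truthTable()] whose `planted_splice_qtl` is honoured.
#' @param replicateMap named character vector sample -> line (defines the
#'   output samples; e.g. `replicateMap(expr)`).
#' @param base_psi baseline PSI target; either a single value or one per
#'   intron. Must be nonnegative.
#' @param mean_coverage mean per-base coverage rate per sample.
#' @param coverage_rates optional samples x introns matrix of per-base
#'   coverage rates, overriding `mean_coverage` (zero rows model unexpressed
#'   genes).
#' @param seed optional integer seed.
#' @return A [SpliceQuant-class] object.
#' @export
simulateSplicingCounts <- function(genotypes, introns, truth,
                                   replicateMap, base_psi = 0.5,
                                   mean_coverage = 20, coverage_rates = NULL,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  introns <- as.data.frame(introns, stringsAsFactors = FALSE)
  if (is.null(introns$size)) introns$size <- introns$end - introns$start + 1
  if (any(introns$size <= 0)) stop("intron sizes must be positive")
  if (any(base_psi < 0)) stop("negative target PSI rejected")
  nI <- nrow(introns)
  psi0 <- rep_len(base_psi, nI)
  samples <- names(replicateMap)
  nS <- length(samples)
  d <- dosages(genotypes)

  ## genotype x intron PSI targets
  target <- matrix(rep(psi0, each = nS), nS, nI,
                   dimnames = list(samples, introns$intron))
  sq <- truth$planted_splice_qtl
  if (!is.null(sq)) {
    ## planted events referring to introns outside this subset are ignored
    sq <- sq[sq$intron %in% introns$intron, , drop = FALSE]
    for (ri in seq_len(nrow(sq))) {
      j <- match(sq$intron[ri], introns$intron)
      x <- d[replicateMap, sq$marker[ri]]
      target[, j] <- pmax(0, target[, j] + sq$shift[ri] * (x / 2))
    }
  }
  if (is.null(coverage_rates)) {
    ## gamma-distributed coverage rates: overdispersed but rarely near zero
    lam <- matrix(rgamma(nS * nI, shape = 4, scale = mean_coverage / 4),
                  nS, nI)
  } else {
    lam <- coverage_rates
    stopifnot(identical(dim(lam), c(nS, nI)))
  }
  size_m <- matrix(rep(introns$size, each = nS), nS, nI)
  depth <- matrix(rpois(nS * nI, size_m * lam), nS, nI,
                  dimnames = list(samples, introns$intron))
  uc <- matrix(rpois(nS * nI, target * lam), nS, nI,
               dimnames = list(samples, introns$intron))
  SpliceQuant(uc, depth, introns)
}

#' Simulate a positive-valued organismal phenotype
#'
#' The trait is `exp(linear predictor + Gaussian noise)` so that the standard
#' log transformation applied before GWAS is exactly defined. Marker effects
#' act per standardized dosage unit.
#'
#' @param genotypes a [GenotypeData-class]; the trait is per line.
#' @param effects data.frame with columns `marker`, `beta`; may be empty
#'   (pure-noise trait).
#' @param noise_sd sd of the Gaussian noise on the log scale.
#' @param baseline intercept on the log scale.
#' @param seed optional integer seed.
#' @return named numeric vector, one positive value per line.
#' @export
simulateOrganismalTrait <- function(genotypes, effects = NULL, noise_sd = 1,
                                    baseline = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- dosages(genotypes)
  eta <- rep(baseline, nrow(d))
  if (!is.null(effects) && nrow(effects)) {
    miss <- setdiff(effects$marker, colnames(d))
    if (length(miss)) stop("effects reference unknown markers: ",
                           paste(miss, collapse = ", "))
    for (ri in seq_len(nrow(effects)))
      eta <- eta + effects$beta[ri] * .stdDosage(d[, effects$marker[ri]])
  }
  setNames(exp(eta + noise_sd * rnorm(nrow(d))), rownames(d))
}

#' Candidate cis markers with adequate local tagging
#'
#' Markers within `dist` bp of a gene's start that are common
#' (MAF >= `maf_min`) and lie in a haplotype block carrying at least
#' `min_tagged` such markers. Planting effects at well-tagged markers
#' emulates dense real panels, where every causal variant has multiple
#' LD proxies; at desk-scale marker densities an effect planted in a
#' one-marker block would be undetectable under a multi-SNP peak-support
#' rule.
#'
#' @param genotypes a [GenotypeData-class].
#' @param gene one gene-model row (`chrom`, `start`).
#' @param dist search window around the gene start in bp (default 100 kb).
#' @param maf_min frequency floor (default 0.2).
#' @param block_bp haplotype block size used for the tagging count
#'   (default 50 kb, the generator's default block length).
#' @param min_tagged required common markers per block (default 3).
#' @return character vector of candidate marker ids (possibly empty).
#' @export
plantableCisMarkers <- function(genotypes, gene, dist = 1e5, maf_min = 0.2,
                                block_bp = 5e4, min_tagged = 3) {
  mk <- markerInfo(genotypes)
  f <- colMeans(dosages(genotypes), na.rm = TRUE) / 2
  common <- pmin(f, 1 - f) >= maf_min
  onchr <- mk$chrom == gene$chrom
  bin <- (mk$pos - 1) %/% block_bp
  tab <- table(bin[onchr & common])
  good <- as.numeric(names(tab)[tab >= min_tagged])
  sel <- onchr & common & abs(mk$pos - gene$start) < dist & bin %in% good
  mk$id[sel]
}

#' Simulate random gene models along the genome
#'
#' @param n_genes number of genes.
#' @param n_chromosomes,chromosome_length_bp genome layout.
#' @param gene_length_bp fixed gene span length.
#' @param gene_ids optional ids (default `gene0001`...).
#' @return data.frame with `gene`, `chrom`, `start`, `end`, `strand`.
#' @export
simulateGeneModels <- function(n_genes, n_chromosomes = 5,
                               chromosome_length_bp = 1e7,
                               gene_length_bp = 3000, gene_ids = NULL) {
  chrom <- paste0("chr", sort(rep_len(seq_len(n_chromosomes), n_genes)))
  start <- integer(n_genes)
  for (cc in unique(chrom)) {
    k <- sum(chrom == cc)
    start[chrom == cc] <- sort(sample.int(chromosome_length_bp - gene_length_bp, k))
  }
  if (is.null(gene_ids)) gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  data.frame(gene = gene_ids, chrom = chrom, start = as.integer(start),
             end = as.integer(start + gene_length_bp - 1),
             strand = sample(c("+", "-"), n_genes, replace = TRUE),
             stringsAsFactors = FALSE)
}

#' Simulate a complete synthetic study with known ground truth
#'
#' Convenience wrapper that builds genotypes (with one planted sweep window),
#' gene models, expression with planted cis effects and co-expression
#' modules, intron splicing counts with planted sQTLs, and one organismal
#' phenotype driven through a planted cis marker. The defaults define the
#' package's standard "small" study: 200 lines x 2 replicates, 5,000 markers
#' on 5 chromosomes, 2,000 genes, 500 introns, two equal subpopulations at
#' Balding-Nichols F = 0.1.
#'
#' @param config a [simConfig()].
#' @param n_genes,n_introns fixture sizes.
#' @param n_cis number of genes with a planted cis-eQTL (PVE `cis_pve`).
#' @param cis_pve target variance explained by each planted cis marker.
#' @param n_modules,module_size planted co-expression modules.
#' @param sweep_gap allele-frequency gap of the planted 100-kb sweep window.
#' @param n_splice_qtl introns given a planted sQTL (`splice_shift` PSI per
#'   homozygous class difference).
#' @param splice_shift PSI difference between homozygous dosage classes.
#' @return list with elements `genotypes`, `expression`, `splice`,
#'   `geneModels`, `phenotype`, `truth`, `config`.
#' @export
simulateStudy <- function(config = simConfig(),
                          n_genes = 2000, n_introns = 500,
                          n_cis = 50, cis_pve = 0.4,
                          n_modules = 3, module_size = 40,
                          sweep_gap = 0.9, n_splice_qtl = 25,
                          splice_shift = 0.3) {
  g <- simulateGenotypes(config)
  set.seed(config$seed + 1000L)
  mk <- markerInfo(g)

  sweep_start <- as.integer(0.45 * config$chromosome_length_bp)
  sweeps <- data.frame(chrom = "chr1", start = sweep_start,
                       end = sweep_start + 99999L, gap = sweep_gap)
  g <- plantSweep(g, sweeps[1, ], sweep_gap)

  genes <- simulateGeneModels(n_genes, config$n_chromosomes,
                              config$chromosome_length_bp)
  h2 <- setNames(runif(n_genes, 0.05, 0.8), genes$gene)

  d <- dosages(g)
  f <- colMeans(d) / 2
  maf <- pmin(f, 1 - f)
  common <- mk$id[maf >= 0.2]

  ## planted cis: a well-tagged common marker within 100 kb of each gene
  cis_genes <- sample(genes$gene, n_cis)
  cis_marker <- character(n_cis)
  keep <- logical(n_cis)
  for (i in seq_len(n_cis)) {
    gi <- genes[genes$gene == cis_genes[i], ]
    cand <- plantableCisMarkers(g, gi,
                                block_bp = max(config$ld_block_bp, 1))
    if (length(cand)) { cis_marker[i] <- sample(cand, 1); keep[i] <- TRUE }
  }
  cis <- data.frame(gene = cis_genes[keep], marker = cis_marker[keep],
                    pve = cis_pve, stringsAsFactors = FALSE)
  h2[cis$gene] <- 0.8

  ## planted modules: drivers at low minor-allele frequency (0.05-0.085) so
  ## the shared factor is a spiky two-point mixture and the per-sample
  ## component coefficients are strongly leptokurtic
  rare <- mk$id[maf >= 0.05 & maf <= 0.085]
  free <- setdiff(genes$gene, cis$gene)
  mods <- list()
  for (j in seq_len(n_modules)) {
    members <- sample(free, module_size)
    free <- setdiff(free, members)
    mods[[j]] <- list(id = paste0("module", j), genes = members,
                      driver = sample(rare, 1), share = 0.7)
    h2[members] <- 0.8
  }

  introns <- local({
    host <- sample(genes$gene, n_introns, replace = n_introns > n_genes)
    gi <- genes[match(host, genes$gene), ]
    size <- sample(80:500, n_introns, replace = TRUE)
    start <- gi$start + 200L
    data.frame(intron = sprintf("intron%04d", seq_len(n_introns)),
               gene = host, chrom = gi$chrom, start = start,
               end = start + size - 1L, size = size, stringsAsFactors = FALSE)
  })
  sq_idx <- sample(n_introns, n_splice_qtl)
  sqtl <- data.frame(intron = introns$intron[sq_idx],
                     marker = vapply(sq_idx, function(i) {
                       cand <- mk$id[mk$chrom == introns$chrom[i] &
                                       abs(mk$pos - introns$start[i]) < 1e5 &
                                       mk$id %in% common]
                       if (length(cand)) sample(cand, 1) else sample(common, 1)
                     }, character(1)),
                     shift = splice_shift, stringsAsFactors = FALSE)

  truth <- truthTable(planted_cis = cis, planted_trans = NULL,
                      planted_modules = mods, per_gene_target_h2 = h2,
                      planted_sweeps = sweeps, planted_splice_qtl = sqtl)

  expr <- simulateExpression(g, truth,
                             replicates = config$replicates_per_genotype,
                             seed = config$seed + 2000L)
  spl <- simulateSplicingCounts(g, introns, truth,
                                replicateMap = replicateMap(expr),
                                base_psi = runif(n_introns, 0.2, 0.8),
                                seed = config$seed + 3000L)
  pheno <- simulateOrganismalTrait(
    g, effects = data.frame(marker = cis$marker[1], beta = 1),
    noise_sd = 1, seed = config$seed + 4000L)

  list(genotypes = g, expression = expr, splice = spl, geneModels = genes,
       phenotype = pheno, truth = truth, config = config)
}
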