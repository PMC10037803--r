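#' Run the full analysis pipeline from a single configuration
#'
#' Orchestrates the stages end-to-end: synthetic-data generation (or
#' loading of user files), expression heritability, PSI quantification,
#' eQTL and sQTL mapping, eQTL-sQTL colocalization, ICA module discovery,
#' and the two-population selective-sweep scan. Each enabled stage writes a
#' TSV into `out_dir` and a `manifest.json` records parameters, the seed,
#' package and R versions, and the MD5 checksum of every output, so a rerun
#' with the same configuration reproduces byte-identical tables.
#'
#' @param config list or path to a YAML file. Recognized fields:
#'   `out_dir` (required), `seed` (default 1), `stages` (character subset
#'   of `c("h2","psi","eqtl","sqtl","coloc","ica","sweep")`; default all),
#'   `sim` (list of [simConfig()]/[simulateStudy()] overrides), and
#'   `thresholds` (`alpha`, `cis_window`, `gap_max`, `min_snps`,
#'   `max_peaks`, `min_beta_sqtl`, `kurtosis_min`, `cluster_min`,
#'   `membership_fdr`, `coloc_r2`, `decile`).
#' @return invisibly, a list with the stage results and the manifest.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$out_dir)) stop("config error: out_dir is required")
  stages <- config$stages %||%
    c("h2", "psi", "eqtl", "sqtl", "coloc", "ica", "sweep")
  seed <- config$seed %||% 1L
  thr <- config$thresholds %||% list()
  alpha <- thr$alpha %||% 0.05
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  simargs <- config$sim %||% list()
  cfgargs <- simargs[intersect(names(simargs), names(formals(simConfig)))]
  cfgargs$seed <- seed
  stuargs <- simargs[intersect(names(simargs), names(formals(simulateStudy)))]
  study <- do.call(simulateStudy,
                   c(list(config = do.call(simConfig, cfgargs)), stuargs))
  writeFixtureSet(study, file.path(config$out_dir, "fixture"))

  results <- list(study = study)
  wr <- function(df, name) {
    path <- file.path(config$out_dir, name)
    df2 <- df
    if (!is.null(df2$members)) df2$members <- NULL
    write.table(format(df2, digits = 10), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    path
  }
  written <- character(0)

  ## shared substrate: genotype-level Box-Cox e-traits + PCs
  expr <- study$expression
  g <- study$genotypes
  rmap <- replicateMap(expr)
  gmeans <- rowsum(fpkm(expr), rmap) / as.vector(table(rmap))
  gmeans <- gmeans[sampleIDs(g), , drop = FALSE]
  pcs <- computePCs(g, k = 5)
  bonf <- bonferroniThreshold(alpha, nMarkers(g))

  if ("h2" %in% stages) {
    h2tab <- estimateH2Matrix(expr)
    written["h2"] <- wr(h2tab, "heritability.tsv")
    results$h2 <- h2tab
  }

  etraits <- NULL
  if (any(c("eqtl", "ica", "coloc") %in% stages)) {
    sel <- if (!is.null(results$h2))
      results$h2$gene[results$h2$H2 > 0.05] else colnames(gmeans)
    etraits <- apply(log(gmeans[, sel, drop = FALSE] + 1e-8), 2,
                     function(y) boxcoxTransform(y)$transformed)
    rownames(etraits) <- rownames(gmeans)
  }

  if ("eqtl" %in% stages) {
    eq <- mapQtl(etraits, g, covariates = pcs, threshold = bonf$p,
                 geneModels = study$geneModels,
                 max_peaks = thr$max_peaks %||% 10,
                 gap_max = thr$gap_max %||% 1e6,
                 min_snps = thr$min_snps %||% 3,
                 cis_window = thr$cis_window %||% 1e6)
    written["eqtl"] <- wr(eq, "eqtl_peaks.tsv")
    results$eqtl <- eq
  }

  psiG <- NULL
  if (any(c("psi", "sqtl", "coloc") %in% stages)) {
    pmat <- psi(study$splice)
    written["psi"] <- wr(data.frame(sample = rownames(pmat), pmat,
                                    check.names = FALSE), "psi_matrix.tsv")
    keep <- filterSTraits(study$splice)
    psiG <- apply(pmat[, keep, drop = FALSE], 2, function(x)
      tapply(x, rmap, mean, na.rm = TRUE))[sampleIDs(g), , drop = FALSE]
    results$psi <- pmat
    results$straits <- keep
  }

  if ("sqtl" %in% stages && length(results$straits)) {
    tg <- setNames(intronInfo(study$splice)$gene,
                   intronInfo(study$splice)$intron)
    sq <- mapQtl(psiG, g, covariates = pcs, threshold = bonf$p,
                 geneModels = study$geneModels, trait_gene = tg,
                 min_beta = thr$min_beta_sqtl %||% 0.05,
                 max_peaks = thr$max_peaks %||% 10)
    sq$gene <- unname(tg[sq$trait])
    written["sqtl"] <- wr(sq, "sqtl_peaks.tsv")
    results$sqtl <- sq
  }

  if ("coloc" %in% stages && !is.null(results$eqtl) &&
      !is.null(results$sqtl)) {
    cl <- colocLeadSnps(results$eqtl, results$sqtl, g,
                        r2_min = thr$coloc_r2 %||% 0.6)
    written["coloc"] <- wr(cl, "colocalization.tsv")
    results$coloc <- cl
  }

  if ("ica" %in% stages) {
    h2v <- if (!is.null(results$h2))
      setNames(results$h2$H2, results$h2$gene)
    else setNames(estimateH2Matrix(expr)$H2, colnames(fpkm(expr)))
    zx <- log(fpkm(expr) + 1e-8)
    icagenes <- selectIcaGenes(expr, h2v, sd_min = 1.0)
    M <- t(scale(zx[, icagenes, drop = FALSE]))  # genes x samples, per-gene std
    k <- min(nComponentsForVariance(M, 0.80), nrow(M) - 1, ncol(M) - 1)
    dec <- runIca(M, k, seed = seed)
    filt <- filterComponents(dec,
                             kurtosis_min = thr$kurtosis_min %||% 6,
                             cluster_min = thr$cluster_min %||% 10)
    mem <- assignModuleMembership(dec,
                                  filt$component[filt$retained],
                                  fdr_max = thr$membership_fdr %||% 0.01)
    written["ica"] <- wr(filt, "ica_components.tsv")
    memdf <- do.call(rbind, lapply(names(mem), function(ic)
      if (length(mem[[ic]])) data.frame(component = ic, gene = mem[[ic]])))
    if (!is.null(memdf)) written["ica_members"] <- wr(memdf, "ica_members.tsv")
    results$ica <- list(decomposition = dec, filter = filt, members = mem)
  }

  if ("sweep" %in% stages) {
    map <- uniformGeneticMap(markerInfo(g), cM_per_Mb = 1)
    fst <- windowedFst(g)
    pw <- windowPi(g)
    xp <- xpclrScan(g, map = map, s_grid_size = thr$s_grid_size %||% 20,
                    max_snps = thr$max_snps %||% 30)
    wt <- combineWindowStats(fst, xp, pw, decile = thr$decile %||% 0.90)
    cand <- sweepCandidateGenes(wt, study$geneModels)
    written["sweep"] <- wr(wt, "sweep_windows.tsv")
    written["sweep_genes"] <- wr(data.frame(gene = cand),
                                 "sweep_candidate_genes.tsv")
    results$sweep <- list(windows = wt, candidates = cand)
  }

  manifest <- list(
    seed = seed, stages = stages, parameters = thr,
    sim = simargs,
    versions = list(heritex = as.character(utils::packageVersion("heritex")),
                    R = paste(R.version$major, R.version$minor, sep = ".")),
    outputs = as.list(tools::md5sum(unname(written[!is.na(written)]))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}

#' Uniform-rate genetic map over a marker set
#'
#' Builds a genetic map with a constant recombination rate, anchored at the
#' observed ends of each chromosome.
#'
#' @param markers marker data.frame (`chrom`, `pos`).
#' @param cM_per_Mb recombination rate (default 1).
#' @return data.frame `chrom`, `bp`, `cM`.
#' @export
uniformGeneticMap <- function(markers, cM_per_Mb = 1) {
  do.call(rbind, lapply(unique(markers$chrom), function(cc) {
    p <- markers$pos[markers$chrom == cc]
    bp <- c(min(p), max(p))
    data.frame(chrom = cc, bp = bp, cM = (bp - bp[1]) / 1e6 * cM_per_Mb)
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
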