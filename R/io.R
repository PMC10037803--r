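#' Load a genotype matrix from a VCF file
#'
#' Reads a VCF (4.x) with GT fields into a [GenotypeData-class]. Only
#' biallelic SNP records are kept; multi-allelic records are skipped with a
#' warning reporting their count. Dosage is the count of alternate alleles;
#' `./.` calls become `NA`. Sample order in the matrix equals the VCF header
#' order; coordinates stay 1-based.
#'
#' @param path path to a VCF file (plain or gzipped).
#' @param labels optional named character vector of subpopulation labels.
#' @return A [GenotypeData-class] object.
#' @export
loadGenotypes <- function(path, labels = character()) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  biall <- !grepl(",", alt) & nchar(ref) == 1 & nchar(alt) == 1
  nskip <- sum(!biall)
  if (nskip) warning(nskip, " multi-allelic/non-SNP record(s) skipped in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")[biall, , drop = FALSE]
  ## count alt alleles, any separator or ploidy representation
  dose <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  dose[clean == "0/0"] <- 0
  dose[clean %in% c("0/1", "1/0")] <- 1
  dose[clean == "1/1"] <- 2
  dose[clean == "0"] <- 0
  dose[clean == "1"] <- 2
  ids <- fix[biall, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[biall, "CHROM"], "_", fix[biall, "POS"])[noid]
  markers <- data.frame(id = ids, chrom = fix[biall, "CHROM"],
                        pos = as.integer(fix[biall, "POS"]),
                        ref = ref[biall], alt = alt[biall],
                        stringsAsFactors = FALSE)
  GenotypeData(t(dose), markers, labels = labels)
}

#' Write genotypes to a plain-text VCF 4.2 file
#'
#' Inbred-friendly writer: dosage 0 -> `0/0`, 1 -> `0/1`, 2 -> `1/1`,
#' `NA` -> `./.`.
#'
#' @param genotypes a [GenotypeData-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGenotypesVCF <- function(genotypes, path) {
  mk <- markerInfo(genotypes)
  d <- dosages(genotypes)
  gt <- matrix("./.", ncol(d), nrow(d))
  td <- t(d)
  gt[td == 0] <- "0/0"; gt[td == 1] <- "0/1"; gt[td == 2] <- "1/1"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=heritex",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(d)), collapse = "\t")), con)
  body <- cbind(mk$chrom, mk$pos, mk$id, mk$ref, mk$alt, ".", "PASS", ".",
                "GT", gt)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read / write a numeric sample-by-feature TSV matrix
#'
#' Header row carries feature ids; first column the sample ids. Orientation
#' is samples x features on disk (one row per sample).
#'
#' @param x numeric matrix with dimnames.
#' @param path file path.
#' @return `readMatrixTSV` returns a numeric matrix; `writeMatrixTSV`
#'   returns `path` invisibly.
#' @export
writeMatrixTSV <- function(x, path) {
  df <- data.frame(sample = rownames(x), x, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMatrixTSV
#' @export
readMatrixTSV <- function(path) {
  if (!file.exists(path)) stop("matrix TSV not found: ", path)
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Read / write gene models as BED (0-based half-open)
#'
#' Internal coordinates are 1-based inclusive; conversion is explicit here
#' (`start0 = start - 1`) so round-trips are exact.
#'
#' @param geneModels data.frame with `gene`, `chrom`, `start`, `end`,
#'   `strand` (1-based inclusive).
#' @param path file path.
#' @return `readGeneModelsBED` returns the data.frame form;
#'   `writeGeneModelsBED` returns `path` invisibly.
#' @export
writeGeneModelsBED <- function(geneModels, path) {
  bed <- data.frame(geneModels$chrom, geneModels$start - 1L, geneModels$end,
                    geneModels$gene, 0L, geneModels$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeGeneModelsBED
#' @export
readGeneModelsBED <- function(path) {
  if (!file.exists(path)) stop("BED not found: ", path)
  bed <- read.table(path, header = FALSE, sep = "\t",
                    stringsAsFactors = FALSE)
  data.frame(gene = bed[[4]], chrom = bed[[1]], start = bed[[2]] + 1L,
             end = bed[[3]], strand = if (ncol(bed) >= 6) bed[[6]] else "+",
             stringsAsFactors = FALSE)
}

#' Write a complete fixture set to a directory
#'
#' Emits every artefact of a synthetic study in plain-text exchange formats:
#' genotypes as VCF 4.2, expression / splicing / phenotype / label tables as
#' TSV, gene models and planted sweep windows as BED, and the ground-truth
#' table as JSON. All files round-trip losslessly through the package
#' readers.
#'
#' @param study a list as returned by [simulateStudy()].
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
writeFixtureSet <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(name) file.path(dir, name)
  out <- c(vcf = wr("genotypes.vcf"))
  writeGenotypesVCF(study$genotypes, out["vcf"])

  out["expression"] <- wr("expression_fpkm.tsv")
  writeMatrixTSV(fpkm(study$expression), out["expression"])
  out["replicate_map"] <- wr("replicate_map.tsv")
  rm_df <- data.frame(sample = names(replicateMap(study$expression)),
                      genotype = unname(replicateMap(study$expression)))
  write.table(rm_df, out["replicate_map"], sep = "\t", quote = FALSE,
              row.names = FALSE)

  out["ucount"] <- wr("splice_ucount.tsv")
  writeMatrixTSV(ucounts(study$splice), out["ucount"])
  out["depth"] <- wr("splice_depth.tsv")
  writeMatrixTSV(depths(study$splice), out["depth"])
  out["introns"] <- wr("introns.tsv")
  write.table(intronInfo(study$splice), out["introns"], sep = "\t",
              quote = FALSE, row.names = FALSE)

  out["genes"] <- wr("gene_models.bed")
  writeGeneModelsBED(study$geneModels, out["genes"])

  out["labels"] <- wr("subpopulations.tsv")
  labs <- subpopLabels(study$genotypes)
  write.table(data.frame(sample = names(labs), subpop = unname(labs)),
              out["labels"], sep = "\t", quote = FALSE, row.names = FALSE)

  out["phenotype"] <- wr("phenotype.tsv")
  write.table(data.frame(genotype = names(study$phenotype),
                         value = unname(study$phenotype)),
              out["phenotype"], sep = "\t", quote = FALSE, row.names = FALSE)

  if (!is.null(study$truth$planted_sweeps)) {
    out["sweeps"] <- wr("planted_sweeps.bed")
    sw <- study$truth$planted_sweeps
    write.table(data.frame(sw$chrom, sw$start - 1L, sw$end, "sweep", sw$gap),
                out["sweeps"], sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }

  out["truth"] <- wr("truth.json")
  tt <- study$truth
  jsonlite::write_json(
    list(planted_cis = tt$planted_cis, planted_trans = tt$planted_trans,
         planted_modules = lapply(tt$planted_modules, function(m)
           list(id = m$id, genes = m$genes, driver = m$driver,
                share = if (is.null(m$share)) 0.5 else m$share)),
         per_gene_target_h2 = as.list(tt$per_gene_target_h2),
         planted_sweeps = tt$planted_sweeps,
         planted_splice_qtl = tt$planted_splice_qtl),
    out["truth"], auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out)
}

#' Read a ground-truth JSON written by [writeFixtureSet()]
#' @param path path to `truth.json`.
#' @return a [truthTable()].
#' @export
readTruthJSON <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  mods <- j$planted_modules
  if (is.data.frame(mods))
    mods <- lapply(seq_len(nrow(mods)), function(i)
      list(id = mods$id[i], genes = unlist(mods$genes[i]),
           driver = mods$driver[i], share = mods$share[i]))
  truthTable(planted_cis = j$planted_cis, planted_trans = j$planted_trans,
             planted_modules = if (is.null(mods)) list() else mods,
             per_gene_target_h2 = unlist(j$per_gene_target_h2),
             planted_sweeps = j$planted_sweeps,
             planted_splice_qtl = j$planted_splice_qtl)
}
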