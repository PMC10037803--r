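#' @import methods
#' @importFrom stats var sd median cor optimize pnorm pchisq pt qnorm rnorm
#'   runif rbinom rpois rbeta quantile p.adjust ks.test fisher.test kmeans
#'   complete.cases setNames aggregate phyper dbinom prcomp ecdf mad dnorm
#'   rgamma lm anova approx
#' @importFrom utils read.table write.table head tail
NULL

#' Genotype data for a panel of (inbred) lines
#'
#' Holds a samples x markers dosage matrix (count of alternate alleles, values
#' in \{0, 1, 2\} or `NA` for missing calls) together with marker coordinates
#' and optional subpopulation labels. Markers are kept sorted by
#' (chromosome, position); coordinates are 1-based.
#'
#' @slot dosage numeric matrix, samples in rows, markers in columns; values in
#'   \{0,1,2\} or `NA`. Row names are sample identifiers, column names marker
#'   identifiers.
#' @slot markers `data.frame` with one row per marker and columns
#'   `id`, `chrom`, `pos` (1-based bp), `ref`, `alt`.
#' @slot labels named character vector of subpopulation labels per sample
#'   (possibly empty).
#'
#' @seealso [GenotypeData()], [dosages()], [markerInfo()], [simulateGenotypes()]
#' @export
setClass("GenotypeData",
  slots = c(dosage = "matrix", markers = "data.frame", labels = "character"))

setValidity("GenotypeData", function(object) {
  d <- object@dosage
  mk <- object@markers
  msg <- character()
  need <- c("id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(mk)))
    msg <- c(msg, paste("markers must have columns:", paste(need, collapse = ", ")))
  else {
    if (ncol(d) != nrow(mk))
      msg <- c(msg, "ncol(dosage) must equal nrow(markers)")
    if (anyDuplicated(mk$id))
      msg <- c(msg, "marker ids must be unique")
    o <- order(mk$chrom, mk$pos)
    if (!identical(o, seq_len(nrow(mk))))
      msg <- c(msg, "markers must be sorted by (chrom, pos)")
  }
  bad <- d[!is.na(d)]
  if (length(bad) && !all(bad %in% c(0, 1, 2)))
    msg <- c(msg, "dosages must be in {0, 1, 2} or NA")
  if (is.null(rownames(d)))
    msg <- c(msg, "dosage must have sample row names")
  if (length(object@labels) && !all(rownames(d) %in% names(object@labels)))
    msg <- c(msg, "labels must be named by sample id and cover all samples")
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeData object
#'
#' @param dosage samples x markers matrix of alt-allele dosages (0/1/2/NA)
#'   with sample row names.
#' @param markers data.frame with columns `id`, `chrom`, `pos`, `ref`, `alt`.
#'   Rows are reordered to (chrom, pos) order; the dosage columns follow.
#' @param labels optional named character vector, sample -> subpopulation.
#' @return A [GenotypeData-class] object.
#' @export
GenotypeData <- function(dosage, markers, labels = character()) {
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  o <- order(markers$chrom, markers$pos)
  markers <- markers[o, , drop = FALSE]
  rownames(markers) <- NULL
  dosage <- as.matrix(dosage)[, o, drop = FALSE]
  colnames(dosage) <- markers$id
  new("GenotypeData", dosage = dosage, markers = markers,
      labels = as.character(labels) |> setNames(names(labels)))
}

#' Expression data with a replicate-to-genotype map
#'
#' FPKM-scale expression (samples x genes, nonnegative) plus the map from each
#' RNA-seq sample to the genotype (line) it was derived from. Replicated
#' genotypes are what make broad-sense heritability estimable.
#'
#' @slot fpkm numeric matrix, samples x genes, finite and >= 0, with sample
#'   row names and gene column names.
#' @slot replicateMap named character vector: sample id -> genotype id,
#'   covering every row of `fpkm`.
#' @seealso [ExpressionData()], [fpkm()], [replicateMap()]
#' @export
setClass("ExpressionData", slots = c(fpkm = "matrix", replicateMap = "character"))

setValidity("ExpressionData", function(object) {
  msg <- character()
  x <- object@fpkm
  if (is.null(rownames(x)) || is.null(colnames(x)))
    msg <- c(msg, "fpkm must have sample row names and gene column names")
  if (any(!is.finite(x)) || any(x < 0))
    msg <- c(msg, "fpkm values must be finite and nonnegative")
  if (!all(rownames(x) %in% names(object@replicateMap)))
    msg <- c(msg, "every sample must appear in replicateMap")
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionData object
#' @param fpkm samples x genes nonnegative matrix (FPKM scale).
#' @param replicateMap named character vector sample -> genotype.
#' @return An [ExpressionData-class] object.
#' @export
ExpressionData <- function(fpkm, replicateMap) {
  new("ExpressionData", fpkm = as.matrix(fpkm),
      replicateMap = replicateMap)
}

#' Intron splicing quantification (junction counts and coverage)
#'
#' Per-sample, per-intron uniquely-mapped junction read counts (`ucount`) and
#' summed per-base intronic read depth (`depth`), plus intron definitions.
#' Percent-spliced-in is derived as `ucount / (depth / size)` and is missing
#' where depth is zero; see [psi()].
#'
#' @slot ucount integer-valued matrix, samples x introns, >= 0.
#' @slot depth numeric matrix, samples x introns, >= 0 (summed per-base depth).
#' @slot introns `data.frame` with columns `intron`, `gene`, `chrom`,
#'   `start`, `end` (1-based inclusive), `size` (= end - start + 1).
#' @seealso [SpliceQuant()], [psi()], [computePsi()]
#' @export
setClass("SpliceQuant",
  slots = c(ucount = "matrix", depth = "matrix", introns = "data.frame"))

setValidity("SpliceQuant", function(object) {
  msg <- character()
  ii <- object@introns
  need <- c("intron", "gene", "chrom", "start", "end", "size")
  if (!all(need %in% names(ii)))
    msg <- c(msg, paste("introns must have columns:", paste(need, collapse = ", ")))
  else {
    if (any(ii$size < 1)) msg <- c(msg, "intron sizes must be >= 1")
    if (any(ii$size != ii$end - ii$start + 1))
      msg <- c(msg, "size must equal end - start + 1")
    if (ncol(object@ucount) != nrow(ii) || ncol(object@depth) != nrow(ii))
      msg <- c(msg, "count matrices must have one column per intron")
  }
  if (!identical(dim(object@ucount), dim(object@depth)))
    msg <- c(msg, "ucount and depth must have identical dimensions")
  if (any(object@ucount < 0, na.rm = TRUE) || any(object@depth < 0, na.rm = TRUE))
    msg <- c(msg, "counts and depths must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Construct a SpliceQuant object
#' @param ucount,depth samples x introns matrices (junction counts; summed
#'   per-base depth).
#' @param introns data.frame of intron definitions (`intron`, `gene`, `chrom`,
#'   `start`, `end`; `size` added if absent).
#' @return A [SpliceQuant-class] object.
#' @export
SpliceQuant <- function(ucount, depth, introns) {
  introns <- as.data.frame(introns, stringsAsFactors = FALSE)
  if (is.null(introns$size)) introns$size <- introns$end - introns$start + 1
  ucount <- as.matrix(ucount); depth <- as.matrix(depth)
  colnames(ucount) <- introns$intron
  colnames(depth) <- introns$intron
  new("SpliceQuant", ucount = ucount, depth = depth, introns = introns)
}
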