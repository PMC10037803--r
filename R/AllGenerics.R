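#' @name heritex-accessors
#' @title Accessors for heritex data classes
#' @description Accessor generics for [GenotypeData-class],
#'   [ExpressionData-class] and [SpliceQuant-class] objects.
#' @param x a heritex data object.
#' @return `dosages`, `fpkm`, `psi`, `ucounts`, `depths` return matrices;
#'   `markerInfo` and `intronInfo` data.frames; `sampleIDs` a character
#'   vector; `replicateMap` and `subpopLabels` named character vectors;
#'   `nSamples`/`nMarkers` integers.
NULL

#' @rdname heritex-accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))
#' @rdname heritex-accessors
#' @export
setGeneric("markerInfo", function(x) standardGeneric("markerInfo"))
#' @rdname heritex-accessors
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))
#' @rdname heritex-accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname heritex-accessors
#' @export
setGeneric("nMarkers", function(x) standardGeneric("nMarkers"))
#' @rdname heritex-accessors
#' @export
setGeneric("subpopLabels", function(x) standardGeneric("subpopLabels"))
#' @rdname heritex-accessors
#' @export
setGeneric("fpkm", function(x) standardGeneric("fpkm"))
#' @rdname heritex-accessors
#' @export
setGeneric("replicateMap", function(x) standardGeneric("replicateMap"))
#' @rdname heritex-accessors
#' @export
setGeneric("ucounts", function(x) standardGeneric("ucounts"))
#' @rdname heritex-accessors
#' @export
setGeneric("depths", function(x) standardGeneric("depths"))
#' @rdname heritex-accessors
#' @export
setGeneric("intronInfo", function(x) standardGeneric("intronInfo"))
#' @rdname heritex-accessors
#' @export
setGeneric("psi", function(x) standardGeneric("psi"))

#' @rdname heritex-accessors
#' @export
setMethod("dosages", "GenotypeData", function(x) x@dosage)
#' @rdname heritex-accessors
#' @export
setMethod("markerInfo", "GenotypeData", function(x) x@markers)
#' @rdname heritex-accessors
#' @export
setMethod("sampleIDs", "GenotypeData", function(x) rownames(x@dosage))
#' @rdname heritex-accessors
#' @export
setMethod("nSamples", "GenotypeData", function(x) nrow(x@dosage))
#' @rdname heritex-accessors
#' @export
setMethod("nMarkers", "GenotypeData", function(x) ncol(x@dosage))
#' @rdname heritex-accessors
#' @export
setMethod("subpopLabels", "GenotypeData", function(x) {
  if (!length(x@labels)) return(setNames(character(0), character(0)))
  x@labels[rownames(x@dosage)]
})
#' @rdname heritex-accessors
#' @export
setMethod("fpkm", "ExpressionData", function(x) x@fpkm)
#' @rdname heritex-accessors
#' @export
setMethod("replicateMap", "ExpressionData", function(x)
  x@replicateMap[rownames(x@fpkm)])
#' @rdname heritex-accessors
#' @export
setMethod("sampleIDs", "ExpressionData", function(x) rownames(x@fpkm))
#' @rdname heritex-accessors
#' @export
setMethod("ucounts", "SpliceQuant", function(x) x@ucount)
#' @rdname heritex-accessors
#' @export
setMethod("depths", "SpliceQuant", function(x) x@depth)
#' @rdname heritex-accessors
#' @export
setMethod("intronInfo", "SpliceQuant", function(x) x@introns)
#' @rdname heritex-accessors
#' @export
setMethod("sampleIDs", "SpliceQuant", function(x) rownames(x@ucount))

#' @rdname heritex-accessors
#' @export
setMethod("psi", "SpliceQuant", function(x) {
  size <- x@introns$size
  p <- sweep(x@ucount, 2, size, `*`) / x@depth
  p[x@depth == 0] <- NA_real_
  p
})

setMethod("show", "GenotypeData", function(object) {
  cat("GenotypeData:", nrow(object@dosage), "samples x",
      ncol(object@dosage), "markers\n")
  cat("  chromosomes:", paste(unique(object@markers$chrom), collapse = ", "), "\n")
  miss <- mean(is.na(object@dosage))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  if (length(object@labels))
    cat("  subpopulations:",
        paste(names(table(object@labels)), table(object@labels),
              sep = "=", collapse = ", "), "\n")
})

setMethod("show", "ExpressionData", function(object) {
  cat("ExpressionData:", nrow(object@fpkm), "samples x",
      ncol(object@fpkm), "genes (FPKM)\n")
  cat("  genotypes:", length(unique(object@replicateMap)), "\n")
})

setMethod("show", "SpliceQuant", function(object) {
  cat("SpliceQuant:", nrow(object@ucount), "samples x",
      nrow(object@introns), "introns\n")
  cat(sprintf("  median intron size: %.0f bp\n", median(object@introns$size)))
})

#' Subset a GenotypeData object
#' @param x a [GenotypeData-class] object.
#' @param i sample index (logical, integer or sample names).
#' @param j marker index (logical, integer or marker ids).
#' @param ... ignored.
#' @param drop ignored (always `FALSE` semantics).
#' @return A [GenotypeData-class] object.
#' @export
setMethod("[", "GenotypeData", function(x, i, j, ..., drop = FALSE) {
  d <- x@dosage
  mk <- x@markers
  if (!missing(j)) {
    if (is.character(j)) j <- match(j, mk$id)
    d <- d[, j, drop = FALSE]
    mk <- mk[j, , drop = FALSE]
    rownames(mk) <- NULL
  }
  if (!missing(i)) d <- d[i, , drop = FALSE]
  labs <- x@labels
  if (length(labs)) labs <- labs[names(labs) %in% rownames(d)]
  new("GenotypeData", dosage = d, markers = mk, labels = labs)
})
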