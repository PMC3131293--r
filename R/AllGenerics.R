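#' @rdname PairedExpression-class
#' @param x,object a `PairedExpression` or `GenotypeData` object.
#' @export
setGeneric("treatedExpr", function(x) standardGeneric("treatedExpr"))

#' @rdname PairedExpression-class
#' @export
setGeneric("controlExpr", function(x) standardGeneric("controlExpr"))

#' @rdname PairedExpression-class
#' @export
setGeneric("logFoldChange", function(x) standardGeneric("logFoldChange"))

#' @rdname PairedExpression-class
#' @export
setGeneric("pairMean", function(x) standardGeneric("pairMean"))

#' @rdname GenotypeData-class
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname GenotypeData-class
#' @export
setGeneric("snpRanges", function(x) standardGeneric("snpRanges"))

#' @rdname GenotypeData-class
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))

#' @rdname PairedPhenotype-class
#' @param x a `PairedPhenotype`.
#' @export
setGeneric("treatedValues", function(x) standardGeneric("treatedValues"))

#' @rdname PairedPhenotype-class
#' @export
setGeneric("controlValues", function(x) standardGeneric("controlValues"))

#' @rdname PairedPhenotype-class
#' @export
setGeneric("lfcValues", function(x) standardGeneric("lfcValues"))

#' @rdname PairedPhenotype-class
#' @export
setGeneric("avgValues", function(x) standardGeneric("avgValues"))

#' @rdname PermutationNull-class
#' @param x a `PermutationNull`.
#' @export
setGeneric("permMatrix", function(x) standardGeneric("permMatrix"))

setMethod("treatedExpr", "PairedExpression", function(x)
    SummarizedExperiment::assay(x, "treated"))

setMethod("controlExpr", "PairedExpression", function(x)
    SummarizedExperiment::assay(x, "control"))

setMethod("logFoldChange", "PairedExpression", function(x)
    SummarizedExperiment::assay(x, "treated") -
        SummarizedExperiment::assay(x, "control"))

setMethod("pairMean", "PairedExpression", function(x)
    (SummarizedExperiment::assay(x, "treated") +
         SummarizedExperiment::assay(x, "control")) / 2)

setMethod("dosages", "GenotypeData", function(x) x@dosages)
setMethod("snpRanges", "GenotypeData", function(x) x@snps)
setMethod("populations", "GenotypeData", function(x) x@population)

setMethod("treatedValues", "PairedPhenotype", function(x) x@treated)
setMethod("controlValues", "PairedPhenotype", function(x) x@control)
setMethod("lfcValues", "PairedPhenotype", function(x) x@diff)
setMethod("avgValues", "PairedPhenotype", function(x) x@avg)

setMethod("permMatrix", "PermutationNull", function(x) x@perms)

setMethod("show", "GenotypeData", function(object) {
    cat("GenotypeData:", nrow(object@dosages), "SNPs x",
        ncol(object@dosages), "individuals\n")
    cat("  populations:",
        paste(sprintf("%s (%d)", levels(object@population),
                      tabulate(object@population)), collapse = ", "), "\n")
    cat("  missing dosages:", sum(is.na(object@dosages)), "\n")
    invisible(object)
})

setMethod("show", "PairedPhenotype", function(object) {
    cat("PairedPhenotype with", length(object@treated), "individuals",
        "(treated/control/diff/avg)\n")
    invisible(object)
})

setMethod("show", "PermutationNull", function(object) {
    cat("PermutationNull:", nrow(object@perms), "rounds x",
        ncol(object@perms), "individuals (seed", object@seed, ")\n")
    invisible(object)
})
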