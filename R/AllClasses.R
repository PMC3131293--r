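#' @import methods
#' @importFrom stats var sd qnorm pnorm pt dnorm rbinom rnorm runif
#'   complete.cases lm fisher.test phyper t.test setNames cor integrate
#' @importFrom utils read.delim write.table
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importClassesFrom GenomicRanges GRanges
NULL

#' Paired two-condition expression container
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding
#' log2 expression measured on the same individuals under two conditions
#' (e.g. dexamethasone-treated and vehicle control aliquots of the same
#' lymphoblastoid cell line). Two assays named `"treated"` and `"control"`
#' are required, with one row per gene and one column per individual.
#'
#' @slot .. inherits all slots from `SummarizedExperiment`.
#' @seealso [PairedExpression()] for construction, [logFoldChange()],
#'   [pairMean()], [treatedExpr()], [controlExpr()].
#' @export
setClass("PairedExpression", contains = "SummarizedExperiment")

setValidity("PairedExpression", function(object) {
    a <- SummarizedExperiment::assayNames(object)
    if (!all(c("treated", "control") %in% a))
        return("assays must include 'treated' and 'control'")
    tr <- SummarizedExperiment::assay(object, "treated")
    ct <- SummarizedExperiment::assay(object, "control")
    if (!is.numeric(tr) || !is.numeric(ct))
        return("assays must be numeric matrices")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        return("individual (column) names must be present and unique")
    TRUE
})

#' Genotype dosage container
#'
#' Holds a SNP x individual dosage matrix together with SNP coordinates.
#' Dosages count copies of the *minor* allele (values 0, 1, 2 or `NA`);
#' [readGenotypes()] orients every SNP to its minor allele and records
#' whether the stored orientation was flipped relative to the file's ALT
#' allele.
#'
#' @slot dosages integer-valued matrix, SNPs x individuals, entries in
#'   \{0, 1, 2, NA\}.
#' @slot snps a [GenomicRanges::GRanges] of SNP positions (width 1,
#'   1-based as in VCF) with metadata columns `ref`, `alt` and `flipped`.
#' @slot population factor of population labels, one per individual (may
#'   have a single level when no population structure is known).
#' @export
setClass("GenotypeData",
    representation(dosages = "matrix", snps = "GRanges",
                   population = "factor"))

setValidity("GenotypeData", function(object) {
    d <- object@dosages
    if (nrow(d) != length(object@snps))
        return("nrow(dosages) must equal length(snps)")
    if (length(object@population) != ncol(d))
        return("one population label per individual required")
    bad <- d[!is.na(d)]
    if (length(bad) && !all(bad %in% 0:2))
        return("dosages must be 0, 1, 2 or NA")
    if (is.null(colnames(d)) || anyDuplicated(colnames(d)))
        return("individual (column) names must be present and unique")
    if (is.null(rownames(d)) || anyDuplicated(rownames(d)))
        return("SNP ids (rownames) must be present and unique")
    TRUE
})

#' Per-gene paired phenotype
#'
#' Per-gene vectors of treated and control log2 expression for one gene,
#' together with the derived difference `d = treated - control` (the log
#' fold change, the response phenotype) and average `m = (treated +
#' control)/2` coordinates. The (d, m) rotation is the coordinate system in
#' which the shared individual-level component loads only on `m`, so the
#' two blocks can be treated as independent regressions.
#'
#' @slot treated,control numeric vectors of per-individual log2 expression.
#' @slot diff,avg the derived difference and average vectors.
#' @seealso [makePaired()]
#' @export
setClass("PairedPhenotype",
    representation(treated = "numeric", control = "numeric",
                   diff = "numeric", avg = "numeric"))

setValidity("PairedPhenotype", function(object) {
    n <- length(object@treated)
    if (length(object@control) != n || length(object@diff) != n ||
        length(object@avg) != n)
        return("all four vectors must have equal length")
    if (n > 0) {
        ok <- is.finite(object@treated) & is.finite(object@control)
        if (any(abs(object@diff[ok] -
                    (object@treated[ok] - object@control[ok])) > 1e-8) ||
            any(abs(object@avg[ok] -
                    (object@treated[ok] + object@control[ok]) / 2) > 1e-8))
            return("diff/avg are not the linear transforms of treated/control")
    }
    TRUE
})

#' Shared permutation rounds for the frequentist scans
#'
#' Stores one reordering of individuals per permutation round. Within a
#' round the *same* reordering is applied to every gene, preserving the
#' correlation structure across genes in the empirical null.
#'
#' @slot perms integer matrix, one row per permutation round, each row a
#'   bijection of `seq_len(ncol)`.
#' @slot seed the integer seed the rounds were drawn from.
#' @export
setClass("PermutationNull",
    representation(perms = "matrix", seed = "integer"))

setValidity("PermutationNull", function(object) {
    p <- object@perms
    n <- ncol(p)
    for (i in seq_len(nrow(p)))
        if (!identical(sort(p[i, ]), seq_len(n)))
            return(sprintf("row %d is not a bijection of 1..%d", i, n))
    TRUE
})

#' @describeIn PairedExpression-class construct from two matrices
#' @param treated,control numeric matrices (genes x individuals) of log2
#'   expression with matching dimnames.
#' @param rowRanges optional [GenomicRanges::GRanges] of gene coordinates.
#' @param colData optional per-individual annotation (e.g. population).
#' @return a `PairedExpression` object.
#' @export
PairedExpression <- function(treated, control, rowRanges = NULL,
                             colData = NULL) {
    treated <- as.matrix(treated)
    control <- as.matrix(control)
    if (!identical(dim(treated), dim(control)))
        stop("treated and control matrices must have identical dimensions")
    if (!identical(colnames(treated), colnames(control)) ||
        !identical(rownames(treated), rownames(control)))
        stop("treated and control matrices must share dimnames")
    args <- list(assays = list(treated = treated, control = control))
    if (!is.null(rowRanges)) args$rowRanges <- rowRanges
    if (!is.null(colData)) args$colData <- colData
    se <- do.call(SummarizedExperiment::SummarizedExperiment, args)
    methods::new("PairedExpression", se)
}

#' @describeIn GenotypeData-class construct from a dosage matrix
#' @param dosages SNP x individual matrix over \{0,1,2,NA\}.
#' @param snps `GRanges` of SNP positions with `ref`, `alt` (and optionally
#'   `flipped`) metadata columns.
#' @param population optional per-individual population labels; defaults to
#'   a single population `"pop1"`.
#' @return a `GenotypeData` object.
#' @export
GenotypeData <- function(dosages, snps, population = NULL) {
    dosages <- as.matrix(dosages)
    if (is.null(population))
        population <- factor(rep("pop1", ncol(dosages)))
    population <- as.factor(population)
    if (is.null(S4Vectors::mcols(snps)$flipped))
        S4Vectors::mcols(snps)$flipped <- FALSE
    if (is.null(names(snps)) && !is.null(rownames(dosages)))
        names(snps) <- rownames(dosages)
    methods::new("GenotypeData", dosages = dosages, snps = snps,
                 population = population)
}

#' Bundle treated/control vectors into a paired phenotype
#'
#' @param treated,control numeric vectors of equal length; if both are
#'   named the names must match (pairing by individual id).
#' @return a [PairedPhenotype-class] with exact `diff` and `avg`.
#' @examples
#' p <- makePaired(c(2, 4), c(1, 2))
#' lfcValues(p)   # 1 2
#' avgValues(p)   # 1.5 3
#' @export
makePaired <- function(treated, control) {
    if (length(treated) != length(control))
        stop("treated and control must have equal length")
    if (!is.null(names(treated)) && !is.null(names(control)) &&
        !identical(names(treated), names(control)))
        stop("individual ids of treated and control do not match")
    methods::new("PairedPhenotype",
                 treated = as.numeric(treated), control = as.numeric(control),
                 diff = as.numeric(treated - control),
                 avg = as.numeric((treated + control) / 2))
}
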