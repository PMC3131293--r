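#' Quantile-normalize a vector to standard normal scores
#'
#' Maps the value of rank r (1-based, ties receiving their average rank) to
#' `qnorm((r - 0.5) / n)`. The output depends on the input only through its
#' ranks, so it is invariant under any strictly monotone transform; it is
#' used both pooled across all samples before differential-expression
#' testing and per gene across individuals for the population contrast.
#'
#' @param x numeric vector with at least two finite values.
#' @return numeric vector of normal scores, same order and names as `x`.
#' @examples
#' quantileNormalizeToNormal(c(5, 1, 9))  # 0  qnorm(1/6)  qnorm(5/6)
#' @export
quantileNormalizeToNormal <- function(x) {
    if (sum(is.finite(x)) < 2)
        stop("need at least two finite values")
    if (length(unique(x[is.finite(x)])) == 1L)
        stop("all values identical; no ranking possible")
    r <- rank(x, ties.method = "average", na.last = "keep")
    out <- qnorm((r - 0.5) / sum(!is.na(r)))
    names(out) <- names(x)
    out
}

#' Normalize a paired expression object
#'
#' Two modes, matching the two uses of normal-scores normalization in the
#' workflow: `"joint"` pools every measurement (all genes, both conditions,
#' all individuals) into one ranking, as done before differential-expression
#' testing; `"per-gene"` normalizes each gene's vector across individuals,
#' separately within each condition, as done before the between-population
#' contrast.
#'
#' @param x a [PairedExpression-class].
#' @param mode `"joint"` or `"per-gene"`.
#' @return a `PairedExpression` of normal scores.
#' @export
normalizeExpression <- function(x, mode = c("joint", "per-gene")) {
    mode <- match.arg(mode)
    tr <- treatedExpr(x); ct <- controlExpr(x)
    if (mode == "joint") {
        all <- c(tr, ct)
        qn <- quantileNormalizeToNormal(all)
        tr[] <- qn[seq_along(tr)]
        ct[] <- qn[length(tr) + seq_along(ct)]
    } else {
        for (g in seq_len(nrow(tr))) {
            tr[g, ] <- quantileNormalizeToNormal(tr[g, ])
            ct[g, ] <- quantileNormalizeToNormal(ct[g, ])
        }
    }
    PairedExpression(tr, ct,
                     colData = SummarizedExperiment::colData(x))
}

## Validate a covariate design and return the full-rank [1 | Z] matrix.
.covDesign <- function(n, covariates) {
    if (is.null(covariates) || NCOL(covariates) == 0)
        return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
    Z <- as.matrix(covariates)
    if (anyNA(Z)) stop("covariates contain missing values")
    if (nrow(Z) != n) stop("covariate rows do not match phenotype length")
    X <- cbind("(Intercept)" = 1, Z)
    q <- qr(X)
    if (q$rank < ncol(X)) {
        drop <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
        stop("rank-deficient design; collinear column(s): ",
             paste(drop, collapse = ", "))
    }
    X
}

#' Remove covariate effects by OLS residualization
#'
#' Regresses `y` on an intercept plus the covariate columns and returns the
#' residuals (mean zero, orthogonal to every covariate). Downstream
#' regressions refit their own intercepts, so centering loses nothing.
#'
#' @param y numeric response vector.
#' @param covariates numeric matrix/data.frame (individuals x covariates),
#'   or `NULL` for intercept-only (returns `y - mean(y)`).
#' @return residual vector, same length and names as `y`.
#' @export
residualize <- function(y, covariates = NULL) {
    n <- length(y)
    X <- .covDesign(n, covariates)
    if (n <= ncol(X)) stop("need more observations than regressors")
    out <- as.numeric(qr.resid(qr(X), y))
    names(out) <- names(y)
    out
}

#' Residualize both conditions of a paired expression object
#'
#' Applies [residualize()] gene by gene to the treated and control vectors
#' separately. Covariates that shift baseline expression in both conditions
#' (EBV copy number, growth rate, mitochondrial copy number) are removed
#' without touching the pairing structure.
#'
#' @param x a [PairedExpression-class].
#' @param covariates individuals x covariates matrix, rows in column order
#'   of `x` (or named by individual).
#' @return a residualized `PairedExpression`.
#' @export
residualizeExpression <- function(x, covariates) {
    Z <- as.matrix(covariates)
    if (!is.null(rownames(Z))) {
        if (!all(colnames(x) %in% rownames(Z)))
            stop("covariate table missing individual(s): ",
                 paste(setdiff(colnames(x), rownames(Z)), collapse = ", "))
        Z <- Z[colnames(x), , drop = FALSE]
    }
    X <- .covDesign(ncol(x), Z)
    qx <- qr(X)
    tr <- t(qr.resid(qx, t(treatedExpr(x))))
    ct <- t(qr.resid(qx, t(controlExpr(x))))
    dimnames(tr) <- dimnames(ct) <- dimnames(treatedExpr(x))
    PairedExpression(tr, ct, colData = SummarizedExperiment::colData(x))
}

#' Correct secretion levels for a shared latent factor
#'
#' Protein secretion levels are strongly correlated across proteins,
#' reflecting a latent factor that affects overall secretion. Each protein
#' row is replaced by its residuals from an OLS regression on the secretion
#' levels of all other measured proteins (plus an intercept).
#'
#' @param mat numeric matrix, proteins x individuals, log2 scale.
#' @param min_level optional per-protein minimum mean level; proteins below
#'   it are dropped before correction (low-signal filter, default off).
#' @return corrected matrix of the same shape (minus dropped proteins).
#' @export
correctSecretion <- function(mat, min_level = NULL) {
    mat <- as.matrix(mat)
    if (!is.null(min_level))
        mat <- mat[rowMeans(mat, na.rm = TRUE) >= min_level, , drop = FALSE]
    p <- nrow(mat); n <- ncol(mat)
    if (p < 3) stop("need at least 3 proteins")
    if (p - 1 + 1 >= n)
        stop("more regressors (", p - 1, " proteins + intercept) than ",
             "individuals (", n, ")")
    out <- mat
    for (i in seq_len(p)) {
        X <- cbind(1, t(mat[-i, , drop = FALSE]))
        out[i, ] <- as.numeric(qr.resid(qr(X), mat[i, ]))
    }
    out
}
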