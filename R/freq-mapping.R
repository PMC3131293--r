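## Two-sided p-value from a correlation on n observations (simple OLS
## slope t-test). Perfect fits are floored at 1e-300 rather than reported
## as zero.
.corP <- function(r, n) {
    df <- n - 2
    r2 <- pmin(r^2, 1)
    p <- ifelse(r2 >= 1 - 1e-14, 1e-300,
                2 * pt(-abs(r * sqrt(df) / sqrt(1 - r2)), df))
    pmax(p, 1e-300)
}

#' Differential-expression test on treatment
#'
#' Per gene, OLS of (normalized) expression on an intercept, the treatment
#' indicator and any measured covariates; the reported p-value is the
#' two-sided t-test on the treatment coefficient. All genes share the
#' design, so the fit is vectorized through one QR decomposition.
#'
#' @param expr genes x samples matrix (both conditions as separate
#'   samples, typically jointly quantile-normalized).
#' @param treatment 0/1 indicator per sample.
#' @param covariates optional samples x covariates matrix.
#' @return data.frame with per-gene `estimate`, `t`, `p`.
#' @export
deTest <- function(expr, treatment, covariates = NULL) {
    expr <- as.matrix(expr)
    n <- ncol(expr)
    if (length(unique(treatment)) < 2)
        stop("both conditions must be represented")
    X <- cbind("(Intercept)" = 1, treatment = as.numeric(treatment))
    if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
    qx <- qr(X)
    if (qx$rank < ncol(X))
        stop("rank-deficient design; collinear column(s): ",
             paste(colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]],
                   collapse = ", "))
    if (n <= ncol(X) + 1) stop("need samples > covariates + 2")
    XtXinv <- chol2inv(qr.R(qx))
    B <- expr %*% X %*% XtXinv
    R <- expr - B %*% t(X)
    df <- n - ncol(X)
    s2 <- rowSums(R^2) / df
    se <- sqrt(s2 * XtXinv[2, 2])
    tt <- ifelse(se > 0, B[, 2] / se, 0)
    p <- ifelse(se > 0, pmax(2 * pt(-abs(tt), df), 1e-300),
                ifelse(abs(B[, 2]) > 1e-12, 1e-300, 1))
    data.frame(estimate = B[, 2], t = tt, p = p,
               row.names = rownames(expr))
}

## Permutation-ratio FDR. For each observed value t:
##   FDR(t) = [mean over rounds of #{p_perm <= t}] / #{p_obs <= t},
## clipped to [0, 1] and made monotone non-decreasing in t by a cumulative
## maximum over the sorted observed values.
.permFDR <- function(obs, nullmat) {
    nullmat <- as.matrix(nullmat)
    P <- ncol(nullmat)
    ord <- order(obs)
    svals <- obs[ord]
    nullv <- sort(as.vector(nullmat))
    exp_null <- findInterval(svals, nullv) / P
    n_obs <- seq_along(svals)          # #{obs <= t} at each sorted obs
    fdr <- pmin(pmax(exp_null / pmax(1, n_obs), 0), 1)
    fdr <- cummax(fdr)
    out <- numeric(length(obs))
    out[ord] <- fdr
    out
}

#' Permutation-based FDR for differential-expression p-values
#'
#' Estimates the FDR at each observed p-value from the empirical null
#' distribution of p-values obtained with permuted sample labels:
#' `FDR(t) = mean_perm #\{p_perm <= t\} / #\{p_obs <= t\}`, clipped to
#' `[0, 1]` with monotonicity enforced by a cumulative maximum.
#'
#' @param obs_p observed per-gene p-values.
#' @param perm_p matrix of null p-values, genes x permutation rounds.
#' @return per-gene FDR estimates aligned to `obs_p`.
#' @export
deFDR <- function(obs_p, perm_p) {
    stopifnot(NCOL(perm_p) >= 1)
    .permFDR(obs_p, perm_p)
}

#' Simple association between response and dosage
#'
#' OLS slope and two-sided t-test p-value of the log fold change on the
#' dosage, complete cases only. p-values below numerical underflow are
#' floored at 1e-300.
#'
#' @param d log-fold-change vector.
#' @param x dosage vector.
#' @return list with `slope`, `p`, `n`; constant dosage gives `NA`s
#'   (SNP skipped).
#' @export
lfcAssoc <- function(d, x) {
    ok <- is.finite(d) & !is.na(x)
    n <- sum(ok)
    if (n < 5) stop("need at least 5 complete cases")
    d <- d[ok]; x <- as.numeric(x[ok])
    if (length(unique(x)) < 2)
        return(list(slope = NA_real_, p = NA_real_, n = n))
    r <- suppressWarnings(cor(d, x))
    if (is.na(r)) return(list(slope = 0, p = 1, n = n))
    slope <- r * sd(d) / sd(x)
    list(slope = slope, p = as.numeric(.corP(r, n)), n = n)
}

#' Shared permutation rounds
#'
#' Draws `n_perms` random reorderings of the individuals from a single
#' master seed. Every gene uses the same reordering within a round, so the
#' empirical null preserves the correlation structure across genes. Each
#' permutation reorders the genotype labels relative to the paired
#' phenotype rows; each individual keeps its own treated/control pair.
#'
#' @param n_individuals number of individuals.
#' @param n_perms number of rounds.
#' @param seed integer seed.
#' @return a [PermutationNull-class].
#' @export
permutationRounds <- function(n_individuals, n_perms, seed = 1L) {
    old <- .Random.seed.save()
    on.exit(.Random.seed.restore(old))
    set.seed(seed)
    perms <- t(vapply(seq_len(n_perms),
                      function(i) sample.int(n_individuals),
                      integer(n_individuals)))
    methods::new("PermutationNull", perms = perms, seed = as.integer(seed))
}

## Save/restore the global RNG state so seeded helpers do not perturb the
## caller's random stream.
.Random.seed.save <- function() {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv())
    else NULL
}
.Random.seed.restore <- function(old) {
    if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
}

#' Log-fold-change association scan with permutation FDR
#'
#' For every gene, tests each cis-window SNP against the gene's log fold
#' change, records the minimum p-value and top SNP, and estimates per-gene
#' FDR by comparing the observed min-p distribution with min-p
#' distributions from permutation rounds (the same reordering applied to
#' every gene within a round). Genes with an empty window are reported
#' with `NA`.
#'
#' @param lfc genes x individuals matrix of log fold changes (rows named).
#' @param geno a [GenotypeData-class] (or dosage matrix).
#' @param cisMap list of SNP indices per gene, e.g. from [mapCisSnps()];
#'   for a candidate-region or genome-wide scope pass the corresponding
#'   index list (all SNPs for every gene = genome-wide).
#' @param perms a [PermutationNull-class] over the individuals.
#' @return list with `results` (per-gene data.frame: `gene_id`,
#'   `top_snp_id`, `min_p`, `slope`, `n_snps_tested`, `fdr`) and
#'   `null_min_p` (genes x rounds matrix).
#' @export
scanLFC <- function(lfc, geno, cisMap, perms) {
    lfc <- as.matrix(lfc)
    dos <- if (methods::is(geno, "GenotypeData")) dosages(geno) else
        as.matrix(geno)
    stopifnot(ncol(lfc) == ncol(dos))
    pm <- permMatrix(perms)
    P <- nrow(pm)
    G <- nrow(lfc)
    genes <- if (!is.null(rownames(lfc))) rownames(lfc)
             else as.character(seq_len(G))
    res <- data.frame(gene_id = genes, top_snp_id = NA_character_,
                      min_p = NA_real_, slope = NA_real_,
                      n_snps_tested = 0L, fdr = NA_real_,
                      stringsAsFactors = FALSE)
    null_min_p <- matrix(NA_real_, G, P)
    for (g in seq_len(G)) {
        idx <- cisMap[[g]]
        if (!length(idx)) next
        X <- dos[idx, , drop = FALSE]
        keep <- apply(X, 1, function(v) length(unique(v[!is.na(v)])) > 1)
        idx <- idx[keep]
        if (!length(idx)) next
        X <- X[keep, , drop = FALSE]
        d <- lfc[g, ]
        D <- cbind(d, vapply(seq_len(P), function(r) d[pm[r, ]],
                             numeric(length(d))))
        n_pair <- crossprod(!is.na(t(X)), !is.na(D) * 1)
        r <- suppressWarnings(cor(t(X), D, use = "pairwise.complete.obs"))
        pv <- matrix(.corP(as.vector(r), as.vector(n_pair)),
                     nrow = nrow(r))
        mins <- apply(pv, 2, min, na.rm = TRUE)
        top <- which.min(pv[, 1])
        res$min_p[g] <- mins[1]
        res$top_snp_id[g] <- rownames(dos)[idx[top]]
        res$slope[g] <- lfcAssoc(d, dos[idx[top], ])$slope
        res$n_snps_tested[g] <- length(idx)
        null_min_p[g, ] <- mins[-1]
    }
    tested <- !is.na(res$min_p)
    if (any(tested))
        res$fdr[tested] <- .permFDR(res$min_p[tested],
                                    null_min_p[tested, , drop = FALSE])
    list(results = res, null_min_p = null_min_p)
}

#' Secretion QTL scan
#'
#' Identical machinery to [scanLFC()] with proteins in place of genes:
#' tests SNPs within a window of each protein-coding gene against the
#' (latent-factor-corrected) log fold change in secretion.
#'
#' @param secretion_lfc proteins x individuals matrix of secretion log fold
#'   changes.
#' @param geno a [GenotypeData-class].
#' @param proteinGenes `GRanges` of the encoding genes, one per protein row.
#' @param window cis window in bp (default 100 kb).
#' @param perms a [PermutationNull-class].
#' @return as [scanLFC()].
#' @export
secretionQTL <- function(secretion_lfc, geno, proteinGenes, window = 1e5,
                         perms) {
    cisMap <- mapCisSnps(proteinGenes, geno, window)
    scanLFC(secretion_lfc, geno, cisMap, perms)
}
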