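#' Gene-level Bayes factors from SNP-level Bayes factors
#'
#' Under the hierarchical model's at-most-one-eQTL-per-gene assumption with
#' a uniform prior over which window SNP is causal, the gene's marginal
#' likelihood is the SNP-averaged mixture, so the gene-level BF for each
#' model is the arithmetic mean over usable SNPs of that model's SNP BFs
#' (computed stably on the log scale).
#'
#' @param snp_bfs data.frame from [geneSnpBFs()] (columns `lbf1`..`lbf4`;
#'   skipped SNPs are dropped).
#' @return named numeric vector `c(M1=, M2=, M3=, M4=)` of log10 gene BFs,
#'   or `NULL` when the gene has no usable SNP.
#' @export
geneBF <- function(snp_bfs) {
    use <- snp_bfs[is.na(snp_bfs$skip_reason), , drop = FALSE]
    if (!nrow(use)) return(NULL)
    L <- as.matrix(use[, c("lbf1", "lbf2", "lbf3", "lbf4")])
    out <- apply(L, 2, .log10MeanExp)
    names(out) <- c("M1", "M2", "M3", "M4")
    out
}

#' EM estimation of genome-wide model proportions
#'
#' Fits the mixture proportions pi = (pi0..pi4) of genes following each of
#' the five models by maximum likelihood, treating the gene-level BFs as
#' the per-gene likelihood ratios (BF(M0) = 1 by definition). E-step:
#' responsibilities `r_g(M) = pi_M BF_g(M) / sum_M' pi_M' BF_g(M')`;
#' M-step: `pi_M = mean_g r_g(M)`. The observed-data log-likelihood
#' `sum_g log sum_M pi_M BF_g(M)` is non-decreasing at every iteration.
#' Any proportion hitting exactly zero is floored at 1e-8 and the vector
#' renormalized.
#'
#' @param lgbf matrix of log10 gene-level BFs, genes x 4 (M1..M4); genes
#'   with any non-finite entry are dropped with a message.
#' @param init initial proportions (length 5, simplex). The default is
#'   null-heavy, reflecting that most genes have no cis signal.
#' @param tol convergence tolerance on the log-likelihood increase.
#' @param max_iter iteration cap.
#' @return list with `pi` (named length-5 vector), `loglik` (trace),
#'   `iterations`, `converged`.
#' @export
emFit <- function(lgbf, init = c(0.9, 0.04, 0.02, 0.02, 0.02),
                  tol = 1e-6, max_iter = 10000L) {
    lgbf <- as.matrix(lgbf)
    stopifnot(ncol(lgbf) == 4, length(init) == 5, all(init >= 0))
    keep <- apply(is.finite(lgbf), 1, all)
    if (!all(keep)) {
        message(sum(!keep), " gene(s) with undefined BFs excluded from EM")
        lgbf <- lgbf[keep, , drop = FALSE]
    }
    if (nrow(lgbf) < 2) stop("need at least 2 genes with finite BFs")
    L <- cbind(0, lgbf) * log(10)   # natural-log BFs, M0 column = 0
    pi <- init / sum(init)
    trace <- numeric(0)
    ll_prev <- -Inf
    converged <- FALSE
    floored <- FALSE
    for (it in seq_len(max_iter)) {
        lw <- sweep(L, 2, log(pi), "+")
        lse <- .rowLogSumExp(lw)
        ll <- sum(lse)
        trace <- c(trace, ll)
        r <- exp(lw - lse)
        pi_new <- colMeans(r)
        if (any(pi_new < 1e-8)) {
            if (!floored) message("EM proportion floored at 1e-8")
            floored <- TRUE
            pi_new <- pmax(pi_new, 1e-8)
            pi_new <- pi_new / sum(pi_new)
        }
        pi <- pi_new
        if (it > 1 && ll - ll_prev < tol) { converged <- TRUE; break }
        ll_prev <- ll
    }
    names(pi) <- modelIds()
    list(pi = pi, loglik = trace, iterations = length(trace),
         converged = converged)
}

#' Per-gene posterior probabilities over the five models
#'
#' `PP_g(M) = pi_M BF_g(M) / sum_M' pi_M' BF_g(M')` with BF(M0) = 1.
#' `PP_interaction = PP(M2) + PP(M3) + PP(M4)`; `best_model` is the argmax
#' posterior among M1..M4 (ties broken in model order), matching the
#' hierarchical logic in which a strong single-SNP general-interaction BF
#' can still be outweighed by a small genome-wide prior.
#'
#' @param lgbf matrix of log10 gene BFs, genes x 4 (M1..M4).
#' @param pi model proportions (length 5, e.g. from [emFit()]).
#' @return data.frame with `PP0`..`PP4`, `PP_interaction`, `best_model`;
#'   genes with non-finite BFs get `NA` rows.
#' @export
genePosteriors <- function(lgbf, pi) {
    lgbf <- as.matrix(lgbf)
    stopifnot(ncol(lgbf) == 4, length(pi) == 5,
              abs(sum(pi) - 1) < 1e-6, all(pi >= 0))
    L <- cbind(0, lgbf) * log(10)
    lw <- sweep(L, 2, log(pi), "+")
    lw[, pi == 0] <- -Inf
    ok <- apply(is.finite(lgbf), 1, all)
    pp <- matrix(NA_real_, nrow(lgbf), 5)
    if (any(ok)) {
        lse <- .rowLogSumExp(lw[ok, , drop = FALSE])
        pp[ok, ] <- exp(lw[ok, , drop = FALSE] - lse)
    }
    colnames(pp) <- paste0("PP", 0:4)
    best <- rep(NA_character_, nrow(lgbf))
    best[ok] <- modelIds()[-1][apply(pp[ok, 2:5, drop = FALSE], 1,
                                     which.max)]
    out <- data.frame(pp, PP_interaction = rowSums(pp[, 3:5, drop = FALSE]),
                      best_model = best, stringsAsFactors = FALSE)
    rownames(out) <- rownames(lgbf)
    out
}

#' Bayesian FDR for a posterior-probability threshold
#'
#' Among genes whose posterior probability exceeds `threshold`, the
#' estimated false discovery rate is the mean posterior probability of
#' *not* belonging to the selected class, `mean(1 - PP)`. Applies equally
#' to `PP_interaction` (interaction calls) and to `PP1` (no-interaction
#' eQTL calls).
#'
#' @param pp vector of posterior probabilities (NA entries are dropped).
#' @param threshold selection cutoff in (0, 1).
#' @return list with `n_selected` and `fdr` (`NA` when nothing selected).
#' @export
bayesianFDR <- function(pp, threshold = 0.7) {
    stopifnot(threshold > 0, threshold < 1)
    pp <- pp[!is.na(pp)]
    sel <- pp > threshold
    n <- sum(sel)
    list(n_selected = n, fdr = if (n) mean(1 - pp[sel]) else NA_real_)
}

#' The eQTN: the most strongly associated SNP of a gene
#'
#' Scores every usable SNP by its prior-weighted total alternative-model
#' support `sum_{M=1..4} pi_M BF_s(M)` and returns the maximizer; ties go
#' to the smallest genomic position.
#'
#' @param snp_bfs data.frame from [geneSnpBFs()].
#' @param pi model proportions.
#' @param positions optional numeric positions aligned to `snp_bfs` rows
#'   (used for tie-breaking; defaults to row order).
#' @return the `snp_id` of the eQTN, or `NA` if no SNP is usable.
#' @export
eqtn <- function(snp_bfs, pi, positions = NULL) {
    use <- which(is.na(snp_bfs$skip_reason))
    if (!length(use)) return(NA_character_)
    if (is.null(positions)) positions <- seq_len(nrow(snp_bfs))
    L <- as.matrix(snp_bfs[use, c("lbf1", "lbf2", "lbf3", "lbf4")]) * log(10)
    lw <- sweep(L, 2, log(pi[2:5]), "+")
    lw[, pi[2:5] == 0] <- -Inf
    score <- .rowLogSumExp(lw)
    best <- use[order(-score, positions[use])[1]]
    as.character(snp_bfs$snp_id[best])
}

#' SNP-level interaction Bayes factor
#'
#' The prior-weighted Bayes factor for the interaction models (M2-M4)
#' against the non-interaction models (M0-M1):
#' `[sum_{M in 2:4} pi_M BF(M) / (pi2+pi3+pi4)] /
#'  [(pi0 + pi1 BF(M1)) / (pi0+pi1)]`.
#' Used for the SNP-level analysis that relaxes the one-eQTL-per-gene
#' assumption of the hierarchical model.
#'
#' @param lbf named or positional vector of log10 BFs `(M1, M2, M3, M4)`.
#' @param pi model proportions (length 5).
#' @return the interaction BF (natural scale).
#' @export
snpInteractionBF <- function(lbf, pi) {
    stopifnot(length(lbf) == 4, length(pi) == 5)
    if (sum(pi[3:5]) <= 0 || sum(pi[1:2]) <= 0)
        stop("both the interaction and non-interaction prior mass must be positive")
    l <- as.numeric(lbf) * log(10)
    num <- log(sum(pi[3:5] * exp(l[2:4] - max(l[2:4])))) + max(l[2:4]) -
        log(sum(pi[3:5]))
    den <- log(pi[1] + pi[2] * exp(l[1])) - log(pi[1] + pi[2])
    exp(num - den)
}

#' Select genes at a target Bayesian FDR
#'
#' Orders genes by decreasing posterior probability and selects the largest
#' set whose estimated FDR (the running mean of `1 - PP`) does not exceed
#' `target`. This is the posterior-based analogue of thresholding a
#' permutation FDR, and makes the two pipelines comparable at a matched
#' nominal FDR.
#'
#' @param pp vector of posterior probabilities (`NA` treated as 0).
#' @param target FDR target in (0, 1).
#' @return logical selection vector aligned to `pp`.
#' @export
selectAtFDR <- function(pp, target = 0.1) {
    stopifnot(target > 0, target < 1)
    pp[is.na(pp)] <- 0
    o <- order(-pp)
    cf <- cumsum(1 - pp[o]) / seq_along(o)
    n <- max(c(0L, which(cf <= target)))
    sel <- logical(length(pp))
    if (n > 0) sel[o[seq_len(n)]] <- TRUE
    sel
}
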