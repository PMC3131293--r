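#' Full Bayesian interaction-eQTL scan
#'
#' Runs the complete hierarchical pipeline: optional covariate
#' residualization, cis-window SNP assignment, per-SNP five-model Bayes
#' factors, SNP-averaged gene-level BFs, EM estimation of genome-wide model
#' proportions, per-gene posteriors and classification, eQTN selection, and
#' the Bayesian FDR at the requested posterior threshold.
#'
#' @param pe a [PairedExpression-class] (log2 scale).
#' @param geno a [GenotypeData-class] with the same individuals.
#' @param genes `GRanges` of gene bodies, one per row of `pe`, named by
#'   gene id.
#' @param window cis-window flank in bp.
#' @param covariates optional individuals x covariates matrix; both
#'   conditions are residualized per gene before the scan.
#' @param priorSd effect-size prior grid (units of the pooled
#'   per-condition phenotype sd).
#' @param posterior_threshold threshold for interaction calls.
#' @param em_init,em_tol,em_max_iter EM settings.
#' @param keep_snp_bfs keep the per-SNP BF tables (one per gene)?
#' @return list with `genes` (per-gene data.frame: gene BFs, posteriors,
#'   `best_model`, `eqtn`, `n_snps`), `pi`, `em`, `fdr`
#'   (at `posterior_threshold`), and optionally `snp_bfs`.
#' @export
bayesScan <- function(pe, geno, genes, window = 1e5, covariates = NULL,
                      priorSd = c(1, 1.5, 2.25),
                      posterior_threshold = 0.7,
                      em_init = c(0.9, 0.04, 0.02, 0.02, 0.02),
                      em_tol = 1e-6, em_max_iter = 10000L,
                      keep_snp_bfs = FALSE) {
    common <- intersect(colnames(pe), colnames(dosages(geno)))
    if (!length(common))
        stop("no overlapping individual ids between expression and genotypes")
    pe <- pe[, common]
    dos <- dosages(geno)[, common, drop = FALSE]
    if (!is.null(covariates))
        pe <- residualizeExpression(pe, covariates)
    cisMap <- mapCisSnps(genes, geno, window)
    tr <- treatedExpr(pe); ct <- controlExpr(pe)
    G <- nrow(tr)
    pos <- GenomicRanges::start(snpRanges(geno))
    lgbf <- matrix(NA_real_, G, 4,
                   dimnames = list(rownames(tr), c("M1", "M2", "M3", "M4")))
    n_snps <- integer(G)
    snp_tabs <- vector("list", G)
    for (g in seq_len(G)) {
        idx <- cisMap[[g]]
        if (!length(idx)) next
        tab <- geneSnpBFs(makePaired(tr[g, ], ct[g, ]),
                          dos[idx, , drop = FALSE], priorSd = priorSd)
        tab$pos <- pos[idx]
        snp_tabs[[g]] <- tab
        gbf <- geneBF(tab)
        if (!is.null(gbf)) lgbf[g, ] <- gbf
        n_snps[g] <- sum(is.na(tab$skip_reason))
    }
    em <- emFit(lgbf, init = em_init, tol = em_tol, max_iter = em_max_iter)
    pp <- genePosteriors(lgbf, em$pi)
    eq <- vapply(seq_len(G), function(g) {
        if (is.null(snp_tabs[[g]])) return(NA_character_)
        eqtn(snp_tabs[[g]], em$pi, positions = snp_tabs[[g]]$pos)
    }, character(1))
    res <- data.frame(gene_id = rownames(tr), lgbf, pp,
                      eqtn = eq, n_snps = n_snps,
                      stringsAsFactors = FALSE, row.names = NULL)
    fdr <- bayesianFDR(res$PP_interaction, posterior_threshold)
    out <- list(genes = res, pi = em$pi, em = em, fdr = fdr,
                posterior_threshold = posterior_threshold)
    if (keep_snp_bfs) out$snp_bfs <- snp_tabs
    out
}

#' Log-fold-change response-eQTL scan (frequentist comparator)
#'
#' Maps the log fold change of every gene against its cis-window SNPs by
#' simple OLS, taking the per-gene minimum p-value, and estimates FDR from
#' permutation rounds shared across genes.
#'
#' @inheritParams bayesScan
#' @param n_perms number of permutation rounds.
#' @param seed master seed for the rounds.
#' @return list with `results` (per-gene data.frame), `null_min_p`, and
#'   the [PermutationNull-class] used.
#' @export
lfcScan <- function(pe, geno, genes, window = 1e5, covariates = NULL,
                    n_perms = 100L, seed = 1L) {
    common <- intersect(colnames(pe), colnames(dosages(geno)))
    if (!length(common))
        stop("no overlapping individual ids between expression and genotypes")
    pe <- pe[, common]
    if (!is.null(covariates))
        pe <- residualizeExpression(pe, covariates)
    geno_sub <- GenotypeData(dosages(geno)[, common, drop = FALSE],
                             snpRanges(geno),
                             population = populations(geno)[
                                 match(common, colnames(dosages(geno)))])
    cisMap <- mapCisSnps(genes, geno_sub, window)
    perms <- permutationRounds(length(common), n_perms, seed = seed)
    sc <- scanLFC(logFoldChange(pe), geno_sub, cisMap, perms)
    c(sc, list(perms = perms))
}
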