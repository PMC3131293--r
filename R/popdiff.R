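#' Population-by-treatment interaction scan
#'
#' Differences in transcriptional response between populations manifest as
#' population differences in average expression that depend on treatment,
#' which is analogous to a genotype-by-treatment interaction. The same
#' Bayesian machinery is therefore applied with the population indicator
#' (coded 0/1) in place of the dosage: per gene, each condition is first
#' quantile-normalized across all individuals (both populations), the
#' five-model BFs are computed, and a separate EM over genes estimates the
#' population-level model proportions and per-gene posteriors.
#'
#' @param pe a [PairedExpression-class] (covariate-corrected).
#' @param population factor/vector with exactly two levels, one per
#'   individual (column of `pe`); at least 5 individuals per population.
#' @param priorSd effect-size prior grid, as in [snpModelLogBFs()].
#' @param normalize quantile-normalize per gene within condition first?
#' @param em_init,em_tol,em_max_iter EM settings, see [emFit()].
#' @return list with `posteriors` (per-gene data.frame including
#'   `direction` -- sign of the mean log fold change -- and `stronger_in`,
#'   the population with the larger mean response), `lgbf`, `pi`, `em`.
#' @export
popInteraction <- function(pe, population,
                           priorSd = c(1, 1.5, 2.25),
                           normalize = TRUE,
                           em_init = c(0.9, 0.04, 0.02, 0.02, 0.02),
                           em_tol = 1e-6, em_max_iter = 10000L) {
    pop <- as.factor(population)
    if (nlevels(pop) != 2)
        stop("exactly two populations required; got ", nlevels(pop))
    if (any(table(pop) < 5))
        stop("each population needs at least 5 individuals")
    x <- as.numeric(pop == levels(pop)[2])
    tr <- treatedExpr(pe); ct <- controlExpr(pe)
    G <- nrow(tr)
    lgbf <- matrix(NA_real_, G, 4,
                   dimnames = list(rownames(tr), c("M1", "M2", "M3", "M4")))
    betaT <- betaC <- rep(NA_real_, G)
    for (g in seq_len(G)) {
        yT <- tr[g, ]; yC <- ct[g, ]
        if (normalize) {
            yT <- quantileNormalizeToNormal(yT)
            yC <- quantileNormalizeToNormal(yC)
        }
        bf <- snpModelLogBFs(makePaired(yT, yC), x, priorSd = priorSd)
        if (is.na(bf$skip_reason)) {
            lgbf[g, ] <- c(bf$lbf1, bf$lbf2, bf$lbf3, bf$lbf4)
            betaT[g] <- bf$beta_T; betaC[g] <- bf$beta_C
        }
    }
    em <- emFit(lgbf, init = em_init, tol = em_tol, max_iter = em_max_iter)
    pp <- genePosteriors(lgbf, em$pi)
    d_mean <- rowMeans(tr - ct)
    d_by_pop <- cbind(rowMeans((tr - ct)[, x == 0, drop = FALSE]),
                      rowMeans((tr - ct)[, x == 1, drop = FALSE]))
    pp$direction <- ifelse(d_mean > 0, "up", "down")
    pp$stronger_in <- levels(pop)[max.col(d_by_pop * sign(d_mean))]
    pp$gene_id <- rownames(tr)
    list(posteriors = pp, lgbf = lgbf, pi = em$pi, em = em,
         beta_T = betaT, beta_C = betaC)
}

#' Tally response directions among population-different genes
#'
#' Among selected genes (population-different at a posterior threshold),
#' counts up- and down-regulated genes and, within the up-regulated ones,
#' the fraction whose response is stronger in a named population.
#'
#' @param posteriors the `posteriors` data.frame from [popInteraction()].
#' @param threshold PP_interaction selection cutoff.
#' @param population the population of interest (e.g. `"YRI"`).
#' @return list with `n_selected`, `n_up`, `n_down`,
#'   `frac_up_stronger_in`.
#' @export
directionTally <- function(posteriors, threshold = 0.7, population) {
    sel <- posteriors[!is.na(posteriors$PP_interaction) &
                      posteriors$PP_interaction > threshold, , drop = FALSE]
    if (!nrow(sel)) stop("no genes selected at threshold ", threshold)
    up <- sel$direction == "up"
    list(n_selected = nrow(sel), n_up = sum(up), n_down = sum(!up),
         frac_up_stronger_in =
             if (any(up)) mean(sel$stronger_in[up] == population)
             else NA_real_)
}

#' Genetic prediction of between-population response differences
#'
#' Under additivity and Hardy-Weinberg equilibrium within each population,
#' the expected between-population difference in mean response contributed
#' by an eQTN with per-copy effect `beta` is
#' `2 * beta * (f_pop1 - f_pop2)` (expected dosage difference times the
#' per-copy effect). Observed mean-response differences are regressed on
#' the predictions (with intercept) and the fit's r-squared and slope
#' p-value are returned.
#'
#' @param beta per-gene slope of the log fold change on dosage at the eQTN.
#' @param f_pop1,f_pop2 eQTN minor-allele frequency in each population.
#' @param observed observed per-gene difference in mean response
#'   (pop1 - pop2); optional -- omit to get predictions only.
#' @return list with `predicted` and, when `observed` is given, `r2`, `p`.
#' @export
predictPopDiff <- function(beta, f_pop1, f_pop2, observed = NULL) {
    stopifnot(all(f_pop1 >= 0 & f_pop1 <= 1),
              all(f_pop2 >= 0 & f_pop2 <= 1))
    pred <- 2 * beta * (f_pop1 - f_pop2)
    out <- list(predicted = pred)
    if (!is.null(observed)) {
        if (var(pred) == 0) {
            out$r2 <- NA_real_; out$p <- NA_real_
        } else {
            fit <- summary(lm(observed ~ pred))
            out$r2 <- fit$r.squared
            out$p <- fit$coefficients["pred", "Pr(>|t|)"]
        }
    }
    out
}

#' Enrichment odds ratio with Fisher exact test
#'
#' For a 2x2 table of counts (e.g. population-different gene? x has
#' interaction eQTL?): odds ratio from the cross product `(a d)/(b c)`,
#' with 0.5 added to every cell iff any cell is zero (reported); two-sided
#' Fisher exact p-value from the hypergeometric distribution of the
#' original counts.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return list with `odds_ratio`, `p`, `continuity` (whether 0.5 was
#'   added).
#' @export
enrichmentOR <- function(tab) {
    tab <- as.matrix(tab)
    stopifnot(identical(dim(tab), c(2L, 2L)), all(tab >= 0))
    cont <- any(tab == 0)
    t2 <- if (cont) tab + 0.5 else tab
    if (cont) message("zero cell: 0.5 added to every cell for the OR")
    or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
    p <- fisher.test(tab, alternative = "two.sided")$p.value
    list(odds_ratio = or, p = p, continuity = cont)
}
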