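## ---- internal numeric helpers ------------------------------------------

## log10 of the mean of values given on log10 scale, stable for large values
.log10MeanExp <- function(l10) {
    m <- max(l10)
    if (!is.finite(m)) return(m)
    m + log10(mean(10 ^ (l10 - m)))
}

## row-wise logsumexp (natural log) for a matrix
.rowLogSumExp <- function(L) {
    m <- do.call(pmax, as.data.frame(L))
    m + log(rowSums(exp(L - m)))
}

## log10 Bayes factor for one Gaussian regression coefficient with known
## residual precision tau and N(0, W) prior, from sufficient statistics.
## V = 1/(tau * Sxx), z = bhat/sqrt(V):
##   BF = sqrt(V/(V+W)) * exp(z^2/2 * W/(V+W))
.lbfStats <- function(Sxx, Sxy, tau, W) {
    V <- 1 / (tau * Sxx)
    bhat <- Sxy / Sxx
    z2 <- bhat^2 / V
    (0.5 * log(V / (V + W)) + 0.5 * z2 * W / (V + W)) / log(10)
}

#' Model identifiers
#'
#' The five competing models relating a SNP (or any two-level predictor) to
#' paired two-condition phenotypes: `M0` no association in either
#' condition; `M1` association with the same effect in both conditions;
#' `M2` effect in treated samples only; `M3` effect in control samples
#' only; `M4` effects in both conditions that differ.
#'
#' @return character vector of the five model names.
#' @export
modelIds <- function() c("M0", "M1", "M2", "M3", "M4")

#' Plug-in residual precisions for the difference and average blocks
#'
#' The paired phenotypes are rotated to difference `d` and average `m`
#' coordinates; the shared individual component loads only on `m`, so the
#' two blocks are modelled as independent Gaussian regressions. Each
#' block's residual precision is estimated once from the residuals of its
#' regression on `[1, x]` (the richest marginal design) and shared across
#' all five models, keeping every Bayes factor closed-form.
#'
#' @param pheno a [PairedPhenotype-class].
#' @param x dosage vector (no missing values; subset to complete cases
#'   first).
#' @return list with elements `tau_d` and `tau_m` (precisions; variance
#'   denominator n - 2).
#' @export
blockPrecisions <- function(pheno, x) {
    d <- lfcValues(pheno); m <- avgValues(pheno)
    n <- length(d)
    if (n < 5) stop("need at least 5 complete cases")
    if (length(unique(x)) < 2) stop("dosage vector is constant")
    xc <- x - mean(x)
    res_var <- function(y) {
        yc <- y - mean(y)
        b <- sum(xc * yc) / sum(xc^2)
        sum((yc - b * xc)^2) / (n - 2)
    }
    vd <- res_var(d); vm <- res_var(m)
    if (vd <= 0 || vm <= 0)
        stop("zero residual variance; degenerate phenotype")
    list(tau_d = 1 / vd, tau_m = 1 / vm)
}

#' Closed-form Bayes factor for one regression block
#'
#' log10 Bayes factor for a single Gaussian regression coefficient with
#' known residual precision `tau` and a `N(0, priorVar)` effect prior:
#' with `V = 1/(tau * sum(x^2))` and `z = bhat/sqrt(V)`,
#' `BF = sqrt(V/(V+W)) * exp(z^2 W / (2(V+W)))`. Exact (not an
#' approximation) for fixed `tau`; symmetric in the sign of the effect.
#'
#' @param response,predictor centered numeric vectors.
#' @param tau residual precision of the block.
#' @param priorVar prior variance W > 0 of the effect.
#' @return log10 Bayes factor versus the null (zero effect).
#' @export
singleBlockLogBF <- function(response, predictor, tau, priorVar) {
    if (!all(is.finite(response)) || !all(is.finite(predictor)) ||
        !is.finite(tau) || !is.finite(priorVar))
        stop("non-finite inputs")
    stopifnot(priorVar > 0, sum(predictor^2) > 0)
    .lbfStats(sum(predictor^2), sum(predictor * response), tau, priorVar)
}

#' Bayes factor for one effect shared across the two blocks
#'
#' A single scalar effect beta enters the difference block with loading
#' `c_d` and the average block with loading `c_m` (treated-only model:
#' `c_d = 1, c_m = 1/2`; control-only: `c_d = -1, c_m = 1/2`). The two
#' blocks are combined by precision weighting:
#' `V = 1/((tau_d c_d^2 + tau_m c_m^2) sum(x^2))`,
#' `bhat = V (tau_d c_d sum(xd) + tau_m c_m sum(xm))`, then the same
#' closed form as [singleBlockLogBF()].
#'
#' @param d,m,x centered difference, average and dosage vectors.
#' @param taus list with `tau_d`, `tau_m` (see [blockPrecisions()]).
#' @param c_d,c_m block loadings, not both zero.
#' @param priorVar prior variance of the shared effect.
#' @return log10 Bayes factor versus the null.
#' @export
sharedCoefficientLogBF <- function(d, m, x, taus, c_d, c_m, priorVar) {
    if (c_d == 0 && c_m == 0) stop("loadings must not both be zero")
    if (!all(is.finite(c(d, m, x, priorVar))))
        stop("non-finite inputs")
    Sxx <- sum(x^2)
    prec <- (taus$tau_d * c_d^2 + taus$tau_m * c_m^2) * Sxx
    V <- 1 / prec
    bhat <- V * (taus$tau_d * c_d * sum(x * d) + taus$tau_m * c_m * sum(x * m))
    z2 <- bhat^2 / V
    (0.5 * log(V / (V + priorVar)) +
        0.5 * z2 * priorVar / (V + priorVar)) / log(10)
}

#' Per-SNP Bayes factors for the four non-null models
#'
#' The engine of the interaction scan. Complete cases are taken over the
#' paired phenotype and dosage; `d`, `m` and `x` are centered; block
#' precisions are plugged in; and for every prior grid point `s` the
#' per-condition effect prior is `N(0, w)` with `w = (s * sd_y)^2`, where
#' `sd_y` is the pooled per-condition phenotype sd. Model assembly on the
#' (d, m) rotation:
#' \itemize{
#'   \item M1 (`beta_T = beta_C = beta`): `beta_d = 0`, `beta_m = beta`,
#'     so the average block alone carries the evidence (prior `w`).
#'   \item M2 (treated only): shared effect with loadings `(1, 1/2)`,
#'     prior `w`.
#'   \item M3 (control only): loadings `(-1, 1/2)`, prior `w`.
#'   \item M4 (independent effects): `beta_d ~ N(0, 2w)` and
#'     `beta_m ~ N(0, w/2)` independent, so the BF factorizes exactly into
#'     the two single-block BFs.
#' }
#' Per-model BFs are averaged over the grid on the natural scale (uniform
#' grid weights). Because the prior scales with `sd_y`, all BFs are
#' invariant under affine transforms `y -> a*y + b` applied to both
#' conditions.
#'
#' @param pheno a [PairedPhenotype-class] for one gene.
#' @param x dosage vector (0/1/2, `NA` allowed) aligned to the phenotype.
#' @param priorSd grid of prior sds in units of `sd_y`.
#' @param keepGrid keep the per-grid-point log10 BFs as an attribute?
#' @return a one-row data.frame with `n_used`, `lbf1`..`lbf4` (log10,
#'   grid-averaged), `beta_T`, `beta_C` (per-condition OLS slopes), and
#'   `skip_reason` (`NA` when usable). Skipped SNPs (too few complete
#'   cases, monomorphic, or minor-allele count < 2) carry `NA` BFs and the
#'   reason.
#' @export
snpModelLogBFs <- function(pheno, x,
                           priorSd = c(1, 1.5, 2.25),
                           keepGrid = FALSE) {
    stopifnot(all(priorSd > 0))
    yT <- treatedValues(pheno); yC <- controlValues(pheno)
    ok <- is.finite(yT) & is.finite(yC) & !is.na(x)
    n <- sum(ok)
    skip <- function(why)
        data.frame(n_used = n, lbf1 = NA_real_, lbf2 = NA_real_,
                   lbf3 = NA_real_, lbf4 = NA_real_,
                   beta_T = NA_real_, beta_C = NA_real_, skip_reason = why,
                   stringsAsFactors = FALSE)
    if (n < 5) return(skip("fewer than 5 complete cases"))
    yT <- yT[ok]; yC <- yC[ok]; xu <- as.numeric(x[ok])
    if (length(unique(xu)) < 2) return(skip("monomorphic dosage"))
    mac <- min(sum(xu), 2 * n - sum(xu))
    if (mac < 2) return(skip("minor-allele count < 2"))
    d <- yT - yC
    m <- (yT + yC) / 2
    sd_y <- sqrt((var(yT) + var(yC)) / 2)
    if (sd_y <= 0) return(skip("constant phenotype"))
    xc <- xu - mean(xu); dc <- d - mean(d); mc <- m - mean(m)
    pp <- makePaired(yT, yC)
    taus <- blockPrecisions(pp, xu)
    Sxx <- sum(xc^2); Sxd <- sum(xc * dc); Sxm <- sum(xc * mc)
    grid <- vapply(priorSd, function(s) {
        w <- (s * sd_y)^2
        c(M1 = .lbfStats(Sxx, Sxm, taus$tau_m, w),
          M2 = sharedCoefficientLogBF(dc, mc, xc, taus, 1, 0.5, w),
          M3 = sharedCoefficientLogBF(dc, mc, xc, taus, -1, 0.5, w),
          M4 = .lbfStats(Sxx, Sxd, taus$tau_d, 2 * w) +
               .lbfStats(Sxx, Sxm, taus$tau_m, w / 2))
    }, numeric(4))
    lbf <- apply(grid, 1, .log10MeanExp)
    out <- data.frame(n_used = n,
                      lbf1 = lbf["M1"], lbf2 = lbf["M2"],
                      lbf3 = lbf["M3"], lbf4 = lbf["M4"],
                      beta_T = sum(xc * (yT - mean(yT))) / Sxx,
                      beta_C = sum(xc * (yC - mean(yC))) / Sxx,
                      skip_reason = NA_character_,
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    if (keepGrid) attr(out, "grid_lbf") <- grid
    out
}

#' Per-SNP Bayes factors for every SNP in one gene's window
#'
#' @param pheno a [PairedPhenotype-class] for the gene.
#' @param X dosage matrix (SNPs x individuals) of the gene's cis SNPs.
#' @param priorSd prior grid, see [snpModelLogBFs()].
#' @return data.frame with one row per SNP (`snp_id` column prepended).
#' @export
geneSnpBFs <- function(pheno, X,
                       priorSd = c(1, 1.5, 2.25)) {
    X <- as.matrix(X)
    rows <- lapply(seq_len(nrow(X)), function(s)
        snpModelLogBFs(pheno, X[s, ], priorSd = priorSd))
    out <- do.call(rbind, rows)
    out <- cbind(snp_id = if (!is.null(rownames(X))) rownames(X)
                          else as.character(seq_len(nrow(X))),
                 out, stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}
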