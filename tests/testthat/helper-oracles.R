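## Shared oracles and small-data generators, independent of the package's
## closed-form code paths.

## Quadrature oracle for a block Bayes factor: one scalar effect b entering
## the diff block with loading c_d and the avg block with loading c_m,
## Gaussian likelihood with fixed precisions, N(0, W) prior. Integrates the
## likelihood ratio exp(loglik(b) - loglik(0)) against the prior, which is
## well-scaled for quadrature.
quadLogBF <- function(dc, mc, xc, tau_d, tau_m, c_d, c_m, W) {
    Sxx <- sum(xc^2); Sxd <- sum(xc * dc); Sxm <- sum(xc * mc)
    dll <- function(b)
        tau_d * (b * c_d * Sxd - b^2 * c_d^2 * Sxx / 2) +
        tau_m * (b * c_m * Sxm - b^2 * c_m^2 * Sxx / 2)
    f <- function(b) exp(dll(b)) * dnorm(b, 0, sqrt(W))
    v <- integrate(f, -20 * sqrt(W), 20 * sqrt(W), rel.tol = 1e-10,
                   abs.tol = 0)$value
    log10(v)
}

## Quadrature oracle for all four models at one grid point w (prior
## variance of the per-condition effect). M4 factorizes into independent
## 1-D integrals over beta_d ~ N(0, 2w) and beta_m ~ N(0, w/2).
quadModelLogBFs <- function(dc, mc, xc, tau_d, tau_m, w) {
    c(M1 = quadLogBF(dc, mc, xc, tau_d, tau_m, 0, 1, w),
      M2 = quadLogBF(dc, mc, xc, tau_d, tau_m, 1, 0.5, w),
      M3 = quadLogBF(dc, mc, xc, tau_d, tau_m, -1, 0.5, w),
      M4 = quadLogBF(dc, mc, xc, tau_d, tau_m, 1, 0, 2 * w) +
           quadLogBF(dc, mc, xc, tau_d, tau_m, 0, 1, w / 2))
}

## Draw one random paired phenotype + dosage instance. Effects are on the
## treated/control scale; pairing via a shared individual component.
randomInstance <- function(n = 30, maf = 0.3, beta_T = 0, beta_C = 0,
                           sigma_u = 1, sigma_e = 1) {
    repeat {
        x <- rbinom(n, 2, maf)
        if (length(unique(x)) >= 2 && min(sum(x), 2 * n - sum(x)) >= 2)
            break
    }
    u <- rnorm(n, 0, sigma_u)
    yC <- beta_C * x + u + rnorm(n, 0, sigma_e)
    yT <- 0.3 + beta_T * x + u + rnorm(n, 0, sigma_e)
    list(pheno = makePaired(yT, yC), x = x)
}

## Reproduce snpModelLogBFs' preprocessing so oracles see the identical
## centered data, precisions and prior scale.
centeredParts <- function(pheno, x) {
    yT <- treatedValues(pheno); yC <- controlValues(pheno)
    d <- yT - yC; m <- (yT + yC) / 2
    taus <- blockPrecisions(pheno, x)
    list(dc = d - mean(d), mc = m - mean(m), xc = x - mean(x),
         tau_d = taus$tau_d, tau_m = taus$tau_m,
         sd_y = sqrt((var(yT) + var(yC)) / 2))
}

## OLS slope/p oracle by explicit normal equations + t distribution.
olsOracle <- function(y, X) {
    XtX <- t(X) %*% X
    b <- solve(XtX, t(X) %*% y)
    res <- y - X %*% b
    df <- length(y) - ncol(X)
    s2 <- sum(res^2) / df
    se <- sqrt(s2 * diag(solve(XtX)))
    t <- as.numeric(b) / se
    list(coef = as.numeric(b), t = t, p = 2 * pt(-abs(t), df))
}
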