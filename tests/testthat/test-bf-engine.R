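test_that("block precisions are consistent, scale-equivariant and guarded", {
    set.seed(21)
    n <- 10000
    x <- rbinom(n, 2, 0.3)
    p <- makePaired(rnorm(n, 0, 1), rnorm(n, 0, 1))
    ## var(d) = 2 when each condition is iid N(0,1): tau_d ~ 1/2
    taus <- blockPrecisions(p, x)
    expect_lt(abs(taus$tau_d - 0.5) / 0.5, 0.05)
    ## doubling d (scaling both conditions' difference) scales tau_d by 1/4
    p2 <- makePaired(2 * treatedValues(p), 2 * controlValues(p))
    expect_equal(blockPrecisions(p2, x)$tau_d, taus$tau_d / 4)
    ## d exactly linear in x: zero residual variance in the diff block
    x2 <- c(0, 1, 2, 1, 0, 1)
    plin <- makePaired(x2, rep(0, 6))
    expect_error(blockPrecisions(plin, x2), "zero residual variance")
    expect_error(blockPrecisions(makePaired(rnorm(4), rnorm(4)), rep(0:1, 2)),
                 "at least 5")
    expect_error(blockPrecisions(makePaired(rnorm(6), rnorm(6)), rep(1, 6)),
                 "constant")
})

test_that("single-block BF matches its closed form at z = 0 and the
           zero-prior limit", {
    x <- c(-1, 0, 1, 1, -1)
    y <- c(1, -2, 1, 0, 0)          # orthogonal to x
    expect_equal(sum(x * y), 0)
    W <- 0.5; tau <- 2
    lbf <- singleBlockLogBF(y, x, tau, W)
    V <- 1 / (tau * sum(x^2))
    expect_equal(lbf, 0.5 * log10(V / (V + W)))
    expect_lt(lbf, 0)
    ## W -> 0+: evidence vanishes
    set.seed(22)
    y2 <- rnorm(5)
    expect_lt(abs(singleBlockLogBF(y2 - mean(y2), x, tau, 1e-16)), 1e-6)
    expect_error(singleBlockLogBF(c(y2, NA), c(x, 1), tau, W), "non-finite")
})

test_that("shared-coefficient BF reduces to the single block and is
           permutation invariant", {
    set.seed(23)
    inst <- randomInstance(n = 30, beta_T = 0.5)
    cp <- centeredParts(inst$pheno, inst$x)
    taus <- list(tau_d = cp$tau_d, tau_m = cp$tau_m)
    expect_equal(
        sharedCoefficientLogBF(cp$dc, cp$mc, cp$xc, taus, 1, 0, 0.4),
        singleBlockLogBF(cp$dc, cp$xc, cp$tau_d, 0.4))
    o <- sample(30)
    expect_equal(
        sharedCoefficientLogBF(cp$dc[o], cp$mc[o], cp$xc[o], taus, 1, .5, .4),
        sharedCoefficientLogBF(cp$dc, cp$mc, cp$xc, taus, 1, .5, .4))
    expect_error(sharedCoefficientLogBF(cp$dc, cp$mc, cp$xc, taus, 0, 0, .4),
                 "loadings")
})

test_that("closed-form BFs agree with numerical quadrature on random data", {
    set.seed(24)
    for (rep in 1:20) {
        inst <- randomInstance(n = 30, beta_T = runif(1, -1, 1),
                               beta_C = runif(1, -1, 1))
        bf <- snpModelLogBFs(inst$pheno, inst$x, keepGrid = TRUE)
        cp <- centeredParts(inst$pheno, inst$x)
        grid <- c(1, 1.5, 2.25)
        for (k in seq_along(grid)) {
            w <- (grid[k] * cp$sd_y)^2
            oracle <- quadModelLogBFs(cp$dc, cp$mc, cp$xc,
                                      cp$tau_d, cp$tau_m, w)
            expect_lt(max(abs(attr(bf, "grid_lbf")[, k] - oracle)), 1e-3)
        }
    }
})

test_that("the general-interaction BF factorizes exactly into its two
           blocks", {
    set.seed(25)
    for (rep in 1:10) {
        inst <- randomInstance(n = 40, beta_T = rnorm(1), beta_C = rnorm(1))
        bf <- snpModelLogBFs(inst$pheno, inst$x, priorSd = 0.9,
                             keepGrid = TRUE)
        cp <- centeredParts(inst$pheno, inst$x)
        w <- (0.9 * cp$sd_y)^2
        expect_equal(bf$lbf4,
                     singleBlockLogBF(cp$dc, cp$xc, cp$tau_d, 2 * w) +
                     singleBlockLogBF(cp$mc, cp$xc, cp$tau_m, w / 2),
                     tolerance = 1e-12)
    }
})

test_that("BFs are invariant under affine phenotype transforms and
           individual relabeling", {
    set.seed(26)
    inst <- randomInstance(n = 50, beta_T = 0.7)
    base <- snpModelLogBFs(inst$pheno, inst$x)
    ## y -> a*y + b on both conditions
    aff <- makePaired(3.7 * treatedValues(inst$pheno) - 2,
                      3.7 * controlValues(inst$pheno) - 2)
    got <- snpModelLogBFs(aff, inst$x)
    expect_equal(got[, c("lbf1", "lbf2", "lbf3", "lbf4")],
                 base[, c("lbf1", "lbf2", "lbf3", "lbf4")],
                 tolerance = 1e-10)
    ## joint relabeling of individuals
    o <- sample(50)
    rel <- makePaired(treatedValues(inst$pheno)[o],
                      controlValues(inst$pheno)[o])
    got2 <- snpModelLogBFs(rel, inst$x[o])
    expect_equal(got2, base, tolerance = 1e-12)
})

test_that("the no-interaction BF depends on the average block only", {
    ## replace d with fresh noise of identical sample variance while keeping
    ## m fixed: sd_y and tau_m are unchanged, so BF(M1) must be identical
    set.seed(27)
    n <- 40
    inst <- randomInstance(n = n, beta_T = 0.5, beta_C = 0.5)
    yT <- treatedValues(inst$pheno); yC <- controlValues(inst$pheno)
    m <- (yT + yC) / 2; d <- yT - yC
    d2 <- rnorm(n)
    d2 <- (d2 - mean(d2)) / sd(d2) * sd(d) + mean(d)
    p2 <- makePaired(m + d2 / 2, m - d2 / 2)
    expect_equal(snpModelLogBFs(p2, inst$x)$lbf1,
                 snpModelLogBFs(inst$pheno, inst$x)$lbf1,
                 tolerance = 1e-10)
})

test_that("the zero-prior limit sends every BF to 1", {
    set.seed(28)
    inst <- randomInstance(n = 30, beta_T = 1)
    bf <- snpModelLogBFs(inst$pheno, inst$x, priorSd = 1e-9)
    expect_lt(max(abs(c(bf$lbf1, bf$lbf2, bf$lbf3, bf$lbf4))), 1e-6)
})

test_that("data simulated under the treated-only model favour the
           treated-only loading over the control-only loading", {
    set.seed(29)
    wins <- 0
    for (rep in 1:50) {
        inst <- randomInstance(n = 114, beta_T = 1.4, beta_C = 0)
        bf <- snpModelLogBFs(inst$pheno, inst$x)
        if (bf$lbf2 > bf$lbf3) wins <- wins + 1
    }
    expect_gte(wins, 47)
})

test_that("degenerate SNPs are skipped with a reason, not an error", {
    set.seed(30)
    p <- makePaired(rnorm(10), rnorm(10))
    expect_match(snpModelLogBFs(p, rep(1, 10))$skip_reason, "monomorphic")
    expect_match(snpModelLogBFs(p, c(1, rep(0, 9)))$skip_reason,
                 "minor-allele")
    short <- makePaired(rnorm(4), rnorm(4))
    expect_match(snpModelLogBFs(short, c(0, 1, 2, 1))$skip_reason,
                 "complete cases")
    xna <- c(0, 1, 2, 1, 0, NA, NA, NA, NA, NA, NA, NA)
    pna <- makePaired(rnorm(12), rnorm(12))
    out <- snpModelLogBFs(pna, xna)
    expect_equal(out$n_used, 5)
})

test_that("per-condition effect estimates are the OLS slopes", {
    set.seed(31)
    inst <- randomInstance(n = 60, beta_T = 0.8, beta_C = -0.3)
    bf <- snpModelLogBFs(inst$pheno, inst$x)
    expect_equal(bf$beta_T,
                 unname(coef(lm(treatedValues(inst$pheno) ~ inst$x))[2]))
    expect_equal(bf$beta_C,
                 unname(coef(lm(controlValues(inst$pheno) ~ inst$x))[2]))
})
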