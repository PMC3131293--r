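test_that("the treatment DE test matches an explicit normal-equations
           oracle", {
    set.seed(51)
    n <- 40
    treat <- rep(0:1, each = n / 2)
    Z <- matrix(rnorm(n * 2), n, 2)
    expr <- matrix(rnorm(5 * n), 5, n)
    expr[1, ] <- expr[1, ] + 0.8 * treat
    got <- deTest(expr, treat, Z)
    X <- cbind(1, treat, Z)
    for (g in 1:5) {
        o <- olsOracle(expr[g, ], X)
        expect_lt(abs(got$p[g] - o$p[2]), 1e-10)
        expect_equal(got$estimate[g], o$coef[2], tolerance = 1e-10)
    }
})

test_that("identical conditions give t = 0, p = 1; collinearity errors", {
    set.seed(52)
    base <- rnorm(10)
    expr <- rbind(g1 = c(base, base))         # treated block == control block
    treat <- rep(0:1, each = 10)
    out <- deTest(expr, treat)
    expect_equal(out$t, 0)
    expect_equal(out$p, 1)
    expect_error(deTest(expr, treat, covariates = cbind(tr2 = treat)),
                 "collinear")
    expect_error(deTest(expr, rep(1, 20)), "both conditions")
})

test_that("permutation FDR follows the counting estimator with
           monotonicity", {
    ## observed {1e-6, 0.5}, one permutation {0.3, 0.6}
    fdr <- deFDR(c(1e-6, 0.5), cbind(c(0.3, 0.6)))
    expect_equal(fdr[1], 0)                   # empty null tail
    expect_equal(fdr[2], 0.5)                 # 1 null hit / 2 observed
    ## observed equal to its own null -> FDR 1 everywhere
    set.seed(53)
    p <- runif(50)
    expect_equal(unname(deFDR(p, cbind(p))), rep(1, 50))
    ## monotone in the observed p after cummax
    p2 <- runif(100)
    nullm <- matrix(runif(500), 100, 5)
    f <- deFDR(p2, nullm)
    expect_true(all(diff(f[order(p2)]) >= -1e-12))
    expect_true(all(f >= 0 & f <= 1))
})

test_that("simple LFC association matches the OLS formulas", {
    x <- c(0, 1, 2, 1, 0, 2, 1, 0)
    d <- 2 * x
    r <- lfcAssoc(d, x)
    expect_equal(r$slope, 2)
    expect_equal(r$p, 1e-300)
    ## orthogonal response
    d2 <- c(1, -1, 0, 0, 1, 0, -1, 0)
    d2 <- residualize(d2, cbind(x))          # force exact orthogonality
    r2 <- lfcAssoc(d2, x)
    expect_equal(r2$slope, 0, tolerance = 1e-12)
    expect_equal(r2$p, 1)
    set.seed(54)
    for (rep in 1:10) {
        xx <- rbinom(30, 2, 0.4); dd <- rnorm(30) + 0.3 * xx
        got <- lfcAssoc(dd, xx)
        o <- olsOracle(dd, cbind(1, xx))
        expect_lt(abs(got$slope - o$coef[2]), 1e-12)
        expect_lt(abs(got$p - o$p[2]), 1e-12)
    }
    expect_true(is.na(lfcAssoc(rnorm(8), rep(1, 8))$p))
    expect_error(lfcAssoc(rnorm(4), c(0, 1, 2, 1)), "complete cases")
})

test_that("permutation rounds are seeded bijections shared across genes", {
    pn <- permutationRounds(20, 5, seed = 9)
    pm <- permMatrix(pn)
    expect_equal(dim(pm), c(5, 20))
    for (i in 1:5) expect_setequal(pm[i, ], 1:20)
    expect_identical(pm, permMatrix(permutationRounds(20, 5, seed = 9)))
    expect_false(identical(pm, permMatrix(permutationRounds(20, 5, seed = 10))))
})

test_that("the scan takes per-gene min p and is consistent with its own
           null rounds", {
    set.seed(55)
    n <- 30
    dos <- matrix(rbinom(5 * n, 2, 0.3), 5, n,
                  dimnames = list(paste0("s", 1:5), paste0("i", 1:n)))
    lfc <- matrix(rnorm(2 * n), 2, n,
                  dimnames = list(c("g1", "g2"), colnames(dos)))
    lfc[1, ] <- lfc[1, ] + dos[2, ]
    perms <- permutationRounds(n, 4, seed = 3)
    cis <- list(g1 = 1:5, g2 = 3L)
    sc <- scanLFC(lfc, dos, cis, perms)
    ## single-SNP gene: min_p equals the direct association p
    expect_equal(sc$results$min_p[2], lfcAssoc(lfc[2, ], dos[3, ])$p,
                 tolerance = 1e-12)
    ## multi-SNP gene: min over the window, top SNP recorded
    ps <- vapply(1:5, function(s) lfcAssoc(lfc[1, ], dos[s, ])$p, numeric(1))
    expect_equal(sc$results$min_p[1], min(ps), tolerance = 1e-12)
    expect_equal(sc$results$top_snp_id[1], paste0("s", which.min(ps)))
    ## scanning phenotypes pre-permuted by round r reproduces null round r
    pm <- permMatrix(perms)
    for (r in c(1, 3)) {
        sc_r <- scanLFC(lfc[, pm[r, ]], dos, cis, perms)
        expect_equal(sc_r$results$min_p, unname(sc$null_min_p[, r]),
                     tolerance = 1e-12)
    }
    ## min-p invariant to SNP order within the window
    sc_shuf <- scanLFC(lfc, dos, list(g1 = c(4, 1, 5, 3, 2), g2 = 3L), perms)
    expect_equal(sc_shuf$results$min_p, sc$results$min_p)
})

test_that("a planted cis signal is found and enriched at low FDR", {
    set.seed(56)
    cfg <- simConfig(n_genes = 120, n_per_pop = c(30, 30),
                     pi_true = c(0.8, 0, 0.1, 0.1, 0), beta = 2.5,
                     snps_per_window = 4, cov_effects = numeric(0))
    st <- simStudy(cfg)
    ls <- lfcScan(st$pe, st$geno, st$genes, n_perms = 20, seed = 5)
    hit <- !is.na(ls$results$fdr) & ls$results$fdr < 0.1
    truth_int <- st$truth$model %in% c(2, 3)
    expect_gt(sum(hit & truth_int), 5)
    ## enrichment of true signals among hits
    expect_gt(mean(truth_int[hit]), 4 * mean(truth_int))
})

test_that("secretion QTL mapping is the same machinery as the gene scan", {
    set.seed(57)
    n <- 40
    dos <- matrix(rbinom(6 * n, 2, 0.3), 6, n,
                  dimnames = list(paste0("s", 1:6), paste0("i", 1:n)))
    snps <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(seq(1e4, 6e4, by = 1e4), width = 1),
        ref = "A", alt = "G")
    names(snps) <- rownames(dos)
    gd <- GenotypeData(dos, snps)
    prot <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(9e3, 4.5e4),
                                                            width = 2e3))
    names(prot) <- c("IL6", "IL8")
    sec <- matrix(rnorm(2 * n), 2, n,
                  dimnames = list(names(prot), colnames(dos)))
    perms <- permutationRounds(n, 3, seed = 2)
    got <- secretionQTL(sec, gd, prot, window = 1.5e4, perms = perms)
    cis <- mapCisSnps(prot, gd, 1.5e4)
    want <- scanLFC(sec, gd, cis, perms)
    expect_identical(got$results, want$results)
})
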