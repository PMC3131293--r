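test_that("simulation is a pure function of the seed, files included", {
    cfg <- simConfig(n_genes = 8, snps_per_window = 3,
                     n_per_pop = c(6, 6), seed = 81L)
    d1 <- file.path(tempdir(), "sim1"); d2 <- file.path(tempdir(), "sim2")
    s1 <- simStudy(cfg, out_dir = d1)
    s2 <- simStudy(cfg, out_dir = d2)
    expect_identical(treatedExpr(s1$pe), treatedExpr(s2$pe))
    expect_identical(dosages(s1$geno), dosages(s2$geno))
    expect_identical(s1$truth, s2$truth)
    for (f in names(s1$files))
        expect_identical(readLines(s1$files[[f]]), readLines(s2$files[[f]]))
    ## bookkeeping matches the config exactly
    expect_equal(nrow(treatedExpr(s1$pe)), 8)
    expect_equal(nrow(dosages(s1$geno)), 8 * 3)
    expect_equal(ncol(dosages(s1$geno)), 12)
    expect_equal(unname(table(populations(s1$geno))[cfg$pop_names]),
                 c(6L, 6L), ignore_attr = TRUE)
})

test_that("written fixtures are read back faithfully by the package
           readers", {
    cfg <- simConfig(n_genes = 5, snps_per_window = 4, n_per_pop = c(8, 8),
                     seed = 82L)
    dir <- file.path(tempdir(), "simrt")
    st <- simStudy(cfg, out_dir = dir)
    pe <- readExpression(st$files$expression)
    expect_equal(treatedExpr(pe), treatedExpr(st$pe), tolerance = 1e-10)
    gd <- readGenotypes(st$files$vcf, format = "vcf")
    flip <- S4Vectors::mcols(snpRanges(gd))$flipped
    orig <- dosages(st$geno)[rownames(dosages(gd)), ]
    want <- ifelse(matrix(flip, nrow(orig), ncol(orig)), 2 - orig, orig)
    expect_equal(unname(dosages(gd)), unname(want))
    genes <- readGeneBed(st$files$bed)
    expect_equal(GenomicRanges::start(genes),
                 GenomicRanges::start(st$genes))
    expect_equal(names(genes), st$genes$name)
})

test_that("genotype moments match Hardy-Weinberg at the configured
           frequency", {
    cfg <- simConfig(n_genes = 1, snps_per_window = 1,
                     n_per_pop = c(5000, 5000),
                     maf_range = list(c(0.5, 0.5), c(0.5, 0.5)), seed = 83L)
    st <- simStudy(cfg)
    x <- dosages(st$geno)[1, ]
    expect_lt(abs(mean(x) - 1), 0.03)
    ## HWE genotype class proportions at f = 0.5: 1/4, 1/2, 1/4
    expect_lt(max(abs(table(x) / length(x) - c(.25, .5, .25))), 0.03)
})

test_that("the LD parameter spans independent to perfectly copied SNPs", {
    cfg1 <- simConfig(n_genes = 1, snps_per_window = 5,
                      n_per_pop = c(5000, 5000), rho_ld = 1,
                      maf_range = list(c(0.3, 0.3), c(0.3, 0.3)), seed = 84L)
    st1 <- simStudy(cfg1)
    d <- dosages(st1$geno)
    for (s in 2:5) expect_identical(d[s, ], d[1, ])
    cfg0 <- simConfig(n_genes = 1, snps_per_window = 5,
                      n_per_pop = c(5000, 5000), rho_ld = 0,
                      maf_range = list(c(0.3, 0.3), c(0.3, 0.3)), seed = 85L)
    d0 <- dosages(simStudy(cfg0)$geno)
    cors <- cor(t(d0))
    expect_lt(max(abs(cors[upper.tri(cors)])), 0.05)
})

test_that("paired phenotypes have the configured pairing correlation and
           effect structure", {
    ## null genes, sigma_u2 = sigma_e2 = 1, no covariates: corr = 0.5
    cfg <- simConfig(n_genes = 3, snps_per_window = 1,
                     n_per_pop = c(2500, 2500),
                     pi_true = c(1, 0, 0, 0, 0), cov_effects = numeric(0),
                     seed = 86L)
    st <- simStudy(cfg)
    for (g in 1:3)
        expect_lt(abs(cor(treatedExpr(st$pe)[g, ],
                          controlExpr(st$pe)[g, ]) - 0.5), 0.03)

    ## M1 genes: the log fold change is independent of genotype
    cfg1 <- simConfig(n_genes = 2, snps_per_window = 1,
                      n_per_pop = c(2500, 2500),
                      pi_true = c(0, 1, 0, 0, 0), beta = 1,
                      cov_effects = numeric(0), seed = 87L)
    st1 <- simStudy(cfg1)
    for (g in 1:2) {
        x <- dosages(st1$geno)[st1$causal[g], ]
        d <- logFoldChange(st1$pe)[g, ]
        expect_lt(abs(unname(coef(lm(d ~ x))[2])), 0.05)
    }

    ## M2 genes with beta = 1: treated slope ~ 1, control slope ~ 0
    cfg2 <- simConfig(n_genes = 2, snps_per_window = 1,
                      n_per_pop = c(2500, 2500),
                      pi_true = c(0, 0, 1, 0, 0), beta = 1,
                      cov_effects = numeric(0), seed = 88L)
    st2 <- simStudy(cfg2)
    for (g in 1:2) {
        x <- dosages(st2$geno)[st2$causal[g], ]
        sT <- unname(coef(lm(treatedExpr(st2$pe)[g, ] ~ x))[2])
        sC <- unname(coef(lm(controlExpr(st2$pe)[g, ] ~ x))[2])
        expect_lt(abs(abs(sT) - 1), 0.07)
        expect_lt(abs(sC), 0.07)
        expect_equal(st2$truth$beta_C[g], 0)
    }
})

test_that("planted model counts follow pi_true exactly and constraints
           hold", {
    cfg <- simConfig(n_genes = 200, snps_per_window = 2,
                     n_per_pop = c(10, 10),
                     pi_true = c(0.7, 0.2, 0.05, 0.03, 0.02), seed = 89L)
    st <- simStudy(cfg)
    expect_equal(unname(table(factor(st$truth$model, levels = 0:4))),
                 c(140L, 40L, 10L, 6L, 4L), ignore_attr = TRUE)
    expect_true(all(st$truth$beta_T[st$truth$model == 0] == 0))
    expect_true(all(st$truth$beta_C[st$truth$model == 2] == 0))
    expect_true(all(st$truth$beta_T[st$truth$model == 3] == 0))
    expect_true(all(st$truth$beta_T[st$truth$model == 1] ==
                    st$truth$beta_C[st$truth$model == 1]))
})

test_that("a small end-to-end study recovers its strongest signals", {
    cfg <- simConfig(n_genes = 60, n_per_pop = c(40, 40), beta = 1.5,
                     snps_per_window = 3,
                     pi_true = c(0.6, 0.2, 0.1, 0.1, 0), seed = 90L)
    st <- simStudy(cfg)
    bs <- bayesScan(st$pe, st$geno, st$genes, covariates = st$covariates)
    expect_equal(nrow(bs$genes), 60)
    expect_equal(sum(bs$pi), 1)
    int_called <- bs$genes$PP_interaction > 0.7
    expect_gt(sum(int_called & st$truth$model %in% 2:3, na.rm = TRUE), 5)
    ## eQTN column points at window SNPs of the right gene
    g_hit <- which(int_called)[1]
    idx <- (g_hit - 1) * 3 + 1:3
    expect_true(bs$genes$eqtn[g_hit] %in%
                rownames(dosages(st$geno))[idx])
})
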