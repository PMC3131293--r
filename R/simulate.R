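#' Simulation configuration
#'
#' Defines the generative model for synthetic studies with known truth.
#' Defaults mirror the study design the method was built for: two
#' populations of 57 individuals each, paired log2 phenotypes with a shared
#' individual-level component giving pairing correlation
#' `sigma_u2/(sigma_u2 + sigma_e2) = 0.5` at null genes, additive per-copy
#' genotype effects following one of the five models with genome-wide
#' mixture proportions `pi_true`, per-gene mean treatment shifts, one
#' baseline covariate affecting both conditions, and simple allele-copying
#' LD within each cis window.
#'
#' @param n_per_pop individuals per population (length 2).
#' @param pop_names population labels.
#' @param n_genes number of genes.
#' @param snps_per_window SNPs in each gene's cis window (one causal).
#' @param maf_range list of two length-2 vectors: per-population allele
#'   frequency range the causal/proxy frequencies are drawn from.
#' @param pi_true model proportions (M0..M4) genes are assigned from.
#' @param beta per-allele effect size in units of the residual sd
#'   `sqrt(sigma_e2)`.
#' @param sigma_u2,sigma_e2 variances of the shared individual component
#'   and of the per-condition residual.
#' @param delta_sd sd of the per-gene mean treatment shift.
#' @param cov_effects effect of each simulated N(0,1) covariate on both
#'   conditions (length = number of covariates; `numeric(0)` for none).
#' @param rho_ld probability a proxy-SNP allele copies the causal allele.
#' @param pop_diff_prop,pop_diff_size fraction of genes given a
#'   treatment-only population response difference, and its size (units of
#'   residual sd), for population-contrast simulations.
#' @param seed integer seed; every output is a pure function of the config.
#' @return a validated list of class `sim_config`.
#' @export
simConfig <- function(n_per_pop = c(57L, 57L), pop_names = c("YRI", "TSI"),
                      n_genes = 500L, snps_per_window = 10L,
                      maf_range = list(c(0.05, 0.5), c(0.05, 0.5)),
                      pi_true = c(0.70, 0.20, 0.05, 0.03, 0.02),
                      beta = 0.8, sigma_u2 = 1, sigma_e2 = 1,
                      delta_sd = 1, cov_effects = 0.5, rho_ld = 0.5,
                      pop_diff_prop = 0, pop_diff_size = 0, seed = 1L) {
    stopifnot(length(n_per_pop) == 2, all(n_per_pop >= 1),
              length(pi_true) == 5, all(pi_true >= 0),
              abs(sum(pi_true) - 1) < 1e-8,
              sigma_u2 > 0, sigma_e2 > 0, rho_ld >= 0, rho_ld <= 1,
              all(vapply(maf_range, function(r)
                  r[1] > 0 && r[2] <= 0.5 && r[1] <= r[2], logical(1))))
    structure(list(n_per_pop = as.integer(n_per_pop), pop_names = pop_names,
                   n_genes = as.integer(n_genes),
                   snps_per_window = as.integer(snps_per_window),
                   maf_range = maf_range, pi_true = pi_true, beta = beta,
                   sigma_u2 = sigma_u2, sigma_e2 = sigma_e2,
                   delta_sd = delta_sd, cov_effects = cov_effects,
                   rho_ld = rho_ld, pop_diff_prop = pop_diff_prop,
                   pop_diff_size = pop_diff_size, seed = as.integer(seed)),
              class = "sim_config")
}

## Gene layout: non-overlapping 10 kb gene bodies spaced 1 Mb apart on a
## single synthetic chromosome, so 100 kb cis windows never collide.
.simGeneRanges <- function(n_genes) {
    start <- seq_len(n_genes) * 1e6
    GenomicRanges::GRanges("chrS",
        IRanges::IRanges(start, start + 9999),
        name = sprintf("gene%04d", seq_len(n_genes)))
}

#' Simulate genotypes
#'
#' Draws, per gene window and population, a causal-SNP allele frequency
#' from the configured range and Hardy-Weinberg dosages
#' `Binomial(2, f)`; proxy SNPs copy each causal allele with probability
#' `rho_ld` and otherwise redraw from their own frequency, giving simple
#' bounded LD with the causal SNP.
#'
#' @param config a [simConfig()] list.
#' @return list with `geno` (a [GenotypeData-class]), `genes` (GRanges),
#'   `causal` (per-gene causal SNP index into the dosage matrix) and
#'   `causal_freq` (genes x 2 matrix of per-population causal frequencies).
#' @export
simGenotypes <- function(config) {
    n1 <- config$n_per_pop[1]; n2 <- config$n_per_pop[2]
    n <- n1 + n2
    G <- config$n_genes; S <- config$snps_per_window
    genes <- .simGeneRanges(G)
    pop <- factor(rep(config$pop_names, c(n1, n2)),
                  levels = config$pop_names)
    ids <- sprintf("ind%03d", seq_len(n))
    nsnp <- G * S
    dos <- matrix(0L, nsnp, n, dimnames = list(NULL, ids))
    pos <- integer(nsnp)
    causal <- integer(G)
    causal_freq <- matrix(NA_real_, G, 2)
    causal_at <- (S + 1L) %/% 2L   # middle SNP of the window is causal
    popidx <- list(seq_len(n1), n1 + seq_len(n2))
    for (g in seq_len(G)) {
        base <- (g - 1L) * S
        w_start <- GenomicRanges::start(genes)[g] - 5e4
        pos[base + seq_len(S)] <- as.integer(round(
            seq(w_start, GenomicRanges::start(genes)[g] + 9999 + 5e4,
                length.out = S)))
        causal[g] <- base + causal_at
        ca1 <- ca2 <- integer(n)   # causal allele pairs
        for (p in 1:2) {
            f <- runif(1, config$maf_range[[p]][1], config$maf_range[[p]][2])
            causal_freq[g, p] <- f
            ca1[popidx[[p]]] <- rbinom(length(popidx[[p]]), 1, f)
            ca2[popidx[[p]]] <- rbinom(length(popidx[[p]]), 1, f)
        }
        dos[causal[g], ] <- ca1 + ca2
        for (s in seq_len(S)) {
            if (s == causal_at) next
            a1 <- a2 <- integer(n)
            for (p in 1:2) {
                ii <- popidx[[p]]
                fs <- runif(1, config$maf_range[[p]][1],
                            config$maf_range[[p]][2])
                cp1 <- runif(length(ii)) < config$rho_ld
                cp2 <- runif(length(ii)) < config$rho_ld
                a1[ii] <- ifelse(cp1, ca1[ii], rbinom(length(ii), 1, fs))
                a2[ii] <- ifelse(cp2, ca2[ii], rbinom(length(ii), 1, fs))
            }
            dos[base + s, ] <- a1 + a2
        }
    }
    rownames(dos) <- sprintf("snp%05d", seq_len(nsnp))
    snps <- GenomicRanges::GRanges("chrS", IRanges::IRanges(pos, width = 1),
                                   ref = "A", alt = "G")
    names(snps) <- rownames(dos)
    list(geno = GenotypeData(dos, snps, population = pop), genes = genes,
         causal = causal, causal_freq = causal_freq)
}

## Largest-remainder rounding of proportions p to integer counts summing
## to n, so the planted mixture matches p exactly up to rounding.
.exactCounts <- function(p, n) {
    raw <- p * n
    cnt <- floor(raw)
    rem <- n - sum(cnt)
    if (rem > 0) {
        up <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
        cnt[up] <- cnt[up] + 1
    }
    as.integer(cnt)
}

## Assign per-gene models and effects. Model counts are planted exactly
## (largest-remainder rounding of pi_true * n_genes, randomly placed), so
## the generating proportions are pi_true and not a multinomial draw. M4
## draws independent per-condition effects from N(0, beta^2); the
## constrained models use +/- beta exactly.
.simTruth <- function(config, gsim) {
    G <- config$n_genes
    beta <- config$beta * sqrt(config$sigma_e2)
    model <- sample(rep(0:4, .exactCounts(config$pi_true, G)))
    sgn <- sample(c(-1, 1), G, replace = TRUE)
    betaT <- betaC <- numeric(G)
    betaT[model == 1] <- (sgn * beta)[model == 1]
    betaC[model == 1] <- (sgn * beta)[model == 1]
    betaT[model == 2] <- (sgn * beta)[model == 2]
    betaC[model == 3] <- (sgn * beta)[model == 3]
    m4 <- model == 4
    betaT[m4] <- rnorm(sum(m4), 0, beta)
    betaC[m4] <- rnorm(sum(m4), 0, beta)
    delta <- rnorm(G, 0, config$delta_sd)
    pop_diff <- numeric(G)
    if (config$pop_diff_prop > 0) {
        hit <- runif(G) < config$pop_diff_prop
        pop_diff[hit] <- sample(c(-1, 1), sum(hit), replace = TRUE) *
            config$pop_diff_size * sqrt(config$sigma_e2)
    }
    data.frame(gene_id = gsim$genes$name, model = model,
               causal_snp = rownames(dosages(gsim$geno))[gsim$causal],
               beta_T = betaT, beta_C = betaC, delta = delta,
               pop_diff = pop_diff, stringsAsFactors = FALSE)
}

#' Simulate paired expression given genotypes and truth
#'
#' Generative model per gene g and individual i:
#' `y_C = beta_C x + c'z + u + e_C` and
#' `y_T = delta + beta_T x + pop_diff * pop + c'z + u + e_T`, with
#' `u ~ N(0, sigma_u2)` shared between conditions (the pairing component)
#' and `e ~ N(0, sigma_e2)` independent, covariates `z ~ N(0,1)` affecting
#' both conditions equally.
#'
#' @param gsim output of [simGenotypes()].
#' @param truth data.frame as built by [simStudy()] (gene model, effects).
#' @param config a [simConfig()] list.
#' @return list with `pe` (a [PairedExpression-class]) and `covariates`
#'   (individuals x covariates matrix).
#' @export
simPairedExpression <- function(gsim, truth, config) {
    dos <- dosages(gsim$geno)
    n <- ncol(dos); G <- config$n_genes
    k <- length(config$cov_effects)
    Z <- matrix(rnorm(n * k), n, k,
                dimnames = list(colnames(dos),
                                if (k) paste0("cov", seq_len(k))))
    covpart <- if (k) as.numeric(Z %*% config$cov_effects) else numeric(n)
    pop01 <- as.numeric(populations(gsim$geno) ==
                        levels(populations(gsim$geno))[1])
    su <- sqrt(config$sigma_u2); se <- sqrt(config$sigma_e2)
    tr <- ct <- matrix(NA_real_, G, n,
                       dimnames = list(truth$gene_id, colnames(dos)))
    for (g in seq_len(G)) {
        x <- dos[gsim$causal[g], ]
        u <- rnorm(n, 0, su)
        ct[g, ] <- truth$beta_C[g] * x + covpart + u + rnorm(n, 0, se)
        tr[g, ] <- truth$delta[g] + truth$beta_T[g] * x +
            truth$pop_diff[g] * pop01 + covpart + u + rnorm(n, 0, se)
    }
    list(pe = PairedExpression(tr, ct,
             colData = S4Vectors::DataFrame(
                 population = populations(gsim$geno))),
         covariates = Z)
}

#' Simulate a complete study with known truth
#'
#' Draws genotypes, model assignments and paired expression from one seed,
#' returning everything in memory and optionally writing the standard file
#' formats (wide expression TSV, VCF, BED, covariates TSV, truth TSV) that
#' the readers of this package consume.
#'
#' @param config a [simConfig()] list.
#' @param out_dir optional directory to write the fixture bundle to.
#' @return list with `pe`, `geno`, `genes`, `covariates`, `truth`,
#'   `causal`, `causal_freq`, `config` (and `files` when written).
#' @export
simStudy <- function(config = simConfig(), out_dir = NULL) {
    old <- .Random.seed.save()
    on.exit(.Random.seed.restore(old))
    set.seed(config$seed)
    gsim <- simGenotypes(config)
    truth <- .simTruth(config, gsim)
    ex <- simPairedExpression(gsim, truth, config)
    out <- list(pe = ex$pe, geno = gsim$geno, genes = gsim$genes,
                covariates = ex$covariates, truth = truth,
                causal = gsim$causal, causal_freq = gsim$causal_freq,
                config = config)
    if (!is.null(out_dir)) {
        dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
        f <- list(expression = file.path(out_dir, "expression.tsv"),
                  vcf = file.path(out_dir, "genotypes.vcf"),
                  bed = file.path(out_dir, "genes.bed"),
                  covariates = file.path(out_dir, "covariates.tsv"),
                  truth = file.path(out_dir, "truth.tsv"))
        writeExpression(ex$pe, f$expression)
        .writeVcf(gsim$geno, f$vcf)
        rtracklayer::export(gsim$genes, f$bed, format = "BED")
        write.table(data.frame(individual = rownames(ex$covariates),
                               ex$covariates,
                               population = populations(gsim$geno)),
                    f$covariates, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        write.table(truth, f$truth, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        out$files <- f
    }
    out
}

## Minimal VCFv4.2 text emitter for simulated biallelic genotypes; read
## back with readGenotypes(format = "vcf").
.writeVcf <- function(geno, path) {
    dos <- dosages(geno)
    snps <- snpRanges(geno)
    gtmap <- c("0/0", "0/1", "1/1")
    gt <- matrix(gtmap[dos + 1L], nrow(dos), ncol(dos))
    gt[is.na(dos)] <- "./."
    header <- c("##fileformat=VCFv4.2",
                "##source=responseQTL-simStudy",
                '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
                paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", colnames(dos)),
                      collapse = "\t"))
    body <- paste(as.character(GenomicRanges::seqnames(snps)),
                  GenomicRanges::start(snps), names(snps),
                  S4Vectors::mcols(snps)$ref, S4Vectors::mcols(snps)$alt,
                  ".", "PASS", ".", "GT",
                  apply(gt, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(c(header, body), path)
    invisible(path)
}
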