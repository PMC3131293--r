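#' Allelic-imbalance test at an eQTL
#'
#' Tests whether heterozygotes at an eQTL show allele-specific expression
#' within one treatment condition. Input log-ratios follow the
#' numerator-is-the-increasing-allele convention (natural log of the
#' allele-1/allele-2 quantity, numerator fixed to the allele associated
#' with increased expression in that condition), so cis-regulation predicts
#' a *positive* shift in heterozygotes. Homozygotes, where both alleles
#' share every cis-regulatory variant, serve as the empirical null for
#' technical imbalance. Log-ratios are quantile-normalized within the
#' treatment, then compared by a one-tailed Welch t-test (heterozygote
#' mean greater).
#'
#' @param log_ratio numeric vector of allelic log-ratios (one treatment).
#' @param genotype_class `"het"`/`"hom"` per measurement.
#' @return list with `effect` (mean normalized heterozygote log-ratio),
#'   `p` (one-tailed), `n_het`, `n_hom`.
#' @export
aseTest <- function(log_ratio, genotype_class) {
    stopifnot(length(log_ratio) == length(genotype_class))
    if (!all(genotype_class %in% c("het", "hom")))
        stop("genotype_class must be 'het' or 'hom'")
    if (any(!is.finite(log_ratio))) stop("log ratios must be finite")
    n_het <- sum(genotype_class == "het")
    n_hom <- sum(genotype_class == "hom")
    if (n_het < 2) stop("too few heterozygote samples (", n_het, ")")
    if (n_hom < 2) stop("too few homozygote samples (", n_hom, ")")
    qn <- quantileNormalizeToNormal(log_ratio)
    het <- qn[genotype_class == "het"]
    hom <- qn[genotype_class == "hom"]
    if (sd(het) == 0 && sd(hom) == 0 && mean(het) == mean(hom))
        return(list(effect = mean(het), p = 0.5, n_het = n_het,
                    n_hom = n_hom))
    tt <- t.test(het, hom, alternative = "greater", var.equal = FALSE)
    list(effect = mean(het), p = tt$p.value, n_het = n_het, n_hom = n_hom)
}

#' Upper-tail hypergeometric overlap test
#'
#' Probability of drawing an overlap at least as large as observed between
#' two gene sets sampled from a common universe (e.g. genes differentially
#' expressed in two cell types).
#'
#' @param size_a,size_b set sizes.
#' @param overlap observed intersection size.
#' @param universe universe size.
#' @return upper-tail p-value, `P(X >= overlap)`.
#' @export
overlapTest <- function(size_a, size_b, overlap, universe) {
    stopifnot(size_a <= universe, size_b <= universe, overlap >= 0)
    if (overlap > min(size_a, size_b))
        stop("overlap exceeds the smaller set size")
    phyper(overlap - 1, size_a, universe - size_a, size_b,
           lower.tail = FALSE)
}
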