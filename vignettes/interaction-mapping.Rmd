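---
title: "Mapping genotype-treatment interactions from paired expression data"
author: "responseQTL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping genotype-treatment interactions from paired expression data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(responseQTL)
```

# The problem

A cellular response phenotype — say the transcriptional response of a
lymphoblastoid cell line to a glucocorticoid such as dexamethasone — is
measured on the *same* individuals under two conditions: a treated aliquot
and a vehicle control. A *response eQTL* (equivalently, a
genotype-by-treatment interaction) is a variant whose effect on expression
differs between the conditions. The scientific question is not just
"is there an interaction?" but *what kind*: an effect present only under
treatment, only at baseline, the same in both, or different in the two.

`responseQTL` compares five models per SNP-gene pair:

* **M0** — no genotype effect in either condition;
* **M1** — the same effect $\beta$ in both conditions (an ordinary,
  non-interacting eQTL);
* **M2** — an effect only in treated samples;
* **M3** — an effect only in control samples;
* **M4** — effects in both conditions that differ.

A per-SNP Bayes factor quantifies the support for each of M1–M4 against
M0; a hierarchical model combines SNPs within each gene and shares model
proportions across genes; posterior probabilities classify genes and give
a direct Bayesian FDR. A conventional log-fold-change association scan
with permutation FDR is included as the frequentist comparator, along
with a population-by-treatment contrast, allelic-imbalance and set-overlap
validation statistics, and a synthetic-data generator with known truth.

# The likelihood: a difference/average rotation

The two measurements of individual $i$ share an individual-level
component $u_i$ (culture conditions, EBV load, cell state), which induces
the pairing correlation. Writing $y_{T,i}$ and $y_{C,i}$ for treated and
control log2 expression,

$$y_{C,i} = \mu + \beta_C x_i + u_i + \varepsilon_{C,i}, \qquad
  y_{T,i} = \mu + \Delta + \beta_T x_i + u_i + \varepsilon_{T,i},$$

with $x_i \in \{0,1,2\}$ the minor-allele dosage. The rotation
$d_i = y_{T,i} - y_{C,i}$ (the log fold change) and
$m_i = (y_{T,i}+y_{C,i})/2$ removes $u_i$ from $d$ and concentrates it in
$m$, so that — assuming equal residual variances in the two conditions,
reasonable after per-condition normalization — the two blocks are
independent Gaussian regressions with effects

$$\beta_d = \beta_T - \beta_C, \qquad \beta_m = (\beta_T + \beta_C)/2 .$$

Each model is a constraint on $(\beta_d, \beta_m)$: M1 has $\beta_d = 0$;
M2 a single effect entering with loadings $(1, \tfrac12)$; M3 with
$(-1, \tfrac12)$; M4 has independent $\beta_d$ and $\beta_m$. Residual
precisions $\tau_d, \tau_m$ are plugged in from the residuals of each
block's regression on $[1, x]$ (variance denominator $n-2$); using the
richest marginal design avoids biasing toward the null, and fixing the
precisions keeps every Bayes factor closed-form:

$$\mathrm{BF} = \sqrt{\frac{V}{V+W}}\,
  \exp\!\Big(\frac{z^2}{2}\,\frac{W}{V+W}\Big),
  \qquad V = \frac{1}{\tau \sum x_i^2},\; z = \hat\beta/\sqrt{V},$$

with $W$ the prior variance of the effect. For fixed $\tau$ this is the
exact Gaussian integral, which is why the test suite can check it against
numerical quadrature to $10^{-3}$ in $\log_{10}$.

# The effect-size prior and why it is wide

Per-condition effects are given a $N(0, (\sigma_b\,\mathrm{sd}_y)^2)$
prior, where $\mathrm{sd}_y$ is the pooled per-condition phenotype
standard deviation, averaged over a small grid of $\sigma_b$ on the
natural scale. Because the prior scales with $\mathrm{sd}_y$, all Bayes
factors are invariant under affine transforms applied to both conditions.
Under M4 the induced priors are $\beta_d \sim N(0, 2w)$ and
$\beta_m \sim N(0, w/2)$, independent, so the M4 BF factorizes exactly
into the two block BFs.

The default grid is $\sigma_b \in \{1.0, 1.5, 2.25\}$ — deliberately
restricted to *large* standardized effects. The reason is an
identifiability requirement of the hierarchical layer, not a belief that
small effects do not exist. A prior component whose variance $W$ is
comparable to the sampling variance $V$ of the effect estimate describes
an alternative that is statistically indistinguishable from the null at
the single-gene level: its Bayes factor hovers near 1 for null genes, and
in the genome-wide mixture the EM can then shift arbitrary amounts of
null mass into such a component with almost no likelihood penalty,
corrupting both the estimated model proportions and every posterior
derived from them. We verified this directly: with near-null grid
components the estimated no-interaction proportion roughly doubles on
data with a known 20% planted proportion, while with the default grid all
proportions are recovered to within a few percent. At the reference
design ($n \approx 114$ individuals, common variants) the smallest
default component has $W/V$ of order $10^2$, comfortably detectable. Users
analysing single SNPs outside the hierarchical model are free to pass any
grid (including the traditional
$\{0.05, 0.1, 0.2, 0.4, 0.8, 1.6\}$) through the `priorSd` argument; for
genome-wide prior estimation the wide default is strongly recommended.

# The hierarchical model

With at most one causal SNP per gene and a uniform prior over which
window SNP it is, the gene-level BF for model $M$ is the arithmetic mean
of its SNP BFs. A uniform SNP prior is used rather than a
distance-decaying one: with 100 kb windows the decay across the window is
modest, and nothing in the intended use requires positional weighting.

Genome-wide model proportions $\pi = (\pi_0, \dots, \pi_4)$ are estimated
by EM on the gene-level BFs (BF of M0 $\equiv$ 1): responsibilities
$r_g(M) \propto \pi_M \mathrm{BF}_g(M)$, M-step $\pi_M = \bar r(M)$, run
to a log-likelihood tolerance of $10^{-6}$ (cap 10,000 iterations, floor
$10^{-8}$ with renormalization, null-heavy initialization
$(0.9, 0.04, 0.02, 0.02, 0.02)$ reflecting that most genes have no cis
signal). Genes are weighted uniformly regardless of window SNP count.
Per-gene posteriors follow by Bayes' rule; a gene's classification is the
argmax posterior among M1–M4, so a large single-SNP BF for the general
interaction can still be outweighed by a small genome-wide prior on M4.
The eQTN is the SNP maximizing prior-weighted total alternative support,
ties to the smallest position. The Bayesian FDR of a selection is the
mean of $1 - \mathrm{PP}$ over the selected genes — applied to
$\mathrm{PP}_{\text{int}} = \mathrm{PP}_2+\mathrm{PP}_3+\mathrm{PP}_4$
for interaction calls and to $\mathrm{PP}_1$ for no-interaction calls.
`selectAtFDR()` inverts the estimator to select at a target FDR, which is
how the Bayesian and permutation pipelines are compared at matched
nominal error.

# The frequentist comparator

`lfcScan()` regresses each gene's log fold change on each cis SNP,
records the minimum p-value per gene, and estimates FDR from permutation
rounds: a single master seed draws each round's reordering of genotype
labels relative to the paired phenotype rows, and the *same* reordering is
applied to every gene within a round so the null preserves the
correlation structure across genes. (A per-gene seed policy would break
exactly that property, so it is not offered.) The estimator is
$\widehat{\mathrm{FDR}}(t) = \frac{\overline{\#\{p^{\mathrm{perm}} \le t\}}}
{\#\{p^{\mathrm{obs}} \le t\}}$, clipped to $[0,1]$ and made monotone by a
cumulative maximum; p-values below numerical underflow are floored at
$10^{-300}$. Default round counts are 10 for differential expression and
wide scans, 100 for 100 kb windows, 3 genome-wide.

# Preprocessing conventions

* Quantile normalization to normal scores maps rank $r$ (ties averaged)
  to $\Phi^{-1}((r-0.5)/n)$; it is applied pooled across all samples
  before differential-expression testing and per gene across individuals
  (each condition separately) before the population contrast. Per-gene,
  per-condition normalization also equalizes the residual variances the
  d/m rotation assumes.
* Covariates that shift baseline expression (EBV copy number, growth
  rate, mitochondrial copy number) are removed per condition by OLS
  residualization before mapping; correction precedes normalization by
  default. Residuals are mean-zero; downstream regressions refit their
  own intercepts.
* Genotypes are oriented so dosages count the minor allele (frequency
  over non-missing individuals; ties at 0.5 keep the ALT orientation).
  Missing dosages are handled per SNP by complete cases — no imputation —
  with a minimum of 5 complete cases and a minor-allele count of at least
  2, below which the SNP is skipped with a recorded reason.
* Gene coordinates are BED (0-based half-open) on disk and `GRanges`
  (1-based) in memory; a SNP at 0-based position $p$ is cis to a gene
  iff $\mathrm{start} - W \le p < \mathrm{end} + W$ on the same
  chromosome, strand ignored, with $W = 100$ kb by default anchored to
  the gene body (the window definition is stated only as "within 100 kb
  of the gene" in the literature this follows; gene-body anchoring is the
  package's choice).

# The population contrast

Between-population differences in transcriptional response are
population-by-treatment interactions, so the same machinery runs with the
0/1 population indicator in place of the dosage, after per-gene
normalization; a separate EM estimates the population-level proportions.
Direction ("up-regulated") is the sign of the mean log fold change and
the "stronger" population is the one with the larger response in that
direction. Under Hardy-Weinberg equilibrium the genetic prediction of a
between-population response difference from an eQTN is
$2\hat\beta\,(f_1 - f_2)$; observed differences are regressed on
predictions with an intercept, and the fit's $r^2$ and slope p-value
reported. Enrichment of interaction eQTLs among population-different
genes uses the cross-product odds ratio (0.5 added to every cell only
when a cell is zero) and a two-sided Fisher exact p-value.

# Validation statistics

Allelic imbalance: within a treatment, allelic log-ratios (natural log,
numerator fixed to the allele associated with increased expression) are
quantile-normalized and heterozygotes compared to homozygotes — the
empirical null for technical imbalance — by a one-tailed Welch t-test
(het $>$ hom; the unequal-variance form is the safer default when group
sizes and variances differ, and the direction is fixed by the numerator
convention). Comparisons are within treatment, matching how the
validation is reported per condition. Set-overlap significance is the
upper-tail hypergeometric probability.

# What the simulator emulates — and what it does not

`simStudy()` draws, from one seed: two populations (57 + 57 individuals
by default) with per-population allele frequencies; Hardy-Weinberg
dosages with window LD by allele copying (a proxy allele copies the
causal allele with probability $\rho_{LD} = 0.5$, else redraws); per-gene
model assignments planted with *exact* counts (largest-remainder rounding
of $\pi_{\text{true}} \cdot G$, randomly placed) so the generating
proportions equal $\pi_{\text{true}}$ rather than a multinomial draw —
recovery experiments then measure estimation error, not assignment noise;
fixed-magnitude effects $\pm\beta$ (default $0.8$ residual sd) for M1–M3
and independent $N(0, \beta^2)$ per-condition effects for M4; a shared
individual component with $\sigma_u^2 = \sigma_e^2 = 1$, giving pairing
correlation 0.5 at null genes; per-gene treatment shifts $N(0,1)$; and
one standard-normal covariate adding 0.5 to both conditions, emulating a
baseline confounder of the EBV-copy-number type.

It does **not** emulate microarray noise models, realistic haplotype
structure or recombination, polygenic trans effects, or
expression-dependent variance. Passing tests therefore demonstrate the
statistical machinery is correct and calibrated under its own
assumptions; they do not certify performance on any particular real
dataset. The M4 generator deserves a caveat in reading results: drawing
$\beta_T, \beta_C$ independently from $N(0, \beta^2)$ produces some genes
whose two effects happen to be similar (M1-like) or both near zero
(null-like); a small downward bias in $\hat\pi_4$ at these study sizes is
the correct Bayesian answer to genuinely ambiguous data, not a defect of
the EM.

# Numerical choices and degenerate inputs

Grid and SNP averaging are done on the natural scale via stable
log-sum-exp; EM responsibilities are computed in log space, so BFs of
$10^{300}$ or more are handled without overflow. Constant phenotypes,
monomorphic SNPs, and windows with no usable SNP are skipped and
reported, never fatal; genes without usable SNPs are excluded from the EM
but appear in the output. Rank-deficient covariate designs and unpaired
individuals are hard errors naming the offending columns or samples.
Problem sizes used by the automated checks — 2,000 genes for prior
recovery and 100 replicates of 1,000 null genes for permutation
calibration — were chosen as the smallest sizes at which the target
tolerances are meaningfully testable.

# Known limitations

One eQTL per gene at most; no LD-aware fine-mapping; plain OLS (no
kinship or mixed models); populations are taken as given labels with no
admixture modelling; equal residual variance across conditions is assumed
by the rotation; the plug-in precisions slightly understate uncertainty
relative to a full inverse-gamma treatment, which matters mainly at very
small $n$.
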