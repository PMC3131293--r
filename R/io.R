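#' Read a paired two-condition expression table
#'
#' Two dialects are supported. In the wide layout every individual
#' contributes a `<id>_treated` and a `<id>_control` column and the first
#' column holds gene ids. In the long layout the columns are `gene_id`,
#' `individual`, `condition` (`treated`/`control`) and `value`.
#'
#' Individuals present in only one condition are a hard error (the method
#' requires paired measurements), as is any non-numeric expression cell.
#'
#' @param path path to a tab-delimited text file.
#' @param layout `"wide"` or `"long"`.
#' @return a [PairedExpression-class] object.
#' @export
readExpression <- function(path, layout = c("wide", "long")) {
    layout <- match.arg(layout)
    tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (layout == "long") {
        need <- c("gene_id", "individual", "condition", "value")
        if (!all(need %in% colnames(tab)))
            stop("long layout requires columns: ", paste(need, collapse = ", "))
        if (!is.numeric(tab$value))
            stop("non-numeric expression value in column 'value', row ",
                 which(!grepl("^\\s*-?[0-9.eE+]+\\s*$", tab$value))[1])
        genes <- unique(tab$gene_id)
        inds <- unique(tab$individual)
        mk <- function(cond) {
            sub <- tab[tab$condition == cond, ]
            m <- matrix(NA_real_, length(genes), length(inds),
                        dimnames = list(genes, inds))
            m[cbind(match(sub$gene_id, genes), match(sub$individual, inds))] <-
                sub$value
            m
        }
        tr <- mk("treated"); ct <- mk("control")
        lone <- inds[colSums(is.na(tr)) == length(genes) |
                     colSums(is.na(ct)) == length(genes)]
        if (length(lone))
            stop("individual(s) present in only one condition: ",
                 paste(lone, collapse = ", "))
        return(PairedExpression(tr, ct))
    }
    gene_ids <- as.character(tab[[1]])
    vals <- tab[, -1, drop = FALSE]
    cn <- colnames(vals)
    is_tr <- grepl("_treated$", cn)
    is_ct <- grepl("_control$", cn)
    if (!all(is_tr | is_ct))
        stop("wide layout columns must end in _treated or _control; bad: ",
             paste(cn[!(is_tr | is_ct)], collapse = ", "))
    ids_tr <- sub("_treated$", "", cn[is_tr])
    ids_ct <- sub("_control$", "", cn[is_ct])
    lone <- c(setdiff(ids_tr, ids_ct), setdiff(ids_ct, ids_tr))
    if (length(lone))
        stop("individual(s) present in only one condition: ",
             paste(lone, collapse = ", "))
    for (j in seq_along(vals)) {
        v <- vals[[j]]
        if (!is.numeric(v)) {
            bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))[1]
            stop("non-numeric expression cell at row ", bad,
                 ", column '", cn[j], "'")
        }
    }
    vals <- as.matrix(vals)
    rownames(vals) <- gene_ids
    tr <- vals[, paste0(ids_tr, "_treated"), drop = FALSE]
    ct <- vals[, paste0(ids_tr, "_control"), drop = FALSE]
    colnames(tr) <- colnames(ct) <- ids_tr
    PairedExpression(tr, ct)
}

#' Write a paired expression table (wide layout)
#'
#' Inverse of [readExpression()]; `readExpression(writeExpression(x, f))`
#' reproduces every value and id.
#'
#' @param x a [PairedExpression-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeExpression <- function(x, path) {
    tr <- treatedExpr(x); ct <- controlExpr(x)
    out <- data.frame(gene_id = rownames(tr), check.names = FALSE)
    for (id in colnames(tr)) {
        out[[paste0(id, "_treated")]] <- tr[, id]
        out[[paste0(id, "_control")]] <- ct[, id]
    }
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

## Orient one dosage matrix to the minor allele. Frequency is computed over
## non-missing individuals; ties at 0.5 keep the alt orientation.
.orientMinor <- function(dos) {
    freq <- rowMeans(dos, na.rm = TRUE) / 2
    flip <- !is.na(freq) & freq > 0.5
    dos[flip, ] <- 2L - dos[flip, , drop = FALSE]
    list(dosages = dos, flipped = flip)
}

#' Read genotypes from VCF or a dosage TSV
#'
#' VCF records are parsed from their GT fields; multi-allelic records are
#' skipped with a warning. Dosages are oriented so that they count copies
#' of the minor allele (allele frequency computed over non-missing
#' individuals; a tie at 0.5 keeps the ALT orientation) and the `flipped`
#' metadata column records any re-orientation.
#'
#' The dosage TSV dialect has columns `snp_id`, `chrom`, `pos` (1-based),
#' `ref`, `alt`, then one column per individual with values 0/1/2, `.` or
#' `NA` for missing.
#'
#' @param path input file.
#' @param format `"vcf"` or `"dosage"`.
#' @param samples optional character vector of individual ids expected to
#'   overlap the file (e.g. the expression individuals); no overlap is an
#'   error.
#' @param population optional per-individual population labels (named, or
#'   in file column order).
#' @return a [GenotypeData-class] object.
#' @export
readGenotypes <- function(path, format = c("vcf", "dosage"), samples = NULL,
                          population = NULL) {
    format <- match.arg(format)
    if (format == "vcf") {
        vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
        alt <- VariantAnnotation::alt(vcf)
        multi <- S4Vectors::elementNROWS(alt) != 1
        if (any(multi)) {
            warning(sum(multi), " multi-allelic record(s) skipped")
            vcf <- vcf[!multi]
            alt <- alt[!multi]
        }
        gt <- VariantAnnotation::geno(vcf)$GT
        dos <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
        clean <- gsub("\\|", "/", gt)
        dos[clean %in% c("0/0")] <- 0L
        dos[clean %in% c("0/1", "1/0")] <- 1L
        dos[clean %in% c("1/1")] <- 2L
        gr <- SummarizedExperiment::rowRanges(vcf)
        snps <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                                       IRanges::ranges(gr))
        names(snps) <- rownames(gt)
        S4Vectors::mcols(snps)$ref <-
            as.character(VariantAnnotation::ref(vcf))
        S4Vectors::mcols(snps)$alt <- as.character(unlist(alt))
    } else {
        tab <- read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = c("NA", "."))
        need <- c("snp_id", "chrom", "pos", "ref", "alt")
        if (!all(need %in% colnames(tab)))
            stop("dosage TSV requires columns: ", paste(need, collapse = ", "))
        ind <- setdiff(colnames(tab), need)
        dos <- as.matrix(tab[, ind, drop = FALSE])
        storage.mode(dos) <- "integer"
        rownames(dos) <- tab$snp_id
        snps <- GenomicRanges::GRanges(tab$chrom,
                                       IRanges::IRanges(tab$pos, width = 1),
                                       ref = tab$ref, alt = tab$alt)
        names(snps) <- tab$snp_id
    }
    if (!is.null(samples) && !length(intersect(samples, colnames(dos))))
        stop("no overlapping individual ids between genotypes and the ",
             "supplied sample list")
    o <- .orientMinor(dos)
    S4Vectors::mcols(snps)$flipped <- o$flipped
    GenotypeData(o$dosages, snps, population = population)
}

#' Read gene coordinates from BED
#'
#' BED intervals are 0-based half-open on disk; the returned
#' [GenomicRanges::GRanges] uses the usual 1-based closed convention. Gene
#' ids come from the BED name column and must be unique.
#'
#' @param path a BED file with at least 4 columns (chrom, start, end, name).
#' @return a `GRanges` named by gene id.
#' @export
readGeneBed <- function(path) {
    gr <- rtracklayer::import(path, format = "BED")
    if (is.null(gr$name) || anyNA(gr$name))
        stop("BED file must carry gene ids in the name column")
    if (anyDuplicated(gr$name))
        stop("duplicate gene ids in BED file: ",
             paste(unique(gr$name[duplicated(gr$name)]), collapse = ", "))
    names(gr) <- gr$name
    gr
}

#' Assign cis-window SNPs to genes
#'
#' A SNP belongs to a gene's cis window iff it lies on the same chromosome
#' within `window` bp of the gene body (boundaries included on the left,
#' strand ignored): in 0-based coordinates, `start - W <= pos < end + W`.
#' The default window of 100 kb around each gene is the scale at which
#' local response-eQTL signal is concentrated.
#'
#' @param genes `GRanges` of gene bodies (e.g. from [readGeneBed()]).
#' @param geno a [GenotypeData-class] (or a `GRanges` of SNP positions).
#' @param window flank size W in bp (>= 0).
#' @return a named list (one element per gene) of integer SNP indices into
#'   `snpRanges(geno)`; empty windows give `integer(0)`.
#' @export
mapCisSnps <- function(genes, geno, window = 1e5) {
    stopifnot(window >= 0)
    snps <- if (methods::is(geno, "GenotypeData")) snpRanges(geno) else geno
    ext <- GenomicRanges::GRanges(
        GenomicRanges::seqnames(genes),
        IRanges::IRanges(pmax(1, GenomicRanges::start(genes) - window),
                         GenomicRanges::end(genes) + window))
    ## non-shared seqlevels (e.g. genes restricted to one chromosome) are a
    ## legitimate empty-overlap case, not a user error
    hits <- suppressWarnings(
        GenomicRanges::findOverlaps(snps, ext, ignore.strand = TRUE))
    out <- rep(list(integer(0)), length(genes))
    names(out) <- if (!is.null(names(genes))) names(genes)
                  else as.character(seq_along(genes))
    sp <- split(S4Vectors::queryHits(hits), S4Vectors::subjectHits(hits))
    out[as.integer(names(sp))] <- lapply(sp, as.integer)
    out
}

#' Run configuration
#'
#' Bundles the tunable parameters shared by the mapping pipelines. Defaults:
#' 100 kb cis window, no MAF filter beyond the minimum minor-allele count
#' rule of the BF engine, the standard six-point effect-size prior grid (in
#' units of the pooled per-condition phenotype sd), EM tolerance 1e-6.
#'
#' @param cis_window_bp,maf_min,prior_sd_grid,em_tolerance,em_max_iter
#'   numeric settings; see Details in the package vignette.
#' @param n_permutations permutation rounds for the frequentist scans.
#' @param seed integer master seed.
#' @param posterior_threshold posterior-probability cutoff for calling
#'   interactions (default 0.7).
#' @return a validated named list of class `run_config`.
#' @export
runConfig <- function(cis_window_bp = 1e5, maf_min = 0,
                      prior_sd_grid = c(1, 1.5, 2.25),
                      em_tolerance = 1e-6, em_max_iter = 10000L,
                      n_permutations = 10L, seed = 1L,
                      posterior_threshold = 0.7) {
    stopifnot(cis_window_bp > 0, all(prior_sd_grid > 0),
              maf_min >= 0, maf_min < 0.5, em_tolerance > 0,
              n_permutations >= 1, posterior_threshold > 0,
              posterior_threshold < 1)
    structure(list(cis_window_bp = cis_window_bp, maf_min = maf_min,
                   prior_sd_grid = prior_sd_grid,
                   em_tolerance = em_tolerance,
                   em_max_iter = as.integer(em_max_iter),
                   n_permutations = as.integer(n_permutations),
                   seed = as.integer(seed),
                   posterior_threshold = posterior_threshold),
              class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [runConfig()]; unknown keys are an error so
#' typos do not silently fall back to defaults. Values supplied in
#' `overrides` (e.g. parsed from command-line flags) win over the file.
#'
#' @param path YAML file, or `NULL` for all defaults.
#' @param overrides named list of values overriding the file.
#' @return a `run_config` list.
#' @export
readRunConfig <- function(path = NULL, overrides = list()) {
    vals <- if (is.null(path)) list() else yaml::read_yaml(path)
    known <- names(formals(runConfig))
    bad <- setdiff(names(vals), known)
    if (length(bad))
        stop("unknown config key(s): ", paste(bad, collapse = ", "))
    vals[names(overrides)] <- overrides
    do.call(runConfig, vals)
}

#' Write a JSON run manifest
#'
#' Records the configuration, seed and package version next to a run's
#' outputs so results can be reproduced.
#'
#' @param config a `run_config` list.
#' @param path output JSON path.
#' @param extra optional named list of additional fields.
#' @return `path`, invisibly.
#' @export
writeRunManifest <- function(config, path, extra = list()) {
    manifest <- c(list(package = "responseQTL",
                       version = as.character(utils::packageVersion("responseQTL")),
                       r_version = R.version.string,
                       timestamp = format(Sys.time(), tz = "UTC"),
                       config = unclass(config)),
                  extra)
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    invisible(path)
}
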