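#' Individual call-rate filter
#'
#' Removes individuals whose fraction of non-missing calls is strictly
#' below \code{minCallRate}; an individual at exactly the threshold is
#' kept. Removed ids are reported via \code{message()} and recorded in
#' \code{metadata(gd)$qc$removed_individuals}.
#'
#' @param gd A \linkS4class{GenotypeData}.
#' @param minCallRate Minimum non-missing fraction, in (0, 1]. Default
#'   0.97.
#' @return The filtered \linkS4class{GenotypeData}.
#' @export
qcIndividuals <- function(gd, minCallRate = 0.97) {
    stopifnot(minCallRate > 0, minCallRate <= 1)
    g <- genoCounts(gd)
    cr <- colMeans(!is.na(g))
    drop <- cr < minCallRate
    if (all(drop))
        stop("call-rate filter at ", minCallRate,
             " removes every individual")
    removed <- colnames(g)[drop]
    if (length(removed))
        message("call-rate filter removed ", length(removed),
                " individual(s)")
    out <- gd[, !drop]
    md <- S4Vectors::metadata(out)
    md$qc$removed_individuals <- removed
    md$qc$min_call_rate <- minCallRate
    S4Vectors::metadata(out) <- md
    out
}

#' SNP filter for the ROH marker set
#'
#' Keeps autosomal SNPs whose missing-call fraction is at most
#' \code{maxMissing}. No minor-allele-frequency filter is applied, so
#' the run-of-homozygosity scan keeps maximal genome coverage.
#'
#' @param gd A \linkS4class{GenotypeData}.
#' @param maxMissing Maximum missing fraction per SNP. Default 0.03.
#' @return The filtered \linkS4class{GenotypeData}.
#' @export
qcSnpsRoh <- function(gd, maxMissing = 0.03) {
    stopifnot(maxMissing >= 0, maxMissing <= 1)
    g <- genoCounts(gd)
    missFrac <- rowMeans(is.na(g))
    keep <- isAutosome(gd) & missFrac <= maxMissing
    if (!any(keep))
        stop("ROH SNP filter removes every SNP")
    out <- gd[keep, ]
    md <- S4Vectors::metadata(out)
    md$qc$roh_snps_removed <- sum(!keep)
    md$qc$max_missing <- maxMissing
    S4Vectors::metadata(out) <- md
    out
}

#' SNP filter for the GRM marker set
#'
#' Applies, in order, two minor-allele-frequency filters on top of the
#' ROH set: SNPs with MAF strictly below \code{minMaf} in the declared
#' reference population are removed first, then remnant SNPs with MAF
#' strictly below \code{minMaf} across all individuals. A SNP at exactly
#' the threshold is kept.
#'
#' @param gd A \linkS4class{GenotypeData} (normally the ROH set).
#' @param ref Character vector of animal ids forming the reference
#'   population (e.g. the first selection generation).
#' @param minMaf MAF threshold. Default 0.05.
#' @return The filtered \linkS4class{GenotypeData}.
#' @export
qcSnpsGrm <- function(gd, ref, minMaf = 0.05) {
    stopifnot(minMaf >= 0, minMaf <= 0.5)
    ids <- sampleInfo(gd)$animal_id
    if (!length(intersect(ref, ids)))
        stop("no reference individuals present in the genotype data")
    pRef <- alleleFreqs(gd, subset = ref, warn = FALSE)$p
    mafRef <- pmin(pRef, 1 - pRef)
    keep1 <- !is.na(mafRef) & mafRef >= minMaf
    pAll <- alleleFreqs(gd, warn = FALSE)$p
    mafAll <- pmin(pAll, 1 - pAll)
    keep <- keep1 & !is.na(mafAll) & mafAll >= minMaf
    if (!any(keep))
        stop("GRM MAF filter removes every SNP")
    out <- gd[keep, ]
    md <- S4Vectors::metadata(out)
    md$qc$grm_removed_ref_maf <- sum(!keep1)
    md$qc$grm_removed_all_maf <- sum(keep1 & !keep)
    md$qc$min_maf <- minMaf
    md$qc$reference <- ref
    S4Vectors::metadata(out) <- md
    out
}

#' Reference-allele frequencies on a declared subset
#'
#' Computes, per SNP, the frequency p of the counted (reference) allele
#' over the non-missing calls of the given individuals.
#'
#' @param gd A \linkS4class{GenotypeData}.
#' @param subset Character vector of animal ids (default: all).
#' @param warn Warn when a SNP has no non-missing call in the subset
#'   (its p is \code{NA}).
#' @return A \code{data.frame} with columns \code{snp}, \code{p},
#'   \code{n_obs}; the subset description is kept in
#'   \code{attr(, "subset")}.
#' @export
alleleFreqs <- function(gd, subset = NULL, warn = TRUE) {
    g <- genoCounts(gd)
    if (!is.null(subset)) {
        keep <- colnames(g) %in% subset
        if (!any(keep)) stop("subset matches no genotyped individual")
        g <- g[, keep, drop = FALSE]
    }
    n <- rowSums(!is.na(g))
    p <- rowSums(g, na.rm = TRUE) / (2 * n)
    p[n == 0] <- NA_real_
    if (warn && any(n == 0))
        warning(sum(n == 0), " SNP(s) entirely missing in the subset")
    out <- data.frame(snp = rownames(g), p = p, n_obs = n,
                      row.names = NULL, stringsAsFactors = FALSE)
    attr(out, "subset") <- if (is.null(subset)) "all" else
        paste0(length(subset), " individuals")
    out
}
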