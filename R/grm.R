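# Shared helper: align a frequency table to the SNPs of gd and return
# the genotype matrix, p vector and validity mask (non-missing genotype,
# defined p).
.alignFreqs <- function(gd, freqs) {
    g <- genoCounts(gd)
    p <- freqs$p[match(rownames(g), freqs$snp)]
    if (anyNA(match(rownames(g), freqs$snp)))
        stop("frequency table does not cover every SNP of the data")
    valid <- !is.na(g) & !is.na(p)
    list(g = g, p = p, valid = valid)
}

#' Nejati-Javaremi inbreeding (individual homozygosity)
#'
#' Diagonal of the allelic relationship matrix: the fraction of an
#' individual's non-missing SNPs that are homozygous. Ranges in [0, 1]
#' and makes no reference to allele frequencies, so it measures identity
#' by state.
#'
#' @param gd A \linkS4class{GenotypeData} (normally the GRM SNP set).
#' @return Named numeric vector per individual (\code{NA} when an
#'   individual has no non-missing SNP).
#' @export
fNej <- function(gd) {
    g <- genoCounts(gd)
    n <- colSums(!is.na(g))
    out <- colSums(g != 1, na.rm = TRUE) / n
    out[n == 0] <- NA_real_
    out
}

#' Li & Horvitz inbreeding (excess homozygosity)
#'
#' Deviation of an individual's observed homozygosity from the
#' Hardy-Weinberg expectation under the reference-population allele
#' frequencies:
#' \deqn{F = (H_{obs} - H_{exp}) / (1 - H_{exp})}
#' with \eqn{H_{exp}} the mean of \eqn{1 - 2p(1-p)} over the
#' individual's non-missing SNPs. May be negative.
#'
#' @param gd A \linkS4class{GenotypeData}.
#' @param freqs Reference-population frequencies from [alleleFreqs()].
#' @return Named numeric vector per individual.
#' @export
fLH <- function(gd, freqs) {
    a <- .alignFreqs(gd, freqs)
    hom <- (a$g != 1) & a$valid
    nv <- colSums(a$valid)
    hobs <- colSums(hom, na.rm = TRUE) / nv
    hexpv <- 1 - 2 * a$p * (1 - a$p)
    hexp <- colSums(a$valid * hexpv, na.rm = TRUE) / nv
    out <- (hobs - hexp) / (1 - hexp)
    out[nv == 0 | hexp == 1] <- NA_real_
    names(out) <- colnames(a$g)
    out
}

#' VanRaden method-1 inbreeding
#'
#' Ratio form of the first VanRaden genomic relationship diagonal:
#' \deqn{F = \frac{\sum_j (x_j - 2p_j)^2}{2 \sum_j p_j (1 - p_j)} - 1}
#' with both sums over the individual's non-missing SNPs.
#'
#' @inheritParams fLH
#' @return Named numeric vector per individual.
#' @export
fVR1 <- function(gd, freqs) {
    a <- .alignFreqs(gd, freqs)
    x <- a$g
    x[!a$valid] <- NA_integer_
    num <- colSums((x - 2 * a$p)^2, na.rm = TRUE)
    den <- 2 * colSums(a$valid * a$p * (1 - a$p), na.rm = TRUE)
    out <- num / den - 1
    out[den == 0] <- NA_real_
    names(out) <- colnames(x)
    out
}

# SNPs fixed in the reference population cannot enter per-locus
# standardised sums; report how many were skipped (drift after the
# reference generation can fix SNPs that passed the MAF filter there).
.dropFixed <- function(a) {
    poly <- a$p > 0 & a$p < 1
    nfix <- sum(!poly, na.rm = TRUE)
    if (nfix > 0)
        message(nfix, " SNP(s) fixed in the reference population ",
                "excluded from per-locus sums")
    a$valid <- a$valid & !is.na(a$p) & poly
    a
}

#' VanRaden method-2 inbreeding
#'
#' Mean of per-locus standardised squared deviations:
#' \deqn{F = \frac{1}{m} \sum_j \frac{(x_j - 2p_j)^2}{2 p_j (1 - p_j)} - 1}
#' over the individual's non-missing SNPs with 0 < p < 1; SNPs fixed in
#' the reference population are excluded with a logged count.
#'
#' @inheritParams fLH
#' @return Named numeric vector per individual.
#' @export
fVR2 <- function(gd, freqs) {
    a <- .dropFixed(.alignFreqs(gd, freqs))
    x <- a$g
    x[!a$valid] <- NA_integer_
    term <- (x - 2 * a$p)^2 / (2 * a$p * (1 - a$p))
    m <- colSums(a$valid)
    out <- colSums(term, na.rm = TRUE) / m - 1
    out[m == 0] <- NA_real_
    names(out) <- colnames(x)
    out
}

#' Yang inbreeding (GCTA-style GRM diagonal)
#'
#' Mean of per-locus terms
#' \deqn{\frac{x_j^2 - (1 + 2p_j) x_j + 2p_j^2}{2 p_j (1 - p_j)}}
#' over the individual's non-missing SNPs with 0 < p < 1. A heterozygous
#' locus contributes -1 identically, regardless of p.
#'
#' @inheritParams fLH
#' @return Named numeric vector per individual.
#' @export
fYan <- function(gd, freqs) {
    a <- .dropFixed(.alignFreqs(gd, freqs))
    x <- a$g
    x[!a$valid] <- NA_integer_
    term <- (x^2 - (1 + 2 * a$p) * x + 2 * a$p^2) /
        (2 * a$p * (1 - a$p))
    m <- colSums(a$valid)
    out <- colSums(term, na.rm = TRUE) / m
    out[m == 0] <- NA_real_
    names(out) <- colnames(x)
    out
}

#' Adjust an estimator to a reference-generation mean
#'
#' Rescales inbreeding values so that the reference population averages
#' zero: \eqn{F_0 = (F - \bar F_{ref}) / (1 - \bar F_{ref})}. Applied to
#' the Nejati-Javaremi, Li & Horvitz and ROH coefficients to make them
#' measure identity by descent relative to the reference generation.
#'
#' @param f Numeric vector of per-individual inbreeding.
#' @param refMean Mean of the estimator over the reference population.
#' @return Adjusted values, same names as \code{f}.
#' @examples
#' adjustToReference(0.73, refMean = 0.61)  # 0.3077
#' @export
adjustToReference <- function(f, refMean) {
    if (is.na(refMean)) stop("reference mean is NA")
    if (refMean == 1) stop("reference mean of 1 leaves no variation")
    (f - refMean) / (1 - refMean)
}

#' Expected homozygosity per generation
#'
#' Within each generation (and optionally within each line), computes
#' allele frequencies on that cohort and averages \eqn{1 - 2p(1-p)}
#' across SNPs. For biallelic SNPs each per-SNP term is at least 0.5
#' (at p = 0.5). SNPs with no non-missing call in a cohort are skipped.
#'
#' @param gd A \linkS4class{GenotypeData} whose \code{colData} carries
#'   \code{generation} (and \code{line} if \code{perLine}).
#' @param perLine Also compute the series within each line.
#' @return A \code{data.frame} with columns \code{group} (\code{"all"}
#'   or a line label), \code{generation}, \code{f_exp},
#'   \code{n_animals}.
#' @export
fExpSeries <- function(gd, perLine = FALSE) {
    info <- sampleInfo(gd)
    if (!"generation" %in% names(info))
        stop("sample metadata has no 'generation'; see annotateSamples()")
    groups <- list(all = rep(TRUE, ncol(gd)))
    if (perLine) {
        if (!"line" %in% names(info))
            stop("perLine requires a 'line' sample column")
        for (l in sort(unique(stats::na.omit(info$line))))
            groups[[l]] <- !is.na(info$line) & info$line == l
    }
    out <- list()
    for (gname in names(groups)) {
        sel <- groups[[gname]]
        for (gen in sort(unique(stats::na.omit(info$generation[sel])))) {
            cols <- sel & !is.na(info$generation) & info$generation == gen
            g <- genoCounts(gd)[, cols, drop = FALSE]
            n <- rowSums(!is.na(g))
            p <- rowSums(g, na.rm = TRUE) / (2 * n)
            hexp <- 1 - 2 * p * (1 - p)
            out[[length(out) + 1L]] <- data.frame(
                group = gname, generation = gen,
                f_exp = mean(hexp[n > 0]), n_animals = sum(cols),
                stringsAsFactors = FALSE)
        }
    }
    do.call(rbind, out)
}
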