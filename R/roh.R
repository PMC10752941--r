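#' Construct ROH scanner parameters
#'
#' @param windowSnps,windowHetMax,windowMissingMax,windowHitThreshold
#'   Sliding-window rule: window size in SNPs, maximum heterozygous and
#'   missing calls for a window to count as homozygous, and the minimum
#'   fraction (inclusive) of overlapping homozygous windows for a SNP to
#'   be called in-run.
#' @param minLenKb,minSnps Minimum segment length (kb) and SNP count,
#'   both inclusive.
#' @param maxKbPerSnp Maximum average spacing (segment kb per SNP),
#'   inclusive.
#' @param maxGapKb Maximum distance between consecutive in-run SNPs of
#'   one segment; larger gaps split the segment.
#' @return A \linkS4class{RohParams}.
#' @export
rohParams <- function(windowSnps = 50, windowHetMax = 1,
                      windowMissingMax = 5, windowHitThreshold = 0.5,
                      minLenKb = 1000, minSnps = 100,
                      maxKbPerSnp = 50, maxGapKb = 1000) {
    new("RohParams",
        windowSnps = as.integer(windowSnps),
        windowHetMax = as.integer(windowHetMax),
        windowMissingMax = as.integer(windowMissingMax),
        windowHitThreshold = windowHitThreshold,
        minLenKb = minLenKb, minSnps = as.integer(minSnps),
        maxKbPerSnp = maxKbPerSnp, maxGapKb = maxGapKb)
}

#' @export
setMethod("show", "RohParams", function(object) {
    cat("RohParams:", object@windowSnps, "SNP windows (<=",
        object@windowHetMax, "het, <=", object@windowMissingMax,
        "missing), hit threshold", object@windowHitThreshold, "\n",
        " segments: >=", object@minSnps, "SNPs, >=", object@minLenKb,
        "kb, <=", object@maxKbPerSnp, "kb/SNP, gap <=", object@maxGapKb,
        "kb\n")
})

# In-run call for one individual on one chromosome. Returns a logical
# vector over the chromosome's SNPs. SNPs near chromosome ends are
# covered by fewer windows; the hit fraction uses the actual number of
# overlapping windows. Chromosomes shorter than one window have no
# windows and therefore no in-run SNPs.
.inRun <- function(x, params) {
    m <- length(x)
    W <- params@windowSnps
    nw <- m - W + 1L
    if (nw < 1L) return(rep(FALSE, m))
    het <- !is.na(x) & x == 1L
    mis <- is.na(x)
    ch <- cumsum(c(0L, het))
    cm <- cumsum(c(0L, mis))
    idx <- seq_len(nw)
    ok <- (ch[idx + W] - ch[idx]) <= params@windowHetMax &
          (cm[idx + W] - cm[idx]) <= params@windowMissingMax
    co <- cumsum(c(0L, ok))
    k <- seq_len(m)
    lo <- pmax(1L, k - W + 1L)
    hi <- pmin(nw, k)
    hits <- co[hi + 1L] - co[lo]
    nwin <- hi - lo + 1L
    hits / nwin >= params@windowHitThreshold
}

# Candidate segments from an in-run mask: maximal stretches, split at
# gaps, then the length/count/density filters.
.maskToSegments <- function(inrun, bp, params) {
    if (!any(inrun)) return(NULL)
    r <- rle(inrun)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    segs <- list()
    for (i in which(r$values)) {
        idx <- starts[i]:ends[i]
        if (length(idx) > 1L) {
            gap <- diff(bp[idx]) > params@maxGapKb * 1000
            parts <- split(idx, cumsum(c(FALSE, gap)))
        } else parts <- list(idx)
        for (part in parts) {
            n <- length(part)
            kb <- (bp[part[n]] - bp[part[1L]]) / 1000
            if (n >= params@minSnps && kb >= params@minLenKb &&
                kb / n <= params@maxKbPerSnp)
                segs[[length(segs) + 1L]] <-
                    c(first = part[1L], last = part[n], n = n)
        }
    }
    if (length(segs)) do.call(rbind, segs) else NULL
}

#' Detect runs of homozygosity
#'
#' Sliding-window scanner over each individual and autosome: windows of
#' \code{windowSnps} consecutive SNPs are homozygous when they contain
#' at most \code{windowHetMax} heterozygous and \code{windowMissingMax}
#' missing calls; a SNP is in-run when at least
#' \code{windowHitThreshold} of the windows overlapping it are
#' homozygous; maximal in-run stretches are split at inter-SNP gaps
#' larger than \code{maxGapKb} and kept when they satisfy the SNP-count,
#' length and density rules. Heterozygotes inside a run are not capped
#' beyond the window rule. The scan is deterministic and independent
#' across individuals.
#'
#' @param gd A \linkS4class{GenotypeData} (the ROH SNP set; no MAF
#'   filter).
#' @param params A \linkS4class{RohParams}.
#' @return A \code{GRanges}: one range per segment spanning the bp of
#'   its first and last SNP, with metadata columns \code{animal_id},
#'   \code{n_snps} and \code{kb} (= (end - start) / 1000).
#' @seealso [fRoh()]
#' @export
detectRoh <- function(gd, params = rohParams()) {
    stopifnot(is(params, "RohParams"))
    g <- genoCounts(gd)
    rr <- markerMap(gd)
    chrom <- as.character(GenomicRanges::seqnames(rr))
    bp <- GenomicRanges::start(rr)
    auto <- isAutosome(gd)
    res <- list()
    for (ch in unique(chrom[auto])) {
        sel <- which(chrom == ch & auto)
        bpc <- bp[sel]
        for (j in seq_len(ncol(g))) {
            seg <- .maskToSegments(.inRun(g[sel, j], params), bpc, params)
            if (!is.null(seg))
                res[[length(res) + 1L]] <- data.frame(
                    chrom = ch,
                    start = bpc[seg[, "first"]],
                    end = bpc[seg[, "last"]],
                    n_snps = seg[, "n"],
                    animal_id = colnames(g)[j],
                    stringsAsFactors = FALSE)
        }
    }
    if (!length(res))
        return(GenomicRanges::GRanges(
            animal_id = character(0), n_snps = integer(0),
            kb = numeric(0)))
    df <- do.call(rbind, res)
    out <- GenomicRanges::GRanges(
        df$chrom, IRanges::IRanges(df$start, df$end))
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
        animal_id = df$animal_id, n_snps = as.integer(df$n_snps),
        kb = (df$end - df$start) / 1000)
    out
}

#' ROH-based inbreeding coefficient
#'
#' Per individual, the summed length of its runs of homozygosity
#' divided by the covered autosome length
#' \eqn{L = \sum_{chr} (bp_{last} - bp_{first})} on the scanned SNP set.
#' Individuals without segments get 0.
#'
#' @param segments Segments from [detectRoh()].
#' @param gd The \linkS4class{GenotypeData} the segments were scanned
#'   on (defines the covered length and the full individual list).
#' @return Named numeric vector of \eqn{F_{ROH}} in [0, 1].
#' @export
fRoh <- function(segments, gd) {
    rr <- markerMap(gd)
    chrom <- as.character(GenomicRanges::seqnames(rr))
    bp <- GenomicRanges::start(rr)
    auto <- isAutosome(gd)
    lAuto <- sum(vapply(unique(chrom[auto]), function(ch) {
        b <- bp[chrom == ch & auto]
        (max(b) - min(b)) / 1000
    }, numeric(1)))
    ids <- sampleInfo(gd)$animal_id
    kb <- S4Vectors::mcols(segments)$kb
    tot <- tapply(kb, S4Vectors::mcols(segments)$animal_id, sum)
    out <- stats::setNames(rep(0, length(ids)), ids)
    out[names(tot)] <- tot / lAuto
    out
}
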