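#' Construct a GenotypeData object
#'
#' Assembles reference-allele counts, a marker map and sample metadata
#' into a \linkS4class{GenotypeData}. Markers are sorted by chromosome
#' (order of first appearance) and bp position; genotype codes count the
#' \code{allele1} (reference) allele.
#'
#' @param geno Integer matrix, SNPs x individuals, values 0/1/2/NA.
#' @param map \code{data.frame} with columns \code{snp}, \code{chrom},
#'   \code{bp}, \code{allele1}, \code{allele2} and optionally
#'   \code{autosomal} (defaults to chromosome label not being one of
#'   X, Y, XY, M, MT).
#' @param samples \code{data.frame} with column \code{animal_id} and any
#'   further per-animal metadata (sex, generation, line, ...).
#' @return A \linkS4class{GenotypeData}.
#' @export
GenotypeData <- function(geno, map, samples) {
    stopifnot(is.matrix(geno), is.data.frame(map), is.data.frame(samples))
    need <- c("snp", "chrom", "bp", "allele1", "allele2")
    if (!all(need %in% names(map)))
        stop("map needs columns: ", paste(need, collapse = ", "))
    if (nrow(map) != nrow(geno))
        stop("map rows (", nrow(map), ") do not match genotype rows (",
             nrow(geno), ")")
    if (nrow(samples) != ncol(geno))
        stop("sample rows (", nrow(samples),
             ") do not match genotype columns (", ncol(geno), ")")
    if (!"animal_id" %in% names(samples))
        stop("samples needs a column 'animal_id'")
    map$chrom <- as.character(map$chrom)
    if (!"autosomal" %in% names(map))
        map$autosomal <- !(toupper(map$chrom) %in%
                           c("X", "Y", "XY", "M", "MT"))
    o <- order(match(map$chrom, unique(map$chrom)), map$bp)
    map <- map[o, , drop = FALSE]
    geno <- geno[o, , drop = FALSE]
    if (anyDuplicated(map$snp))
        stop("marker identifiers must be unique")
    dup <- stats::aggregate(seq_len(nrow(map)), list(map$chrom),
                            function(i) anyDuplicated(map$bp[i]) > 0)
    if (any(dup$x))
        stop("duplicate bp positions within chromosome(s): ",
             paste(dup$Group.1[dup$x], collapse = ", "))
    storage.mode(geno) <- "integer"
    rr <- GenomicRanges::GRanges(map$chrom,
                                 IRanges::IRanges(map$bp, width = 1L))
    names(rr) <- map$snp
    S4Vectors::mcols(rr) <- S4Vectors::DataFrame(
        allele1 = as.character(map$allele1),
        allele2 = as.character(map$allele2),
        autosomal = map$autosomal)
    cd <- S4Vectors::DataFrame(samples)
    rownames(cd) <- samples$animal_id
    dimnames(geno) <- list(map$snp, samples$animal_id)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = S4Vectors::SimpleList(geno = geno),
        rowRanges = rr, colData = cd)
    new("GenotypeData", se)
}

#' Accessors for GenotypeData
#'
#' @param gd A \linkS4class{GenotypeData}.
#' @return \code{genoCounts}: the integer SNP x individual matrix;
#'   \code{markerMap}: the marker \code{GRanges} (alleles and autosomal
#'   flag in \code{mcols}); \code{sampleInfo}: the sample \code{DataFrame};
#'   \code{isAutosome}: logical per SNP.
#' @name GenotypeData-accessors
NULL

#' @describeIn GenotypeData-accessors Genotype code matrix.
#' @export
genoCounts <- function(gd) SummarizedExperiment::assay(gd, "geno")

#' @describeIn GenotypeData-accessors Marker map as GRanges.
#' @export
markerMap <- function(gd) SummarizedExperiment::rowRanges(gd)

#' @describeIn GenotypeData-accessors Sample metadata.
#' @export
sampleInfo <- function(gd) SummarizedExperiment::colData(gd)

#' @describeIn GenotypeData-accessors Autosomal flag per SNP.
#' @export
isAutosome <- function(gd) S4Vectors::mcols(markerMap(gd))$autosomal

#' @export
setMethod("show", "GenotypeData", function(object) {
    cat("GenotypeData:", nrow(object), "SNPs x", ncol(object),
        "individuals\n")
    chrom <- as.character(GenomicRanges::seqnames(markerMap(object)))
    cat("  chromosomes:", paste(unique(chrom), collapse = ", "), "\n")
    g <- genoCounts(object)
    cat(sprintf("  missing calls: %.2f%%\n", 100 * mean(is.na(g))))
})

#' Attach pedigree metadata to genotyped samples
#'
#' Copies \code{sex}, \code{generation} and \code{line} from a pedigree
#' onto the matching samples (by \code{animal_id}).
#'
#' @param gd A \linkS4class{GenotypeData}.
#' @param ped A \linkS4class{Pedigree}.
#' @return The annotated \linkS4class{GenotypeData}.
#' @export
annotateSamples <- function(gd, ped) {
    df <- pedTable(ped)
    i <- match(sampleInfo(gd)$animal_id, df$id)
    cd <- SummarizedExperiment::colData(gd)
    for (f in c("sex", "generation", "line")) cd[[f]] <- df[[f]][i]
    SummarizedExperiment::colData(gd) <- cd
    gd
}
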