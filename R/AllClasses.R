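#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start end mcols mcols<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowRanges colData
#' @importFrom IRanges IRanges
#' @useDynLib inbreedNe, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Pedigree of a population bred over discrete generations
#'
#' An S4 container for a validated, topologically sorted pedigree. Each
#' record holds an animal identifier, its sire and dam (\code{NA} when
#' unknown), its sex (\code{"male"}, \code{"female"} or \code{NA}), its
#' discrete generation (integer, founders at 0) and a line label (e.g.
#' \code{"base"}, \code{"high"}, \code{"low"}).
#'
#' Validity requires unique identifiers, every named parent present as a
#' record, an acyclic parent graph with parents ordered before offspring,
#' strictly increasing generation from parent to offspring (when
#' generations are given), and sex consistency (animals used as sires are
#' male, dams female, whenever sex is recorded).
#'
#' @slot ped A \code{data.frame} with columns \code{id}, \code{sire},
#'   \code{dam}, \code{sex}, \code{generation}, \code{line}, sorted so
#'   that parents precede offspring.
#' @seealso [Pedigree()], [readPedigree()], [pedInbreeding()]
#' @export
setClass("Pedigree", slots = c(ped = "data.frame"))

#' SNP genotypes with a marker map and sample metadata
#'
#' Extends \linkS4class{RangedSummarizedExperiment}. The single assay
#' \code{"geno"} is an integer matrix of reference-allele counts (rows =
#' SNPs, columns = individuals) with values in \{0, 1, 2, NA\}; \code{NA}
#' is a missing call. Row ranges give chromosome and 1-based bp position
#' of each SNP, with metadata columns \code{allele1} (the counted,
#' reference allele), \code{allele2} and \code{autosomal}. Column data
#' carries at least \code{animal_id} and typically \code{sex},
#' \code{generation} and \code{line}.
#'
#' @seealso [GenotypeData()], [readPlink()], [qcIndividuals()]
#' @export
setClass("GenotypeData", contains = "RangedSummarizedExperiment")

setValidity("GenotypeData", function(object) {
    msg <- character()
    if (!"geno" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'geno' is required")
    else {
        g <- SummarizedExperiment::assay(object, "geno")
        bad <- !is.na(g) & !(g %in% 0:2)
        if (any(bad))
            msg <- c(msg, "genotype codes must be 0, 1, 2 or NA")
    }
    rr <- SummarizedExperiment::rowRanges(object)
    need <- c("allele1", "allele2", "autosomal")
    if (!all(need %in% names(S4Vectors::mcols(rr))))
        msg <- c(msg, sprintf("marker metadata columns required: %s",
                              paste(need, collapse = ", ")))
    if (anyDuplicated(names(rr)))
        msg <- c(msg, "marker identifiers must be unique")
    if (!"animal_id" %in% names(SummarizedExperiment::colData(object)))
        msg <- c(msg, "colData column 'animal_id' is required")
    if (length(msg)) msg else TRUE
})

#' Parameters of the sliding-window runs-of-homozygosity scanner
#'
#' Defaults follow a widely used PLINK-style parameterisation for dense
#' arrays: 50-SNP windows with at most one heterozygote and five missing
#' calls, a window-hit threshold of 0.5, a minimum run length of 1,000 kb
#' and 100 SNPs, a maximum average spacing of 50 kb per SNP, a maximum
#' gap of 1,000 kb between consecutive SNPs of one run, and no cap on
#' heterozygotes per run (heterozygotes act only through the window rule).
#'
#' @slot windowSnps Window size in SNPs.
#' @slot windowHetMax Maximum heterozygous calls for a homozygous window.
#' @slot windowMissingMax Maximum missing calls for a homozygous window.
#' @slot windowHitThreshold Minimum fraction of overlapping homozygous
#'   windows for a SNP to be in-run (inclusive).
#' @slot minLenKb Minimum run length in kb (inclusive).
#' @slot minSnps Minimum SNPs per run (inclusive).
#' @slot maxKbPerSnp Maximum run kb per SNP (inclusive).
#' @slot maxGapKb Maximum gap between consecutive in-run SNPs in kb.
#' @seealso [rohParams()], [detectRoh()]
#' @export
setClass("RohParams", slots = c(
    windowSnps = "integer", windowHetMax = "integer",
    windowMissingMax = "integer", windowHitThreshold = "numeric",
    minLenKb = "numeric", minSnps = "integer",
    maxKbPerSnp = "numeric", maxGapKb = "numeric"))

setValidity("RohParams", function(object) {
    msg <- character()
    pos <- c(windowSnps = object@windowSnps, minSnps = object@minSnps,
             minLenKb = object@minLenKb, maxKbPerSnp = object@maxKbPerSnp,
             maxGapKb = object@maxGapKb)
    if (any(pos <= 0)) msg <- c(msg, "all size parameters must be positive")
    if (object@windowHetMax < 0 || object@windowMissingMax < 0)
        msg <- c(msg, "window allowances must be non-negative")
    th <- object@windowHitThreshold
    if (!(th > 0 && th <= 1))
        msg <- c(msg, "windowHitThreshold must lie in (0, 1]")
    if (length(msg)) msg else TRUE
})

#' Breeding design of the gene-dropping simulator
#'
#' Describes a population history in four phases: a pool of fully inbred
#' founder lines, a panmictic burn-in, a random-mating phase with a fixed
#' sex ratio, and a phase of closed selected lines bred over discrete
#' generations with mating that avoids shared grandparents. Candidate
#' offspring are thinned at random (no trait is simulated); the retained
#' animals are recorded and genotyped.
#'
#' @slot nFounderLines Number of fully inbred founder lines.
#' @slot foundersPerLine Founder animals per line entering burn-in.
#' @slot burnInGenerations Panmictic burn-in generations (not recorded).
#' @slot randomGenerations Recorded random-mating generations.
#' @slot randomMales,randomFemales Breeding males/females of the random
#'   phase (each male mated to \code{randomFemales/randomMales} females).
#' @slot selectionGenerations Generations of the selected-line phase.
#' @slot nLines Number of closed selected lines.
#' @slot damsPerLine,siresPerLine Breeding females/males per line.
#' @slot selectedFemalesPerLine,selectedMalesPerLine Recorded (genotyped)
#'   offspring per line and generation, by sex.
#' @slot selectedProportion Fraction of born candidates retained at
#'   random; the remainder are never recorded.
#' @slot avoidSharedGrandparents Reject matings sharing a grandparent.
#' @slot nChromosomes,snpsPerChromosome,snpSpacingKb Genome layout:
#'   equally spaced SNPs on equally sized autosomes.
#' @slot cmPerMb Genetic map density (uniform).
#' @slot discriminatingFraction Fraction of SNPs at which one founder
#'   line carries the alternate allele (the rest are monomorphic).
#' @seealso [breedingDesign()], [simulateBreeding()]
#' @export
setClass("BreedingDesign", slots = c(
    nFounderLines = "integer", foundersPerLine = "integer",
    burnInGenerations = "integer",
    randomGenerations = "integer", randomMales = "integer",
    randomFemales = "integer",
    selectionGenerations = "integer", nLines = "integer",
    damsPerLine = "integer", siresPerLine = "integer",
    selectedFemalesPerLine = "integer", selectedMalesPerLine = "integer",
    selectedProportion = "numeric", avoidSharedGrandparents = "logical",
    nChromosomes = "integer", snpsPerChromosome = "integer",
    snpSpacingKb = "numeric", cmPerMb = "numeric",
    discriminatingFraction = "numeric"))

setValidity("BreedingDesign", function(object) {
    msg <- character()
    counts <- c(object@nFounderLines, object@foundersPerLine,
                object@randomGenerations, object@randomMales,
                object@randomFemales, object@selectionGenerations,
                object@nLines, object@damsPerLine, object@siresPerLine,
                object@selectedFemalesPerLine, object@selectedMalesPerLine,
                object@nChromosomes, object@snpsPerChromosome)
    if (any(counts <= 0)) msg <- c(msg, "all census counts must be positive")
    if (object@burnInGenerations < 0)
        msg <- c(msg, "burnInGenerations must be >= 0")
    if (!(object@selectedProportion > 0 && object@selectedProportion <= 1))
        msg <- c(msg, "selectedProportion must lie in (0, 1]")
    if (object@selectedFemalesPerLine < object@damsPerLine ||
        object@selectedMalesPerLine < object@siresPerLine)
        msg <- c(msg, "recorded offspring per line must cover the breeders")
    if (object@snpSpacingKb <= 0 || object@cmPerMb < 0)
        msg <- c(msg, "genome parameters must be positive")
    if (object@discriminatingFraction < 0 || object@discriminatingFraction > 1)
        msg <- c(msg, "discriminatingFraction must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})
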