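#' Assemble the per-animal inbreeding table
#'
#' Computes every estimator on the prepared marker sets and merges them
#' with pedigree inbreeding: \eqn{F_{PED}} (Meuwissen-Luo),
#' \eqn{F_{NEJ}}, \eqn{F_{L\&H}}, \eqn{F_{VR1}}, \eqn{F_{VR2}},
#' \eqn{F_{YAN}} on the GRM set with reference-population allele
#' frequencies, \eqn{F_{ROH}} on the ROH set, and the
#' reference-adjusted \eqn{F_{NEJ0}}, \eqn{F_{L\&H0}},
#' \eqn{F_{ROH0}}.
#'
#' @param rohSet \linkS4class{GenotypeData} after [qcSnpsRoh()].
#' @param grmSet \linkS4class{GenotypeData} after [qcSnpsGrm()].
#' @param ped \linkS4class{Pedigree} covering the genotyped animals.
#' @param refGeneration Selection generation defining the reference
#'   population (default 1), matched against the \code{generation}
#'   sample column.
#' @param params \linkS4class{RohParams} for the scanner.
#' @return A \code{data.frame}, one row per genotyped animal, with the
#'   sample metadata and one column per estimator; the ROH segments are
#'   attached as \code{attr(, "segments")} and the reference means as
#'   \code{attr(, "ref_means")}.
#' @export
computeInbreeding <- function(rohSet, grmSet, ped,
                              refGeneration = 1,
                              params = rohParams()) {
    info <- as.data.frame(sampleInfo(grmSet))
    if (!"generation" %in% names(info))
        stop("samples carry no 'generation' column")
    refIds <- info$animal_id[!is.na(info$generation) &
                             info$generation == refGeneration]
    if (!length(refIds))
        stop("no genotyped animals in reference generation ",
             refGeneration)
    freqs <- alleleFreqs(grmSet, subset = refIds, warn = FALSE)

    out <- data.frame(animal_id = info$animal_id,
                      generation = info$generation,
                      line = if ("line" %in% names(info)) info$line
                             else NA_character_,
                      stringsAsFactors = FALSE)
    fped <- pedInbreeding(ped)
    out$f_ped <- unname(fped[out$animal_id])
    out$f_nej <- unname(fNej(grmSet))
    out$f_lh <- unname(fLH(grmSet, freqs))
    out$f_vr1 <- unname(fVR1(grmSet, freqs))
    out$f_vr2 <- unname(fVR2(grmSet, freqs))
    out$f_yan <- unname(fYan(grmSet, freqs))
    segs <- detectRoh(rohSet, params)
    froh <- fRoh(segs, rohSet)
    out$f_roh <- unname(froh[out$animal_id])

    isRef <- out$animal_id %in% refIds
    refMeans <- c(f_nej = mean(out$f_nej[isRef], na.rm = TRUE),
                  f_lh = mean(out$f_lh[isRef], na.rm = TRUE),
                  f_roh = mean(out$f_roh[isRef], na.rm = TRUE))
    out$f_nej0 <- adjustToReference(out$f_nej, refMeans[["f_nej"]])
    out$f_lh0 <- adjustToReference(out$f_lh, refMeans[["f_lh"]])
    out$f_roh0 <- adjustToReference(out$f_roh, refMeans[["f_roh"]])
    attr(out, "segments") <- segs
    attr(out, "ref_means") <- refMeans
    attr(out, "ref_generation") <- refGeneration
    out
}

#' Per-animal increases in inbreeding for every estimator
#'
#' Pedigree rates use the classic parent-referenced form
#' (\code{PEDt}) and the depth-standardised individual form
#' (\code{PEDi}); molecular rates standardise each coefficient by the
#' generations elapsed since the reference generation
#' (\eqn{t = g - g_{ref}}; the reference generation itself has no
#' molecular rate).
#'
#' @param inbr Table from [computeInbreeding()].
#' @param ped The \linkS4class{Pedigree} used there.
#' @return Long \code{data.frame}: \code{animal_id},
#'   \code{generation}, \code{estimator} (PEDi, PEDt, NEJ0, L&H, L&H0,
#'   VR1, VR2, YAN, ROH0), \code{delta_f}.
#' @export
computeRates <- function(inbr, ped) {
    refGen <- attr(inbr, "ref_generation")
    if (is.null(refGen)) refGen <- 1
    fped <- pedInbreeding(ped)
    dfT <- deltaFPedT(ped, fped)
    dfI <- deltaFPedI(ped, fped)
    t <- inbr$generation - refGen
    t[t < 1] <- NA_integer_
    mol <- list("NEJ0" = inbr$f_nej0, "L&H" = inbr$f_lh,
                "L&H0" = inbr$f_lh0, "VR1" = inbr$f_vr1,
                "VR2" = inbr$f_vr2, "YAN" = inbr$f_yan,
                "ROH0" = inbr$f_roh0)
    rows <- list(
        data.frame(animal_id = inbr$animal_id,
                   generation = inbr$generation, estimator = "PEDi",
                   delta_f = unname(dfI[inbr$animal_id]),
                   stringsAsFactors = FALSE),
        data.frame(animal_id = inbr$animal_id,
                   generation = inbr$generation, estimator = "PEDt",
                   delta_f = unname(dfT[inbr$animal_id]),
                   stringsAsFactors = FALSE))
    for (nm in names(mol))
        rows[[length(rows) + 1L]] <- data.frame(
            animal_id = inbr$animal_id, generation = inbr$generation,
            estimator = nm,
            delta_f = deltaFMolecular(mol[[nm]], t),
            stringsAsFactors = FALSE)
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Run the full analysis pipeline
#'
#' Executes the whole workflow: obtain data (simulate a
#' \linkS4class{BreedingDesign} or read a pedigree file plus PLINK
#' prefix), apply quality control (individual call rate, ROH SNP set,
#' GRM SNP set), compute every inbreeding coefficient, runs of
#' homozygosity, expected homozygosity, increases in inbreeding,
#' per-generation effective population sizes, founder distances and
#' Pearson correlation matrices, and write all tables (and a run log)
#' to \code{outDir}.
#'
#' @param config A named list or path to a YAML file. Recognised
#'   entries: \code{seed}; \code{simulate} (list of [breedingDesign()]
#'   arguments) or \code{pedigree} (file path; with
#'   \code{pedigree_columns}, \code{pedigree_sep}) and \code{plink}
#'   (prefix); \code{reference_generation} (default 1);
#'   \code{min_call_rate} (0.97), \code{max_missing} (0.03),
#'   \code{min_maf} (0.05); \code{roh} (list of [rohParams()]
#'   arguments); \code{sex_ratio} (list \code{males}, \code{females};
#'   default 32/64).
#' @param outDir Output directory; created if missing. \code{NULL}
#'   skips writing.
#' @return Invisibly, a list with every intermediate and final result
#'   (\code{geno}, \code{ped}, \code{inbreeding}, \code{rates},
#'   \code{ne}, \code{neExpected}, \code{correlations},
#'   \code{founderDistance}, ...).
#' @export
runPipeline <- function(config = list(), outDir = NULL) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    cfg <- function(name, default) {
        if (!is.null(config[[name]])) config[[name]] else default
    }
    log <- character(0)
    note <- function(...) log <<- c(log, paste0(...))

    seed <- cfg("seed", NULL)
    if (!is.null(config$simulate) || is.null(config$pedigree)) {
        design <- do.call(breedingDesign,
                          as.list(cfg("simulate", list())))
        note("stage simulate: seed ", ifelse(is.null(seed), "none",
                                             seed))
        sim <- simulateBreeding(design, seed = seed)
        ped <- sim$ped
        gd <- sim$geno
        truth <- sim$truth
    } else {
        note("stage load: ", config$pedigree, " + ", config$plink)
        ped <- readPedigree(config$pedigree,
                            columns = unlist(cfg("pedigree_columns",
                                c(id = "id", sire = "sire", dam = "dam",
                                  sex = "sex", generation = "generation",
                                  line = "line"))),
                            sep = cfg("pedigree_sep", ","))
        gd <- readPlink(config$plink)
        gd <- annotateSamples(gd, ped)
        truth <- NULL
    }

    mcr <- cfg("min_call_rate", 0.97)
    gd1 <- qcIndividuals(gd, mcr)
    note("stage qc_individuals: call rate >= ", mcr, "; removed ",
         ncol(gd) - ncol(gd1), " of ", ncol(gd))
    mm <- cfg("max_missing", 0.03)
    rohSet <- qcSnpsRoh(gd1, mm)
    note("stage qc_roh_set: missing <= ", mm, ", autosomal; kept ",
         nrow(rohSet), " of ", nrow(gd1), " SNPs")
    refGen <- cfg("reference_generation", 1)
    info <- as.data.frame(sampleInfo(rohSet))
    refIds <- info$animal_id[!is.na(info$generation) &
                             info$generation == refGen]
    maf <- cfg("min_maf", 0.05)
    grmSet <- qcSnpsGrm(rohSet, refIds, maf)
    note("stage qc_grm_set: MAF >= ", maf, " (reference then all); kept ",
         nrow(grmSet), " of ", nrow(rohSet), " SNPs")

    rp <- do.call(rohParams, as.list(cfg("roh", list())))
    inbr <- computeInbreeding(rohSet, grmSet, ped,
                              refGeneration = refGen, params = rp)
    note("stage inbreeding: ", nrow(inbr), " animals, reference means ",
         paste(sprintf("%s=%.4f", names(attr(inbr, "ref_means")),
                       attr(inbr, "ref_means")), collapse = ", "))

    rates <- computeRates(inbr, ped)
    ne <- nePerGeneration(rates)
    fes <- fExpSeries(grmSet, perLine = TRUE)
    nex <- neExpected(fes)
    note("stage rates_ne: ", nrow(ne$byGeneration),
         " generation x estimator cells")

    coefCols <- c("generation", "f_ped", "f_nej", "f_lh", "f_vr1",
                  "f_vr2", "f_yan", "f_roh")
    corF <- correlateInbreeding(inbr[coefCols])
    wide <- stats::reshape(rates, idvar = c("animal_id", "generation"),
                           timevar = "estimator", direction = "wide")
    names(wide) <- sub("^delta_f\\.", "dF_", names(wide))
    corD <- correlateInbreeding(wide[-1])
    note("stage correlations: groups ",
         paste(names(corF), collapse = ", "))

    sr <- cfg("sex_ratio", list(males = 32, females = 64))
    nes <- neSexRatio(sr$males, sr$females)
    refRows <- !is.na(inbr$generation) & inbr$generation == refGen
    tSafe <- function(fref, delta) tryCatch(estimateT(fref, delta),
                                            error = function(e) NA_real_)
    pedi <- rates$delta_f[rates$estimator == "PEDi"]
    fd <- data.frame(
        quantity = c("ne_sex_ratio", "t_nej", "t_roh", "t_ped"),
        value = c(nes,
                  tSafe(mean(inbr$f_nej[refRows], na.rm = TRUE),
                        1 / (2 * nes)),
                  tSafe(mean(inbr$f_roh[refRows], na.rm = TRUE),
                        1 / (2 * nes)),
                  tSafe(mean(inbr$f_ped[refRows], na.rm = TRUE),
                        mean(pedi, na.rm = TRUE))),
        stringsAsFactors = FALSE)
    note("stage founder_distance: ",
         paste(sprintf("%s=%.2f", fd$quantity, fd$value),
               collapse = ", "))

    res <- list(ped = ped, geno = gd1, rohSet = rohSet, grmSet = grmSet,
                truth = truth, inbreeding = inbr,
                segments = attr(inbr, "segments"), rates = rates,
                ne = ne, fExp = fes, neExpected = nex,
                correlations = list(coefficients = corF, rates = corD),
                founderDistance = fd, log = log)
    if (!is.null(outDir)) .writePipelineOutputs(res, outDir)
    invisible(res)
}

# Tables are the single source of truth; figures (when ggplot2 is
# available) are rendered from the written tables, never from
# in-memory state.
.writePipelineOutputs <- function(res, outDir) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    wt <- function(x, name) utils::write.table(
        x, file.path(outDir, name), sep = "\t", quote = FALSE,
        row.names = FALSE)
    inbr <- res$inbreeding
    tidy <- stats::reshape(
        inbr, direction = "long",
        varying = list(setdiff(names(inbr),
                               c("animal_id", "generation", "line"))),
        v.names = "value", timevar = "estimator",
        times = setdiff(names(inbr),
                        c("animal_id", "generation", "line")),
        idvar = "animal_id")
    rownames(tidy) <- NULL
    wt(tidy, "inbreeding.tsv")
    segs <- res$segments
    wt(data.frame(animal_id = S4Vectors::mcols(segs)$animal_id,
                  chrom = as.character(GenomicRanges::seqnames(segs)),
                  start = GenomicRanges::start(segs),
                  end = GenomicRanges::end(segs),
                  n_snps = S4Vectors::mcols(segs)$n_snps,
                  kb = S4Vectors::mcols(segs)$kb),
       "roh_segments.tsv")
    wt(res$rates, "rates.tsv")
    wt(res$ne$byGeneration, "ne_by_generation.tsv")
    wt(res$ne$summary, "ne_summary.tsv")
    wt(res$neExpected, "f_exp_ne.tsv")
    wt(res$founderDistance, "founder_distance.tsv")
    for (grp in names(res$correlations$coefficients))
        wt(cbind(estimator =
                     rownames(res$correlations$coefficients[[grp]]),
                 as.data.frame(res$correlations$coefficients[[grp]])),
           paste0("cor_coefficients_", grp, ".tsv"))
    for (grp in names(res$correlations$rates))
        wt(cbind(estimator = rownames(res$correlations$rates[[grp]]),
                 as.data.frame(res$correlations$rates[[grp]])),
           paste0("cor_rates_", grp, ".tsv"))
    writeLines(res$log, file.path(outDir, "log.txt"))
    if (requireNamespace("ggplot2", quietly = TRUE))
        .writePipelineFigures(outDir)
    invisible(outDir)
}

.writePipelineFigures <- function(outDir) {
    tidy <- utils::read.delim(file.path(outDir, "inbreeding.tsv"))
    means <- stats::aggregate(value ~ generation + estimator, tidy,
                              mean, na.rm = TRUE)
    p1 <- ggplot2::ggplot(means,
            ggplot2::aes(x = .data$generation, y = .data$value,
                         colour = .data$estimator)) +
        ggplot2::geom_line() +
        ggplot2::labs(x = "selection generation",
                      y = "mean inbreeding coefficient")
    ggplot2::ggsave(file.path(outDir, "inbreeding_trends.pdf"), p1,
                    width = 7, height = 5)
    ne <- utils::read.delim(file.path(outDir, "ne_by_generation.tsv"))
    p2 <- ggplot2::ggplot(ne[!is.na(ne$ne), ],
            ggplot2::aes(x = .data$generation, y = .data$ne,
                         colour = .data$estimator)) +
        ggplot2::geom_line() +
        ggplot2::labs(x = "selection generation", y = "Ne")
    ggplot2::ggsave(file.path(outDir, "ne_trends.pdf"), p2,
                    width = 7, height = 5)
    invisible(NULL)
}
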