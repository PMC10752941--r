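#' Construct a breeding design for the simulator
#'
#' Defaults emulate a divergent selection experiment in mice: a founder
#' pool mixing three fully inbred lines, 40 generations of panmictic
#' burn-in, five recorded random-mating generations of 32 males by 64
#' females (two females per male), then 26 discrete generations of two
#' reproductively closed lines with 43 dams and 13 sires each, mating
#' that avoids shared grandparents, and roughly 30% of born candidates
#' retained (at random; no trait is simulated) as the recorded,
#' genotyped animals. The genome is 5 autosomes of 1,000 SNPs at 25 kb
#' spacing with a uniform 1 cM/Mb map; at 70% of SNPs one random
#' founder line carries the alternate allele, the rest are monomorphic.
#'
#' @param nFounderLines,foundersPerLine Founder pool composition.
#' @param burnInGenerations Unrecorded panmictic generations.
#' @param randomGenerations,randomMales,randomFemales Recorded
#'   random-mating phase.
#' @param selectionGenerations,nLines,damsPerLine,siresPerLine Closed
#'   selected-line phase.
#' @param selectedFemalesPerLine,selectedMalesPerLine Recorded
#'   offspring per line and generation; must cover the breeders.
#' @param selectedProportion Fraction of born candidates recorded.
#' @param avoidSharedGrandparents Reject sire-dam pairs sharing a
#'   grandparent in the selection phase.
#' @param nChromosomes,snpsPerChromosome,snpSpacingKb,cmPerMb Genome.
#' @param discriminatingFraction Fraction of SNPs distinguishing one
#'   founder line from the others.
#' @return A \linkS4class{BreedingDesign}.
#' @export
breedingDesign <- function(nFounderLines = 3, foundersPerLine = 32,
                           burnInGenerations = 40,
                           randomGenerations = 5, randomMales = 32,
                           randomFemales = 64,
                           selectionGenerations = 26, nLines = 2,
                           damsPerLine = 43, siresPerLine = 13,
                           selectedFemalesPerLine = 50,
                           selectedMalesPerLine = 20,
                           selectedProportion = 0.30,
                           avoidSharedGrandparents = TRUE,
                           nChromosomes = 5, snpsPerChromosome = 1000,
                           snpSpacingKb = 25, cmPerMb = 1,
                           discriminatingFraction = 0.7) {
    new("BreedingDesign",
        nFounderLines = as.integer(nFounderLines),
        foundersPerLine = as.integer(foundersPerLine),
        burnInGenerations = as.integer(burnInGenerations),
        randomGenerations = as.integer(randomGenerations),
        randomMales = as.integer(randomMales),
        randomFemales = as.integer(randomFemales),
        selectionGenerations = as.integer(selectionGenerations),
        nLines = as.integer(nLines),
        damsPerLine = as.integer(damsPerLine),
        siresPerLine = as.integer(siresPerLine),
        selectedFemalesPerLine = as.integer(selectedFemalesPerLine),
        selectedMalesPerLine = as.integer(selectedMalesPerLine),
        selectedProportion = selectedProportion,
        avoidSharedGrandparents = avoidSharedGrandparents,
        nChromosomes = as.integer(nChromosomes),
        snpsPerChromosome = as.integer(snpsPerChromosome),
        snpSpacingKb = snpSpacingKb, cmPerMb = cmPerMb,
        discriminatingFraction = discriminatingFraction)
}

#' @export
setMethod("show", "BreedingDesign", function(object) {
    cat("BreedingDesign:", object@nFounderLines, "founder lines x",
        object@foundersPerLine, "animals;", object@burnInGenerations,
        "burn-in +", object@randomGenerations, "random (",
        object@randomMales, "M x", object@randomFemales, "F ) +",
        object@selectionGenerations, "selection generations,",
        object@nLines, "lines x", object@damsPerLine, "dams /",
        object@siresPerLine, "sires\n  genome:", object@nChromosomes,
        "chromosomes x", object@snpsPerChromosome, "SNPs @",
        object@snpSpacingKb, "kb,", object@cmPerMb, "cM/Mb\n")
})

# --- internal machinery -------------------------------------------------

.simGenome <- function(design) {
    k <- design@snpsPerChromosome
    nc <- design@nChromosomes
    bp1 <- (seq_len(k) - 1L) * as.integer(design@snpSpacingKb * 1000) + 1L
    cm1 <- (bp1 - 1) / 1e6 * design@cmPerMb
    list(m = k * nc,
         chromIdx = lapply(seq_len(nc), function(c) (c - 1L) * k +
                                                    seq_len(k)),
         cmWithin = rep(list(cm1), nc),
         chromLenCm = rep(cm1[k], nc),
         map = data.frame(
             snp = sprintf("snp%d_%d", rep(seq_len(nc), each = k),
                           rep(seq_len(k), nc)),
             chrom = as.character(rep(seq_len(nc), each = k)),
             bp = rep(bp1, nc), stringsAsFactors = FALSE))
}

# One meiosis: recombination as a Poisson process on the genetic map,
# no interference, no mutation. Both tracking layers of a haplotype
# (founder line, recorded-founder gamete) recombine with the same mask.
.gameteFrom <- function(h1, h2, genome) {
    pick <- logical(genome$m)
    for (c in seq_along(genome$chromIdx)) {
        len <- genome$chromLenCm[c]
        k <- stats::rpois(1L, len / 100)
        first <- stats::runif(1L) < 0.5
        if (k == 0L) {
            pick[genome$chromIdx[[c]]] <- first
        } else {
            pos <- sort(stats::runif(k, 0, len))
            seg <- findInterval(genome$cmWithin[[c]], pos)
            pick[genome$chromIdx[[c]]] <- xor(first, seg %% 2L == 1L)
        }
    }
    out <- h2
    for (nm in names(h1)) out[[nm]][pick] <- h1[[nm]][pick]
    out
}

.offspringOf <- function(pa, ma, genome) {
    list(h1 = .gameteFrom(pa$h1, pa$h2, genome),
         h2 = .gameteFrom(ma$h1, ma$h2, genome))
}

# Dams assigned to sires, each sire carrying at most ceiling(nd/ns)
# dams, rejecting pairs that share a grandparent. Randomised greedy,
# most-constrained dam first, restarted on dead ends.
.assignMates <- function(sires, dams, grands, avoid, maxRestarts = 200) {
    ns <- length(sires)
    nd <- length(dams)
    cap <- ceiling(nd / ns)
    compat <- matrix(TRUE, nrow = nd, ncol = ns)
    if (avoid) {
        gpS <- lapply(sires, function(s) grands[[s]])
        for (i in seq_len(nd)) {
            gd <- grands[[dams[i]]]
            if (length(gd))
                compat[i, ] <- !vapply(gpS, function(g)
                    any(g %in% gd), logical(1))
        }
        if (any(rowSums(compat) == 0L))
            stop("no mating assignment avoids shared grandparents; ",
                 "increase the census or the number of sires")
    }
    for (r in seq_len(maxRestarts)) {
        ord <- order(rowSums(compat) + stats::runif(nd))
        load <- integer(ns)
        pick <- integer(nd)
        okAll <- TRUE
        for (i in ord) {
            cand <- which(load < cap & compat[i, ])
            if (!length(cand)) { okAll <- FALSE; break }
            s <- if (length(cand) == 1L) cand else sample(cand, 1L)
            pick[i] <- s
            load[s] <- load[s] + 1L
        }
        if (okAll)
            return(data.frame(dam = dams, sire = sires[pick],
                              stringsAsFactors = FALSE))
    }
    stop("no mating assignment avoids shared grandparents; ",
         "increase the census or the number of sires")
}

# Draw breeders from the selected candidates until a feasible mating
# plan exists (a breeding programme picks its breeders so that the
# avoidance rule can be honoured).
.matingPlan <- function(selMales, selFemales, nSire, nDam, grands,
                        avoid, maxDraws = 50) {
    for (k in seq_len(maxDraws)) {
        sires <- sample(selMales, nSire)
        dams <- sample(selFemales, nDam)
        mates <- tryCatch(.assignMates(sires, dams, grands, avoid),
                          error = function(e) NULL)
        if (!is.null(mates)) return(mates)
    }
    stop("no mating assignment avoids shared grandparents; ",
         "increase the census or the number of sires")
}

#' Simulate a breeding design by gene dropping
#'
#' Drops founder haplotypes through the design's pedigree with
#' recombination (Poisson crossovers on a uniform genetic map, no
#' mutation). Every haplotype carries two identity labels: the founder
#' line it descends from (which determines the allele) and the
#' recorded-founder gamete it descends from. From these, each recorded
#' animal gets two true autozygosity values: \code{autoz_line}, the
#' genome fraction where both haplotypes stem from the same fully
#' inbred founder line (identity relative to the line foundation), and
#' \code{autoz_ped}, the fraction where both haplotypes coalesce to the
#' same recorded-founder gamete — the quantity pedigree inbreeding
#' estimates, since the recorded pedigree treats its founders as
#' unrelated and non-inbred. All selection-phase animals are genotyped.
#'
#' @param design A \linkS4class{BreedingDesign}.
#' @param seed Integer seed; the run is fully reproducible given the
#'   seed.
#' @return A list with elements \code{ped} (\linkS4class{Pedigree} of
#'   all recorded animals; generation 0 = recorded founders),
#'   \code{geno} (\linkS4class{GenotypeData} of the genotyped animals;
#'   its \code{generation} column is the selection generation 1..S),
#'   \code{truth} (per recorded animal: pedigree generation, selection
#'   generation, line, genotyped flag, \code{autoz_line},
#'   \code{autoz_ped}) and \code{design}.
#' @examples
#' \donttest{
#' sim <- simulateBreeding(breedingDesign(
#'   burnInGenerations = 2, randomGenerations = 2,
#'   selectionGenerations = 3, damsPerLine = 6, siresPerLine = 2,
#'   selectedFemalesPerLine = 8, selectedMalesPerLine = 4,
#'   nChromosomes = 2, snpsPerChromosome = 100), seed = 1)
#' sim$ped
#' }
#' @export
simulateBreeding <- function(design, seed = NULL) {
    stopifnot(is(design, "BreedingDesign"))
    if (!is.null(seed)) set.seed(seed)
    genome <- .simGenome(design)
    m <- genome$m
    nL <- design@nFounderLines

    # founder line alleles: allele1 ("A") is the reference; at a
    # discriminating SNP one random line carries allele2 ("B")
    lineRef <- matrix(1L, nrow = nL, ncol = m)
    disc <- stats::runif(m) < design@discriminatingFraction
    if (nL > 1L) {
        carrier <- sample.int(nL, m, replace = TRUE)
        lineRef[cbind(carrier[disc], which(disc))] <- 0L
    } else lineRef[1L, disc] <- 0L

    # founder pool and unrecorded panmictic burn-in
    census <- nL * design@foundersPerLine
    pop <- lapply(seq_len(census), function(i) {
        l <- ((i - 1L) %/% design@foundersPerLine) + 1L
        list(h1 = list(d = rep(l, m)), h2 = list(d = rep(l, m)))
    })
    for (g in seq_len(design@burnInGenerations)) {
        pop <- lapply(seq_len(census), function(i) {
            pr <- sample.int(census, 2L)
            .offspringOf(pop[[pr[1L]]], pop[[pr[2L]]], genome)
        })
    }

    nM <- design@randomMales
    nF <- design@randomFemales
    if (census < nM + nF)
        stop("founder pool smaller than the random-phase census")

    counter <- 0L
    newId <- function(n) {
        ids <- sprintf("A%06d", counter + seq_len(n))
        counter <<- counter + n
        ids
    }

    records <- list()
    grands <- list()   # id -> grandparent ids
    parentsOf <- list() # id -> c(sire, dam)
    truth <- list()
    addRecord <- function(ids, sire, dam, sex, gen, line, selGen,
                          genotyped, animals) {
        sire <- rep_len(sire, length(ids))
        dam <- rep_len(dam, length(ids))
        records[[length(records) + 1L]] <<- data.frame(
            id = ids, sire = sire, dam = dam, sex = sex,
            generation = gen, line = line, stringsAsFactors = FALSE)
        for (i in seq_along(ids)) {
            parentsOf[[ids[i]]] <<- c(sire[i], dam[i])
            gp <- c(if (!is.na(sire[i])) parentsOf[[sire[i]]],
                    if (!is.na(dam[i])) parentsOf[[dam[i]]])
            grands[[ids[i]]] <<- gp[!is.na(gp)]
        }
        truth[[length(truth) + 1L]] <<- data.frame(
            id = ids, generation = gen, selection_generation = selGen,
            line = line, genotyped = genotyped,
            autoz_line = vapply(animals, function(a)
                mean(a$h1$d == a$h2$d), numeric(1)),
            autoz_ped = vapply(animals, function(a)
                mean(a$h1$r == a$h2$r), numeric(1)),
            stringsAsFactors = FALSE)
    }

    # recorded founders: a random draw of the burnt-in pool (so sex is
    # not confounded with founder line when the burn-in is short);
    # tracking of recorded-pedigree coalescence starts here
    founders <- pop[sample.int(census, nM + nF)]
    for (i in seq_along(founders)) {
        founders[[i]]$h1$r <- rep(2L * i - 1L, m)
        founders[[i]]$h2$r <- rep(2L * i, m)
    }
    fId <- newId(nM + nF)
    fSex <- rep(c("male", "female"), c(nM, nF))
    addRecord(fId, NA_character_, NA_character_, fSex, 0L, "base",
              NA_integer_, FALSE, founders)
    names(founders) <- fId

    # random-mating phase: each male with randomFemales/randomMales
    # females; offspring census refills the breeding roster
    perMale <- nF %/% nM
    offPerFemale <- as.integer(ceiling(3 * (nM + nF) / (2 * nF)))
    cur <- founders
    curSex <- stats::setNames(fSex, fId)
    for (g in seq_len(design@randomGenerations)) {
        males <- sample(names(curSex)[curSex == "male"], nM)
        females <- sample(names(curSex)[curSex == "female"], nF)
        sireOfDam <- stats::setNames(rep(males, each = perMale)[
            seq_len(nF)], sample(females))
        offDam <- rep(names(sireOfDam), offPerFemale)
        offSire <- sireOfDam[offDam]
        nOff <- length(offDam)
        kids <- lapply(seq_len(nOff), function(i)
            .offspringOf(cur[[offSire[i]]], cur[[offDam[i]]], genome))
        ids <- newId(nOff)
        sex <- rep_len(c("male", "female"), nOff)
        addRecord(ids, unname(offSire), offDam, sex, g, "base",
                  NA_integer_, FALSE, kids)
        names(kids) <- ids
        cur <- kids
        curSex <- stats::setNames(sex, ids)
    }

    # selection phase: nLines closed lines
    nSelF <- design@selectedFemalesPerLine
    nSelM <- design@selectedMalesPerLine
    nDam <- design@damsPerLine
    nSire <- design@siresPerLine
    genoIds <- character(0)
    genoRows <- list()

    availM <- sample(names(curSex)[curSex == "male"])
    availF <- sample(names(curSex)[curSex == "female"])
    if (length(availM) < nSire * design@nLines ||
        length(availF) < nDam * design@nLines)
        stop("random phase provides too few breeders for the lines; ",
             "increase the census")
    # disjoint candidate pools per line; breeders are drawn from the
    # pool at mating time so an unlucky draw can be repeated
    shareM <- floor(length(availM) / design@nLines)
    shareF <- floor(length(availF) / design@nLines)
    linePool <- lapply(seq_len(design@nLines), function(l) {
        list(males = availM[(l - 1L) * shareM + seq_len(shareM)],
             females = availF[(l - 1L) * shareF + seq_len(shareF)])
    })
    lineNames <- if (design@nLines == 2L) c("high", "low") else
        paste0("line", seq_len(design@nLines))

    pedGen0 <- design@randomGenerations
    for (s in seq_len(design@selectionGenerations)) {
        nextCur <- list()
        nextSex <- character(0)
        for (l in seq_len(design@nLines)) {
            pool <- linePool[[l]]
            mates <- .matingPlan(pool$males, pool$females, nSire, nDam,
                                 grands,
                                 design@avoidSharedGrandparents)
            nKeep <- nSelF + nSelM
            nBorn <- max(nKeep, round(nKeep / design@selectedProportion))
            bornDam <- sample(rep_len(mates$dam, nBorn))
            sireOf <- stats::setNames(mates$sire, mates$dam)
            keepDam <- bornDam[sample.int(nBorn, nKeep)]
            keepSire <- unname(sireOf[keepDam])
            kids <- lapply(seq_len(nKeep), function(i)
                .offspringOf(cur[[keepSire[i]]], cur[[keepDam[i]]],
                             genome))
            ids <- newId(nKeep)
            sex <- sample(rep(c("female", "male"), c(nSelF, nSelM)))
            addRecord(ids, keepSire, keepDam, sex, pedGen0 + s,
                      lineNames[l], s, TRUE, kids)
            names(kids) <- ids
            genoRows[[length(genoRows) + 1L]] <- vapply(kids, function(a)
                lineRef[cbind(a$h1$d, seq_len(m))] +
                lineRef[cbind(a$h2$d, seq_len(m))], integer(m))
            genoIds <- c(genoIds, ids)
            nextCur <- c(nextCur, kids)
            nextSex <- c(nextSex, stats::setNames(sex, ids))
            linePool[[l]] <- list(males = ids[sex == "male"],
                                  females = ids[sex == "female"])
        }
        cur <- nextCur
        curSex <- nextSex
    }

    pedDf <- do.call(rbind, records)
    truthDf <- do.call(rbind, truth)
    rownames(truthDf) <- NULL
    ped <- Pedigree(pedDf)

    geno <- do.call(cbind, genoRows)
    colnames(geno) <- genoIds
    map <- genome$map
    map$allele1 <- "A"
    map$allele2 <- "B"
    ti <- match(genoIds, truthDf$id)
    samples <- data.frame(
        animal_id = genoIds,
        sex = pedDf$sex[match(genoIds, pedDf$id)],
        generation = truthDf$selection_generation[ti],
        line = truthDf$line[ti], stringsAsFactors = FALSE)
    gd <- GenotypeData(geno, map, samples)
    S4Vectors::metadata(gd)$seed <- seed
    list(ped = ped, geno = gd, truth = truthDf, design = design,
         seed = seed)
}

#' Write a simulated data set to disk
#'
#' Emits the genotypes in both PLINK dialects
#' (\code{prefix.ped/.map} and \code{prefix.bed/.bim/.fam}), the
#' pedigree as \code{prefix_pedigree.csv} and the true-autozygosity
#' table as \code{prefix_truth.csv}. CSV files carry a header comment
#' with the seed and a design checksum; byte-identical across runs with
#' the same seed.
#'
#' @param sim Result of [simulateBreeding()].
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return The file prefix path, invisibly.
#' @export
writeFixture <- function(sim, dir, prefix = "sim") {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    path <- file.path(dir, prefix)
    writePlink(sim$geno, path, format = "ped")
    writePlink(sim$geno, path, format = "bed")
    hdr <- sprintf("# seed: %s; design checksum: %d",
                   if (is.null(sim$seed)) "none" else sim$seed,
                   .designChecksum(sim$design))
    pedFile <- paste0(path, "_pedigree.csv")
    writeLines(hdr, pedFile)
    df <- pedTable(sim$ped)
    df$sire[is.na(df$sire)] <- "0"
    df$dam[is.na(df$dam)] <- "0"
    suppressWarnings(utils::write.table(
        df, pedFile, sep = ",", quote = FALSE, row.names = FALSE,
        append = TRUE))
    truthFile <- paste0(path, "_truth.csv")
    writeLines(hdr, truthFile)
    suppressWarnings(utils::write.table(
        sim$truth, truthFile, sep = ",", quote = FALSE,
        row.names = FALSE, append = TRUE))
    invisible(path)
}

.designChecksum <- function(design) {
    vals <- unlist(lapply(slotNames(design), function(s)
        as.numeric(slot(design, s))))
    as.integer(sum(vals * seq_along(vals)) %% 2147483647)
}
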