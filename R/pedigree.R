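#' Construct a validated, topologically sorted Pedigree
#'
#' Validates the parent graph (unique ids, no orphan parent references,
#' no cycles, generations increasing from parent to offspring, sex
#' consistent with parental roles) and sorts records so that parents
#' precede their offspring. The on-disk order of records is irrelevant:
#' two shuffles of the same pedigree yield identical objects up to the
#' deterministic sort (generation, then id, within topological levels).
#'
#' @param df A \code{data.frame} with columns \code{id}, \code{sire},
#'   \code{dam} and optionally \code{sex}, \code{generation},
#'   \code{line}. Unknown parents are \code{NA}.
#' @return A \linkS4class{Pedigree}.
#' @examples
#' ped <- Pedigree(data.frame(
#'   id = c("o", "s", "d"), sire = c("s", NA, NA), dam = c("d", NA, NA),
#'   sex = c("female", "male", "female"), generation = c(1, 0, 0)))
#' pedId(ped)  # parents first
#' @export
Pedigree <- function(df) {
    stopifnot(is.data.frame(df))
    need <- c("id", "sire", "dam")
    if (!all(need %in% names(df)))
        stop("pedigree needs columns: ", paste(need, collapse = ", "))
    df$id <- as.character(df$id)
    df$sire <- as.character(df$sire)
    df$dam <- as.character(df$dam)
    if (!"sex" %in% names(df)) df$sex <- NA_character_
    if (!"generation" %in% names(df)) df$generation <- NA_integer_
    if (!"line" %in% names(df)) df$line <- NA_character_
    df$sex <- tolower(as.character(df$sex))
    df$sex[!df$sex %in% c("male", "female")] <- NA_character_
    df$generation <- as.integer(df$generation)
    df$line <- as.character(df$line)
    df <- df[c("id", "sire", "dam", "sex", "generation", "line")]

    if (anyDuplicated(df$id))
        stop("duplicate animal id(s): ",
             paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
    parents <- c(df$sire, df$dam)
    orphan <- setdiff(parents[!is.na(parents)], df$id)
    if (length(orphan))
        stop("parent id(s) without a pedigree record: ",
             paste(sort(orphan), collapse = ", "))

    df <- .topoSortPedigree(df)

    idx <- match(df$id, df$id)
    si <- match(df$sire, df$id)
    di <- match(df$dam, df$id)
    gen <- df$generation
    badg <- which(!is.na(gen) &
                  ((!is.na(si) & !is.na(gen[si]) & gen[si] >= gen) |
                   (!is.na(di) & !is.na(gen[di]) & gen[di] >= gen)))
    if (length(badg))
        stop("parent generation must be strictly less than offspring's; ",
             "offending id(s): ", paste(df$id[badg], collapse = ", "))
    rownames(df) <- NULL
    sire_sex <- df$sex[si[!is.na(si)]]
    if (any(!is.na(sire_sex) & sire_sex != "male"))
        stop("animal(s) used as sire are not recorded as male")
    dam_sex <- df$sex[di[!is.na(di)]]
    if (any(!is.na(dam_sex) & dam_sex != "female"))
        stop("animal(s) used as dam are not recorded as female")

    new("Pedigree", ped = df)
}

# Kahn's algorithm; deterministic tie-break by (generation, id).
.topoSortPedigree <- function(df) {
    n <- nrow(df)
    si <- match(df$sire, df$id)
    di <- match(df$dam, df$id)
    indeg <- integer(n)
    kids <- vector("list", n)
    for (i in seq_len(n)) {
        for (p in c(si[i], di[i])) {
            if (!is.na(p)) {
                indeg[i] <- indeg[i] + 1L
                kids[[p]] <- c(kids[[p]], i)
            }
        }
    }
    key <- order(ifelse(is.na(df$generation), .Machine$integer.max,
                        df$generation), df$id)
    rank <- integer(n); rank[key] <- seq_len(n)
    ready <- which(indeg == 0L)
    out <- integer(0)
    while (length(ready)) {
        ready <- ready[order(rank[ready])]
        i <- ready[1L]; ready <- ready[-1L]
        out <- c(out, i)
        for (k in kids[[i]]) {
            indeg[k] <- indeg[k] - 1L
            if (indeg[k] == 0L) ready <- c(ready, k)
        }
    }
    if (length(out) < n) {
        stuck <- setdiff(seq_len(n), out)
        stop("pedigree contains a cycle involving animal '",
             df$id[stuck[1L]], "'")
    }
    df[out, , drop = FALSE]
}

#' Read a pedigree from delimited text
#'
#' @param path Path to a delimited text file with a header.
#' @param columns Named character vector mapping the required fields to
#'   file column names; names \code{id}, \code{sire}, \code{dam} are
#'   required, \code{sex}, \code{generation}, \code{line} optional.
#' @param unknown Codes (besides empty) read as "parent unknown".
#' @param sep Field separator.
#' @return A \linkS4class{Pedigree}.
#' @seealso [writePedigree()]
#' @export
readPedigree <- function(path,
                         columns = c(id = "id", sire = "sire", dam = "dam",
                                     sex = "sex", generation = "generation",
                                     line = "line"),
                         unknown = c("0", ""), sep = ",") {
    raw <- utils::read.table(path, header = TRUE, sep = sep,
                             colClasses = "character",
                             stringsAsFactors = FALSE, comment.char = "#")
    need <- c("id", "sire", "dam")
    if (!all(need %in% names(columns)))
        stop("'columns' must map at least id, sire and dam")
    miss <- setdiff(columns[names(columns) %in% names(raw) == FALSE &
                            names(columns) %in% need], names(raw))
    df <- data.frame(id = character(nrow(raw)))
    for (field in c("id", "sire", "dam", "sex", "generation", "line")) {
        col <- columns[[field]]
        if (!is.null(col) && !is.na(col) && col %in% names(raw))
            df[[field]] <- raw[[col]]
        else if (field %in% need)
            stop("column '", col, "' (", field, ") not found in ", path)
        else df[[field]] <- NA
    }
    for (f in c("sire", "dam"))
        df[[f]][df[[f]] %in% unknown | is.na(df[[f]])] <- NA_character_
    Pedigree(df)
}

#' Write a pedigree as delimited text
#'
#' @param ped A \linkS4class{Pedigree}.
#' @param path Output file.
#' @param unknown Code written for unknown parents.
#' @param sep Field separator.
#' @return \code{path}, invisibly.
#' @export
writePedigree <- function(ped, path, unknown = "0", sep = ",") {
    df <- pedTable(ped)
    df$sire[is.na(df$sire)] <- unknown
    df$dam[is.na(df$dam)] <- unknown
    utils::write.table(df, path, sep = sep, quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @describeIn Pedigree-accessors The full pedigree table (sorted).
#' @export
pedTable <- function(ped) {
    stopifnot(is(ped, "Pedigree"))
    ped@ped
}

#' Accessors for Pedigree objects
#'
#' @param ped A \linkS4class{Pedigree}.
#' @name Pedigree-accessors
#' @return \code{pedTable}: the underlying \code{data.frame};
#'   \code{pedId}, \code{pedGeneration}, \code{pedLine}: per-animal
#'   vectors in pedigree order.
NULL

#' @describeIn Pedigree-accessors Animal identifiers.
#' @export
pedId <- function(ped) pedTable(ped)$id

#' @describeIn Pedigree-accessors Discrete generation per animal.
#' @export
pedGeneration <- function(ped) {
    g <- pedTable(ped)$generation
    names(g) <- pedId(ped)
    g
}

#' @describeIn Pedigree-accessors Line label per animal.
#' @export
pedLine <- function(ped) {
    l <- pedTable(ped)$line
    names(l) <- pedId(ped)
    l
}

#' @export
setMethod("show", "Pedigree", function(object) {
    df <- pedTable(object)
    founders <- sum(is.na(df$sire) & is.na(df$dam))
    cat("Pedigree with", nrow(df), "animals (", founders, "founders )\n")
    if (!all(is.na(df$generation)))
        cat("  generations:", min(df$generation, na.rm = TRUE), "-",
            max(df$generation, na.rm = TRUE), "\n")
    if (!all(is.na(df$line)))
        cat("  lines:", paste(sort(unique(stats::na.omit(df$line))),
                              collapse = ", "), "\n")
})

#' Pedigree inbreeding coefficients (Meuwissen-Luo recursion)
#'
#' Computes per-animal inbreeding F as the probability of carrying two
#' alleles identical by descent relative to the pedigree founders, using
#' the Meuwissen & Luo (1992) algorithm (linear traversal of each
#' animal's ancestor list; equivalent to half the parents' additive
#' relationship). Founders and animals with an unknown parent get F = 0.
#'
#' @param ped A \linkS4class{Pedigree}.
#' @return Named numeric vector of F in [0, 1], in pedigree order.
#' @examples
#' ped <- Pedigree(data.frame(
#'   id = c("a", "b", "s", "d", "x"),
#'   sire = c(NA, NA, "a", "a", "s"), dam = c(NA, NA, "b", "b", "d")))
#' pedInbreeding(ped)[["x"]]  # full-sib mating: 0.25
#' @export
pedInbreeding <- function(ped) {
    df <- pedTable(ped)
    si <- match(df$sire, df$id)
    di <- match(df$dam, df$id)
    si[is.na(si)] <- 0L
    di[is.na(di)] <- 0L
    f <- .Call(`_inbreedNe_ml_inbreeding`, si, di)
    names(f) <- df$id
    f
}

#' Classic per-generation increase in inbreeding
#'
#' For each animal with both parents known,
#' \deqn{\Delta F_t = (F_t - \bar F_{par}) / (1 - \bar F_{par})}
#' where \eqn{\bar F_{par}} is the mean inbreeding of its parents. The
#' value may be negative. Animals with an unknown parent get \code{NA}
#' unless \code{unknownParentZero} treats the missing parent as F = 0.
#'
#' @param ped A \linkS4class{Pedigree}.
#' @param f Per-animal inbreeding from [pedInbreeding()] (recomputed when
#'   missing).
#' @param unknownParentZero Treat unknown parents as non-inbred founders
#'   instead of emitting \code{NA}. Default \code{FALSE}: in a complete
#'   experimental pedigree an unknown parent signals a data problem.
#' @return Named numeric vector of \eqn{\Delta F_t} (with \code{NA}s).
#' @export
deltaFPedT <- function(ped, f = pedInbreeding(ped),
                       unknownParentZero = FALSE) {
    df <- pedTable(ped)
    f <- f[df$id]
    fs <- ifelse(is.na(df$sire), NA_real_, f[match(df$sire, df$id)])
    fd <- ifelse(is.na(df$dam), NA_real_, f[match(df$dam, df$id)])
    if (unknownParentZero) {
        fs[is.na(fs) & !(is.na(df$sire) & is.na(df$dam))] <- 0
        fd[is.na(fd) & !(is.na(df$sire) & is.na(df$dam))] <- 0
    }
    fp <- (fs + fd) / 2
    out <- (f - fp) / (1 - fp)
    sat <- !is.na(fp) & fp == 1
    if (any(sat)) {
        warning("parents fully inbred (mean F = 1) for ",
                sum(sat), " animal(s); Delta F undefined")
        out[sat] <- NA_real_
    }
    names(out) <- df$id
    out
}

#' Individual increase in inbreeding from pedigree depth
#'
#' Standardises an animal's inbreeding by its number of discrete
#' generations from the pedigree founders:
#' \deqn{\Delta F_i = 1 - (1 - F)^{1/(t-1)}}
#' with t = generation index + 1 (founders at generation 0 have t = 1),
#' so offspring of founders use exponent 1 and \eqn{\Delta F_i = F} after
#' one generation of inbreeding. Defined for t >= 2; founders and
#' generation-0 animals get \code{NA}.
#'
#' @param ped A \linkS4class{Pedigree} with a \code{generation} column.
#' @param f Per-animal inbreeding from [pedInbreeding()].
#' @return Named numeric vector of \eqn{\Delta F_i}.
#' @export
deltaFPedI <- function(ped, f = pedInbreeding(ped)) {
    df <- pedTable(ped)
    if (all(is.na(df$generation)))
        stop("pedigree has no generation information")
    f <- f[df$id]
    t <- df$generation + 1L
    out <- ifelse(!is.na(t) & t >= 2L, 1 - (1 - f)^(1 / (t - 1)), NA_real_)
    names(out) <- df$id
    out
}

#' Effective population size from a mean rate of inbreeding
#'
#' \eqn{N_e = 1 / (2 \overline{\Delta F})} over the non-missing rates.
#' Negative mean rates yield negative Ne, reported as-is.
#'
#' @param rates Numeric vector of per-individual \eqn{\Delta F}.
#' @return A single Ne value (\code{NA} with a warning if the mean rate
#'   is zero or no rates remain).
#' @export
neFromRate <- function(rates) {
    rates <- rates[!is.na(rates)]
    if (!length(rates)) {
        warning("no non-missing rates; Ne undefined")
        return(NA_real_)
    }
    m <- mean(rates)
    if (m == 0) {
        warning("mean rate of inbreeding is zero; Ne undefined")
        return(NA_real_)
    }
    1 / (2 * m)
}

#' Effective population size from the sex ratio
#'
#' \eqn{N_{e,s} = 4MF / (M + F)} for M breeding males and F breeding
#' females.
#'
#' @param males,females Positive breeding counts.
#' @return Ne based on the sex ratio.
#' @examples
#' neSexRatio(32, 64)  # 85.33
#' @export
neSexRatio <- function(males, females) {
    if (males <= 0 || females <= 0)
        stop("both sexes need a positive breeding count")
    4 * males * females / (males + females)
}

#' Generations elapsed from a founder population
#'
#' Inverts \eqn{F_t = 1 - (1 - \Delta F)^t} to estimate the number of
#' discrete generations separating a reference population with mean
#' inbreeding \code{fRef} from its (unrelated, non-inbred) founders,
#' given a per-generation rate \code{deltaF}:
#' \deqn{t = \ln(1 - F_t) / \ln(1 - \Delta F)}
#'
#' @param fRef Mean inbreeding of the reference population, in (0, 1).
#' @param deltaF Per-generation increase in inbreeding, in (0, 1);
#'   e.g. \eqn{1 / (2 N_{e,s})} from [neSexRatio()], or a mean
#'   individual rate from [deltaFPedI()].
#' @return Estimated number of generations.
#' @examples
#' estimateT(0.61, 1 / (2 * neSexRatio(32, 64)))
#' @export
estimateT <- function(fRef, deltaF) {
    if (!(fRef > 0 && fRef < 1))
        stop("fRef must lie strictly in (0, 1)")
    if (!(deltaF > 0 && deltaF < 1))
        stop("deltaF must lie strictly in (0, 1)")
    log(1 - fRef) / log(1 - deltaF)
}
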