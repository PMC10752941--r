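#' Read PLINK genotype files
#'
#' Reads either a text pair (\code{prefix.ped}/\code{prefix.map}) or a
#' binary triplet (\code{prefix.bed}/\code{prefix.bim}/\code{prefix.fam},
#' SNP-major). Genotype codes count the reference allele: for binary
#' input this is the first (\code{A1}) allele of the \code{.bim} file;
#' for text input the \code{.map} carries no alleles, so the counted
#' allele is taken from \code{refAlleles} when supplied and otherwise
#' defaults to the lexicographically smallest allele observed at the
#' SNP.
#'
#' @param prefix Path prefix of the fileset (no extension).
#' @param refAlleles Optional character vector, named by SNP id, giving
#'   the allele to count for text input.
#' @return A \linkS4class{GenotypeData}.
#' @seealso [writePlink()]
#' @export
readPlink <- function(prefix, refAlleles = NULL) {
    if (file.exists(paste0(prefix, ".bed")))
        .readPlinkBed(prefix)
    else if (file.exists(paste0(prefix, ".ped")))
        .readPlinkPed(prefix, refAlleles)
    else stop("no .bed or .ped file found for prefix '", prefix, "'")
}

.readFam <- function(path) {
    fam <- utils::read.table(path, colClasses = "character")
    names(fam)[1:6] <- c("fid", "iid", "pat", "mat", "sexcode", "pheno")
    data.frame(animal_id = fam$iid,
               family = fam$fid,
               sex = c("1" = "male", "2" = "female")[fam$sexcode],
               stringsAsFactors = FALSE)
}

.readPlinkBed <- function(prefix) {
    bim <- utils::read.table(paste0(prefix, ".bim"),
                             colClasses = "character")
    names(bim) <- c("chrom", "snp", "cm", "bp", "allele1", "allele2")
    bim$bp <- as.integer(bim$bp)
    samples <- .readFam(paste0(prefix, ".fam"))
    n <- nrow(samples); m <- nrow(bim)
    con <- file(paste0(prefix, ".bed"), "rb")
    on.exit(close(con))
    magic <- readBin(con, "raw", 3L)
    if (!identical(as.integer(magic), c(0x6cL, 0x1bL, 0x01L)))
        stop(".bed magic bytes wrong or not SNP-major")
    bpS <- ceiling(n / 4)
    raw <- readBin(con, "raw", bpS * m)
    if (length(raw) != bpS * m)
        stop(".bed size does not match .bim/.fam dimensions")
    b <- as.integer(raw)
    # unpack 2-bit codes, individuals packed LSB-first within each byte
    codes <- matrix(NA_integer_, nrow = 4 * bpS, ncol = m)
    shift <- c(1L, 4L, 16L, 64L)
    for (k in 1:4)
        codes[seq(k, 4 * bpS, by = 4), ] <- (b %/% shift[k]) %% 4L
    codes <- codes[seq_len(n), , drop = FALSE]
    # 00 -> hom A1 (2), 01 -> missing, 10 -> het, 11 -> hom A2 (0)
    lut <- c(2L, NA_integer_, 1L, 0L)
    geno <- matrix(lut[codes + 1L], nrow = n, ncol = m)
    GenotypeData(t(geno),
                 map = bim[c("snp", "chrom", "bp", "allele1", "allele2")],
                 samples = samples)
}

.readPlinkPed <- function(prefix, refAlleles = NULL) {
    map <- utils::read.table(paste0(prefix, ".map"),
                             colClasses = "character")
    names(map) <- c("chrom", "snp", "cm", "bp")
    map$bp <- as.integer(map$bp)
    m <- nrow(map)
    ped <- utils::read.table(paste0(prefix, ".ped"),
                             colClasses = "character")
    if (ncol(ped) != 6 + 2 * m)
        stop(".ped has ", ncol(ped) - 6,
             " allele columns but .map lists ", m, " SNPs")
    samples <- data.frame(animal_id = ped[[2]], family = ped[[1]],
                          sex = c("1" = "male", "2" = "female")[ped[[5]]],
                          stringsAsFactors = FALSE)
    n <- nrow(ped)
    a1 <- as.matrix(ped[, 6 + 2 * seq_len(m) - 1, drop = FALSE])
    a2 <- as.matrix(ped[, 6 + 2 * seq_len(m), drop = FALSE])
    geno <- matrix(NA_integer_, nrow = m, ncol = n)
    ref <- alt <- character(m)
    for (j in seq_len(m)) {
        x1 <- a1[, j]; x2 <- a2[, j]
        miss <- x1 == "0" | x2 == "0"
        obs <- sort(unique(c(x1[!miss], x2[!miss])))
        if (length(obs) > 2)
            stop("SNP '", map$snp[j], "' has more than two alleles: ",
                 paste(obs, collapse = ", "))
        rj <- refAlleles[[map$snp[j]]]
        if (is.null(rj)) rj <- if (length(obs)) obs[1] else "A"
        if (length(obs) && !rj %in% obs && length(obs) == 2)
            stop("reference allele '", rj, "' not observed at SNP '",
                 map$snp[j], "'")
        aj <- setdiff(obs, rj)
        if (!length(aj)) aj <- "0"
        geno[j, ] <- ifelse(miss, NA_integer_,
                            (x1 == rj) + (x2 == rj))
        ref[j] <- rj; alt[j] <- aj[1]
    }
    GenotypeData(geno,
                 map = data.frame(snp = map$snp, chrom = map$chrom,
                                  bp = map$bp, allele1 = ref,
                                  allele2 = alt,
                                  stringsAsFactors = FALSE),
                 samples = samples)
}

#' Write PLINK genotype files
#'
#' Writes a \linkS4class{GenotypeData} as a PLINK text pair
#' (\code{.ped}/\code{.map}) or binary triplet
#' (\code{.bed}/\code{.bim}/\code{.fam}; magic bytes \code{6c 1b 01},
#' SNP-major). The counted allele is written as \code{A1} of the
#' \code{.bim}, so a binary round trip preserves codes exactly; text
#' round trips are exact whenever the allele labels sort with the
#' reference allele first (as the simulated fixtures do), or when the
#' reader is given \code{refAlleles}.
#'
#' @param gd A \linkS4class{GenotypeData}.
#' @param prefix Output path prefix.
#' @param format \code{"ped"} (text) or \code{"bed"} (binary).
#' @return \code{prefix}, invisibly.
#' @export
writePlink <- function(gd, prefix, format = c("ped", "bed")) {
    format <- match.arg(format)
    rr <- markerMap(gd)
    map <- data.frame(chrom = as.character(GenomicRanges::seqnames(rr)),
                      snp = names(rr), cm = 0,
                      bp = GenomicRanges::start(rr),
                      a1 = S4Vectors::mcols(rr)$allele1,
                      a2 = S4Vectors::mcols(rr)$allele2,
                      stringsAsFactors = FALSE)
    info <- sampleInfo(gd)
    sex <- if ("sex" %in% names(info)) info$sex
           else rep(NA_character_, nrow(info))
    sexcode <- ifelse(is.na(sex), "0",
                      ifelse(sex == "male", "1", "2"))
    fam <- data.frame(fid = if ("line" %in% names(info) &&
                                !all(is.na(info$line)))
                                as.character(info$line) else "0",
                      iid = info$animal_id, pat = "0", mat = "0",
                      sex = sexcode, pheno = "-9",
                      stringsAsFactors = FALSE)
    fam$fid[is.na(fam$fid)] <- "0"
    g <- genoCounts(gd)
    if (format == "ped") {
        utils::write.table(map[c("chrom", "snp", "cm", "bp")],
                           paste0(prefix, ".map"), quote = FALSE,
                           row.names = FALSE, col.names = FALSE, sep = "\t")
        m <- nrow(g); n <- ncol(g)
        al <- matrix("0", nrow = 2 * m, ncol = n)
        first <- ifelse(is.na(g) | g == 0, rep(map$a2, ncol(g)),
                        rep(map$a1, ncol(g)))
        second <- ifelse(is.na(g) | g < 2, rep(map$a2, ncol(g)),
                         rep(map$a1, ncol(g)))
        first[is.na(as.vector(g))] <- "0"
        second[is.na(as.vector(g))] <- "0"
        al[2 * seq_len(m) - 1, ] <- first
        al[2 * seq_len(m), ] <- second
        lines <- paste(fam$fid, fam$iid, fam$pat, fam$mat, fam$sex,
                       fam$pheno,
                       apply(al, 2, paste, collapse = " "))
        writeLines(lines, paste0(prefix, ".ped"))
    } else {
        utils::write.table(map[c("chrom", "snp", "cm", "bp", "a1", "a2")],
                           paste0(prefix, ".bim"), quote = FALSE,
                           row.names = FALSE, col.names = FALSE, sep = "\t")
        utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE,
                           row.names = FALSE, col.names = FALSE, sep = " ")
        n <- ncol(g); m <- nrow(g); bpS <- ceiling(n / 4)
        # code -> 2-bit: 2 -> 00, NA -> 01, 1 -> 10, 0 -> 11; pad with 00
        two <- matrix(0L, nrow = 4 * bpS, ncol = m)
        lut <- c(3L, 2L, 0L)
        tw <- matrix(lut[as.vector(g) + 1L], nrow = m, ncol = n)
        tw[is.na(g)] <- 1L
        two[seq_len(n), ] <- t(tw)
        shift <- c(1L, 4L, 16L, 64L)
        bytes <- integer(bpS * m)
        for (k in 1:4)
            bytes <- bytes + shift[k] *
                as.vector(two[seq(k, 4 * bpS, by = 4), , drop = FALSE])
        con <- file(paste0(prefix, ".bed"), "wb")
        on.exit(close(con))
        writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
        writeBin(as.raw(bytes), con)
    }
    invisible(prefix)
}
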