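# Independent oracles and fixture builders. These deliberately use
# naive loops / the full tabular recursion so they share no code path
# with the package implementations they check.

# Pedigree F via the full additive-relationship (tabular) recursion:
# A[i,i] = 1 + 0.5 * A[sire, dam]; F = diag(A) - 1.
oracle_ped_f <- function(df) {
    si <- match(df$sire, df$id)
    di <- match(df$dam, df$id)
    n <- nrow(df)
    A <- matrix(0, n, n)
    for (i in seq_len(n)) {
        s <- si[i]; d <- di[i]
        A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
        if (i > 1L) for (j in seq_len(i - 1L)) {
            a <- 0
            if (!is.na(s)) a <- a + 0.5 * A[j, s]
            if (!is.na(d)) a <- a + 0.5 * A[j, d]
            A[i, j] <- A[j, i] <- a
        }
    }
    stats::setNames(diag(A) - 1, df$id)
}

# Random generational pedigree: founders appear with probability
# pFounder, otherwise parents are sampled from earlier animals of the
# right sex.
random_pedigree <- function(n, pFounder = 0.35) {
    id <- sprintf("I%03d", seq_len(n))
    sex <- sample(rep_len(c("male", "female"), n))
    sire <- dam <- rep(NA_character_, n)
    gen <- integer(n)
    for (i in seq_len(n)) {
        pm <- which(sex[seq_len(i - 1L)] == "male")
        pf <- which(sex[seq_len(i - 1L)] == "female")
        if (length(pm) && length(pf) && stats::runif(1) > pFounder) {
            s <- if (length(pm) == 1L) pm else sample(pm, 1L)
            d <- if (length(pf) == 1L) pf else sample(pf, 1L)
            sire[i] <- id[s]; dam[i] <- id[d]
            gen[i] <- max(gen[s], gen[d]) + 1L
        }
    }
    data.frame(id = id, sire = sire, dam = dam, sex = sex,
               generation = gen, stringsAsFactors = FALSE)
}

# Quick GenotypeData from a SNP x individual matrix.
make_gd <- function(geno, chrom = NULL, bp = NULL, samples = NULL,
                    spacing = 10000L) {
    m <- nrow(geno); n <- ncol(geno)
    if (is.null(chrom)) chrom <- rep("1", m)
    if (is.null(bp)) {
        bp <- integer(m)
        for (c in unique(chrom)) {
            i <- chrom == c
            bp[i] <- seq_len(sum(i)) * spacing
        }
    }
    if (is.null(samples))
        samples <- data.frame(animal_id = sprintf("id%03d", seq_len(n)),
                              stringsAsFactors = FALSE)
    GenotypeData(geno,
                 map = data.frame(snp = sprintf("s%04d", seq_len(m)),
                                  chrom = chrom, bp = bp,
                                  allele1 = "A", allele2 = "B",
                                  stringsAsFactors = FALSE),
                 samples = samples)
}

random_gd <- function(nInd, nSnp, missing = 0.05, nChrom = 1L) {
    g <- matrix(sample(0:2, nSnp * nInd, replace = TRUE),
                nrow = nSnp, ncol = nInd)
    if (missing > 0)
        g[stats::runif(length(g)) < missing] <- NA_integer_
    make_gd(g, chrom = as.character(rep_len(seq_len(nChrom),
                                            nSnp)[order(rep_len(
                                                seq_len(nChrom), nSnp))]))
}

# Per-locus brute-force GRM estimators, explicit loops per individual.
oracle_grm <- function(g, p) {
    n <- ncol(g)
    out <- data.frame(nej = numeric(n), lh = numeric(n),
                      vr1 = numeric(n), vr2 = numeric(n),
                      yan = numeric(n))
    hexp_locus <- 1 - 2 * p * (1 - p)
    for (i in seq_len(n)) {
        x <- g[, i]
        use <- !is.na(x) & !is.na(p)
        out$nej[i] <- mean(x[!is.na(x)] != 1)
        hobs <- mean(x[use] != 1)
        hexp <- mean(hexp_locus[use])
        out$lh[i] <- (hobs - hexp) / (1 - hexp)
        num <- den <- 0
        s2 <- 0; m2 <- 0L
        sy <- 0
        for (j in which(use)) {
            num <- num + (x[j] - 2 * p[j])^2
            den <- den + 2 * p[j] * (1 - p[j])
            if (p[j] > 0 && p[j] < 1) {
                s2 <- s2 + (x[j] - 2 * p[j])^2 / (2 * p[j] * (1 - p[j]))
                sy <- sy + (x[j]^2 - (1 + 2 * p[j]) * x[j] +
                            2 * p[j]^2) / (2 * p[j] * (1 - p[j]))
                m2 <- m2 + 1L
            }
        }
        out$vr1[i] <- num / den - 1
        out$vr2[i] <- s2 / m2 - 1
        out$yan[i] <- sy / m2
    }
    out
}

# Exhaustive ROH oracle for one individual on one chromosome: naive
# window scan, per-SNP hit fractions, maximal interval enumeration with
# gap splitting and the count/length/density filters. Returns a
# data.frame of segments (first/last SNP index, n).
oracle_roh <- function(x, bp, par) {
    m <- length(x)
    W <- par@windowSnps
    nw <- m - W + 1L
    inrun <- rep(FALSE, m)
    if (nw >= 1L) {
        okwin <- logical(nw)
        for (w in seq_len(nw)) {
            win <- x[w:(w + W - 1L)]
            okwin[w] <- sum(win == 1L, na.rm = TRUE) <= par@windowHetMax &&
                sum(is.na(win)) <= par@windowMissingMax
        }
        for (k in seq_len(m)) {
            ws <- max(1L, k - W + 1L):min(nw, k)
            ws <- ws[ws >= 1L & ws <= nw]
            if (length(ws))
                inrun[k] <- mean(okwin[ws]) >= par@windowHitThreshold
        }
    }
    segs <- list()
    k <- 1L
    while (k <= m) {
        if (!inrun[k]) { k <- k + 1L; next }
        run <- k
        while (k < m && inrun[k + 1L] &&
               (bp[k + 1L] - bp[k]) <= par@maxGapKb * 1000) {
            k <- k + 1L
            run <- c(run, k)
        }
        n <- length(run)
        kb <- (bp[run[n]] - bp[run[1L]]) / 1000
        if (n >= par@minSnps && kb >= par@minLenKb &&
            kb / n <= par@maxKbPerSnp)
            segs[[length(segs) + 1L]] <- data.frame(
                first = run[1L], last = run[n], n = n)
        k <- k + 1L
    }
    if (length(segs)) do.call(rbind, segs) else
        data.frame(first = integer(0), last = integer(0),
                   n = integer(0))
}
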