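# Fixtures use one individual; genotype vectors are SNP-ordered along
# a single chromosome unless stated.

roh_gd <- function(x, bp = seq_along(x) * 10000L,
                   chrom = rep("1", length(x))) {
    make_gd(matrix(as.integer(x), ncol = 1), chrom = chrom, bp = bp)
}

test_that("a clean homozygous chromosome yields exactly one full run", {
    # 120 homozygous SNPs at uniform 10-kb spacing (1,190 kb span) on
    # one chromosome; a second, fully heterozygous chromosome
    x <- c(rep(2L, 120), rep(1L, 120))
    gd <- roh_gd(x, bp = rep(seq_len(120) * 10000L, 2),
                 chrom = rep(c("1", "2"), each = 120))
    segs <- detectRoh(gd)
    expect_length(segs, 1)
    expect_identical(S4Vectors::mcols(segs)$n_snps, 120L)
    expect_equal(S4Vectors::mcols(segs)$kb, 1190)
    expect_identical(as.character(GenomicRanges::seqnames(segs)), "1")

    # 90 homozygous SNPs spanning 890 kb fail both minima
    expect_length(detectRoh(roh_gd(rep(0L, 90))), 0)
})

test_that("segments satisfy every parameter constraint", {
    set.seed(81)
    par <- rohParams(windowSnps = 10, minSnps = 15, minLenKb = 140,
                     maxKbPerSnp = 20, maxGapKb = 100)
    for (rep in 1:10) {
        x <- sample(c(0L, 1L, 2L, NA), 300, TRUE,
                    prob = c(0.45, 0.06, 0.45, 0.04))
        gd <- roh_gd(x)
        segs <- detectRoh(gd, par)
        if (!length(segs)) next
        mc <- S4Vectors::mcols(segs)
        expect_true(all(mc$n_snps >= 15))
        expect_true(all(mc$kb >= 140))
        expect_true(all(mc$kb / mc$n_snps <= 20))
        expect_true(all(GenomicRanges::width(segs) > 0))
    }
})

test_that("scanner equals the exhaustive-enumeration oracle", {
    pars <- list(
        rohParams(windowSnps = 10, windowHetMax = 1,
                  windowMissingMax = 2, minSnps = 12, minLenKb = 100,
                  maxKbPerSnp = 30, maxGapKb = 150),
        rohParams(windowSnps = 20, windowHetMax = 0,
                  windowMissingMax = 5, minSnps = 25, minLenKb = 200,
                  maxKbPerSnp = 15, maxGapKb = 1000),
        rohParams(windowSnps = 15, windowHetMax = 2,
                  windowMissingMax = 1, windowHitThreshold = 0.7,
                  minSnps = 10, minLenKb = 80, maxKbPerSnp = 50,
                  maxGapKb = 60))
    for (seed in 1:20) {
        set.seed(seed)
        x <- sample(c(0L, 1L, 2L, NA), 300, TRUE,
                    prob = c(0.46, 0.05, 0.46, 0.03))
        bp <- cumsum(sample(c(5000L, 10000L, 80000L), 300, TRUE,
                            prob = c(0.55, 0.4, 0.05)))
        gd <- roh_gd(x, bp = bp)
        for (par in pars) {
            segs <- detectRoh(gd, par)
            ora <- oracle_roh(x, bp, par)
            expect_identical(length(segs), nrow(ora))
            if (nrow(ora)) {
                expect_identical(GenomicRanges::start(segs),
                                 bp[ora$first])
                expect_identical(GenomicRanges::end(segs),
                                 bp[ora$last])
                expect_identical(S4Vectors::mcols(segs)$n_snps,
                                 as.integer(ora$n))
            }
        }
    }
})

test_that("scan order and relaxation behave monotonically", {
    set.seed(91)
    x1 <- sample(c(0L, 1L, 2L), 300, TRUE, prob = c(0.48, 0.04, 0.48))
    x2 <- sample(c(0L, 1L, 2L), 300, TRUE, prob = c(0.48, 0.04, 0.48))
    g <- cbind(x1, x2)
    colnames(g) <- NULL
    gdA <- make_gd(g, samples = data.frame(animal_id = c("u", "v")))
    gdB <- make_gd(g[, 2:1], samples = data.frame(animal_id = c("v", "u")))
    par <- rohParams(windowSnps = 10, minSnps = 12, minLenKb = 100,
                     maxKbPerSnp = 30, maxGapKb = 200)
    a <- detectRoh(gdA, par)
    b <- detectRoh(gdB, par)
    keyOf <- function(s) sort(paste(S4Vectors::mcols(s)$animal_id,
                                    GenomicRanges::start(s),
                                    GenomicRanges::end(s)))
    expect_identical(keyOf(a), keyOf(b))
    # relaxing the thresholds never removes a reported segment
    relax <- rohParams(windowSnps = 10, minSnps = 8, minLenKb = 50,
                       maxKbPerSnp = 30, maxGapKb = 200)
    r <- detectRoh(gdA, relax)
    expect_true(all(keyOf(a) %in% keyOf(r)))
})

test_that("F_ROH is summed run length over covered autosome length", {
    # one 1,500-kb run on its own chromosome; a heterozygous second
    # chromosome brings the covered length to 100,000 kb
    x <- c(rep(2L, 151), rep(1L, 9851))
    gd <- roh_gd(x,
                 bp = c(seq_len(151) * 10000L, seq_len(9851) * 10000L),
                 chrom = rep(c("1", "2"), c(151, 9851)))
    segs <- detectRoh(gd)
    expect_length(segs, 1)
    expect_equal(S4Vectors::mcols(segs)$kb, 1500)
    fr <- fRoh(segs, gd)
    expect_equal(unname(fr), 1500 / 100000)  # 0.015
    # no segments -> 0
    gd0 <- roh_gd(rep(1L, 200))
    expect_equal(unname(fRoh(detectRoh(gd0), gd0)), 0)
})
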