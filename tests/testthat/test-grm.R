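freqs_of <- function(p) data.frame(snp = sprintf("s%04d", seq_along(p)),
                                   p = p, n_obs = 10L)

test_that("homozygosity-based estimators hit their fixed points", {
    # all homozygous / all heterozygous / mixed count
    g <- matrix(c(2L, 2L, 0L, 2L,
                  1L, 1L, 1L, 1L,
                  0L, 2L, 1L, 2L), ncol = 3)
    gd <- make_gd(g)
    expect_equal(unname(fNej(gd)), c(1, 0, 0.75))

    p <- c(0.5, 0.5, 0.5, 0.5)
    f <- freqs_of(p)
    expect_equal(unname(fLH(gd, f))[1], 1)     # fully homozygous
    expect_equal(unname(fVR1(gd, f))[1:2], c(1, -1))
    expect_equal(unname(fVR2(gd, f))[1:2], c(1, -1))
    expect_equal(unname(fYan(gd, f))[2], -1)
    o <- oracle_grm(genoCounts(gd), p)
    expect_equal(unname(fVR1(gd, f)), o$vr1, tolerance = 1e-12)

    # Hobs equal to Hexp gives F_L&H = 0: one het among two SNPs at
    # p = 0.5 gives Hobs = 0.5 = Hexp
    g2 <- matrix(c(1L, 2L), ncol = 1)
    expect_equal(unname(fLH(make_gd(g2), freqs_of(c(0.5, 0.5)))), 0)

    # heterozygous locus contributes -1 to Yang at any p
    for (pp in c(0.1, 0.3, 0.7))
        expect_equal(unname(fYan(make_gd(matrix(1L, 1, 1)),
                                 freqs_of(pp))), -1)
})

test_that("five-SNP worked example matches per-locus evaluation", {
    p <- c(0.5, 0.5, 0.2, 0.2, 0.1)
    x <- matrix(c(2L, 1L, 0L, 2L, 2L), ncol = 1)
    gd <- make_gd(x)
    o <- oracle_grm(x, p)
    f <- freqs_of(p)
    expect_equal(unname(fLH(gd, f)), o$lh, tolerance = 1e-12)
    expect_equal(unname(fVR1(gd, f)), o$vr1, tolerance = 1e-12)
    expect_equal(unname(fVR2(gd, f)), o$vr2, tolerance = 1e-12)
    expect_equal(unname(fYan(gd, f)), o$yan, tolerance = 1e-12)
})

test_that("all GRM estimators equal the brute-force oracle on random fixtures", {
    set.seed(31)
    for (rep in 1:25) {
        gd <- random_gd(20, 50, missing = 0.08)
        p <- round(stats::runif(50, 0.05, 0.95), 2)
        f <- freqs_of(p)
        o <- oracle_grm(genoCounts(gd), p)
        expect_equal(unname(fNej(gd)), o$nej, tolerance = 1e-12)
        expect_equal(unname(fLH(gd, f)), o$lh, tolerance = 1e-12)
        expect_equal(unname(fVR1(gd, f)), o$vr1, tolerance = 1e-12)
        expect_equal(unname(fVR2(gd, f)), o$vr2, tolerance = 1e-12)
        expect_equal(unname(fYan(gd, f)), o$yan, tolerance = 1e-12)
    }
})

test_that("fixed reference SNPs are excluded from VR2/Yang with a note", {
    g <- matrix(c(1L, 1L, 2L, 0L), ncol = 2)
    gd <- make_gd(g)
    f <- freqs_of(c(0.5, 1))
    expect_message(v <- fVR2(gd, f), "fixed")
    o <- oracle_grm(genoCounts(gd), c(0.5, 1))
    expect_equal(unname(v), o$vr2)
})

test_that("Yang averages to zero under Hardy-Weinberg sampling", {
    set.seed(41)
    m <- 200; n <- 500
    p <- stats::runif(m, 0.1, 0.9)
    g <- matrix(stats::rbinom(m * n, 2, rep(p, n)), nrow = m)
    gd <- make_gd(g)
    fy <- fYan(gd, freqs_of(p))
    se <- stats::sd(fy) / sqrt(n)
    expect_lt(abs(mean(fy)), 3 * se)
})

test_that("reference adjustment is a fixed-point-preserving rescale", {
    expect_equal(adjustToReference(0.61, 0.61), 0)
    expect_equal(adjustToReference(1, 0.61), 1)
    expect_equal(adjustToReference(0.73, 0.61), 0.3077, tolerance = 1e-4)
    expect_equal(adjustToReference(0.68, 0.54), 0.3043, tolerance = 1e-3)
    expect_error(adjustToReference(0.5, 1))
    # adjusted values of the reference cohort average exactly zero
    set.seed(51)
    f <- stats::runif(30, 0.2, 0.9)
    expect_lt(abs(mean(adjustToReference(f, mean(f)))), 1e-12)
})

test_that("raw and adjusted homozygosity estimators rank identically", {
    set.seed(61)
    gd <- random_gd(25, 60, missing = 0)
    p <- stats::runif(60, 0.1, 0.9)
    f <- freqs_of(p)
    nej <- fNej(gd)
    lh <- fLH(gd, f)
    expect_equal(stats::cor(nej, lh, method = "spearman"), 1)
    expect_equal(stats::cor(nej, adjustToReference(nej, 0.4),
                            method = "spearman"), 1)
})

test_that("expected homozygosity series covers its bounds and oracle", {
    g <- matrix(c(0L, 2L,    # p = .5 -> per-SNP term .5
                  0L, 2L,
                  2L, 2L),   # fixed -> 1
                nrow = 3, byrow = TRUE)
    samples <- data.frame(animal_id = c("a", "b"), generation = c(1, 1))
    gd <- make_gd(g, samples = samples)
    s <- fExpSeries(gd)
    expect_equal(s$f_exp, mean(c(0.5, 0.5, 1)))

    set.seed(71)
    g2 <- matrix(sample(0:2, 40 * 12, TRUE), nrow = 40)
    samples2 <- data.frame(animal_id = sprintf("i%02d", 1:12),
                           generation = rep(1:3, each = 4),
                           line = rep_len(c("high", "low"), 12))
    gd2 <- make_gd(g2, samples = samples2)
    s2 <- fExpSeries(gd2, perLine = TRUE)
    expect_setequal(unique(s2$group), c("all", "high", "low"))
    expect_true(all(s2$f_exp >= 0.5 & s2$f_exp <= 1))
    # oracle: generation-2 overall cell
    cols <- samples2$generation == 2
    p <- rowMeans(g2[, cols]) / 2
    expect_equal(s2$f_exp[s2$group == "all" & s2$generation == 2],
                 mean(1 - 2 * p * (1 - p)), tolerance = 1e-12)
})
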