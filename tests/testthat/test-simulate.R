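# Scaled-down designs keep runtimes short; the breeding structure under
# test (phases, mating rules, gene dropping) is unchanged.

small_design <- function(...) {
    args <- list(nFounderLines = 3, foundersPerLine = 16,
                 burnInGenerations = 3, randomGenerations = 2,
                 randomMales = 16, randomFemales = 32,
                 selectionGenerations = 4, nLines = 2,
                 damsPerLine = 8, siresPerLine = 3,
                 selectedFemalesPerLine = 10, selectedMalesPerLine = 5,
                 avoidSharedGrandparents = FALSE,
                 nChromosomes = 2, snpsPerChromosome = 120)
    args[names(list(...))] <- list(...)
    do.call(breedingDesign, args)
}

test_that("a single founder line yields complete homozygosity", {
    sim <- simulateBreeding(small_design(nFounderLines = 1,
                                         foundersPerLine = 48),
                            seed = 5)
    g <- genoCounts(sim$geno)
    expect_true(all(g %in% c(0L, 2L)))
    expect_equal(unname(fNej(sim$geno)), rep(1, ncol(g)))
    expect_true(all(sim$truth$autoz_line == 1))
})

test_that("crosses of distinct inbred lines are heterozygous and non-autozygous", {
    genome <- inbreedNe:::.simGenome(small_design())
    m <- genome$m
    pure <- function(l) list(h1 = list(d = rep(l, m)),
                             h2 = list(d = rep(l, m)))
    set.seed(6)
    f1 <- inbreedNe:::.offspringOf(pure(1L), pure(2L), genome)
    expect_true(all(f1$h1$d == 1L) && all(f1$h2$d == 2L))
    expect_equal(mean(f1$h1$d == f1$h2$d), 0)  # autozygosity 0
})

test_that("full-sib offspring of outbred parents average 0.25 autozygosity", {
    genome <- inbreedNe:::.simGenome(
        small_design(nChromosomes = 2, snpsPerChromosome = 60))
    m <- genome$m
    pure <- function(l) list(h1 = list(d = rep(l, m)),
                             h2 = list(d = rep(l, m)))
    set.seed(8)
    az <- replicate(300, {
        x <- inbreedNe:::.offspringOf(pure(1L), pure(2L), genome)
        y <- inbreedNe:::.offspringOf(pure(3L), pure(4L), genome)
        s1 <- inbreedNe:::.offspringOf(x, y, genome)
        s2 <- inbreedNe:::.offspringOf(x, y, genome)
        o <- inbreedNe:::.offspringOf(s1, s2, genome)
        mean(o$h1$d == o$h2$d)
    })
    se <- stats::sd(az) / sqrt(length(az))
    expect_lt(abs(mean(az) - 0.25), 3 * se)
})

test_that("simulation is reproducible and fixtures round-trip", {
    d <- small_design()
    s1 <- simulateBreeding(d, seed = 33)
    s2 <- simulateBreeding(d, seed = 33)
    expect_identical(genoCounts(s1$geno), genoCounts(s2$geno))
    expect_identical(pedTable(s1$ped), pedTable(s2$ped))
    expect_identical(s1$truth, s2$truth)
    s3 <- simulateBreeding(d, seed = 34)
    expect_false(identical(genoCounts(s1$geno), genoCounts(s3$geno)))

    dir1 <- withr::local_tempdir()
    dir2 <- withr::local_tempdir()
    writeFixture(s1, dir1)
    writeFixture(s2, dir2)
    for (f in c("sim.ped", "sim.map", "sim.bed", "sim.bim", "sim.fam",
                "sim_pedigree.csv", "sim_truth.csv"))
        expect_identical(readBin(file.path(dir1, f), "raw",
                                 file.size(file.path(dir1, f))),
                         readBin(file.path(dir2, f), "raw",
                                 file.size(file.path(dir2, f))))
    back <- readPlink(file.path(dir1, "sim"))
    expect_identical(unname(genoCounts(back)),
                     unname(genoCounts(s1$geno)))
    ped <- readPedigree(file.path(dir1, "sim_pedigree.csv"))
    expect_setequal(pedId(ped), pedId(s1$ped))
})

test_that("recorded pedigree structure matches the design", {
    # grandparent avoidance needs the full breeder census to stay
    # feasible (few sires exhaust compatible pairs within two
    # generations), so this test runs the default counts briefly
    d <- breedingDesign(burnInGenerations = 2,
                        selectionGenerations = 4,
                        nChromosomes = 1, snpsPerChromosome = 100)
    sim <- simulateBreeding(d, seed = 44)
    df <- pedTable(sim$ped)
    expect_identical(sum(df$generation == 0), 96L)
    expect_true(all(df$line[df$generation <= d@randomGenerations] ==
                    "base"))
    sel <- df[df$generation > d@randomGenerations, ]
    expect_setequal(unique(sel$line), c("high", "low"))
    expect_identical(nrow(sel), (50L + 20L) * 2L * 4L)
    # lines are closed: parents of later selection animals stay in-line
    late <- sel[sel$generation > d@randomGenerations + 1L, ]
    sireLine <- df$line[match(late$sire, df$id)]
    expect_true(all(sireLine == late$line))
    # no mating shares a grandparent
    gp <- function(id) {
        p <- df[match(id, df$id), c("sire", "dam")]
        stats::na.omit(unlist(df[match(unlist(p), df$id),
                                 c("sire", "dam")]))
    }
    pairs <- unique(sel[c("sire", "dam")])
    shared <- mapply(function(s, d2) length(intersect(gp(s), gp(d2))) > 0,
                     pairs$sire, pairs$dam)
    expect_false(any(shared))
    # genotyped animals are exactly the selection phase
    expect_setequal(sampleInfo(sim$geno)$animal_id,
                    sim$truth$id[sim$truth$genotyped])
})

test_that("pedigree inbreeding predicts recorded-base autozygosity", {
    # regression of true (recorded-pedigree-base) autozygosity on
    # F_PED, pooled over replicates: shared-ancestor Mendelian
    # sampling correlates animals within one replicate, so the slope
    # is stable only across replicates
    d <- small_design(burnInGenerations = 2, randomGenerations = 2,
                      selectionGenerations = 10, damsPerLine = 10,
                      siresPerLine = 4, selectedFemalesPerLine = 14,
                      selectedMalesPerLine = 8,
                      nChromosomes = 6, snpsPerChromosome = 200,
                      snpSpacingKb = 100)
    xy <- do.call(rbind, lapply(101:105, function(s) {
        sim <- simulateBreeding(d, seed = s)
        f <- pedInbreeding(sim$ped)
        tr <- sim$truth
        data.frame(f = unname(f[tr$id]), a = tr$autoz_ped)
    }))
    slope <- stats::coef(stats::lm(a ~ f, xy))[[2]]
    expect_gt(slope, 0.9)
    expect_lt(slope, 1.1)
})

test_that("allele-frequency drift is consistent with the sex-ratio Ne", {
    # founders carry fully inbred line haplotypes, so per-generation
    # drift is inflated by (1 + F) relative to the Hardy-Weinberg
    # formula (upper limit), while the equal maternal litters of the
    # design damp it at most towards the full-equalization limit of
    # about twice the sex-ratio Ne (lower limit); the observed
    # cumulative variance must fall between these a-priori bounds.
    d <- breedingDesign(nFounderLines = 3, foundersPerLine = 32,
                        burnInGenerations = 0, randomGenerations = 5,
                        selectionGenerations = 1, nLines = 1,
                        damsPerLine = 64, siresPerLine = 32,
                        selectedFemalesPerLine = 96,
                        selectedMalesPerLine = 96,
                        avoidSharedGrandparents = FALSE,
                        nChromosomes = 2, snpsPerChromosome = 100)
    nes <- neSexRatio(32, 64)
    res <- sapply(1:25, function(s) {
        sim <- simulateBreeding(d, seed = 1000 + s)
        af <- alleleFreqs(sim$geno, warn = FALSE)
        tr <- sim$truth
        fbar <- tapply(tr$autoz_line, tr$generation, mean)
        disc <- af$p < 0.999   # discriminating SNPs start at p0 = 2/3
        c(v = mean((af$p[disc] - 2/3)^2),
          bias = mean(af$p[disc]) - 2/3,
          cumq = 1 - prod(1 - (1 + fbar[as.character(0:5)]) /
                          (2 * nes)))
    })
    v <- res["v", ]
    p0 <- 2 / 3
    upper <- p0 * (1 - p0) * mean(res["cumq", ])        # (1+F), no equalization
    lower <- p0 * (1 - p0) * (1 - (1 - 1 / (4 * nes))^6) # full equalization
    se <- stats::sd(v) / sqrt(length(v))
    expect_gt(mean(v) + 3 * se, lower)
    expect_lt(mean(v) - 3 * se, upper)
    expect_lt(abs(mean(res["bias", ])), 0.01)           # drift, not bias
})

test_that("infeasible grandparent avoidance fails with advice", {
    d <- small_design(avoidSharedGrandparents = TRUE,
                      foundersPerLine = 4, randomMales = 3,
                      randomFemales = 6, damsPerLine = 3,
                      siresPerLine = 1, selectedFemalesPerLine = 4,
                      selectedMalesPerLine = 2)
    expect_error(simulateBreeding(d, seed = 2), "census")
})
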