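test_that("minimal pedigree loads, sorts and validates", {
    path <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("id,sire,dam,sex,generation",
                 "kid,pa,ma,female,1",
                 "pa,0,0,male,0",
                 "ma,0,0,female,0"), path)
    ped <- readPedigree(path)
    expect_s4_class(ped, "Pedigree")
    expect_identical(nrow(pedTable(ped)), 3L)
    expect_identical(pedId(ped)[3], "kid")  # offspring last

    rt <- withr::local_tempfile(fileext = ".csv")
    writePedigree(ped, rt)
    expect_identical(pedTable(readPedigree(rt)), pedTable(ped))
})

test_that("structural errors are detected and named", {
    expect_error(
        Pedigree(data.frame(id = c("A", "B"), sire = c("B", "A"),
                            dam = c(NA, NA))),
        "cycle")
    expect_error(
        Pedigree(data.frame(id = c("A", "A"), sire = NA, dam = NA)),
        "duplicate")
    expect_error(
        Pedigree(data.frame(id = "A", sire = "ghost", dam = NA)),
        "ghost")
    expect_error(
        Pedigree(data.frame(id = c("p", "k"), sire = c(NA, "p"),
                            dam = c(NA, NA), sex = c("female", NA))),
        "sire")
    expect_error(
        Pedigree(data.frame(id = c("p", "k"), sire = c(NA, "p"),
                            dam = NA, generation = c(3, 1))),
        "generation")
})

test_that("topological sort matches an independent sorting oracle", {
    skip_if_not_installed("igraph")
    set.seed(11)
    for (rep in 1:10) {
        df <- random_pedigree(10)
        shuffled <- df[sample(nrow(df)), ]
        ped <- Pedigree(shuffled)
        out <- pedTable(ped)
        # every ordering accepted by igraph's topological sort must put
        # parents first; check ours satisfies the same partial order
        edges <- stats::na.omit(data.frame(
            from = c(df$sire, df$dam), to = c(df$id, df$id)))
        g <- igraph::graph_from_data_frame(edges, vertices = df$id)
        expect_true(igraph::is_dag(g))
        pos <- match(out$id, out$id)
        names(pos) <- out$id
        expect_true(all(pos[edges$from] < pos[edges$to]))
        expect_setequal(out$id, df$id)
    }
})

test_that("Meuwissen-Luo equals the tabular oracle and known identities", {
    # offspring of unrelated founders and a full-sib mating
    ped <- Pedigree(data.frame(
        id = c("a", "b", "s", "d", "x"),
        sire = c(NA, NA, "a", "a", "s"),
        dam = c(NA, NA, "b", "b", "d")))
    f <- pedInbreeding(ped)
    expect_identical(unname(f[c("s", "d")]), c(0, 0))
    expect_identical(unname(f[["x"]]), 0.25)

    set.seed(21)
    for (rep in 1:30) {
        df <- random_pedigree(12)
        ped <- Pedigree(df)
        f <- pedInbreeding(ped)
        expect_lt(max(abs(f[df$id] - oracle_ped_f(pedTable(ped))[df$id])),
                  1e-12)
        expect_true(all(f >= 0 & f <= 1))
        # invariance to on-disk record order
        f2 <- pedInbreeding(Pedigree(df[sample(nrow(df)), ]))
        expect_equal(f2[names(f)], f, tolerance = 1e-15)
    }
})

test_that("classic parent-referenced Delta F follows its definition", {
    ped <- Pedigree(data.frame(
        id = c("s", "d", "k"), sire = c(NA, NA, "s"),
        dam = c(NA, NA, "d")))
    f <- c(s = 0.2, d = 0.2, k = 0.1)
    expect_equal(unname(deltaFPedT(ped, f)[["k"]]), -0.125)
    f2 <- c(s = 0, d = 0, k = 0.25)
    expect_equal(unname(deltaFPedT(ped, f2)[["k"]]), 0.25)
    f3 <- c(s = 0.3, d = 0.1, k = 0.2)  # equals parents' mean
    expect_equal(unname(deltaFPedT(ped, f3)[["k"]]), 0)
    expect_true(all(is.na(deltaFPedT(ped, f)[c("s", "d")])))

    # one unknown parent: missing by default, F = 0 when opted in
    ped1 <- Pedigree(data.frame(id = c("s", "k"), sire = c(NA, "s"),
                                dam = c(NA, NA),
                                sex = c("male", NA)))
    fk <- c(s = 0.2, k = 0.1)
    expect_true(is.na(deltaFPedT(ped1, fk)[["k"]]))
    expect_equal(
        unname(deltaFPedT(ped1, fk, unknownParentZero = TRUE)[["k"]]),
        (0.1 - 0.1) / (1 - 0.1))
})

test_that("individual Delta F is the exact inverse of compounding", {
    ped <- Pedigree(data.frame(
        id = c("f1", "f2", "x"), sire = c(NA, NA, "f1"),
        dam = c(NA, NA, "f2"), generation = c(0, 0, 2)))
    f <- c(f1 = 0, f2 = 0, x = 0.75)
    expect_equal(unname(deltaFPedI(ped, f)[["x"]]), 0.5)  # (1-.75)^(1/2)
    expect_true(all(is.na(deltaFPedI(ped, f)[c("f1", "f2")])))
    expect_equal(unname(deltaFPedI(ped, c(f1 = 0, f2 = 0, x = 0))[["x"]]),
                 0)

    # roundtrip 1 - (1 - dF)^(t-1) recovers F on a grid
    for (t in 2:8) for (F in c(0.01, 0.1, 0.35, 0.6, 0.9)) {
        df <- 1 - (1 - F)^(1 / (t - 1))
        expect_lt(abs((1 - (1 - df)^(t - 1)) - F), 1e-12)
    }
})

test_that("Ne from rates and from the sex ratio behave as defined", {
    expect_equal(neFromRate(c(0.005, 0.005)), 100)
    expect_equal(neFromRate(-0.005), -100)
    expect_equal(neFromRate(c(0.0125, NA)), 40)
    expect_warning(expect_true(is.na(neFromRate(c(-1, 1) * 0.01))))

    expect_equal(neSexRatio(32, 64), 85.33, tolerance = 1e-4)
    expect_equal(neSexRatio(10, 10), 20)
    expect_equal(neSexRatio(1, 1000), 3.996, tolerance = 1e-4)
    expect_equal(neSexRatio(7, 3), neSexRatio(3, 7))
    expect_error(neSexRatio(0, 5), "positive")
})

test_that("founder-distance t inverts inbreeding accumulation", {
    expect_equal(estimateT(0.75, 0.5), 2)
    expect_equal(estimateT(1 - (1 - 0.01)^40, 0.01), 40)
    t <- estimateT(0.61, 1 / (2 * 85.33))
    expect_gt(t, 155); expect_lt(t, 165)
    expect_error(estimateT(1.2, 0.01))
    expect_error(estimateT(0.5, 0))
    expect_equal(founderDistance(0.75, ne = 1), 2)
})
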