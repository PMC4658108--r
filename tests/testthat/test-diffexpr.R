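test_that("normalization scales to reads per million", {
    expect_equal(normalize_expression(1e6, 1e6), 1e6)
    expect_equal(normalize_expression(0, 1000), 0)
    expect_equal(normalize_expression(50, 1e6), 50)
    expect_error(normalize_expression(5, 0), ">= 1")
    expect_error(normalize_expression(10, 5), "count")
})

test_that("zero substitution and exclusion rules fire in the right order", {
    p <- preprocess_pair(0, 120)
    expect_equal(p$ne1, 0.01)
    expect_equal(p$ne2, 120)
    expect_identical(p$status, "zero_substituted")

    expect_identical(preprocess_pair(0.3, 0.7)$status, "excluded_low_NE")
    expect_identical(preprocess_pair(1.0, 1.0)$status, "tested")  # strict "<"
    # mode either also drops one-sided low expression
    expect_identical(preprocess_pair(0.3, 50, mode = "either")$status,
                     "excluded_low_NE")
    expect_identical(preprocess_pair(0.3, 50, mode = "both")$status, "tested")
})

test_that("log2 fold change is the exact binary log of the ratio", {
    expect_equal(log2_fold_change(20, 20), 0)
    expect_equal(log2_fold_change(40, 10), 2)
    expect_equal(log2_fold_change(0.01, 10.24), -10)
    expect_error(log2_fold_change(0, 1), "positive")
})

test_that("the exact pmf matches the closed form and normalizes", {
    expect_equal(ac_pmf(0, 0, 1000, 1000), 0.5)

    # sums to one for x = 3, N2/N1 = 2 (numeric summation oracle)
    expect_equal(sum(ac_pmf(0:5000, 3, 1000, 2000)), 1, tolerance = 1e-12)

    # equality with the independent negative-binomial closed form
    set.seed(8)
    for (i in 1:100) {
        x <- sample(0:50, 1)
        N1 <- sample(1e3:1e6, 1); N2 <- sample(1e3:1e6, 1)
        y <- sample(0:100, 1)
        expect_equal(ac_pmf(y, x, N1, N2),
                     dnbinom(y, size = x + 1, prob = N1 / (N1 + N2)),
                     tolerance = 1e-12)
    }

    expect_error(ac_pmf(-1, 0, 10, 10), "non-negative")
    expect_error(ac_pmf(0.5, 0, 10, 10), "non-negative")
    expect_error(ac_pmf(0, 0, 0, 10), ">= 1")
})

test_that("pmf normalization holds across the ratio grid", {
    for (x in c(0:10, 15, 20)) {
        for (r in c(0.1, 0.5, 1, 2, 10)) {
            N1 <- 1e5; N2 <- r * 1e5
            ymax <- qnbinom(1e-14, size = x + 1, prob = N1 / (N1 + N2),
                            lower.tail = FALSE) + 10
            expect_equal(sum(ac_pmf(0:ymax, x, N1, N2)), 1,
                         tolerance = 1e-9)
        }
    }
})

test_that("the cumulative tails obey their identities", {
    t0 <- ac_tails(0, 0, 5e5, 5e5)
    expect_equal(t0$C, 0.5)
    expect_equal(t0$D, 1)

    set.seed(14)
    for (i in 1:20) {
        x <- sample(0:40, 1); y <- sample(0:40, 1)
        N1 <- sample(1e4:1e6, 1); N2 <- sample(1e4:1e6, 1)
        t <- ac_tails(x, y, N1, N2)
        # C + D = 1 + pmf(y_obs)
        expect_equal(t$C + t$D, 1 + ac_pmf(y, x, N1, N2), tolerance = 1e-12)
        # swapping (x, N1) with (y, N2) exchanges the tails up to the overlap
        ts <- ac_tails(y, x, N2, N1)
        expect_lt(abs(ts$C - (t$D - ac_pmf(y, x, N1, N2))), 1e-9)
        expect_true(t$p_two_sided >= 0 && t$p_two_sided <= 1)
    }

    # D decreases monotonically in the observed count
    D <- vapply(0:30, function(y) ac_tails(5, y, 2e5, 3e5)$D, numeric(1))
    expect_true(all(diff(D) < 0))

    # independent oracle for the upper tail
    expect_equal(ac_tails(5, 12, 2e5, 3e5)$D,
                 pnbinom(11, size = 6, prob = 2e5 / 5e5,
                         lower.tail = FALSE),
                 tolerance = 1e-12)
})

test_that("identical libraries yield no significant calls", {
    counts <- matrix(rep(c(50, 400, 3), 2), ncol = 2,
                     dimnames = list(c("m1", "m2", "m3"), c("a", "b")))
    em <- build_expression_matrix(counts, totals = c(a = 1e5, b = 1e5))
    de <- call_differential(em, data.frame(sample = c("a", "b"),
                                           group = c("young", "adult")),
                            contrast = c("young", "adult"))
    expect_identical(sum(de$pairwise$significant), 0L)
    expect_identical(sum(de$consensus$consensus), 0L)
})

test_that("differential calls validate the grouping and record rule firing", {
    counts <- matrix(c(10, 0, 20, 30), 2, 2,
                     dimnames = list(c("m1", "m2"), c("a", "b")))
    em <- build_expression_matrix(counts, totals = c(a = 1e5, b = 1e5))
    expect_error(call_differential(em, data.frame(sample = c("a", "zzz"),
                                                  group = c("g1", "g2"))),
                 "unknown sample")
    de <- call_differential(em, data.frame(sample = c("a", "b"),
                                           group = c("g1", "g2")),
                            contrast = c("g1", "g2"))
    m2 <- de$pairwise[de$pairwise$mirna == "m2", ]
    expect_identical(m2$status, "zero_substituted")
    expect_equal(m2$NE1, 0.01)
    m1 <- de$pairwise[de$pairwise$mirna == "m1", ]
    expect_identical(m1$status, "tested")
})

test_that("a planted eight-fold miRNA is called consensus-up in all pairs", {
    t0 <- build_truth(seed = 37)
    low <- names(sort(t0$base_prop))[2]
    truth <- build_truth(seed = 37, fold_change = setNames(8, low))
    sc <- simulate_counts(truth,
                          samples = data.frame(
                              sample = c("M05", "F06", "M12", "F18"),
                              group = c("young", "young", "adult", "adult"),
                              depth = rep(100000L, 4)),
                          seed = 38)
    em <- build_expression_matrix(sc$counts, totals = sc$totals)
    de <- call_differential(em,
                            data.frame(sample = colnames(sc$counts),
                                       group = c("young", "young",
                                                 "adult", "adult")),
                            contrast = c("young", "adult"))
    cons <- de$consensus
    expect_true(cons$consensus[cons$mirna == low])
    expect_identical(cons$direction[cons$mirna == low], "up")
    expect_identical(cons$n_pairs[cons$mirna == low], 4L)
    # null precursors stay quiet
    expect_lte(sum(cons$consensus), 1L)
})

test_that("the exact test holds its size under a Poisson null", {
    set.seed(55)
    n <- 400L
    x <- rpois(n, 100); y <- rpois(n, 100)
    counts <- cbind(a = x, b = y)
    rownames(counts) <- sprintf("m%03d", seq_len(n))
    em <- build_expression_matrix(counts, totals = c(a = 2e5, b = 2e5))
    de <- call_differential(em, data.frame(sample = c("a", "b"),
                                           group = c("g1", "g2")),
                            contrast = c("g1", "g2"))
    reject <- de$pairwise$p_two_sided < 0.01
    expect_lte(mean(reject, na.rm = TRUE), 0.02)
})
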