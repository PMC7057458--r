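test_that("metric arithmetic matches the defining formulas exactly", {
    m <- metricsFromCounts(tp = 478, tp0 = 168, noCalls = 1468,
                           benchmarkN = 238)
    expect_equal(unname(m["precision"]), 478 / 1468)
    expect_equal(unname(m["recall"]), 168 / 238)
    # fold-count mode: recall from TP/(TP+FN)
    m2 <- metricsFromCounts(tp = 111, fp = 19, fn = 51)
    expect_equal(unname(m2["precision"]), 111 / 130)
    expect_equal(unname(m2["recall"]), 111 / 162)
    expect_equal(unname(m2["f1"]),
                 2 * (111 / 130) * (111 / 162) / (111 / 130 + 111 / 162))
    # degenerate zeros
    expect_warning(z <- metricsFromCounts(tp = 0, fp = 0, fn = 5))
    expect_equal(unname(z), c(0, 0, 0))
})

test_that("half-up percent reporting differs from banker's rounding where it matters", {
    expect_equal(roundHalfUp(70.585, 2), 70.59)
    expect_equal(roundHalfUp(0.125, 2), 0.13)   # base round() gives 0.12
    expect_equal(percentValue(168 / 238), 70.59)
})

test_that("breakpoint matching honors the k x ISPE thresholds", {
    st <- statsFixture(mean = 400)
    bench <- grFixture("11", c(10001L, 30001L), c(15000L, 34000L))
    # perfect calls
    ev <- matchCalls(bench, bench, st, k = 1)
    expect_equal(c(ev@tp, ev@tp0, ev@fp, ev@fn), c(2L, 2L, 0L, 0L))
    expect_equal(c(ev@precision, ev@recall, ev@f1), c(1, 1, 1))
    # one breakpoint off by 2.5 x ISPE: only k = 3 matches
    off <- grFixture("11", 10001L + 1000L, 15000L)
    expect_equal(matchCalls(off, bench, st, k = 1)@tp, 0L)
    expect_equal(matchCalls(off, bench, st, k = 2)@tp, 0L)
    expect_equal(matchCalls(off, bench, st, k = 3)@tp, 1L)
    # two calls on one benchmark entry: tp counts both, tp0 once
    dup <- c(bench[1], GenomicRanges::shift(bench[1], 50L))
    ev2 <- matchCalls(dup, bench, st, k = 1)
    expect_equal(ev2@tp, 2L)
    expect_equal(ev2@tp0, 1L)
    expect_equal(ev2@fn, 1L)              # second benchmark entry missed
    # chromosome namespaces are respected
    other <- grFixture("12", 10001L, 15000L)
    expect_equal(matchCalls(other, bench, st, k = 3)@tp, 0L)
    expect_warning(matchCalls(bench, bench, st, k = 5), "conventional")
})

test_that("confusion identities hold on randomized call/benchmark sets", {
    st <- statsFixture(mean = 400)
    set.seed(17)
    for (i in 1:20) {
        nb <- sample(2:6, 1)
        bs <- sort(sample(seq(1000L, 200000L, by = 4000L), nb))
        bench <- grFixture("11", bs, bs + sample(500:3000, nb,
                                                 replace = TRUE))
        nc <- sample(0:8, 1)
        if (nc == 0L) {
            calls <- bench[0]
        } else {
            cs <- sample(seq(1000L, 200000L, by = 1000L), nc)
            calls <- grFixture("11", cs, cs + sample(500:3000, nc,
                                                     replace = TRUE))
        }
        ev <- suppressWarnings(matchCalls(calls, bench, st, k = 3))
        expect_equal(ev@fp, ev@noCalls - ev@tp)
        expect_equal(ev@fn, ev@benchmarkN - ev@tp0)
        expect_lte(ev@tp0, min(ev@tp, ev@benchmarkN))
        expect_true(all(c(ev@precision, ev@recall, ev@f1) >= 0))
        expect_true(all(c(ev@precision, ev@recall, ev@f1) <= 1))
        # permutation invariance of both lists
        if (nc > 1L) {
            ev2 <- suppressWarnings(matchCalls(
                calls[sample.int(nc)], bench[sample.int(nb)], st, k = 3))
            expect_equal(c(ev2@tp, ev2@tp0), c(ev@tp, ev@tp0))
        }
    }
})

test_that("repeated cross-validation is exact on separable data and deterministic", {
    set.seed(23)
    X <- matrix(abs(rnorm(60 * 15)), ncol = 15,
                dimnames = list(NULL, paste0("f", 1:15)))
    y <- rep(c(0L, 1L), 30)
    X[y == 1L, ] <- X[y == 1L, ] + 10
    cv <- crossValidate(X, y, selectedIds = 1:15, nRepeats = 5L,
                        seed = 7L)
    expect_equal(cv@fp, 0)
    expect_equal(cv@fn, 0)
    expect_equal(cv@precision, 1)
    expect_equal(cv@recall, 1)
    # partition conservation: per-repeat TP + FN equals the positives
    expect_true(all(cv@perRepeat$tp + cv@perRepeat$fn == sum(y == 1L)))
    expect_true(all(cv@perRepeat$tn + cv@perRepeat$fp == sum(y == 0L)))
    # determinism under the seed
    cv2 <- crossValidate(X, y, selectedIds = 1:15, nRepeats = 5L,
                         seed = 7L)
    expect_equal(cv2@perRepeat, cv@perRepeat)
    # a score mask restricts counting but not training
    mask <- rep(c(TRUE, FALSE), 30)
    cvM <- crossValidate(X, y, selectedIds = 1:15, nRepeats = 2L,
                         seed = 7L, scoreMask = mask)
    expect_equal(cvM@perRepeat$tp + cvM@perRepeat$tn +
                 cvM@perRepeat$fp + cvM@perRepeat$fn,
                 rep(sum(mask), 2L))
})
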