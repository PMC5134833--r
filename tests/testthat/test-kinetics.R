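test_that("rate laws reproduce their closed-form special cases", {
    expect_identical(ic50Fraction(0, 150), 1)
    expect_identical(ic50Fraction(150, 150), 0.5)
    expect_identical(ic50Fraction(450, 150), 0.25)
    expect_error(ic50Fraction(10, -1), "positive")

    # Michaelis-Menten limit at I = 0
    expect_equal(noncompetitiveRate(80, 0, 10, 50, 200, 400),
                 10 * 80 / (80 + 50), tolerance = 1e-12)
    # S = Km, I = Ki = Kii collapses to Vmax/4
    expect_equal(noncompetitiveRate(50, 300, 10, 50, 300, 300), 10 / 4,
                 tolerance = 1e-12)
    # saturating substrate: v -> Vmax/(1 + I/Kii)
    expect_equal(noncompetitiveRate(1e6 * 50, 200, 10, 50, 300, 400),
                 10 / (1 + 200 / 400), tolerance = 1e-4)

    expect_identical(yonetaniTheorellRate(0, 0, 5, 150, 30), 5)
    expect_error(yonetaniTheorellRate(1, 1, 5, 150, 30, beta = -1),
                 "beta")
})

test_that("monotonicity: inhibition decreases velocity, substrate
           increases it", {
    I <- seq(0, 1000, by = 50)
    expect_true(all(diff(ic50Fraction(I, 150)) < 0))
    expect_true(all(diff(noncompetitiveRate(100, I, 10, 50, 200, 400))
                    < 0))
    S <- seq(1, 500, by = 20)
    expect_true(all(diff(noncompetitiveRate(S, 100, 10, 50, 200, 400))
                    > 0))
})

test_that("pure noncompetitive inhibition has an S-independent apparent
           IC50", {
    # Ki = Kii: vi/v0 = 1/(1 + I/Ki) at every substrate concentration
    for (S in c(10, 50, 250)) {
        v0 <- noncompetitiveRate(S, 0, 10, 50, 300, 300)
        vi <- noncompetitiveRate(S, 300, 10, 50, 300, 300)
        expect_equal(vi / v0, 0.5, tolerance = 1e-12)
    }
})

test_that("reciprocal velocity is exactly linear in I at fixed J", {
    I <- seq(0, 400, by = 40)
    for (J in c(0, 20, 60)) {
        y <- 1 / yonetaniTheorellRate(I, J, 5, 150, 30, beta = 0.7)
        res <- residuals(lm(y ~ I))
        expect_lt(max(abs(res)), 1e-10)
    }
})

test_that("Yonetani-Theorell line geometry diagnoses the binding mode", {
    exc <- new("CrossCompetitionFit", v0 = 5, ki = 150, kj = 30,
               beta = 0, exclusivity = "mutually exclusive", r2 = 1,
               aiccFree = 0, aiccExclusive = 0)
    ln <- yonetaniPlotData(exc, J = c(0, 10, 30, 90))
    expect_lt(diff(range(ln$slope)), 1e-12)   # parallel lines
    expect_true(all(diff(ln$intercept) > 0))

    ind <- new("CrossCompetitionFit", v0 = 5, ki = 150, kj = 30,
               beta = 1, exclusivity = "distinct sites", r2 = 1,
               aiccFree = 0, aiccExclusive = 0)
    li <- yonetaniPlotData(ind, J = c(0, 30))
    # alpha = 1: lines intersect at I = -Ki
    icross <- -diff(li$intercept) / diff(li$slope)
    expect_equal(icross, -150, tolerance = 1e-9)
    # slopes grow linearly with J
    l3 <- yonetaniPlotData(ind, J = c(0, 30, 60))
    expect_equal(diff(l3$slope)[1], diff(l3$slope)[2], tolerance = 1e-12)
    expect_identical(nrow(yonetaniPlotData(ind)), 0L)
})

test_that("noiseless generate-then-fit recovers parameters exactly", {
    d <- generateVelocityData("ic50", list(ic50 = 150, v0 = 2),
                              list(I = c(0, 25, 75, 150, 300, 600,
                                         1200)),
                              relativeSd = 0, seed = 1)
    f <- fitIC50(d)
    expect_equal(f@ic50, 150, tolerance = 1e-6)
    expect_equal(f@v0, 2, tolerance = 1e-6)
    expect_equal(f@r2, 1, tolerance = 1e-9)

    d2 <- generateVelocityData("noncompetitive",
                               list(vmax = 10, km = 50, ki = 200,
                                    kii = 400),
                               list(S = c(10, 25, 50, 100, 200, 400),
                                    I = c(0, 50, 150, 450)),
                               relativeSd = 0, seed = 1)
    f2 <- fitNoncompetitive(d2)
    expect_equal(f2@vmax, 10, tolerance = 1e-6)
    expect_equal(f2@km, 50, tolerance = 1e-6)
    expect_equal(f2@ki, 200, tolerance = 1e-6)
    expect_equal(f2@kii, 400, tolerance = 1e-6)
    expect_equal(f2@r2, 1, tolerance = 1e-9)
})

test_that("fitters reject degenerate designs", {
    expect_error(fitIC50(data.frame(I = c(0, 10, 20), v = c(3, 2, 1))),
                 "4 distinct")
    expect_error(fitIC50(data.frame(I = c(0, 10, 100, 1000),
                                    v = rep(2, 4))),
                 "identical")
    expect_error(
        fitNoncompetitive(data.frame(S = 50, I = c(0, 10, 100),
                                     v = c(3, 2, 1))),
        "non-identifiable")
    expect_error(
        fitCrossCompetition(data.frame(I = c(0, 10, 100), J = 0,
                                       v = c(3, 2, 1))),
        "unidentifiable")
})

test_that("competitive data yield Kii far above Ki in the global fit", {
    # competitive limit: inhibitor only binds free enzyme (Kii -> Inf);
    # simulate with a very large Kii and check the fit separates them
    d <- generateVelocityData("noncompetitive",
                              list(vmax = 10, km = 50, ki = 100,
                                   kii = 1e7),
                              list(S = c(10, 25, 50, 100, 200, 400),
                                   I = c(0, 30, 100, 300),
                                   replicates = 2),
                              relativeSd = 0.02, seed = 42)
    f <- fitNoncompetitive(d)
    expect_lt(abs(f@ki - 100) / 100, 0.15)
    expect_gt(f@kii, 10 * f@ki)
})

test_that("exclusivity calls separate alpha = Inf from alpha = 1", {
    design <- list(I = c(0, 50, 150, 450, 1350), J = c(0, 10, 30, 90),
                   replicates = 2)
    dx <- generateVelocityData("cross",
                               list(v0 = 5, ki = 150, kj = 30, beta = 0),
                               design, relativeSd = 0.02, seed = 7)
    fx <- fitCrossCompetition(dx)
    expect_identical(fx@exclusivity, "mutually exclusive")
    expect_identical(fx@beta, 0)

    di <- generateVelocityData("cross",
                               list(v0 = 5, ki = 150, kj = 30, beta = 1),
                               design, relativeSd = 0.02, seed = 8)
    fi <- fitCrossCompetition(di)
    expect_identical(fi@exclusivity, "distinct sites")
    expect_gt(fi@beta, 0.5)
})
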