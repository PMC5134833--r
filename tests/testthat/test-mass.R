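test_that("residue mass table matches the elemental-composition oracle", {
    tab <- residueMassTable()
    for (aa in names(oracle_residue_mass))
        expect_equal(tab[[aa]], oracle_residue_mass[[aa]],
                     tolerance = 0.01 / oracle_residue_mass[[aa]])
    expect_equal(attr(tab, "water"), 2 * 1.008 + 15.999, tolerance = 1e-4)
})

test_that("averageMass is residue sum plus one water", {
    expect_equal(averageMass("G"), 75.07, tolerance = 1e-4)
    expect_equal(averageMass("GG") - averageMass("G"),
                 residueMassTable()[["G"]], tolerance = 1e-9)
    # oracle uses the revised atomic weights; conventions differ by
    # ~0.002 Da per residue, so compare at that accumulated scale
    expect_equal(averageMass("DYKDDDDK"),
                 oracle_peptide_mass("DYKDDDDK"), tolerance = 3e-5)
    expect_error(averageMass(""), "empty")
    expect_error(averageMass("AXA"), "unknown residue")
})

test_that("AICD fragment masses are additive residue by residue", {
    wt <- wt_substrate()
    for (s in 44:54) {
        d <- predictAicdMass(s)@avgMass - predictAicdMass(s + 1)@avgMass
        expect_equal(d, residueMassTable()[[residueAt(wt, s)]],
                     tolerance = 0.01 / d)
    }
    # one leucine separates the two wild-type epsilon products
    expect_equal(predictAicdMass(49)@avgMass - predictAicdMass(50)@avgMass,
                 113.16, tolerance = 0.05 / 113.16)
})

test_that("a single substitution shifts the mass by the residue
           difference", {
    tab <- residueMassTable()
    dVF <- predictAicdMass(48, "V50F")@avgMass -
        predictAicdMass(48)@avgMass
    expect_equal(dVF, tab[["F"]] - tab[["V"]], tolerance = 1e-9)
    expect_equal(dVF, 48.05, tolerance = 0.05 / 48.05)
})

test_that("mutations outside the fragment are ignored with a note", {
    ref <- predictAicdMass(51, "M51F")@avgMass
    expect_message(both <- predictAicdMass(51, "V50F,M51F"),
                   "N-terminal of the fragment")
    expect_equal(both@avgMass, ref, tolerance = 1e-9)
    expect_message(ab <- predictAbetaMass(38, "V40F"),
                   "C-terminal of the fragment")
    expect_equal(ab@avgMass, predictAbetaMass(38)@avgMass,
                 tolerance = 1e-9)
    expect_error(predictAicdMass(40), "44..55")
    expect_error(predictAbetaMass(50), "37..49")
})

test_that("Abeta species masses obey the additivity oracle", {
    tab <- residueMassTable()
    d4240 <- predictAbetaMass(42)@avgMass - predictAbetaMass(40)@avgMass
    expect_equal(d4240, tab[["I"]] + tab[["A"]], tolerance = 1e-9)
    expect_equal(d4240, 184.24, tolerance = 0.05 / 184.24)
    d4238 <- predictAbetaMass(42)@avgMass - predictAbetaMass(38)@avgMass
    expect_equal(d4238, sum(tab[c("V", "V", "I", "A")]), tolerance = 1e-9)
})

test_that("peak matching is greedy, one-to-one and tolerance-bounded", {
    wt5099 <- predictAicdMass(50)
    m <- matchPeaks(list(wt5099), 6907.4)
    expect_identical(m$species, "AICD 50-99")
    expect_equal(m$delta, 1.8, tolerance = 0.3 / 1.8)

    # the unexplained 7030.4 peak of the double mutant stays unassigned
    dbl <- list(predictAicdMass(51, "M51F"),
                suppressMessages(predictAicdMass(48, "V50F,M51F")),
                suppressMessages(predictAicdMass(47, "V50F,M51F")),
                suppressMessages(predictAicdMass(46, "V50F,M51F")))
    obs <- c(6817.1, 7030.4, 7179.2, 7292.5, 7396.1)
    m2 <- matchPeaks(dbl, obs)
    expect_true(is.na(m2$species[m2$observed == 7030.4]))
    expect_identical(sum(!is.na(m2$species)), 4L)
    expect_false(anyDuplicated(stats::na.omit(m2$species)) > 0)

    expect_identical(nrow(matchPeaks(dbl, numeric(0))), 0L)
    expect_error(matchPeaks(dbl, obs, tolerance = 0), "tolerance")
})
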