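test_that("S2' blocking follows the P2' residue", {
    wt <- wt_substrate()
    expect_false(isBlocked(wt, 48))
    expect_true(isBlocked(applyMutations(wt, "V50F"), 48))
    # with both epsilon P2' residues aromatic, the next site up is free
    expect_false(isBlocked(applyMutations(wt, "V50F,M51F"), 47))
    expect_error(isBlocked(wt, 98), "P2'")
})

test_that("site scores encode hard S2' exclusion, S1'/S3' preference and
           no S4' contribution", {
    wt <- wt_substrate()
    p <- default_params()
    expect_identical(siteScore(applyMutations(wt, "V50F"), 48), 0)
    # aromatic P3' raises the score (favourable P3'-S3' interaction)
    expect_gt(siteScore(applyMutations(wt, "I45F"), 42), siteScore(wt, 42))
    # P4' is irrelevant: A42F leaves the Gly-Gly site score unchanged
    expect_identical(siteScore(applyMutations(wt, "A42F"), 38),
                     siteScore(wt, 38))
    # a configurable residual weight softens the exclusion
    soft <- new("PocketProfile", blockedWeight = 0.1)
    expect_gt(siteScore(applyMutations(wt, "V50F"), 48, soft), 0)
})

test_that("epsilon-site selection matches the observed usage pattern", {
    wt <- wt_substrate()
    w <- selectEpsilon(wt)
    expect_gt(w[["49"]], w[["48"]])
    expect_gt(w[["48"]], w[["47"]])
    expect_gt(w[["49"]] + w[["48"]], 0.9)

    wV50F <- selectEpsilon(applyMutations(wt, "V50F"))
    expect_false("48" %in% names(wV50F))
    expect_true(all(c("49", "47") %in% names(wV50F)))

    # the double mutant skips both phenylalanines: 47 dominant, 50 minor
    wdbl <- selectEpsilon(applyMutations(wt, "V50F,M51F"))
    expect_identical(names(which.max(wdbl)), "47")
    expect_gt(wdbl[["50"]], 0.03)
    expect_error(
        selectEpsilon(applyMutations(wt,
                                     "T48F,L49F,V50F,M51F,L52F")),
        "no epsilon site")
})

test_that("trimming prefers the in-register tripeptide site and scans
           past blocked ones", {
    wt <- wt_substrate()
    s49 <- trimStep(wt, 49)
    expect_identical(names(which.max(s49)), "46")
    expect_gt(s49[["46"]], 0.98)
    s46 <- trimStep(wt, 46)
    expect_identical(names(which.max(s46)), "43")
    expect_identical(releasedFragment(wt, 46, 43), "VIV")
    # blocked Gly-Gly site: V40F is the P2' of the bond after G38
    s42 <- trimStep(applyMutations(wt, "V40F"), 42)
    expect_false("38" %in% names(s42))
    # unblocked, the labile Gly-Gly site out-competes the register from 42
    expect_gt(trimStep(wt, 42)[["38"]], 0.5)
    expect_error(trimStep(wt, 3), "minRelease")
})

test_that("wild-type products concentrate on the two major pathways", {
    dist <- simulate_mutant("")
    ab <- abetaWeights(dist)
    expect_gt(ab[["40"]], ab[["42"]])
    expect_gt(ab[["42"]], ab[["38"]])
    expect_gt(ab[["38"]], ab[["43"]])
    tr <- enumerateTrajectories(wt_substrate())
    lbl <- vapply(tr, function(t) paste(t$sites, collapse = "-"), "")
    w <- vapply(tr, `[[`, 0, "weight")
    major <- sum(w[lbl %in% c("49-46-43-40", "48-45-42")])
    expect_gt(major, 0.90)
})

test_that("trajectories conserve sequence, never release dipeptides, and
           never place an aromatic in S2'", {
    wt <- wt_substrate()
    full <- paste0(paste(residueAt(wt), collapse = ""), "DYKDDDDK")
    for (muts in c("", "V50F", "M51F", "V50F,M51F", "I45F",
                   "V44F,I45F")) {
        sub <- if (nzchar(muts)) applyMutations(wt, muts) else wt
        fullm <- paste0(paste(residueAt(sub), collapse = ""), sub@tag)
        tr <- enumerateTrajectories(sub, prune = 1e-7)
        expect_equal(sum(vapply(tr, `[[`, 0, "weight")), 1,
                     tolerance = 1e-5)
        for (t in tr) {
            # conservation: fragments concatenate to the full substrate
            expect_identical(paste(rev(t$released), collapse = ""),
                             fullm)
            # never a released fragment shorter than three residues
            expect_true(all(nchar(t$released) >= 3))
            # monotone processivity: sites strictly decrease
            expect_true(all(diff(t$sites) < 0))
            # exclusion: no event has an aromatic P2'
            p2 <- residueAt(sub, t$sites + 2L)
            expect_false(any(p2 %in% c("F", "Y", "W")))
        }
    }
})

test_that("sampled mode is seeded, reproducible and converges to the
           exhaustive distribution", {
    wt <- wt_substrate()
    ex <- simulateCleavage(wt)
    s1 <- simulateCleavage(wt, mode = "sampled", nsample = 2e4, seed = 11)
    s2 <- simulateCleavage(wt, mode = "sampled", nsample = 2e4, seed = 11)
    expect_identical(abetaWeights(s1), abetaWeights(s2))
    expect_lt(total_variation(abetaWeights(ex), abetaWeights(s1)), 0.02)
    expect_lt(total_variation(aicdWeights(ex), aicdWeights(s1)), 0.02)
})

test_that("pathway-blocking mutants shift products as observed", {
    # A42F is the P2' residue of the Abeta40-producing site: no Abeta40
    a42f <- simulate_mutant("A42F")
    expect_false("40" %in% names(abetaWeights(a42f)))
    expect_warning(ratio42_40(a42f), "undefined")
    # V40F eliminates Abeta38 (P2' of the Gly-Gly site)
    v40f <- simulate_mutant("V40F")
    expect_false("38" %in% names(abetaWeights(v40f)))
    # blocking both Abeta38 precursors still floods Abeta38
    dbl <- simulate_mutant("V44F,I45F")
    expect_gt(abetaWeights(dbl)[["38"]], 0.5)
})

test_that("ratio directions and FAD classification follow the pocket
           rules", {
    expect_identical(as.character(predictRatioDirection("V50F")), "down")
    expect_identical(as.character(predictRatioDirection("M51F")), "up")
    expect_identical(as.character(predictRatioDirection("I45F,T48F,M51F")),
                     "up")
    # a hard block of the Abeta40-producing site leaves the ratio
    # undefined, reported as up with a note
    upA42F <- predictRatioDirection("A42F")
    expect_identical(as.character(upA42F), "up")
    expect_match(attr(upA42F, "note"), "Abeta40 eliminated")
    expect_identical(as.character(classifyFadMechanism("I45F")),
                     "uncoupled")
    expect_identical(as.character(classifyFadMechanism("V46F")),
                     "rescued_by_V50F")
    expect_identical(as.character(classifyFadMechanism("T43I")),
                     "rescued_by_V50F")
    expect_error(classifyFadMechanism("V50F"), "position 50")
})

test_that("a non-APP substrate with native phenylalanines is cleaved
           without aromatic S2' occupancy", {
    nt <- notchLikeTMD()
    tr <- enumerateTrajectories(nt$substrate, eps = nt$epsilon,
                                prune = 1e-6)
    expect_gt(length(tr), 0)
    for (t in tr) {
        p2 <- residueAt(nt$substrate, t$sites + 2L)
        expect_false(any(p2 %in% c("F", "Y", "W")))
    }
})
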