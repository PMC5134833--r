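# Core mechanism: weighted epsilon-site selection followed by processive
# carboxy-terminal trimming, both constrained by the three S' pockets.
# All weights are relative; the simulator is flux-conserving, so every unit
# of epsilon flux ends in exactly one released Abeta species.

aromatic <- function(res) res %in% c("F", "Y", "W")

release_prob <- function(trim, cterm) {
    key <- as.character(cterm)
    if (key %in% names(trim@releaseProb)) trim@releaseProb[[key]]
    else trim@defaultRelease
}

#' Is a cleavage site blocked by the S2' pocket?
#'
#' A site is blocked when its P2' residue (position + 2) belongs to the
#' excluded aromatic set of the small S2' pocket.
#'
#' @param seq a [SubstrateSequence-class].
#' @param position P1 position; its P2' residue must exist.
#' @param profile a [PocketProfile-class].
#' @return logical.
#' @examples
#' wt <- loadSubstrate("APP_C99_WT")
#' isBlocked(wt, 48)                             # FALSE: P2' = V50
#' isBlocked(applyMutations(wt, "V50F"), 48)     # TRUE
#' @export
isBlocked <- function(seq, position, profile = new("PocketProfile")) {
    n <- substrateLength(seq)
    if (position < 1L || position + 2L > n)
        stop("position ", position, " has no defined P2' residue")
    seq@residues[position + 2L] %in% profile@s2Excluded
}

#' Pocket-adjusted score of a cleavage site
#'
#' The score is the product of: the S2' factor (\code{blockedWeight}, 0 by
#' default, when the P2' residue is aromatic; 1 otherwise), a
#' \code{bulkyBonus} factor per aromatic residue at P1' or P3' (the large
#' S1'/S3' pockets prefer phenylalanine), and the Gly-Gly lability bonus
#' when the site is position 38 with glycines at 37 and 38.  The P4'
#' residue never enters (no contributory S4' pocket).
#'
#' @inheritParams isBlocked
#' @param trim a [TrimPolicy-class] (supplies the Gly-Gly bonus).
#' @return nonnegative numeric score.
#' @export
siteScore <- function(seq, position, profile = new("PocketProfile"),
                      trim = new("TrimPolicy")) {
    n <- substrateLength(seq)
    if (position < 1L || position + 2L > n)
        stop("position ", position, " has no defined P2' residue")
    s <- if (isBlocked(seq, position, profile)) profile@blockedWeight else 1
    if (s == 0) return(0)
    if (aromatic(seq@residues[position + 1L])) s <- s * profile@bulkyBonus
    if (position + 3L <= n && aromatic(seq@residues[position + 3L]))
        s <- s * profile@bulkyBonus
    if (position == 38L && n >= 38L &&
        identical(seq@residues[37L], "G") &&
        identical(seq@residues[38L], "G"))
        s <- s * trim@ggBonus
    s
}

#' Normalized epsilon-site usage
#'
#' Multiplies the base epsilon weights by the pocket-adjusted site score
#' and renormalizes over unblocked candidates, so flux lost to a blocked
#' site redistributes to the remaining ones (overall substrate turnover is
#' treated as conserved).
#'
#' @param seq a [SubstrateSequence-class].
#' @param eps an [EpsilonProfile-class].
#' @param profile a [PocketProfile-class].
#' @param trim a [TrimPolicy-class].
#' @return named numeric of normalized weights over P1 positions (zero
#'   weights dropped).
#' @examples
#' selectEpsilon(loadSubstrate("APP_C99_WT"))  # 49 > 48 >> 47
#' @export
selectEpsilon <- function(seq, eps = new("EpsilonProfile"),
                          profile = new("PocketProfile"),
                          trim = new("TrimPolicy")) {
    pos <- as.integer(names(eps@baseWeights))
    keep <- pos + 2L <= substrateLength(seq) & pos >= 1L
    pos <- pos[keep]
    w <- eps@baseWeights[keep] *
        vapply(pos, function(p) siteScore(seq, p, profile, trim), 0)
    w <- w[w > 0]
    if (length(w) == 0L)
        stop("no epsilon site: all candidates in the window are blocked")
    sort(w / sum(w), decreasing = TRUE)
}

#' One carboxy-terminal trimming step
#'
#' From a retained species with C-terminus \code{currentCterm}, candidate
#' next sites are \code{currentCterm - 3} (the in-register tripeptide site)
#' down to \code{currentCterm - 3 - maxScan}; each candidate k residues
#' past the register is weighted \code{skipPenalty^k * siteScore}.  The
#' Gly-Gly site after G38 competes through its lability bonus.  Weights
#' are normalized; an empty result means no available site (the species
#' stalls and is released as-is).
#'
#' @param seq a [SubstrateSequence-class].
#' @param currentCterm C-terminal position of the retained species.
#' @param trim a [TrimPolicy-class].
#' @param profile a [PocketProfile-class].
#' @return named numeric of normalized weights over next P1 positions
#'   (possibly empty).
#' @examples
#' trimStep(loadSubstrate("APP_C99_WT"), 49)  # site 46 dominant
#' @export
trimStep <- function(seq, currentCterm, trim = new("TrimPolicy"),
                     profile = new("PocketProfile")) {
    stopifnot(currentCterm > trim@minRelease)
    first <- currentCterm - trim@step
    last <- max(first - trim@maxScan, 1L)
    if (first < 1L)
        return(stats::setNames(numeric(0), character(0)))
    cand <- seq(first, last, by = -1L)
    w <- vapply(cand, function(p)
        trim@skipPenalty^(first - p) * siteScore(seq, p, profile, trim), 0)
    names(w) <- cand
    w <- w[w > 0]
    if (length(w) == 0L) return(w)
    w / sum(w)
}

# Exhaustive flux propagation over retained-species states.  Returns the
# normalized Abeta and AICD weight maps.  Deterministic.
propagate_flux <- function(seq, eps, trim, profile) {
    epsw <- selectEpsilon(seq, eps, profile, trim)
    aicd <- stats::setNames(as.numeric(epsw),
                            as.character(as.integer(names(epsw)) + 1L))
    flux <- stats::setNames(as.numeric(epsw), names(epsw))
    abeta <- numeric(0)
    add <- function(vec, key, val) {
        key <- as.character(key)
        if (key %in% names(vec)) vec[key] <- vec[key] + val
        else vec[key] <- val
        vec
    }
    while (length(flux)) {
        c0 <- max(as.integer(names(flux)))
        w <- flux[[as.character(c0)]]
        flux <- flux[names(flux) != as.character(c0)]
        if (c0 <= trim@minRelease) {
            abeta <- add(abeta, c0, w)
            next
        }
        r <- release_prob(trim, c0)
        if (r > 0) abeta <- add(abeta, c0, w * r)
        wc <- w * (1 - r)
        if (wc <= 0) next
        nxt <- trimStep(seq, c0, trim, profile)
        if (length(nxt) == 0L) {
            abeta <- add(abeta, c0, wc)   # stalled: released as-is
            next
        }
        for (k in names(nxt)) flux <- add(flux, k, wc * nxt[[k]])
    }
    abeta <- abeta[order(-as.numeric(names(abeta)))]
    list(abeta = abeta / sum(abeta), aicd = aicd / sum(aicd))
}

# Stochastic counterpart: particles are propagated stage-by-stage with
# multinomial draws (statistically identical to sampling trajectories one
# at a time, but vectorized).  Deterministic given `seed`.
sample_flux <- function(seq, eps, trim, profile, nsample, seed) {
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", globalenv()))
            get(".Random.seed", globalenv()) else NULL
        on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
        set.seed(seed)
    }
    epsw <- selectEpsilon(seq, eps, profile, trim)
    ncount <- stats::rmultinom(1L, nsample, epsw)[, 1L]
    aicd <- stats::setNames(as.numeric(ncount),
                            as.character(as.integer(names(epsw)) + 1L))
    flux <- ncount[ncount > 0]
    abeta <- numeric(0)
    add <- function(vec, key, val) {
        key <- as.character(key)
        if (key %in% names(vec)) vec[key] <- vec[key] + val
        else vec[key] <- val
        vec
    }
    while (length(flux)) {
        c0 <- max(as.integer(names(flux)))
        n0 <- flux[[as.character(c0)]]
        flux <- flux[names(flux) != as.character(c0)]
        if (c0 <= trim@minRelease) {
            abeta <- add(abeta, c0, n0)
            next
        }
        r <- release_prob(trim, c0)
        nrel <- stats::rbinom(1L, n0, r)
        if (nrel > 0) abeta <- add(abeta, c0, nrel)
        ncont <- n0 - nrel
        if (ncont == 0L) next
        nxt <- trimStep(seq, c0, trim, profile)
        if (length(nxt) == 0L) {
            abeta <- add(abeta, c0, ncont)
            next
        }
        draws <- stats::rmultinom(1L, ncont, nxt)[, 1L]
        for (k in names(draws)[draws > 0])
            flux <- add(flux, k, draws[[k]])
    }
    abeta <- abeta[order(-as.numeric(names(abeta)))]
    list(abeta = abeta / sum(abeta), aicd = aicd / sum(aicd))
}

#' Simulate processive cleavage of a substrate
#'
#' Runs epsilon-site selection and sequential carboxy-terminal trimming,
#' either by exhaustive flux enumeration (deterministic, the default) or by
#' seeded stochastic sampling that converges to the exhaustive result.
#'
#' @param seq a [SubstrateSequence-class].
#' @param eps an [EpsilonProfile-class].
#' @param trim a [TrimPolicy-class].
#' @param profile a [PocketProfile-class].
#' @param mode \code{"exhaustive"} or \code{"sampled"}.
#' @param nsample number of sampled trajectories in sampled mode.
#' @param seed RNG seed for sampled mode.
#' @return a [ProductDistribution-class].
#' @examples
#' wt <- simulateCleavage(loadSubstrate("APP_C99_WT"))
#' abetaWeights(wt)[c("40", "42")]
#' ratio42_40(wt)
#' @export
simulateCleavage <- function(seq, eps = new("EpsilonProfile"),
                             trim = new("TrimPolicy"),
                             profile = new("PocketProfile"),
                             mode = c("exhaustive", "sampled"),
                             nsample = 1e5, seed = NULL) {
    mode <- match.arg(mode)
    out <- if (mode == "exhaustive")
        propagate_flux(seq, eps, trim, profile)
    else
        sample_flux(seq, eps, trim, profile, as.integer(nsample), seed)
    new("ProductDistribution", abeta = out$abeta, aicd = out$aicd)
}

#' Enumerate complete cleavage trajectories
#'
#' Exhaustively enumerates trajectories (epsilon cut followed by trimming
#' events down to terminal release), each with its probability weight.
#' Trajectories with weight below \code{prune} are dropped; the retained
#' weights sum to 1 minus the pruned mass.
#'
#' @inheritParams simulateCleavage
#' @param prune minimal trajectory weight retained.
#' @return list of trajectories; each has \code{sites} (ordered P1
#'   positions, epsilon first), \code{released} (fragments in release
#'   order: AICD first, trimmed fragments, final Abeta last),
#'   \code{abeta} (terminal species) and \code{weight}.
#' @export
enumerateTrajectories <- function(seq, eps = new("EpsilonProfile"),
                                  trim = new("TrimPolicy"),
                                  profile = new("PocketProfile"),
                                  prune = 1e-9) {
    epsw <- selectEpsilon(seq, eps, profile, trim)
    n <- substrateLength(seq)
    out <- list()
    recurse <- function(cterm, w, sites, frags) {
        if (w < prune) return()
        terminal <- function(wt) {
            out[[length(out) + 1L]] <<- list(
                sites = sites,
                released = c(frags,
                             paste(seq@residues[seq_len(cterm)],
                                   collapse = "")),
                abeta = cterm, weight = wt)
        }
        if (cterm <= trim@minRelease) { terminal(w); return() }
        r <- release_prob(trim, cterm)
        if (r > 0) terminal(w * r)
        wc <- w * (1 - r)
        if (wc < prune) return()
        nxt <- trimStep(seq, cterm, trim, profile)
        if (length(nxt) == 0L) { terminal(wc); return() }
        for (k in names(nxt)) {
            p <- as.integer(k)
            recurse(p, wc * nxt[[k]], c(sites, p),
                    c(frags, releasedFragment(seq, cterm, p)))
        }
    }
    for (k in names(epsw)) {
        p <- as.integer(k)
        aicdseq <- paste0(paste(seq@residues[(p + 1L):n], collapse = ""),
                          seq@tag)
        recurse(p, epsw[[k]], p, aicdseq)
    }
    out
}

#' @describeIn abetaWeights AICD weight map (names are start positions).
#' @export
aicdWeights <- function(dist) {
    stopifnot(is(dist, "ProductDistribution"))
    dist@aicd
}

#' Product weights and the Abeta42/40 ratio
#'
#' @param dist a [ProductDistribution-class].
#' @return \code{abetaWeights}/\code{aicdWeights}: named numeric weight
#'   maps; \code{ratio42_40}: the Abeta42/Abeta40 weight quotient
#'   (\code{NaN} with a warning when Abeta40 carries no weight).
#' @export
abetaWeights <- function(dist) {
    stopifnot(is(dist, "ProductDistribution"))
    dist@abeta
}

weight_of <- function(w, key) if (key %in% names(w)) w[[key]] else 0

#' @describeIn abetaWeights the Abeta42/40 ratio.
#' @export
ratio42_40 <- function(dist) {
    w40 <- weight_of(abetaWeights(dist), "40")
    w42 <- weight_of(abetaWeights(dist), "42")
    if (w40 <= 0) {
        warning("Abeta40 weight is zero; ratio undefined")
        return(NaN)
    }
    w42 / w40
}

#' Detected AICD species
#'
#' AICD species whose weight reaches the detection threshold, mimicking
#' which fragment peaks a linear-mode MALDI-TOF spectrum of the product
#' pool would show.
#'
#' @param dist a [ProductDistribution-class].
#' @param threshold minimal weight fraction for detection (default 0.03).
#' @return character vector of labels \code{"AICD <start>-99"}-style start
#'   positions, ordered by decreasing weight.
#' @export
detectedAicd <- function(dist, threshold = 0.03) {
    w <- sort(aicdWeights(dist), decreasing = TRUE)
    names(w)[w >= threshold]
}

#' Direction of the Abeta42/40 ratio change of a mutant versus wild type
#'
#' Simulates wild type and mutant under identical parameters and reports
#' the sign of the ratio change, with a relative dead-band for
#' \code{"unchanged"}.  When the mutant produces essentially no Abeta40,
#' the ratio diverges and the direction is \code{"up"} (attribute
#' \code{note} says the ratio is undefined because Abeta40 is eliminated).
#'
#' @param muts mutation spec (string, tokens, or data.frame).
#' @param eps,trim,profile model parameters shared by both simulations.
#' @param deadband relative change below which the ratio counts as
#'   unchanged (default 0.2).
#' @param wtDist optional precomputed wild-type [ProductDistribution-class]
#'   to avoid resimulating it.
#' @return one of \code{"down"}, \code{"up"}, \code{"unchanged"}; attribute
#'   \code{ratios} carries the two ratios.
#' @examples
#' predictRatioDirection("V50F")  # "down"
#' predictRatioDirection("M51F")  # "up"
#' @export
predictRatioDirection <- function(muts, eps = new("EpsilonProfile"),
                                  trim = new("TrimPolicy"),
                                  profile = new("PocketProfile"),
                                  deadband = 0.2, wtDist = NULL) {
    if (is.null(wtDist))
        wtDist <- simulateCleavage(loadSubstrate("APP_C99_WT"),
                                   eps, trim, profile)
    mut <- simulateCleavage(applyMutations(loadSubstrate("APP_C99_WT"),
                                           muts),
                            eps, trim, profile)
    r0 <- ratio42_40(wtDist)
    w40 <- weight_of(abetaWeights(mut), "40")
    if (w40 < 1e-9) {
        out <- "up"
        attr(out, "note") <- "Abeta40 eliminated; ratio undefined"
        attr(out, "ratios") <- c(wt = r0, mutant = Inf)
        return(out)
    }
    r1 <- suppressWarnings(ratio42_40(mut))
    rel <- (r1 - r0) / r0
    out <- if (abs(rel) <= deadband) "unchanged"
           else if (rel > 0) "up" else "down"
    attr(out, "ratios") <- c(wt = r0, mutant = r1)
    out
}

#' Classify the mechanism of a familial Alzheimer's disease mutation
#'
#' Pairs the mutation with V50F, which forces endoproteolysis away from the
#' T48 (Abeta42) pathway.  If the double mutant's ratio direction is down
#' (like V50F alone) the mutation's effect is routed through epsilon-site
#' choice or trimming along the Abeta48 pathway and is \emph{rescued}; if
#' the ratio stays up, the mutation uncouples final cleavages from the
#' initial cut (\emph{uncoupled}), as an aromatic P2' clash does.
#'
#' @param fad mutation spec for a single TMD mutation (not at position 50).
#' @inheritParams predictRatioDirection
#' @return \code{"rescued_by_V50F"} or \code{"uncoupled"}; attribute
#'   \code{direction} holds the double mutant's ratio direction.
#' @examples
#' classifyFadMechanism("I45F")  # uncoupled
#' classifyFadMechanism("V46F")  # rescued_by_V50F
#' @export
classifyFadMechanism <- function(fad, eps = new("EpsilonProfile"),
                                 trim = new("TrimPolicy"),
                                 profile = new("PocketProfile"),
                                 deadband = 0.2) {
    fad <- as_mutation_frame(fad)
    if (any(fad$position == 50L))
        stop("the FAD mutation may not itself be at position 50")
    dbl <- rbind(fad, data.frame(position = 50L, wt = "V", mut = "F",
                                 stringsAsFactors = FALSE))
    dir <- predictRatioDirection(dbl, eps, trim, profile, deadband)
    out <- if (identical(as.character(dir), "down")) "rescued_by_V50F"
           else "uncoupled"
    attr(out, "direction") <- as.character(dir)
    out
}

setMethod("show", "ProductDistribution", function(object) {
    cat("ProductDistribution\n  Abeta:\n")
    ab <- sort(object@abeta, decreasing = TRUE)
    for (k in names(ab))
        if (ab[[k]] >= 5e-4)
            cat(sprintf("    Abeta%-3s %6.3f\n", k, ab[[k]]))
    cat("  AICD:\n")
    ai <- sort(object@aicd, decreasing = TRUE)
    for (k in names(ai))
        if (ai[[k]] >= 5e-4)
            cat(sprintf("    AICD %s-99 %6.3f\n", k, ai[[k]]))
    r <- suppressWarnings(ratio42_40(object))
    cat(sprintf("  Abeta42/40 ratio: %s\n",
                ifelse(is.nan(r), "undefined (no Abeta40)",
                       format(r, digits = 4))))
})
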