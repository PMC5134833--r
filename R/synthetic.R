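# Seeded generators for everything the other modules consume: noisy
# initial-velocity datasets under the three rate laws, ELISA-like Abeta
# readouts from simulated product distributions, and the mutant panel with
# its qualitative truth table.

with_seed <- function(seed, expr) {
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", globalenv()))
            get(".Random.seed", globalenv()) else NULL
        on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
        set.seed(seed)
    }
    force(expr)
}

#' Generate a noisy initial-velocity dataset
#'
#' Evaluates the chosen rate law on a full factorial design and perturbs
#' each velocity multiplicatively with Gaussian noise, truncated below at
#' a detection floor.  Bit-reproducible for a given seed.
#'
#' @param model \code{"ic50"}, \code{"noncompetitive"} or \code{"cross"}.
#' @param params named list of true parameters for the chosen model
#'   (\code{ic50, v0}; \code{vmax, km, ki, kii}; or
#'   \code{v0, ki, kj, beta}).
#' @param design named list of concentration grids: \code{I} (all models),
#'   \code{S} (noncompetitive), \code{J} (cross), and \code{replicates}.
#' @param relativeSd relative standard deviation of the noise (0 = exact).
#' @param floor minimal reported velocity.
#' @param seed RNG seed.
#' @return data.frame with the design columns, \code{replicate} and
#'   \code{v}.
#' @examples
#' d <- generateVelocityData("ic50", list(ic50 = 150, v0 = 1),
#'                           list(I = c(0, 50, 150, 450)), 0.02, seed = 1)
#' @export
generateVelocityData <- function(model = c("ic50", "noncompetitive",
                                           "cross"),
                                 params, design, relativeSd = 0.02,
                                 floor = 0, seed = NULL) {
    model <- match.arg(model)
    stopifnot(relativeSd >= 0)
    reps <- if (is.null(design$replicates)) 1L
            else as.integer(design$replicates)
    grid <- switch(model,
        ic50 = expand.grid(I = design$I, replicate = seq_len(reps)),
        noncompetitive = expand.grid(S = design$S, I = design$I,
                                     replicate = seq_len(reps)),
        cross = expand.grid(I = design$I, J = design$J,
                            replicate = seq_len(reps)))
    if (nrow(grid) == 0L) stop("degenerate design: empty grid")
    mu <- switch(model,
        ic50 = {
            if (length(unique(design$I)) < 2L)
                stop("degenerate design: single inhibitor concentration")
            params$v0 * ic50Fraction(grid$I, params$ic50)
        },
        noncompetitive = {
            if (length(unique(design$S)) < 2L)
                stop("degenerate design: single substrate concentration")
            noncompetitiveRate(grid$S, grid$I, params$vmax, params$km,
                               params$ki, params$kii)
        },
        cross = yonetaniTheorellRate(grid$I, grid$J, params$v0,
                                     params$ki, params$kj, params$beta))
    v <- with_seed(seed,
        mu * (1 + stats::rnorm(length(mu), 0, relativeSd)))
    grid$v <- pmax(v, floor)
    grid
}

#' Generate ELISA-like Abeta38/40/42 readouts
#'
#' Scales the simulated weights of the three reported species and applies
#' multiplicative noise with a detection floor, emulating plate-based
#' sandwich-ELISA quantification of secreted products.
#'
#' @param dist a [ProductDistribution-class].
#' @param scale total signal of the product pool (arbitrary units).
#' @param relativeSd relative noise SD.
#' @param replicates number of replicate wells.
#' @param floor minimal reported signal.
#' @param seed RNG seed.
#' @return data.frame with columns \code{replicate}, \code{ab38},
#'   \code{ab40}, \code{ab42}, \code{ratio42_40}.
#' @export
generateElisaReadouts <- function(dist, scale = 1000, relativeSd = 0,
                                  replicates = 1L, floor = 0,
                                  seed = NULL) {
    stopifnot(is(dist, "ProductDistribution"), relativeSd >= 0)
    w <- abetaWeights(dist)
    truth <- scale * c(weight_of(w, "38"), weight_of(w, "40"),
                       weight_of(w, "42"))
    out <- with_seed(seed, {
        m <- matrix(rep(truth, replicates), ncol = 3L, byrow = TRUE) *
            (1 + stats::rnorm(3L * replicates, 0, relativeSd))
        pmax(m, floor)
    })
    data.frame(replicate = seq_len(replicates),
               ab38 = out[, 1L], ab40 = out[, 2L], ab42 = out[, 3L],
               ratio42_40 = out[, 3L] / out[, 2L])
}

fad_panel_entries <- function() {
    # TMD FAD substitutions screened alone and with an epsilon-controlling
    # V50F; I45T and T48P are flagged excluded (their uncoupling mechanism
    # is unexplained and deliberately not modelled).
    fads <- c("T43I", "V44A", "V44M", "I45F", "I45T", "I45V",
              "V46F", "V46G", "V46I", "T48P")
    data.frame(
        label = fads, mutations = fads, type = "fad",
        expect_direction = NA_character_, expect_aicd = NA_character_,
        expect_eliminated = NA_character_, expect_elevated = NA_character_,
        expect_fad = ifelse(fads == "I45F", "uncoupled",
                            "rescued_by_V50F"),
        excluded = fads %in% c("I45T", "T48P"),
        source = "FAD screen with/without V50F",
        stringsAsFactors = FALSE)
}

#' Build the mutant-panel truth table
#'
#' Qualitative expectations for the substrate panel: the direction of the
#' Abeta42/40 ratio change, the MS-detected AICD start positions,
#' eliminated and elevated Abeta species, and the V50F-rescue
#' classification for familial Alzheimer's disease (FAD) mutations.
#' Expectations are stored as directions and species sets only, never as
#' quantitative levels.  Entries whose mechanism the model deliberately
#' does not encode (I45T, T48P; helix-stability effects) carry
#' \code{excluded = TRUE}.
#'
#' @return data.frame, one row per panel entry.
#' @export
buildPanel <- function() {
    e <- function(label, muts = label, dir = NA, aicd = NA, elim = NA,
                  elev = NA, excl = FALSE, src = "") {
        data.frame(label = label, mutations = muts,
                   type = "direction",
                   expect_direction = as.character(dir),
                   expect_aicd = as.character(aicd),
                   expect_eliminated = as.character(elim),
                   expect_elevated = as.character(elev),
                   expect_fad = NA_character_, excluded = excl,
                   source = src, stringsAsFactors = FALSE)
    }
    hexa <- "V44F,I45F,I47F,T48F,V50F,M51F"
    octa <- "V44F,I45F,V46F,I47F,T48F,L49F,V50F,M51F"
    panel <- rbind(
        e("WT", "", dir = "unchanged", aicd = "50,49",
          src = "in vitro MS of wild type"),
        # aromatic substitutions at the P2' residues of the two epsilon
        # sites: block one pathway each
        e("V50F", dir = "down", aicd = "50,48"),
        e("V50W", dir = "down"), e("V50Y", dir = "down"),
        e("M51F", dir = "up", aicd = "49,48"),
        e("M51W", dir = "up"), e("M51Y", dir = "up"),
        # P2' Phe scan of the downstream tripeptide sites
        e("V44F", dir = "down"), e("I45F", dir = "up"),
        e("I47F", dir = "down"), e("T48F", dir = "up"),
        # non-blocking singles; V46F never clashes with S2' on a major
        # pathway.  L49F carries no directional expectation: no published
        # observation covers it alone, and its Phe sits in the S1' pocket
        # of the T48 site, which the model rewards
        e("V46F", dir = "unchanged"), e("L49F"),
        # epsilon-controlled doubles: behave like the N-terminal Phe
        e("V44F-M51F", "V44F,M51F", dir = "down"),
        e("I45F-V50F", "I45F,V50F", dir = "up"),
        e("I47F-M51F", "I47F,M51F", dir = "down"),
        e("T48F-V50F", "T48F,V50F", dir = "up"),
        # tandem doubles: follow the blocking partner
        e("I45F-V46F", "I45F,V46F", dir = "up"),
        e("V46F-I47F", "V46F,I47F", dir = "down"),
        e("T48F-L49F", "T48F,L49F", dir = "up"),
        e("L49F-V50F", "L49F,V50F", dir = "down"),
        e("V50F-M51F", "V50F,M51F", dir = "down", aicd = "48,51"),
        # Abeta38 scan: occupancy of the three S' pockets is required for
        # the Gly-Gly site (V40F is its P2'); V39F/I41F elevate Abeta38 in
        # cells, a magnitude the weight model does not assert
        e("V39F"), e("V40F", elim = "38"), e("I41F"),
        e("A42F", elim = "40"),
        # triples along each pathway
        e("V44F-I47F-V50F", "V44F,I47F,V50F", dir = "down", elim = "42"),
        e("I45F-T48F-M51F", "I45F,T48F,M51F", dir = "up", elim = "40"),
        # blocking both Abeta38 precursors elevates Abeta38
        e("V44F-I45F", "V44F,I45F", elev = "38"),
        # consecutive-phenylalanine stretches
        e("hexa-F 44-51", hexa, elev = "38"),
        e("octa-F 44-51", octa, elev = "38"),
        fad_panel_entries())
    rownames(panel) <- NULL
    panel
}

#' Score the mutant panel against the simulator
#'
#' Runs [simulateCleavage()] on every panel entry and checks each stored
#' expectation: ratio direction (with "Abeta40 eliminated" counting as
#' up), detected AICD start-position sets (exact match), eliminated
#' species (weight below \code{elimThreshold}), elevated species (weight
#' above \code{elevFactor} times wild type) and FAD rescue class.
#'
#' @param panel a panel data.frame from [buildPanel()].
#' @param eps,trim,profile model parameters.
#' @param deadband dead-band for ratio directions.
#' @param detectionThreshold MS detection threshold for AICD species.
#' @param elimThreshold weight below which a species counts as eliminated.
#' @param elevFactor fold-change above which a species counts as elevated.
#' @return the panel with columns \code{observed} and \code{pass} added;
#'   attribute \code{accuracy} is the pass fraction over non-excluded
#'   entries that carry at least one expectation.
#' @export
scorePanel <- function(panel = buildPanel(),
                       eps = new("EpsilonProfile"),
                       trim = new("TrimPolicy"),
                       profile = new("PocketProfile"),
                       deadband = 0.2, detectionThreshold = 0.03,
                       elimThreshold = 0.01, elevFactor = 1.5) {
    wtSub <- loadSubstrate("APP_C99_WT")
    wtDist <- simulateCleavage(wtSub, eps, trim, profile)
    wtAb <- abetaWeights(wtDist)
    obs <- character(nrow(panel))
    pass <- rep(NA, nrow(panel))
    for (i in seq_len(nrow(panel))) {
        muts <- panel$mutations[i]
        dist <- if (nzchar(muts))
            simulateCleavage(applyMutations(wtSub, muts), eps, trim,
                             profile)
        else wtDist
        checks <- logical(0)
        notes <- character(0)
        if (!is.na(panel$expect_direction[i])) {
            d <- if (nzchar(muts))
                predictRatioDirection(muts, eps, trim, profile, deadband,
                                      wtDist = wtDist)
            else "unchanged"
            checks <- c(checks, identical(as.character(d),
                                          panel$expect_direction[i]))
            notes <- c(notes, paste0("direction=", as.character(d)))
        }
        if (!is.na(panel$expect_aicd[i])) {
            want <- sort(strsplit(panel$expect_aicd[i], ",")[[1L]])
            got <- detectedAicd(dist, detectionThreshold)
            checks <- c(checks, identical(sort(got), want))
            notes <- c(notes, paste0("aicd={", paste(got, collapse = ","),
                                     "}"))
        }
        if (!is.na(panel$expect_eliminated[i])) {
            sp <- strsplit(panel$expect_eliminated[i], ",")[[1L]]
            w <- vapply(sp, function(s)
                weight_of(abetaWeights(dist), s), 0)
            checks <- c(checks, all(w < elimThreshold))
            notes <- c(notes, paste0("w", sp, "=",
                                     signif(w, 3), collapse = " "))
        }
        if (!is.na(panel$expect_elevated[i])) {
            sp <- strsplit(panel$expect_elevated[i], ",")[[1L]]
            w <- vapply(sp, function(s)
                weight_of(abetaWeights(dist), s), 0)
            w0 <- vapply(sp, function(s) weight_of(wtAb, s), 0)
            checks <- c(checks, all(w > elevFactor * w0))
            notes <- c(notes, paste0("w", sp, "=", signif(w, 3),
                                     " (wt ", signif(w0, 3), ")",
                                     collapse = " "))
        }
        if (!is.na(panel$expect_fad[i])) {
            cl <- classifyFadMechanism(muts, eps, trim, profile, deadband)
            checks <- c(checks, identical(as.character(cl),
                                          panel$expect_fad[i]))
            notes <- c(notes, paste0("fad=", as.character(cl)))
        }
        obs[i] <- paste(notes, collapse = "; ")
        if (length(checks)) pass[i] <- all(checks)
    }
    panel$observed <- obs
    panel$pass <- pass
    scored <- !panel$excluded & !is.na(panel$pass)
    attr(panel, "accuracy") <- mean(panel$pass[scored])
    panel
}
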