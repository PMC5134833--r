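#' @import methods
NULL

#' SubstrateSequence: a gamma-secretase substrate in Abeta numbering
#'
#' Holds an ordered amino-acid sequence indexed from 1 (Asp1 of the
#' amyloid-beta region for APP C99), an optional C-terminal epitope tag that
#' travels with the intracellular-domain product, and a record of the point
#' mutations applied relative to the wild-type fixture.
#'
#' @slot name substrate name, e.g. \code{"APP_C99_WT"}.
#' @slot residues character vector of one-letter residue codes, position i of
#'   the vector is residue i in Abeta numbering.
#' @slot tag single string, C-terminal epitope tag in one-letter codes
#'   (\code{""} for untagged substrates).
#' @slot mutations data.frame with columns \code{position}, \code{wt},
#'   \code{mut} recording applied substitutions.
#'
#' @exportClass SubstrateSequence
setClass("SubstrateSequence",
    representation(
        name = "character",
        residues = "character",
        tag = "character",
        mutations = "data.frame"
    ),
    prototype(
        name = NA_character_,
        residues = character(),
        tag = "",
        mutations = data.frame(position = integer(), wt = character(),
                               mut = character(), stringsAsFactors = FALSE)
    )
)

AA_STANDARD <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

setValidity("SubstrateSequence", function(object) {
    msg <- character()
    if (length(object@residues) < 10L)
        msg <- c(msg, "substrate must have at least 10 residues")
    bad <- setdiff(unique(object@residues), AA_STANDARD)
    if (length(bad))
        msg <- c(msg, paste0("non-standard residue code(s): ",
                             paste(bad, collapse = ", ")))
    if (length(object@tag) != 1L)
        msg <- c(msg, "tag must be a single string")
    else if (nzchar(object@tag)) {
        badt <- setdiff(unique(strsplit(object@tag, "")[[1L]]), AA_STANDARD)
        if (length(badt))
            msg <- c(msg, "tag contains non-standard residue codes")
    }
    if (length(msg)) msg else TRUE
})

#' CleavageSite: a scissile bond and its S'-pocket residue mapping
#'
#' Cleavage "after residue i" (position = i, the P1 residue) severs the bond
#' between residues i and i+1, yielding the N-terminal product 1..i and the
#' C-terminal product (i+1)..end.  The P1'/P2'/P3' residues are those that
#' occupy the S1'/S2'/S3' pockets of the protease.
#'
#' @slot position integer, the P1 position i.
#' @slot p1,p1Prime,p2Prime,p3Prime one-letter codes of residues i..i+3;
#'   \code{p3Prime} is \code{NA} when i+3 exceeds the substrate.
#'
#' @exportClass CleavageSite
setClass("CleavageSite",
    representation(position = "integer", p1 = "character",
                   p1Prime = "character", p2Prime = "character",
                   p3Prime = "character"))

#' PocketProfile: the three S' subsite rules
#'
#' Encodes the subsite constraints of the presenilin active site: the small
#' S2' pocket excludes aromatic residues, the large S1' and S3' pockets
#' prefer aromatics (a multiplicative bonus), and there is no contributory
#' S4' pocket (no term for P4' anywhere in the scoring).
#'
#' @slot s2Excluded residue classes excluded at S2' (default F, Y, W).
#' @slot bulkyBonus multiplicative weight (> 1) applied once per aromatic
#'   residue at P1' or P3'.
#' @slot blockedWeight residual weight in [0, 1) given to an S2'-blocked
#'   site; 0 means hard exclusion.
#'
#' @exportClass PocketProfile
setClass("PocketProfile",
    representation(s2Excluded = "character", bulkyBonus = "numeric",
                   blockedWeight = "numeric"),
    prototype(s2Excluded = c("F", "Y", "W"), bulkyBonus = 1.5,
              blockedWeight = 0))

setValidity("PocketProfile", function(object) {
    msg <- character()
    if (length(object@blockedWeight) != 1L || object@blockedWeight < 0 ||
        object@blockedWeight >= 1)
        msg <- c(msg, "blockedWeight must be a single value in [0, 1)")
    if (length(object@bulkyBonus) != 1L || object@bulkyBonus <= 0)
        msg <- c(msg, "bulkyBonus must be a single positive value")
    if (length(msg)) msg else TRUE
})

#' EpsilonProfile: base preference over endoproteolysis (epsilon) sites
#'
#' Base weights over candidate P1 positions of the initial epsilon cut.
#' Defaults are calibrated to the qualitative usage pattern of APP C99:
#' predominantly after L49 or T48, sparingly after I47, with near-zero
#' weight just outside that core.  Weights are multiplied by the
#' pocket-adjusted site score and renormalized over unblocked candidates,
#' so flux from a blocked site redistributes to the remaining ones.
#'
#' @slot baseWeights named nonnegative numeric; names are P1 positions.
#'
#' @exportClass EpsilonProfile
setClass("EpsilonProfile",
    representation(baseWeights = "numeric"),
    prototype(baseWeights = c(`46` = 0.001, `47` = 0.025, `48` = 0.30,
                              `49` = 0.63, `50` = 0.003)))

setValidity("EpsilonProfile", function(object) {
    msg <- character()
    if (is.null(names(object@baseWeights)) ||
        anyNA(suppressWarnings(as.integer(names(object@baseWeights)))))
        msg <- c(msg, "baseWeights must be named by integer positions")
    if (any(object@baseWeights < 0))
        msg <- c(msg, "baseWeights must be nonnegative")
    if (!any(object@baseWeights > 0))
        msg <- c(msg, "at least one base weight must be positive")
    if (length(msg)) msg else TRUE
})

#' TrimPolicy: processive carboxy-terminal trimming rules
#'
#' After the epsilon cut the enzyme retains the Abeta species and trims it
#' from the C-terminus.  The preferred step is exactly three residues (the
#' three S' pockets); when the in-register site is blocked the enzyme scans
#' further N-terminally, each extra residue of skipping paying a
#' multiplicative penalty.  A released fragment is never shorter than
#' \code{minRelease} residues (never a dipeptide).  The helix-destabilizing
#' Gly-Gly motif at G37/G38 makes the bond after G38 unusually labile:
#' site 38 carries a large multiplicative bonus (applied only when glycines
#' are present at 37 and 38), enough to out-compete one skipping step
#' (Abeta42 -> Abeta38) but not two (Abeta43 still mostly goes to Abeta40).
#' After each trim the species dissociates from the enzyme with a
#' per-species release probability.
#'
#' @slot step preferred trimming step in residues (3).
#' @slot minRelease minimal released fragment length (3).
#' @slot maxScan maximal extra residues scanned N-terminally past the
#'   in-register site when searching for an available site.
#' @slot skipPenalty multiplicative weight per residue of skipping.
#' @slot ggBonus multiplicative lability bonus for the site after G38.
#' @slot releaseProb named numeric, per-species dissociation probability
#'   keyed by Abeta C-terminal length; \code{defaultRelease} applies to
#'   lengths not listed (long, enzyme-retained species).
#' @slot defaultRelease release probability for unlisted long species.
#'
#' @exportClass TrimPolicy
setClass("TrimPolicy",
    representation(step = "integer", minRelease = "integer",
                   maxScan = "integer", skipPenalty = "numeric",
                   ggBonus = "numeric", releaseProb = "numeric",
                   defaultRelease = "numeric"),
    prototype(step = 3L, minRelease = 3L, maxScan = 8L,
              skipPenalty = 0.005, ggBonus = 1000,
              releaseProb = c(`37` = 1, `38` = 1, `39` = 1, `40` = 1,
                              `41` = 0.05, `42` = 0.97, `43` = 0.015),
              defaultRelease = 0.005))

setValidity("TrimPolicy", function(object) {
    msg <- character()
    if (object@step != 3L)
        msg <- c(msg, "preferred step is fixed at 3 residues")
    if (object@minRelease < 3L)
        msg <- c(msg, "minRelease must be >= 3 (never a dipeptide)")
    if (object@maxScan < 0L)
        msg <- c(msg, "maxScan must be nonnegative")
    if (any(object@releaseProb < 0) || any(object@releaseProb > 1) ||
        object@defaultRelease < 0 || object@defaultRelease > 1)
        msg <- c(msg, "release probabilities must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' ProductDistribution: normalized weights over released products
#'
#' @slot abeta named numeric summing to 1; names are Abeta C-terminal
#'   lengths (e.g. \code{"40"} for Abeta40).
#' @slot aicd named numeric summing to 1; names are AICD start positions
#'   (e.g. \code{"50"} for AICD 50-99).
#'
#' @exportClass ProductDistribution
setClass("ProductDistribution",
    representation(abeta = "numeric", aicd = "numeric"))

setValidity("ProductDistribution", function(object) {
    msg <- character()
    if (abs(sum(object@abeta) - 1) > 1e-6)
        msg <- c(msg, "abeta weights must sum to 1")
    if (abs(sum(object@aicd) - 1) > 1e-6)
        msg <- c(msg, "aicd weights must sum to 1")
    if (any(object@abeta < 0) || any(object@aicd < 0))
        msg <- c(msg, "weights must be nonnegative")
    if (length(msg)) msg else TRUE
})

#' PeptideSpecies: a concrete fragment with its isotope-averaged mass
#'
#' @slot label species label, e.g. \code{"AICD 50-99"}.
#' @slot sequence residue string including any C-terminal tag.
#' @slot avgMass isotope-averaged (uncharged) mass in Da.
#'
#' @exportClass PeptideSpecies
setClass("PeptideSpecies",
    representation(label = "character", sequence = "character",
                   avgMass = "numeric"))

#' Ic50Fit: fractional-inhibition dose-response fit
#' @slot ic50 fitted IC50 (concentration units of the input data).
#' @slot v0 fitted uninhibited velocity.
#' @slot r2 coefficient of determination of the global fit.
#' @slot rss residual sum of squares.
#' @exportClass Ic50Fit
setClass("Ic50Fit",
    representation(ic50 = "numeric", v0 = "numeric", r2 = "numeric",
                   rss = "numeric"))

#' NoncompetitiveFit: global noncompetitive-inhibition fit
#' @slot vmax,km,ki,kii fitted rate-law parameters; \code{ki} is the
#'   dissociation constant of the inhibitor from free enzyme, \code{kii}
#'   from the enzyme-substrate complex.
#' @slot r2 global coefficient of determination.
#' @slot rss residual sum of squares.
#' @exportClass NoncompetitiveFit
setClass("NoncompetitiveFit",
    representation(vmax = "numeric", km = "numeric", ki = "numeric",
                   kii = "numeric", r2 = "numeric", rss = "numeric"))

#' CrossCompetitionFit: Yonetani-Theorell double-inhibitor fit
#'
#' The interaction factor alpha is parameterized internally as
#' beta = 1/alpha in [0, Inf): beta = 0 corresponds to mutually exclusive
#' binding (alpha = Inf, parallel reciprocal lines), beta = 1 to fully
#' independent sites (alpha = 1).
#'
#' @slot v0,ki,kj,beta fitted parameters of the reciprocal rate law.
#' @slot exclusivity \code{"mutually exclusive"} or \code{"distinct sites"},
#'   decided by small-sample information-criterion comparison of the
#'   beta-free and beta = 0 fits.
#' @slot r2 global coefficient of determination of the selected model.
#' @slot aiccFree,aiccExclusive AICc of the two candidate models.
#' @exportClass CrossCompetitionFit
setClass("CrossCompetitionFit",
    representation(v0 = "numeric", ki = "numeric", kj = "numeric",
                   beta = "numeric", exclusivity = "character",
                   r2 = "numeric", aiccFree = "numeric",
                   aiccExclusive = "numeric"))
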