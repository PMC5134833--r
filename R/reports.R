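# Configuration-driven entry points tying the stages into a pipeline.
# These back the thin command-line script shipped in inst/scripts/.

default_run_config <- function() {
    list(substrate = "APP_C99_WT", mutations = "", outdir = ".",
         seed = 1L, mode = "exhaustive", nsample = 1e5,
         deadband = 0.2, detectionThreshold = 0.03,
         epsilon = NULL, trim = NULL, pocket = NULL)
}

#' Read a run configuration (YAML or JSON)
#'
#' Unspecified fields fall back to package defaults; the epsilon, trim and
#' pocket blocks override individual slots of the corresponding parameter
#' classes.  The configuration round-trips losslessly through
#' serialization.
#'
#' @param path path to a \code{.yaml}/\code{.yml} or \code{.json} file, or
#'   \code{NULL} for pure defaults.
#' @return named list of settings.
#' @export
readRunConfig <- function(path = NULL) {
    cfg <- default_run_config()
    if (is.null(path)) return(cfg)
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- if (grepl("\\.json$", path, ignore.case = TRUE))
        jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
    cfg[names(user)] <- user
    cfg
}

config_params <- function(cfg) {
    eps <- new("EpsilonProfile")
    if (!is.null(cfg$epsilon$baseWeights))
        eps@baseWeights <- unlist(cfg$epsilon$baseWeights)
    trim <- new("TrimPolicy")
    for (s in intersect(names(cfg$trim),
                        c("maxScan", "skipPenalty", "ggBonus",
                          "defaultRelease")))
        slot(trim, s) <- if (s == "maxScan") as.integer(cfg$trim[[s]])
                         else as.numeric(cfg$trim[[s]])
    if (!is.null(cfg$trim$releaseProb))
        trim@releaseProb <- unlist(cfg$trim$releaseProb)
    pocket <- new("PocketProfile")
    for (s in intersect(names(cfg$pocket),
                        c("s2Excluded", "bulkyBonus", "blockedWeight")))
        slot(pocket, s) <- if (s == "s2Excluded")
            as.character(cfg$pocket[[s]]) else as.numeric(cfg$pocket[[s]])
    validObject(eps); validObject(trim); validObject(pocket)
    list(eps = eps, trim = trim, pocket = pocket)
}

#' Predict the product spectrum of a (mutant) substrate
#'
#' Simulates cleavage of the configured substrate, derives the ratio
#' direction versus wild type, and predicts masses for the detected
#' FLAG-tagged AICD species.  Optionally writes the report as JSON.
#'
#' @param config a configuration list from [readRunConfig()].
#' @param file optional output path for the JSON report.
#' @return (invisibly when written) list with the product distribution,
#'   ratio, direction and AICD species table.
#' @examples
#' cfg <- readRunConfig()
#' cfg$mutations <- "V50F"
#' rep <- runPredict(cfg)
#' rep$aicdSpecies
#' @export
runPredict <- function(config = readRunConfig(), file = NULL) {
    p <- config_params(config)
    sub <- loadSubstrate(config$substrate)
    muts <- as_mutation_frame(config$mutations)
    mut <- applyMutations(sub, muts)
    dist <- simulateCleavage(mut, p$eps, p$trim, p$pocket,
                             mode = config$mode,
                             nsample = config$nsample,
                             seed = config$seed)
    direction <- if (nrow(muts))
        predictRatioDirection(muts, p$eps, p$trim, p$pocket,
                              config$deadband)
    else "unchanged"
    starts <- detectedAicd(dist, config$detectionThreshold)
    species <- lapply(starts, function(s)
        predictAicdMass(as.integer(s),
                        muts[muts$position >= as.integer(s), ,
                             drop = FALSE]))
    out <- list(
        substrate = mut@name,
        mutations = config$mutations,
        abeta = as.list(abetaWeights(dist)),
        aicd = as.list(aicdWeights(dist)),
        ratio42_40 = suppressWarnings(ratio42_40(dist)),
        direction_vs_wt = as.character(direction),
        aicdSpecies = data.frame(
            label = vapply(species, function(x) x@label, ""),
            weight = as.numeric(aicdWeights(dist)[starts]),
            avgMass = round(vapply(species, function(x) x@avgMass, 0),
                            1)))
    if (!is.null(file)) {
        jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA,
                             dataframe = "rows", pretty = TRUE)
        return(invisible(out))
    }
    out
}

#' Run the mutant-panel scorecard
#'
#' @param config a configuration list.
#' @param file optional output TSV path for the per-entry scorecard.
#' @return the scored panel from [scorePanel()] (accuracy in attribute
#'   \code{accuracy}).
#' @export
runPanel <- function(config = readRunConfig(), file = NULL) {
    p <- config_params(config)
    scored <- scorePanel(eps = p$eps, trim = p$trim, profile = p$pocket,
                         deadband = config$deadband,
                         detectionThreshold = config$detectionThreshold)
    if (!is.null(file))
        utils::write.table(scored, file, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    scored
}

#' Simulate or fit a kinetics dataset
#'
#' \code{action = "simulate"} writes a CSV of noisy velocities under the
#' configured rate law; \code{action = "fit"} reads a CSV (columns among
#' S, I, J, v) and dispatches to the matching fitter.
#'
#' @param config configuration list with a \code{kinetics} block
#'   (\code{model}, \code{params}, \code{design}, \code{relativeSd}).
#' @param action \code{"simulate"} or \code{"fit"}.
#' @param file CSV path to write (simulate) or read (fit).
#' @return the dataset (simulate) or the fit object (fit).
#' @export
runKinetics <- function(config = readRunConfig(),
                        action = c("simulate", "fit"), file = NULL) {
    action <- match.arg(action)
    kc <- config$kinetics
    if (action == "simulate") {
        if (is.null(kc$model))
            stop("config$kinetics must give model, params and design")
        dat <- generateVelocityData(kc$model, kc$params, kc$design,
                                    relativeSd = kc$relativeSd %||% 0.02,
                                    seed = config$seed)
        if (!is.null(file))
            utils::write.csv(dat, file, row.names = FALSE)
        return(dat)
    }
    if (is.null(file)) stop("fit requires a CSV file")
    dat <- utils::read.csv(file)
    if (!"v" %in% names(dat))
        stop("schema error: CSV must contain a velocity column 'v'")
    if (all(c("I", "J") %in% names(dat))) fitCrossCompetition(dat)
    else if ("S" %in% names(dat)) fitNoncompetitive(dat)
    else fitIC50(dat)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
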