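# Isotope-averaged peptide masses for linear-mode MALDI-TOF assignment.
# Residue (monomer) masses are derived from elemental composition and
# standard average atomic weights rather than taken from a pre-rounded
# per-residue table: at ~60 residues the accumulated rounding of 4-decimal
# tables already shifts a 7 kDa fragment by ~0.1 Da.
# Peptide mass = sum of residue masses + one water.

ATOMIC_AVG_MASS <- c(C = 12.0107, H = 1.00794, N = 14.0067,
                     O = 15.9994, S = 32.065)

# residue (amino acid minus water) formulas as C, H, N, O, S counts
RESIDUE_COMPOSITION <- rbind(
    G = c(2, 3, 1, 1, 0),  A = c(3, 5, 1, 1, 0),
    S = c(3, 5, 1, 2, 0),  P = c(5, 7, 1, 1, 0),
    V = c(5, 9, 1, 1, 0),  T = c(4, 7, 1, 2, 0),
    C = c(3, 5, 1, 1, 1),  L = c(6, 11, 1, 1, 0),
    I = c(6, 11, 1, 1, 0), N = c(4, 6, 2, 2, 0),
    D = c(4, 5, 1, 3, 0),  Q = c(5, 8, 2, 2, 0),
    K = c(6, 12, 2, 1, 0), E = c(5, 7, 1, 3, 0),
    M = c(5, 9, 1, 1, 1),  H = c(6, 7, 3, 1, 0),
    F = c(9, 9, 1, 1, 0),  R = c(6, 12, 4, 1, 0),
    Y = c(9, 9, 1, 2, 0),  W = c(11, 10, 2, 1, 0))

RESIDUE_AVG_MASS <- drop(RESIDUE_COMPOSITION %*% ATOMIC_AVG_MASS)

WATER_AVG_MASS <- unname(2 * ATOMIC_AVG_MASS["H"] + ATOMIC_AVG_MASS["O"])

#' Average residue-mass table
#'
#' @return named numeric of average residue (monomer) masses in Da, with
#'   attribute \code{water} holding the mass of one water.
#' @export
residueMassTable <- function() {
    out <- RESIDUE_AVG_MASS
    attr(out, "water") <- WATER_AVG_MASS
    out
}

#' Isotope-averaged mass of a peptide
#'
#' Sum of average residue masses plus one water; uncharged, no covalent
#' modifications.
#'
#' @param sequence residue string (one-letter codes) or character vector of
#'   codes.
#' @return mass in Da.
#' @examples
#' averageMass("G")  # 75.07
#' @export
averageMass <- function(sequence) {
    if (length(sequence) == 1L && nchar(sequence) > 1L)
        sequence <- strsplit(sequence, "")[[1L]]
    if (length(sequence) == 0L || !any(nzchar(sequence)))
        stop("empty sequence")
    unknown <- setdiff(unique(sequence), names(RESIDUE_AVG_MASS))
    if (length(unknown))
        stop("unknown residue code(s): ", paste(unknown, collapse = ", "))
    sum(RESIDUE_AVG_MASS[sequence]) + WATER_AVG_MASS
}

#' Predict the mass of a FLAG-tagged AICD fragment
#'
#' Builds the species AICD \code{start}-99: mutated C99 residues
#' \code{start..99} followed directly by the epitope tag, and computes its
#' isotope-averaged mass.  Mutations at positions N-terminal of the
#' fragment cannot appear in it and are ignored with a message.
#'
#' @param start fragment start position in Abeta numbering (44..55).
#' @param muts mutation spec (string, tokens or data.frame); may be empty.
#' @param tag C-terminal tag sequence (default FLAG, \code{DYKDDDDK}).
#' @return a [PeptideSpecies-class].
#' @examples
#' predictAicdMass(50)           # 6905.6 Da (wild type)
#' predictAicdMass(49, "M51F")   # 7034.8 Da
#' @export
predictAicdMass <- function(start, muts = NULL, tag = FLAG_TAG) {
    start <- as.integer(start)
    if (length(start) != 1L || is.na(start) || start < 44L || start > 55L)
        stop("start must be a single integer in 44..55")
    muts <- as_mutation_frame(muts)
    outside <- muts$position < start
    if (any(outside))
        message("ignoring mutation(s) N-terminal of the fragment: ",
                paste0(muts$wt[outside], muts$position[outside],
                       muts$mut[outside], collapse = ", "))
    seq <- applyMutations(loadSubstrate("APP_C99_WT", tag = tag),
                          muts[!outside, , drop = FALSE])
    frag <- paste0(paste(seq@residues[start:99L], collapse = ""), seq@tag)
    new("PeptideSpecies",
        label = sprintf("AICD %d-99", start),
        sequence = frag, avgMass = averageMass(frag))
}

#' Predict the mass of an Abeta species
#'
#' Species Abeta\code{cterm}: residues 1..\code{cterm}, untagged.
#' Mutations C-terminal of the fragment are ignored with a message.
#'
#' @param cterm C-terminal position (37..49).
#' @param muts mutation spec; may be empty.
#' @return a [PeptideSpecies-class].
#' @export
predictAbetaMass <- function(cterm, muts = NULL) {
    cterm <- as.integer(cterm)
    if (length(cterm) != 1L || is.na(cterm) || cterm < 37L || cterm > 49L)
        stop("cterm must be a single integer in 37..49")
    muts <- as_mutation_frame(muts)
    outside <- muts$position > cterm
    if (any(outside))
        message("ignoring mutation(s) C-terminal of the fragment: ",
                paste0(muts$wt[outside], muts$position[outside],
                       muts$mut[outside], collapse = ", "))
    seq <- applyMutations(loadSubstrate("APP_C99_WT", tag = ""),
                          muts[!outside, , drop = FALSE])
    frag <- paste(seq@residues[seq_len(cterm)], collapse = "")
    new("PeptideSpecies",
        label = sprintf("Abeta%d", cterm),
        sequence = frag, avgMass = averageMass(frag))
}

#' Assign observed MALDI-TOF peaks to predicted species
#'
#' Greedy nearest-mass assignment: candidate (species, peak) pairs are
#' ranked by absolute mass difference and assigned in order, each species
#' and each peak used at most once, within the tolerance.  Unassigned
#' peaks are flagged (e.g. contaminants or unmodelled fragments).
#'
#' @param predicted list of [PeptideSpecies-class] objects.
#' @param observed numeric vector of observed masses (Da).
#' @param tolerance maximal |observed - expected| for assignment (Da);
#'   default 6, covering typical linear-mode calibration error at ~7 kDa.
#' @return data.frame with one row per observed peak: \code{observed},
#'   \code{species} (label or \code{NA}), \code{expected}, \code{delta}.
#' @export
matchPeaks <- function(predicted, observed, tolerance = 6) {
    stopifnot(tolerance > 0)
    if (is(predicted, "PeptideSpecies")) predicted <- list(predicted)
    nobs <- length(observed)
    out <- data.frame(observed = as.numeric(observed),
                      species = rep(NA_character_, nobs),
                      expected = rep(NA_real_, nobs),
                      delta = rep(NA_real_, nobs),
                      stringsAsFactors = FALSE)
    if (length(observed) == 0L || length(predicted) == 0L) return(out)
    exp_mass <- vapply(predicted, function(p) p@avgMass, 0)
    labels <- vapply(predicted, function(p) p@label, "")
    pairs <- expand.grid(pk = seq_along(observed),
                         sp = seq_along(predicted))
    pairs$d <- abs(out$observed[pairs$pk] - exp_mass[pairs$sp])
    pairs <- pairs[pairs$d <= tolerance, , drop = FALSE]
    pairs <- pairs[order(pairs$d), , drop = FALSE]
    used_pk <- logical(length(observed))
    used_sp <- logical(length(predicted))
    for (r in seq_len(nrow(pairs))) {
        i <- pairs$pk[r]; j <- pairs$sp[r]
        if (used_pk[i] || used_sp[j]) next
        used_pk[i] <- TRUE; used_sp[j] <- TRUE
        out$species[i] <- labels[j]
        out$expected[i] <- exp_mass[j]
        out$delta[i] <- out$observed[i] - exp_mass[j]
    }
    out
}

setMethod("show", "PeptideSpecies", function(object) {
    cat(sprintf("PeptideSpecies %s | %d residues | average mass %.1f Da\n",
                object@label, nchar(object@sequence), object@avgMass))
})
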