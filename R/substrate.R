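# Canonical human APP C99 (Abeta numbering 1-99).  The intracellular-domain
# masses printed for the FLAG-tagged assay substrate pin this sequence down:
# residues 50-99 + DYKDDDDK must weigh 6905.6 Da (average), which the
# mass-additivity oracle in the test-suite confirms residue by residue.
C99_SEQ <- paste0(
    "DAEFRHDSGYEVHHQKLVFFAEDVGSNKGA",
    "IIGLMVGGVVIATVIVITLVMLKKKQYTSI",
    "HHGVVEVDAAVTPEERHLSKMQQNGYENPT",
    "YKFFEQMQN")

FLAG_TAG <- "DYKDDDDK"

#' Load a gamma-secretase substrate
#'
#' Returns a validated [SubstrateSequence-class] from either a built-in
#' fixture or a FASTA file.  The built-in \code{"APP_C99_WT"} is the
#' canonical human APP C99 fragment in Abeta numbering (99 residues) with a
#' C-terminal FLAG tag, i.e. the recombinant C100-FLAG assay substrate; the
#' initiator methionine of that construct is ignored as it appears in no
#' cleavage product.
#'
#' @param source either \code{"APP_C99_WT"} or a path to a FASTA file whose
#'   first record is a 99-residue C99 sequence.
#' @param tag C-terminal epitope tag appended to the intracellular-domain
#'   product (default FLAG, \code{"DYKDDDDK"}); set \code{""} for none.
#' @return a [SubstrateSequence-class] of 99 residues.
#' @examples
#' wt <- loadSubstrate("APP_C99_WT")
#' residueAt(wt, 49:51)   # L V M
#' @export
loadSubstrate <- function(source = "APP_C99_WT", tag = FLAG_TAG) {
    if (identical(source, "APP_C99_WT")) {
        seqstr <- C99_SEQ
        name <- "APP_C99_WT"
    } else {
        if (!file.exists(source))
            stop("unknown built-in substrate or missing FASTA file: ", source)
        aas <- Biostrings::readAAStringSet(source)
        if (length(aas) < 1L)
            stop("FASTA file contains no records: ", source)
        seqstr <- as.character(aas[[1L]])
        name <- names(aas)[1L]
    }
    res <- strsplit(seqstr, "")[[1L]]
    if (length(res) != 99L)
        stop("C99 substrate must have exactly 99 residues, got ",
             length(res))
    new("SubstrateSequence", name = name, residues = res, tag = tag)
}

#' A synthetic Notch-like transmembrane-domain substrate
#'
#' A constructed (synthetic) stand-in for the Notch1 TMD stub, carrying
#' several native phenylalanines in its membrane-spanning segment.  It is
#' used only for the qualitative audit that predicted cleavages of a
#' non-APP substrate never place an aromatic residue in the S2' pocket; it
#' is not the published Notch sequence.
#'
#' @param epsilonPosition P1 position of the dominant endoproteolysis site
#'   to centre the epsilon window on (default 30).
#' @return list with elements \code{substrate} (a
#'   [SubstrateSequence-class]) and \code{epsilon} (an
#'   [EpsilonProfile-class] centred on \code{epsilonPosition}).
#' @export
notchLikeTMD <- function(epsilonPosition = 30L) {
    res <- strsplit(paste0(
        "QSETVEPPPPAQLHFMYVAAAAFVLLFFVGCGVLLSRKRRRQHGQLWFPEGF"), "")[[1L]]
    sub <- new("SubstrateSequence", name = "Notch_like_TMD_synthetic",
               residues = res, tag = "")
    w <- c(0.05, 0.6, 0.3, 0.05)
    names(w) <- as.character(epsilonPosition + c(-1L, 0L, 1L, 2L))
    list(substrate = sub, epsilon = new("EpsilonProfile", baseWeights = w))
}

#' Residues of a substrate
#'
#' @param x a [SubstrateSequence-class].
#' @param i optional integer positions; default all.
#' @return character vector of one-letter codes.
#' @export
residueAt <- function(x, i = seq_along(x@residues)) {
    stopifnot(is(x, "SubstrateSequence"))
    if (any(i < 1L) || any(i > length(x@residues)))
        stop("position out of range 1..", length(x@residues))
    x@residues[i]
}

#' Substrate length (number of residues, excluding tag)
#' @param x a [SubstrateSequence-class].
#' @export
substrateLength <- function(x) length(x@residues)

#' Parse mutation tokens like "V50F,M51F"
#'
#' @param spec character; either a single comma-separated string or a
#'   vector of tokens of the form \code{<wt><position><mut>}.
#' @return data.frame with columns \code{position}, \code{wt}, \code{mut}.
#' @examples
#' parseMutations("V50F,M51F")
#' @export
parseMutations <- function(spec) {
    if (length(spec) == 0L || identical(spec, ""))
        return(data.frame(position = integer(), wt = character(),
                          mut = character(), stringsAsFactors = FALSE))
    tokens <- unlist(strsplit(spec, "[,;]"))
    tokens <- trimws(tokens[nzchar(trimws(tokens))])
    m <- regmatches(tokens, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", tokens))
    bad <- tokens[vapply(m, length, 1L) != 4L]
    if (length(bad))
        stop("malformed mutation token(s): ", paste(bad, collapse = ", "),
             " (expected e.g. 'V50F')")
    out <- data.frame(
        position = as.integer(vapply(m, `[`, "", 3L)),
        wt = toupper(vapply(m, `[`, "", 2L)),
        mut = toupper(vapply(m, `[`, "", 4L)),
        stringsAsFactors = FALSE)
    badaa <- c(setdiff(out$wt, AA_STANDARD), setdiff(out$mut, AA_STANDARD))
    if (length(badaa))
        stop("non-standard residue code(s) in mutation spec: ",
             paste(unique(badaa), collapse = ", "))
    out
}

as_mutation_frame <- function(muts) {
    if (is.character(muts)) muts <- parseMutations(muts)
    if (is.null(muts))
        muts <- parseMutations("")
    stopifnot(is.data.frame(muts),
              all(c("position", "wt", "mut") %in% names(muts)))
    muts
}

#' Apply point mutations to a substrate
#'
#' Each mutation's stated wild-type residue must match the substrate at its
#' position (mismatches are rejected rather than silently overwritten) and
#' duplicate positions are an error.  The input object is unchanged.
#'
#' @param seq a [SubstrateSequence-class].
#' @param muts mutation specification: a string like \code{"V50F,M51F"}, a
#'   character vector of tokens, or a data.frame from [parseMutations()].
#' @return a new [SubstrateSequence-class] with substitutions applied and
#'   the mutation record extended.
#' @examples
#' v50f <- applyMutations(loadSubstrate("APP_C99_WT"), "V50F")
#' residueAt(v50f, 50)
#' @export
applyMutations <- function(seq, muts) {
    stopifnot(is(seq, "SubstrateSequence"))
    muts <- as_mutation_frame(muts)
    if (nrow(muts) == 0L) return(seq)
    if (anyDuplicated(muts$position))
        stop("duplicate mutation position(s): ",
             paste(unique(muts$position[duplicated(muts$position)]),
                   collapse = ", "))
    if (any(muts$position < 1L | muts$position > substrateLength(seq)))
        stop("mutation position out of range 1..", substrateLength(seq))
    actual <- seq@residues[muts$position]
    mism <- actual != muts$wt
    if (any(mism))
        stop("wild-type mismatch at position(s) ",
             paste(sprintf("%d (is %s, spec says %s)",
                           muts$position[mism], actual[mism],
                           muts$wt[mism]), collapse = "; "))
    if (any(muts$mut == muts$wt))
        stop("mutation must change the residue")
    res <- seq@residues
    res[muts$position] <- muts$mut
    new("SubstrateSequence",
        name = paste0(seq@name, "_",
                      paste0(muts$wt, muts$position, muts$mut,
                             collapse = "-")),
        residues = res, tag = seq@tag,
        mutations = rbind(seq@mutations, muts))
}

#' Map a cleavage position to its S'-pocket residues
#'
#' Cleavage after residue \code{position} places residues
#' \code{position+1..position+3} into the S1'/S2'/S3' pockets.
#'
#' @param seq a [SubstrateSequence-class].
#' @param position integer P1 position, 1 <= position <= length-1.
#' @return a [CleavageSite-class].
#' @examples
#' sitePrimes(loadSubstrate("APP_C99_WT"), 49)  # P1' = V50, P2' = M51
#' @export
sitePrimes <- function(seq, position) {
    stopifnot(is(seq, "SubstrateSequence"))
    n <- substrateLength(seq)
    position <- as.integer(position)
    if (length(position) != 1L || is.na(position) ||
        position < 1L || position > n - 1L)
        stop("position must be a single integer in 1..", n - 1L)
    getr <- function(i) if (i <= n) seq@residues[i] else NA_character_
    new("CleavageSite", position = position,
        p1 = seq@residues[position],
        p1Prime = seq@residues[position + 1L],
        p2Prime = getr(position + 2L),
        p3Prime = getr(position + 3L))
}

#' @describeIn sitePrimes released tripeptide (or longer fragment) between
#'   two successive retained C-termini: residues \code{to+1..from}.
#' @param from,to C-terminal positions before and after a trimming event.
#' @export
releasedFragment <- function(seq, from, to) {
    stopifnot(is(seq, "SubstrateSequence"), to < from)
    paste(seq@residues[(to + 1L):from], collapse = "")
}

setMethod("show", "SubstrateSequence", function(object) {
    cat("SubstrateSequence:", object@name, "\n")
    cat(" ", substrateLength(object), "residues")
    if (nzchar(object@tag)) cat(" + C-terminal tag", object@tag)
    cat("\n")
    if (nrow(object@mutations))
        cat("  mutations:",
            paste0(object@mutations$wt, object@mutations$position,
                   object@mutations$mut, collapse = ", "), "\n")
})

setMethod("show", "CleavageSite", function(object) {
    cat(sprintf("CleavageSite after %s%d | P1'=%s P2'=%s P3'=%s\n",
                object@p1, object@position, object@p1Prime,
                object@p2Prime,
                ifelse(is.na(object@p3Prime), "-", object@p3Prime)))
})
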