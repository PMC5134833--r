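# Shared fixtures: wild-type substrate, default model parameters, and an
# independent elemental-composition mass oracle.

wt_substrate <- function() loadSubstrate("APP_C99_WT")

default_params <- function() {
    list(eps = new("EpsilonProfile"), trim = new("TrimPolicy"),
         pocket = new("PocketProfile"))
}

simulate_mutant <- function(muts, ...) {
    sub <- wt_substrate()
    if (nzchar(muts)) sub <- applyMutations(sub, muts)
    simulateCleavage(sub, ...)
}

# Average residue masses recomputed from elemental composition and IUPAC
# average atomic weights -- independent of the table inside the package.
oracle_residue_mass <- local({
    atoms <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999, S = 32.06)
    comp <- list(  # residue (minus water) formulas as C,H,N,O,S counts
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
    vapply(comp, function(x) sum(x * atoms), 0)
})

oracle_peptide_mass <- function(seqstr) {
    res <- strsplit(seqstr, "")[[1L]]
    sum(oracle_residue_mass[res]) + 2 * 1.008 + 15.999
}

total_variation <- function(p, q) {
    keys <- union(names(p), names(q))
    gp <- function(w, k) ifelse(k %in% names(w), w[k], 0)
    sum(abs(gp(p, keys) - gp(q, keys))) / 2
}
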