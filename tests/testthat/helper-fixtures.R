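suppressPackageStartupMessages({
    library(S4Vectors)
    library(IRanges)
})

toyProtein <- function(residues = "MKACDEFKGHIKLMNPQRSTVWYACDEFK",
                       id = "TOY1") {
    new("ProteinSequence", identifier = id, residues = residues)
}

# Minimal DependentPeptideSet builder; probabilities default to all-zero
# vectors of the right length.
makeDPs <- function(seqs, deltas, proteins = "P1", rawFile = "t1",
                    pep = 0.001, rt = NULL, probs = NULL) {
    n <- length(seqs)
    stopifnot(length(deltas) == n)
    if (is.null(probs)) probs <- lapply(nchar(seqs), numeric)
    if (is.null(rt)) rt <- 30 + seq_len(n) - 1
    new("DependentPeptideSet", DataFrame(
        baseSequence = as.character(seqs),
        deltaMass = as.numeric(deltas),
        probabilities = NumericList(probs),
        proteins = CharacterList(as.list(rep(proteins, length.out = n))),
        rawFile = rep(rawFile, length.out = n),
        retentionTime = as.numeric(rt),
        charge = rep(2, length.out = n),
        intensity = rep(1e6, length.out = n),
        pep = rep(pep, length.out = n)))
}

# FeatureSet builder from parallel vectors (NA = absent cell).
makeFeatures <- function(sequence = NA_character_, proteins = "P1",
                         dpBase = NA_character_, dpDelta = NA_real_,
                         dpProb = NA_character_, dpPEP = NA_real_,
                         dpDecoy = FALSE, rawFile = "t1") {
    n <- max(lengths(list(sequence, proteins, dpBase, dpDelta, dpProb,
                          dpPEP, dpDecoy)))
    rec <- function(x) rep(x, length.out = n)
    dpBase <- rec(dpBase); dpDelta <- rec(dpDelta)
    sequence <- rec(sequence)
    new("FeatureSet", DataFrame(
        rawFile = rec(rawFile),
        featureType = ifelse(!is.na(dpBase) & !is.na(dpDelta),
                             "dependent_peptide",
                             ifelse(!is.na(sequence), "base_hit",
                                    "unidentified")),
        sequence = sequence,
        proteins = CharacterList(lapply(rec(proteins), function(p)
            if (is.na(p)) character()
            else strsplit(p, ";", fixed = TRUE)[[1]])),
        dpBaseSequence = dpBase,
        dpMassDifference = dpDelta,
        dpProbabilities = rec(dpProb),
        dpPEP = rec(dpPEP),
        dpDecoy = rec(dpDecoy),
        retentionTime = rec(35.5),
        charge = rec(2),
        intensity = rec(1e6)))
}

# Random key set over a small sequence/delta pool, for set-logic
# property trials.
randomDPs <- function(nMax = 8, seqPool = c("PEK", "AGR", "WLDK", "TTVR",
                                            "MNPQK", "CYSR"),
                      deltaPool = seq(-50, 50, by = 5)) {
    n <- sample(0:nMax, 1)
    if (n == 0) return(makeDPs(character(), numeric()))
    makeDPs(sample(seqPool, n, replace = TRUE),
            sample(deltaPool, n, replace = TRUE) + runif(n, -0.002, 0.002))
}

# Direct membership oracle: does (seq, dm) have a tolerance-match in
# the reference keys? Accepts a DependentPeptideSet or parallel vectors.
keyInSet <- function(seqs, dms, dps, tol) {
    refSeq <- dps$baseSequence
    refDm <- dps$deltaMass
    vapply(seq_along(seqs), function(i)
        any(refSeq == seqs[i] & abs(refDm - dms[i]) <= tol), TRUE)
}

writeToyFasta <- function(path, records) {
    writeLines(unlist(lapply(names(records), function(h)
        c(paste0(">", h), records[[h]]))), path)
}
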