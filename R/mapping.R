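#' @include AllClasses.R
#' @importFrom IRanges start end width
NULL

#' Locate a peptide on the protein by sliding-window search
#'
#' Exact substring search returning every occurrence, including
#' overlapping ones, in ascending start order (1-based inclusive
#' protein coordinates). A peptide longer than the protein, or one that
#' does not occur, yields an empty range set.
#'
#' @param protein a [ProteinSequence-class].
#' @param peptide non-empty peptide string.
#' @return an [IRanges::IRanges] of occurrences.
#' @export
#' @examples
#' p <- new("ProteinSequence", identifier = "X", residues = "AAAA")
#' locatePeptide(p, "AA")  # starts 1, 2, 3
locatePeptide <- function(protein, peptide) {
    stopifnot(is(protein, "ProteinSequence"), is.character(peptide),
              length(peptide) == 1L, nzchar(peptide))
    if (nchar(peptide) > nchar(protein@residues))
        return(IRanges())
    m <- matchPattern(AAString(peptide), AAString(protein@residues))
    IRanges(start = start(m), width = width(m))
}

#' Localise dependent peptides onto the protein
#'
#' Fills the `intervals` column with every occurrence of each DP's base
#' sequence on the protein, and flags peptides mapping to two or more
#' positions as `ambiguous` and peptides mapping nowhere as `unmapped`
#' (these are excluded from plots and site calls, but retained and
#' logged, never silently dropped). Within each interval the per-residue
#' probability vector is addressable in protein coordinates as
#' `protein position = interval start + peptide offset`.
#'
#' @param dps a [DependentPeptideSet-class].
#' @param protein a [ProteinSequence-class].
#' @param verbose message the ambiguous/unmapped counts (default TRUE).
#' @return the set with `intervals` (an `IRangesList`), `ambiguous` and
#'   `unmapped` columns added.
#' @export
localiseDependentPeptides <- function(dps, protein, verbose = TRUE) {
    stopifnot(is(dps, "DependentPeptideSet"), is(protein, "ProteinSequence"))
    ivs <- lapply(dps$baseSequence, function(p) locatePeptide(protein, p))
    nOcc <- lengths(ivs)
    # assign via the parent DFrame: S4Vectors' column replacement on a
    # DFrame subclass mis-dispatches for List-valued columns
    df <- as(dps, "DFrame", strict = TRUE)
    df[["intervals"]] <- IRangesList(ivs)
    df[["ambiguous"]] <- nOcc >= 2L
    df[["unmapped"]] <- nOcc == 0L
    dps <- new(class(dps), df)
    if (verbose && nrow(dps))
        message("localiseDependentPeptides: ", sum(nOcc == 1L),
                " unique, ", sum(dps$ambiguous), " ambiguous, ",
                sum(dps$unmapped), " unmapped of ", nrow(dps), " DPs")
    dps
}

#' Peptide strings observed for a protein
#'
#' Collects the peptide strings used for sequence coverage: base-hit
#' sequences and/or DP base sequences attributed to the protein of
#' interest.
#'
#' @param features a [FeatureSet-class].
#' @param proteinId accession of the protein of interest.
#' @param include which feature classes to use; default both.
#' @return character vector of unique peptide strings.
#' @export
observedPeptides <- function(features, proteinId,
                             include = c("base", "dp")) {
    stopifnot(is(features, "FeatureSet"))
    include <- match.arg(include, several.ok = TRUE)
    ofProtein <- vapply(features$proteins, function(p) proteinId %in% p, TRUE)
    peps <- character()
    if ("base" %in% include)
        peps <- c(peps, features$sequence[ofProtein &
                      features$featureType == "base_hit"])
    if ("dp" %in% include)
        peps <- c(peps, features$dpBaseSequence[ofProtein &
                      features$featureType == "dependent_peptide"])
    unique(peps[!is.na(peps)])
}

#' Compute the coverage mask of a peptide collection
#'
#' @param protein a [ProteinSequence-class].
#' @param peptides character vector of peptide strings.
#' @return logical vector over protein positions, `TRUE` where at least
#'   one occurrence of at least one peptide covers the position.
#' @export
#' @examples
#' p <- new("ProteinSequence", identifier = "X", residues = "ABCDEFG")
#' computeCoverage(p, c("ABC", "EFG"))
computeCoverage <- function(protein, peptides) {
    stopifnot(is(protein, "ProteinSequence"))
    n <- nchar(protein@residues)
    mask <- logical(n)
    for (pep in peptides) {
        iv <- locatePeptide(protein, pep)
        for (k in seq_along(iv))
            mask[start(iv)[k]:end(iv)[k]] <- TRUE
    }
    mask
}

#' Most probable modification sites of a localised DP
#'
#' Returns the protein positions at which the DP's localisation
#' probability attains its maximum. Ties are ordered by a residue-class
#' priority list (e.g. `c("C", "K", "H")` for N-ethylmaleimide
#' chemistry: residues of classes earlier in the list come first),
#' then N-terminal-most first; tied sites are never dropped. The
#' default priority is empty, i.e. pure probability with an N-terminal
#' tie-break.
#'
#' @param dps a localised [DependentPeptideSet-class].
#' @param i row index of the DP to interrogate.
#' @param priority character vector of one-letter residue codes in
#'   decreasing priority.
#' @return integer vector of protein positions (empty when the profile
#'   is all zero).
#' @export
bestSites <- function(dps, i, priority = character()) {
    stopifnot(is(dps, "DependentPeptideSet"),
              "intervals" %in% colnames(dps))
    if (dps$unmapped[i]) stop("DP ", i, " is unmapped")
    if (dps$ambiguous[i])
        stop("DP ", i, " maps ambiguously; site calls need a unique interval")
    probs <- dps$probabilities[[i]]
    m <- max(probs)
    if (m <= 0) return(integer())
    offs <- which(probs == m)
    startPos <- start(dps$intervals[[i]])[1L]
    pos <- startPos + offs - 1L
    res <- strsplit(dps$baseSequence[i], "")[[1L]][offs]
    prio <- match(res, priority)
    prio[is.na(prio)] <- length(priority) + 1L
    pos[order(prio, pos)]
}
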