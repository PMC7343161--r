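#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols isEmpty
#' @importFrom IRanges IRanges IRangesList NumericList CharacterList
NULL

.AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                  "K", "M", "F", "P", "S", "T", "W", "Y", "V",
                  "X", "U", "B", "Z")

#' ProteinSequence: a single protein of interest
#'
#' Holds the amino-acid sequence of the protein that dependent peptides
#' are mapped onto. Positions are 1-based with position 1 the N-terminal
#' residue. `numberingNote` records how the sequence was numbered (for
#' example "mature sequence, no initiator Met"), because mature versus
#' full-length numbering shifts every reported site by one and must never
#' be changed silently.
#'
#' @slot identifier accession string, e.g. a UniProt accession.
#' @slot residues uppercase one-letter amino-acid string.
#' @slot numberingNote free-text note on the numbering convention.
#' @exportClass ProteinSequence
setClass("ProteinSequence",
    representation(identifier = "character",
                   residues = "character",
                   numberingNote = "character"),
    prototype(numberingNote = ""))

setValidity("ProteinSequence", function(object) {
    msg <- character()
    if (length(object@identifier) != 1L || !nzchar(object@identifier))
        msg <- c(msg, "'identifier' must be a single non-empty string")
    if (length(object@residues) != 1L || !nzchar(object@residues))
        msg <- c(msg, "'residues' must be a single non-empty string")
    if (length(object@residues) == 1L && nzchar(object@residues)) {
        letters <- strsplit(object@residues, "")[[1L]]
        bad <- setdiff(unique(letters), .AA_ALPHABET)
        if (length(bad))
            msg <- c(msg, paste0("invalid residue code(s): ",
                                 paste(bad, collapse = ", ")))
    }
    if (length(msg)) msg else TRUE
})

#' LocalisationProfile: per-residue modification probabilities
#'
#' The parsed form of a search engine's annotated probability string such
#' as `"AAC(0.95)DK(0.05)R"`: the plain peptide sequence plus one
#' probability in `[0, 1]` per residue (0 where no annotation was given).
#'
#' @slot sequence plain peptide string (annotations stripped).
#' @slot probabilities numeric vector, one value per residue.
#' @exportClass LocalisationProfile
setClass("LocalisationProfile",
    representation(sequence = "character", probabilities = "numeric"))

setValidity("LocalisationProfile", function(object) {
    msg <- character()
    if (length(object@sequence) != 1L)
        msg <- c(msg, "'sequence' must be a single string")
    else if (length(object@probabilities) != nchar(object@sequence))
        msg <- c(msg, "length(probabilities) must equal nchar(sequence)")
    if (any(object@probabilities < 0 | object@probabilities > 1))
        msg <- c(msg, "probabilities must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' FeatureSet: one row per chromatographic feature
#'
#' A `DataFrame` subclass holding the typed content of a MaxQuant
#' `allPeptides.txt` table: every row is a feature, classified as a
#' `base_hit` (database-search identification), a `dependent_peptide`
#' (row with a DP base sequence and mass difference) or `unidentified`.
#'
#' @exportClass FeatureSet
setClass("FeatureSet", contains = "DFrame")

.FEATURE_COLS <- c("rawFile", "featureType", "sequence", "proteins",
                   "dpBaseSequence", "dpMassDifference", "dpProbabilities",
                   "dpPEP", "dpDecoy", "retentionTime", "charge",
                   "intensity")

setValidity("FeatureSet", function(object) {
    missing <- setdiff(.FEATURE_COLS, colnames(object))
    if (length(missing))
        return(paste0("missing column(s): ", paste(missing, collapse = ", ")))
    if (!all(object$featureType %in%
             c("base_hit", "dependent_peptide", "unidentified")))
        return("featureType must be base_hit/dependent_peptide/unidentified")
    is_dp <- object$featureType == "dependent_peptide"
    has_dp <- !is.na(object$dpBaseSequence) & !is.na(object$dpMassDifference)
    if (!identical(unname(is_dp), unname(has_dp)))
        return(paste0("featureType 'dependent_peptide' must coincide with ",
                      "presence of dpBaseSequence and dpMassDifference"))
    pep <- object$dpPEP
    if (any(!is.na(pep) & (pep < 0 | pep > 1)))
        return("dpPEP must lie in [0, 1] when present")
    TRUE
})

#' DependentPeptideSet: filtered dependent peptides of one protein
#'
#' A `DataFrame` subclass with one row per dependent peptide surviving
#' the filter battery. Columns: `baseSequence`, `deltaMass` (Da, signed),
#' `probabilities` (a `NumericList` aligned to the base sequence),
#' `proteins` (a `CharacterList`), `rawFile`, `retentionTime`, `charge`,
#' `intensity`, `pep`. After localisation, `intervals` (an `IRangesList`
#' of 1-based inclusive protein coordinates), `ambiguous` and `unmapped`
#' are added. The per-rule rejection tally of the filter that produced
#' the set lives in `metadata(x)$rejections`.
#'
#' @exportClass DependentPeptideSet
setClass("DependentPeptideSet", contains = "DFrame")

.DP_COLS <- c("baseSequence", "deltaMass", "probabilities", "proteins",
              "rawFile", "retentionTime", "charge", "intensity", "pep")

setValidity("DependentPeptideSet", function(object) {
    missing <- setdiff(.DP_COLS, colnames(object))
    if (length(missing))
        return(paste0("missing column(s): ", paste(missing, collapse = ", ")))
    if (nrow(object)) {
        np <- lengths(object$probabilities)
        if (!all(np == nchar(object$baseSequence)))
            return("probabilities must have one value per base-sequence residue")
    }
    TRUE
})

#' DeltaMassSpec: an expected mass shift with tolerance
#'
#' Describes a hypothesised modification as a mass shift (Da) with a
#' symmetric matching tolerance. When built from elemental compositions,
#' `added` and `removed` record the provenance and the value is their
#' monoisotopic mass difference; fixed-modification cancellation (e.g.
#' subtracting carbamidomethyl from a cysteine adduct) is expressed by
#' putting the fixed modification's composition in `removed`.
#'
#' @slot value mass shift in Da (signed, full precision).
#' @slot tolerance matching half-width in Da (>= 0).
#' @slot label free-text name.
#' @slot added named integer vector, elemental composition gained.
#' @slot removed named integer vector, elemental composition lost.
#' @exportClass DeltaMassSpec
setClass("DeltaMassSpec",
    representation(value = "numeric", tolerance = "numeric",
                   label = "character", added = "integer",
                   removed = "integer"),
    prototype(tolerance = 0.01, label = "", added = integer(),
              removed = integer()))

setValidity("DeltaMassSpec", function(object) {
    msg <- character()
    if (length(object@value) != 1L || is.na(object@value))
        msg <- c(msg, "'value' must be a single number")
    if (length(object@tolerance) != 1L || is.na(object@tolerance) ||
        object@tolerance < 0)
        msg <- c(msg, "'tolerance' must be a single number >= 0")
    if (length(object@added) || length(object@removed)) {
        expected <- .compositionMass(object@added) -
            .compositionMass(object@removed)
        if (!isTRUE(all.equal(object@value, expected, tolerance = 5e-5)))
            msg <- c(msg, sprintf(
                "value (%.6f) disagrees with mass(added) - mass(removed) (%.6f)",
                object@value, expected))
    }
    if (length(msg)) msg else TRUE
})

#' DeltaMassHistogram: binned mass-shift counts
#'
#' Uniform half-open bins `[edge, edge + width)` over a stated range;
#' values outside the range are tallied in `overflow`, never dropped
#' silently.
#'
#' @slot breaks numeric vector of bin edges, strictly increasing.
#' @slot counts integer vector, one count per bin.
#' @slot overflow integer, number of values outside the range.
#' @exportClass DeltaMassHistogram
setClass("DeltaMassHistogram",
    representation(breaks = "numeric", counts = "integer",
                   overflow = "integer"),
    prototype(overflow = 0L))

setValidity("DeltaMassHistogram", function(object) {
    msg <- character()
    if (length(object@breaks) < 2L || any(diff(object@breaks) <= 0))
        msg <- c(msg, "'breaks' must be strictly increasing, length >= 2")
    if (length(object@counts) != length(object@breaks) - 1L)
        msg <- c(msg, "length(counts) must be length(breaks) - 1")
    if (any(object@counts < 0))
        msg <- c(msg, "counts must be nonnegative")
    if (length(msg)) msg else TRUE
})

#' ProbabilityCanvas: lane-packed probability matrices
#'
#' The matrix pair behind a probability localisation plot: each placed
#' dependent peptide is etched as a contiguous run of ones into one lane
#' of the occupancy matrix, and its localisation probabilities are
#' deposited into the same cells of the probability matrix. Peptides
#' that fit into no lane are listed in `overflow` (the matrices were
#' full), so `placed` and `overflow` always partition the input.
#'
#' @slot occupancy 0/1 matrix, lanes x protein positions.
#' @slot probability numeric matrix of the same shape, values in [0, 1].
#' @slot placed integer indices (into the input set) of placed peptides.
#' @slot lane integer lane assigned to each placed peptide.
#' @slot overflow integer indices of peptides that could not be placed.
#' @slot capacity integer number of lanes.
#' @exportClass ProbabilityCanvas
setClass("ProbabilityCanvas",
    representation(occupancy = "matrix", probability = "matrix",
                   placed = "integer", lane = "integer",
                   overflow = "integer", capacity = "integer"))

setValidity("ProbabilityCanvas", function(object) {
    msg <- character()
    if (!identical(dim(object@occupancy), dim(object@probability)))
        msg <- c(msg, "occupancy and probability must have identical shape")
    if (nrow(object@occupancy) != object@capacity)
        msg <- c(msg, "matrix row count must equal capacity")
    if (length(object@lane) != length(object@placed))
        msg <- c(msg, "one lane per placed peptide required")
    if (length(intersect(object@placed, object@overflow)))
        msg <- c(msg, "placed and overflow must be disjoint")
    if (any(object@probability < 0 | object@probability > 1))
        msg <- c(msg, "probability cells must lie in [0, 1]")
    if (any(object@probability[object@occupancy == 0] != 0))
        msg <- c(msg, "probability must be zero outside occupied cells")
    if (length(msg)) msg else TRUE
})

#' EnrichmentResult: outcome of a DP enrichment run
#'
#' Wraps the output of `none`/`conjoined`/`constantly conjoined`
#' enrichment together with the fold-enrichment of a target mass-shift
#' set. The fold is undefined (and `foldDefined` is `FALSE`) when no
#' pre-enrichment peptide matches any target.
#'
#' @slot mode one of "none", "conjoined", "constantly_conjoined".
#' @slot inputCount number of DPs entering enrichment (treated analysis 1).
#' @slot output the enriched [DependentPeptideSet-class].
#' @slot fold fold-enrichment (NA when undefined).
#' @slot foldDefined logical, whether the fold is defined.
#' @slot targets list of [DeltaMassSpec-class] used for quantification.
#' @exportClass EnrichmentResult
setClass("EnrichmentResult",
    representation(mode = "character", inputCount = "integer",
                   output = "DependentPeptideSet", fold = "numeric",
                   foldDefined = "logical", targets = "list"))

setValidity("EnrichmentResult", function(object) {
    if (!object@mode %in% c("none", "conjoined", "constantly_conjoined"))
        return("mode must be none/conjoined/constantly_conjoined")
    if (nrow(object@output) > object@inputCount)
        return("output cannot exceed the input of the treated analysis")
    TRUE
})

#' FilterConfig: the dependent-peptide filter battery
#'
#' Configuration of the rules that reduce a feature table to the DPs of
#' a protein of interest. Every rule can be disabled. The mass-shift
#' window is inclusive on both bounds; an absent PEP never causes
#' rejection.
#'
#' @slot proteinId accession of the protein of interest.
#' @slot maxAbsDeltaMass Da, window half-width (default 500).
#' @slot maxDpPEP posterior-error-probability ceiling (default 0.01).
#' @slot dropDecoys drop decoy DPs (default TRUE).
#' @slot backgroundExclusions list of [DeltaMassSpec-class] to exclude.
#' @slot requireUniqueProtein require the DP to map to no other protein.
#' @exportClass FilterConfig
setClass("FilterConfig",
    representation(proteinId = "character", maxAbsDeltaMass = "numeric",
                   maxDpPEP = "numeric", dropDecoys = "logical",
                   backgroundExclusions = "list",
                   requireUniqueProtein = "logical"),
    prototype(maxAbsDeltaMass = 500, maxDpPEP = 0.01, dropDecoys = TRUE,
              backgroundExclusions = list(), requireUniqueProtein = FALSE))

setValidity("FilterConfig", function(object) {
    msg <- character()
    if (length(object@proteinId) != 1L || !nzchar(object@proteinId))
        msg <- c(msg, "'proteinId' must be a single non-empty string")
    if (!(object@maxAbsDeltaMass > 0))
        msg <- c(msg, "'maxAbsDeltaMass' must be > 0")
    if (!(object@maxDpPEP > 0 && object@maxDpPEP <= 1))
        msg <- c(msg, "'maxDpPEP' must lie in (0, 1]")
    if (!all(vapply(object@backgroundExclusions, is, TRUE, "DeltaMassSpec")))
        msg <- c(msg, "'backgroundExclusions' must contain DeltaMassSpec objects")
    if (length(msg)) msg else TRUE
})
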