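#' @include AllClasses.R
NULL

#' Accessors for dpvis classes
#'
#' Small accessor generics: `identifier()` and `residues()` for
#' [ProteinSequence-class]; `profileSequence()` and `probabilities()` for
#' [LocalisationProfile-class]; `specValue()`, `specTolerance()` and
#' `specLabel()` for [DeltaMassSpec-class]; `histCounts()`,
#' `histBreaks()` and `histOverflow()` for [DeltaMassHistogram-class];
#' `placedIndices()`, `overflowIndices()` for [ProbabilityCanvas-class];
#' `enrichedSet()`, `foldValue()` and `foldDefined()` for
#' [EnrichmentResult-class].
#'
#' @param x an object of the relevant class.
#' @return the slot value.
#' @name dpvis-accessors
#' @aliases identifier residues numberingNote profileSequence
#'   probabilities specValue specTolerance specLabel histCounts
#'   histBreaks histOverflow placedIndices overflowIndices laneOf
#'   enrichedSet foldValue foldDefined
NULL

#' @rdname dpvis-accessors
#' @export
setGeneric("identifier", function(x) standardGeneric("identifier"))
#' @rdname dpvis-accessors
#' @export
setGeneric("residues", function(x) standardGeneric("residues"))
#' @rdname dpvis-accessors
#' @export
setGeneric("numberingNote", function(x) standardGeneric("numberingNote"))
#' @rdname dpvis-accessors
#' @export
setGeneric("profileSequence", function(x) standardGeneric("profileSequence"))
#' @rdname dpvis-accessors
#' @export
setGeneric("probabilities", function(x) standardGeneric("probabilities"))
#' @rdname dpvis-accessors
#' @export
setGeneric("specValue", function(x) standardGeneric("specValue"))
#' @rdname dpvis-accessors
#' @export
setGeneric("specTolerance", function(x) standardGeneric("specTolerance"))
#' @rdname dpvis-accessors
#' @export
setGeneric("specLabel", function(x) standardGeneric("specLabel"))
#' @rdname dpvis-accessors
#' @export
setGeneric("histCounts", function(x) standardGeneric("histCounts"))
#' @rdname dpvis-accessors
#' @export
setGeneric("histBreaks", function(x) standardGeneric("histBreaks"))
#' @rdname dpvis-accessors
#' @export
setGeneric("histOverflow", function(x) standardGeneric("histOverflow"))
#' @rdname dpvis-accessors
#' @export
setGeneric("placedIndices", function(x) standardGeneric("placedIndices"))
#' @rdname dpvis-accessors
#' @export
setGeneric("overflowIndices", function(x) standardGeneric("overflowIndices"))
#' @rdname dpvis-accessors
#' @export
setGeneric("laneOf", function(x) standardGeneric("laneOf"))
#' @rdname dpvis-accessors
#' @export
setGeneric("enrichedSet", function(x) standardGeneric("enrichedSet"))
#' @rdname dpvis-accessors
#' @export
setGeneric("foldValue", function(x) standardGeneric("foldValue"))
#' @rdname dpvis-accessors
#' @export
setGeneric("foldDefined", function(x) standardGeneric("foldDefined"))

#' @rdname dpvis-accessors
setMethod("identifier", "ProteinSequence", function(x) x@identifier)
#' @rdname dpvis-accessors
setMethod("residues", "ProteinSequence", function(x) x@residues)
#' @rdname dpvis-accessors
setMethod("numberingNote", "ProteinSequence", function(x) x@numberingNote)

#' @describeIn dpvis-accessors protein length in residues.
#' @exportMethod nchar
setMethod("nchar", "ProteinSequence", function(x) nchar(x@residues))

#' @rdname dpvis-accessors
setMethod("profileSequence", "LocalisationProfile", function(x) x@sequence)
#' @rdname dpvis-accessors
setMethod("probabilities", "LocalisationProfile", function(x) x@probabilities)

#' @rdname dpvis-accessors
setMethod("specValue", "DeltaMassSpec", function(x) x@value)
#' @rdname dpvis-accessors
setMethod("specTolerance", "DeltaMassSpec", function(x) x@tolerance)
#' @rdname dpvis-accessors
setMethod("specLabel", "DeltaMassSpec", function(x) x@label)

#' @rdname dpvis-accessors
setMethod("histCounts", "DeltaMassHistogram", function(x) x@counts)
#' @rdname dpvis-accessors
setMethod("histBreaks", "DeltaMassHistogram", function(x) x@breaks)
#' @rdname dpvis-accessors
setMethod("histOverflow", "DeltaMassHistogram", function(x) x@overflow)

#' @rdname dpvis-accessors
setMethod("placedIndices", "ProbabilityCanvas", function(x) x@placed)
#' @rdname dpvis-accessors
setMethod("overflowIndices", "ProbabilityCanvas", function(x) x@overflow)
#' @rdname dpvis-accessors
setMethod("laneOf", "ProbabilityCanvas", function(x) x@lane)

#' @rdname dpvis-accessors
setMethod("enrichedSet", "EnrichmentResult", function(x) x@output)
#' @rdname dpvis-accessors
setMethod("foldValue", "EnrichmentResult", function(x) x@fold)
#' @rdname dpvis-accessors
setMethod("foldDefined", "EnrichmentResult", function(x) x@foldDefined)

setMethod("show", "ProteinSequence", function(object) {
    cat(sprintf("ProteinSequence %s: %d aa", object@identifier,
                nchar(object@residues)))
    if (nzchar(object@numberingNote))
        cat(sprintf(" (%s)", object@numberingNote))
    cat("\n")
    head <- substr(object@residues, 1L, 60L)
    cat("  ", head, if (nchar(object@residues) > 60L) "..." else "", "\n",
        sep = "")
})

setMethod("show", "LocalisationProfile", function(object) {
    nz <- which(object@probabilities > 0)
    cat(sprintf("LocalisationProfile %s: %d site(s) annotated\n",
                object@sequence, length(nz)))
    if (length(nz)) {
        res <- strsplit(object@sequence, "")[[1L]][nz]
        cat("  ", paste0(res, nz, "=", signif(object@probabilities[nz], 3),
                         collapse = " "), "\n", sep = "")
    }
})

setMethod("show", "DeltaMassSpec", function(object) {
    cat(sprintf("DeltaMassSpec %s: %+.2f ± %.3g Da",
                if (nzchar(object@label)) object@label else "<unlabelled>",
                roundHalfUp(object@value, 2), object@tolerance))
    fmt <- function(comp) paste0(names(comp), ifelse(comp == 1L, "", comp),
                                 collapse = "")
    if (length(object@added) || length(object@removed))
        cat(sprintf("  [added %s; removed %s]",
                    if (length(object@added)) fmt(object@added) else "-",
                    if (length(object@removed)) fmt(object@removed) else "-"))
    cat("\n")
})

setMethod("show", "DeltaMassHistogram", function(object) {
    cat(sprintf(
        "DeltaMassHistogram: %d bins over [%g, %g), %d value(s), %d overflow\n",
        length(object@counts), min(object@breaks), max(object@breaks),
        sum(object@counts), object@overflow))
})

setMethod("show", "ProbabilityCanvas", function(object) {
    cat(sprintf(
        "ProbabilityCanvas: %d lanes x %d positions; %d placed, %d overflow\n",
        nrow(object@occupancy), ncol(object@occupancy),
        length(object@placed), length(object@overflow)))
})

setMethod("show", "EnrichmentResult", function(object) {
    cat(sprintf("EnrichmentResult (%s): %d -> %d DPs", object@mode,
                object@inputCount, nrow(object@output)))
    if (object@foldDefined)
        cat(sprintf("; fold-enrichment %.3g", object@fold))
    else
        cat("; fold-enrichment undefined (no pre-enrichment target match)")
    cat("\n")
})

setMethod("show", "FilterConfig", function(object) {
    cat(sprintf(
        "FilterConfig: protein %s, |dm| <= %g Da, PEP <= %g, decoys %s,\n",
        object@proteinId, object@maxAbsDeltaMass, object@maxDpPEP,
        if (object@dropDecoys) "dropped" else "kept"))
    cat(sprintf("  %d background exclusion(s), unique-protein %s\n",
                length(object@backgroundExclusions),
                if (object@requireUniqueProtein) "required" else "not required"))
})
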