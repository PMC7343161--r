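#' @include AllClasses.R masses.R
NULL

# For every row of 'a', is there a row of 'b' with the same base
# sequence and |delta m difference| <= tol (and, optionally, retention
# time within rtTolerance)? Matching is pairwise against 'b', never by
# clustering: tolerance matching is not transitive and must not be made
# to look as if it were.
.keyMatched <- function(a, b, tol, rtTolerance = Inf) {
    if (!nrow(a)) return(logical())
    if (!nrow(b)) return(rep(FALSE, nrow(a)))
    aSeq <- a$baseSequence; aDm <- a$deltaMass
    bSeq <- b$baseSequence; bDm <- b$deltaMass
    useRt <- is.finite(rtTolerance)
    if (useRt) { aRt <- a$retentionTime; bRt <- b$retentionTime }
    bBySeq <- split(seq_along(bSeq), bSeq)
    vapply(seq_along(aSeq), function(i) {
        js <- bBySeq[[aSeq[i]]]
        if (is.null(js)) return(FALSE)
        ok <- abs(bDm[js] - aDm[i]) <= tol
        if (useRt) ok <- ok & abs(bRt[js] - aRt[i]) <= rtTolerance
        any(ok)
    }, TRUE)
}

#' Conjoined DPs: treated minus untreated
#'
#' Subtracts the DPs observed in an untreated analysis from those of a
#' treated analysis. A DP is a combination of base sequence and mass
#' shift: two DPs match when their sequences are identical and their
#' mass shifts differ by at most `matchTolerance` (pairwise, symmetric,
#' inclusive). Retention time is not part of the key by default;
#' `rtTolerance` adds an RT window to the match if wanted.
#'
#' @param treated,untreated [DependentPeptideSet-class] objects from
#'   comparable, already-filtered searches.
#' @param matchTolerance Da (default 0.01).
#' @param rtTolerance minutes; `Inf` (default) ignores retention time.
#' @return the treated DPs whose key matches no untreated DP.
#' @export
conjoin <- function(treated, untreated, matchTolerance = 0.01,
                    rtTolerance = Inf) {
    stopifnot(is(treated, "DependentPeptideSet"),
              is(untreated, "DependentPeptideSet"))
    matched <- .keyMatched(treated, untreated, matchTolerance, rtTolerance)
    treated[!matched, , drop = FALSE]
}

#' Constantly conjoined DPs across replicates
#'
#' DPs observed in every treated replicate and in no untreated
#' replicate. Each surviving DP is represented by its record in treated
#' replicate 1 (matching how counts are reported for "analysis 1").
#'
#' @param treatedReps list of >= 2 [DependentPeptideSet-class] objects.
#' @param untreatedReps list of >= 0 such objects.
#' @param matchTolerance Da (default 0.01).
#' @param rtTolerance minutes; `Inf` (default) ignores retention time.
#' @return subset of `treatedReps[[1]]`.
#' @export
constantConjoin <- function(treatedReps, untreatedReps = list(),
                            matchTolerance = 0.01, rtTolerance = Inf) {
    stopifnot(is.list(treatedReps), is.list(untreatedReps))
    if (length(treatedReps) < 2L)
        stop("constant conjunction requires >= 2 treated replicates")
    rep1 <- treatedReps[[1L]]
    keep <- rep(TRUE, nrow(rep1))
    for (tr in treatedReps[-1L])
        keep <- keep & .keyMatched(rep1, tr, matchTolerance, rtTolerance)
    for (un in untreatedReps)
        keep <- keep & !.keyMatched(rep1, un, matchTolerance, rtTolerance)
    rep1[keep, , drop = FALSE]
}

#' Fold-enrichment of target mass shifts
#'
#' Enrichment is quantified as the increase in the percentage of DPs
#' whose mass shift matches any target specification: the fold is
#' `pct(after) / pct(before)`. When no pre-enrichment DP matches a
#' target the fold is undefined and reported as such (`defined =
#' FALSE`), never as a number; an empty `after` set against a nonzero
#' denominator gives fold 0.
#'
#' @param before the pre-enrichment [DependentPeptideSet-class]
#'   (non-empty).
#' @param after the post-enrichment set.
#' @param targets list of [DeltaMassSpec-class].
#' @return list with `fold` (numeric, `NA` when undefined), `defined`
#'   (logical), `pctBefore`, `pctAfter` (percentages) and the matched
#'   counts `nBefore`, `nAfter`.
#' @export
#' @examples
#' # 2 of 20 match before (10%), 4 of 10 after (40%): fold 4
foldEnrichment <- function(before, after, targets) {
    stopifnot(is(before, "DependentPeptideSet"),
              is(after, "DependentPeptideSet"), nrow(before) > 0L,
              is.list(targets), length(targets) > 0L)
    mb <- .matchAnyDelta(before$deltaMass, targets)
    ma <- .matchAnyDelta(after$deltaMass, targets)
    pctBefore <- 100 * sum(mb) / nrow(before)
    pctAfter <- if (nrow(after)) 100 * sum(ma) / nrow(after) else 0
    if (pctBefore == 0)
        return(list(fold = NA_real_, defined = FALSE, pctBefore = 0,
                    pctAfter = pctAfter, nBefore = 0L, nAfter = sum(ma)))
    list(fold = pctAfter / pctBefore, defined = TRUE, pctBefore = pctBefore,
         pctAfter = pctAfter, nBefore = sum(mb), nAfter = sum(ma))
}

#' Run an enrichment mode over treated/untreated analyses
#'
#' Dispatches to no enrichment (treated analysis 1 as-is), conjunction
#' (analysis 1 of treated minus analysis 1 of untreated) or constant
#' conjunction (all treated, no untreated), and quantifies the
#' fold-enrichment of the target specs relative to treated analysis 1.
#'
#' @param treatedReps list of filtered [DependentPeptideSet-class]
#'   objects (treated replicates, analysis 1 first).
#' @param untreatedReps list of untreated replicates.
#' @param mode "none", "conjoined" or "constantly_conjoined".
#' @param targets list of [DeltaMassSpec-class] for quantification
#'   (may be empty; the fold is then undefined).
#' @param matchTolerance Da (default 0.01).
#' @param verbose message counts and fold (default TRUE).
#' @return an [EnrichmentResult-class].
#' @export
enrichDependentPeptides <- function(treatedReps, untreatedReps = list(),
                                    mode = c("none", "conjoined",
                                             "constantly_conjoined"),
                                    targets = list(), matchTolerance = 0.01,
                                    verbose = TRUE) {
    mode <- match.arg(mode)
    if (!is.list(treatedReps)) treatedReps <- list(treatedReps)
    if (!is.list(untreatedReps)) untreatedReps <- list(untreatedReps)
    if (!length(treatedReps)) stop("at least one treated analysis required")
    rep1 <- treatedReps[[1L]]
    out <- switch(mode,
        none = rep1,
        conjoined = {
            if (!length(untreatedReps))
                stop("conjunction requires an untreated analysis")
            conjoin(rep1, untreatedReps[[1L]], matchTolerance)
        },
        constantly_conjoined = constantConjoin(treatedReps, untreatedReps,
                                               matchTolerance))
    fe <- if (length(targets) && nrow(rep1))
        foldEnrichment(rep1, out, targets)
    else list(fold = NA_real_, defined = FALSE)
    if (verbose)
        message("enrichDependentPeptides (", mode, "): ", nrow(rep1),
                " -> ", nrow(out), " DPs",
                if (fe$defined) sprintf("; fold %.3g", fe$fold)
                else "; fold undefined")
    new("EnrichmentResult", mode = mode, inputCount = nrow(rep1),
        output = out, fold = fe$fold, foldDefined = fe$defined,
        targets = targets)
}
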