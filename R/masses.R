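#' @include AllClasses.R
NULL

# Monoisotopic atomic masses (Da), >= 6 decimal places.
.MONOISOTOPIC <- c(
    H  = 1.0078250319,
    C  = 12.0000000000,
    N  = 14.0030740052,
    O  = 15.9949146221,
    S  = 31.9720706900,
    P  = 30.9737615100,
    Na = 22.9897696700,
    K  = 38.9637069000,
    Cl = 34.9688527100,
    F  = 18.9984031630,
    Se = 79.9165218000,
    Fe = 55.9349421000,
    I  = 126.9044730000
)

#' Round half away from zero
#'
#' Mass shifts are displayed rounded to two decimal places with halves
#' rounded up in magnitude (so 125.045 displays as 125.05, not 125.04 as
#' banker's rounding would give). Comparisons always use full precision;
#' this is a display convention only.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' roundHalfUp(125.045, 2)  # 125.05
#' roundHalfUp(-25.0316, 2) # -25.03
roundHalfUp <- function(x, digits = 2L) {
    f <- 10^digits
    sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Parse a molecular formula
#'
#' Accepts Hill-style formulas such as `"C6H7NO2"`; `"+"` joins summed
#' parts (`"C6H7NO2+H2O"`). Element symbols are one uppercase letter
#' optionally followed by one lowercase letter; counts default to 1.
#'
#' @param formula a formula string, or a named numeric vector which is
#'   returned coerced to integer counts.
#' @return named integer vector mapping element symbol to count.
#' @export
#' @examples
#' parseFormula("C6H7NO2")
#' parseFormula("C6H7NO2+H2O")
parseFormula <- function(formula) {
    if (is.numeric(formula)) {
        if (is.null(names(formula)) || any(!nzchar(names(formula))))
            stop("numeric composition must be fully named")
        counts <- as.integer(formula)
        names(counts) <- names(formula)
        return(.mergeComposition(counts, integer()))
    }
    stopifnot(is.character(formula), length(formula) == 1L)
    total <- integer()
    for (part in strsplit(formula, "+", fixed = TRUE)[[1L]]) {
        part <- trimws(part)
        if (!nzchar(part)) next
        tokens <- gregexpr("[A-Z][a-z]?[0-9]*", part)[[1L]]
        matched <- regmatches(part, list(tokens))[[1L]]
        if (!length(matched) || sum(attr(tokens, "match.length")) != nchar(part))
            stop("cannot parse formula: '", part, "'")
        elems <- sub("[0-9]*$", "", matched)
        counts <- sub("^[A-Za-z]+", "", matched)
        counts <- as.integer(ifelse(nzchar(counts), counts, "1"))
        names(counts) <- elems
        total <- .mergeComposition(total, counts)
    }
    total
}

.mergeComposition <- function(a, b) {
    elems <- union(names(a), names(b))
    out <- integer(length(elems))
    names(out) <- elems
    out[names(a)] <- out[names(a)] + a
    out[names(b)] <- out[names(b)] + b
    if (any(out < 0)) stop("element counts must be nonnegative")
    out[out > 0L]
}

.compositionMass <- function(comp) {
    if (!length(comp)) return(0)
    unknown <- setdiff(names(comp), names(.MONOISOTOPIC))
    if (length(unknown))
        stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
    sum(.MONOISOTOPIC[names(comp)] * comp)
}

#' Monoisotopic mass of an elemental composition
#'
#' @param comp a formula string (see [parseFormula()]) or a named
#'   integer vector of element counts.
#' @return monoisotopic mass in Da.
#' @export
#' @examples
#' compositionMass("H2O")      # 18.0106
#' compositionMass("C6H7NO2")  # 125.0477, the N-ethylsuccinimidyl group
compositionMass <- function(comp) {
    .compositionMass(parseFormula(comp))
}

#' Construct an expected mass-shift specification
#'
#' Either give `value` directly, or give `added`/`removed` compositions
#' from which the value is computed as `mass(added) - mass(removed)`.
#' Removing a composition expresses fixed-modification cancellation: a
#' cysteine adduct observed against a carbamidomethylated base peptide
#' has the carbamidomethyl group (`C2H3NO`) in `removed`.
#'
#' @param value mass shift in Da; computed from compositions if missing.
#' @param tolerance symmetric matching tolerance in Da (default 0.01).
#' @param label free-text name.
#' @param added,removed formula strings or named count vectors.
#' @return a [DeltaMassSpec-class].
#' @export
#' @examples
#' deltaMassSpec(added = "C6H7NO2", label = "NESyl")            # +125.05
#' deltaMassSpec(added = "C6H7NO2+H2O", removed = "C2H3NO")     # +86.04
#' deltaMassSpec(value = 390.10, tolerance = 0.01, label = "sulfo-HDMP")
deltaMassSpec <- function(value, tolerance = 0.01, label = "",
                          added = NULL, removed = NULL) {
    addedC <- if (is.null(added)) integer() else parseFormula(added)
    removedC <- if (is.null(removed)) integer() else parseFormula(removed)
    if (missing(value)) {
        if (!length(addedC) && !length(removedC))
            stop("give either 'value' or at least one composition")
        value <- .compositionMass(addedC) - .compositionMass(removedC)
    }
    new("DeltaMassSpec", value = as.numeric(value),
        tolerance = as.numeric(tolerance), label = as.character(label),
        added = addedC, removed = removedC)
}

#' Expected mass shift from added and removed compositions
#'
#' @param added,removed formula strings or named count vectors; either
#'   may be empty (`NULL`).
#' @param tolerance matching tolerance in Da.
#' @param label free-text name.
#' @return a [DeltaMassSpec-class] whose value is
#'   `mass(added) - mass(removed)` at full precision.
#' @export
#' @examples
#' expectedDeltaMass("C6H7NO2+H2O", "C2H3NO", label = "hydrolysed NESyl on Cys")
expectedDeltaMass <- function(added = NULL, removed = NULL, tolerance = 0.01,
                              label = "") {
    deltaMassSpec(tolerance = tolerance, label = label, added = added,
                  removed = removed)
}

#' Built-in modification compositions
#'
#' Named [DeltaMassSpec-class] objects for the chemistry this toolkit
#' was exercised on: N-ethylmaleimide Michael adducts (NESyl,
#' `C6H7NO2`), their hydrolysis products (+`H2O`), the cysteine-fixed
#' modifications that cancel in a dependent peptide's mass shift
#' (carbamidomethyl `C2H3NO`, pyridylethyl `C7H7N`), cysteine oxidation
#' to the sulfinic acid against a carbamidomethylated base (`O2` added,
#' `C2H3NO` removed), and the monomethyl fumarate adduct against a
#' pyridylethylated base (`C5H6O4` added, `C7H7N` removed).
#'
#' @param tolerance matching tolerance in Da applied to every spec.
#' @return named list of [DeltaMassSpec-class].
#' @export
#' @examples
#' sapply(builtinModifications(), specValue)
builtinModifications <- function(tolerance = 0.01) {
    list(
        nesyl = deltaMassSpec(added = "C6H7NO2", tolerance = tolerance,
                              label = "NESyl"),
        water = deltaMassSpec(added = "H2O", tolerance = tolerance,
                              label = "hydrolysis water"),
        nesyl_hydrolysed = deltaMassSpec(added = "C6H7NO2+H2O",
                                         tolerance = tolerance,
                                         label = "hydrolysed NESyl"),
        carbamidomethyl = deltaMassSpec(added = "C2H3NO",
                                        tolerance = tolerance,
                                        label = "carbamidomethyl"),
        pyridylethyl = deltaMassSpec(added = "C7H7N", tolerance = tolerance,
                                     label = "pyridylethyl"),
        nesyl_cys = deltaMassSpec(added = "C6H7NO2", removed = "C2H3NO",
                                  tolerance = tolerance,
                                  label = "NESyl on carbamidomethyl-Cys"),
        nesyl_hydrolysed_cys = deltaMassSpec(added = "C6H7NO2+H2O",
                                             removed = "C2H3NO",
                                             tolerance = tolerance,
                                             label = "hydrolysed NESyl on carbamidomethyl-Cys"),
        cys_sulfinic = deltaMassSpec(added = "O2", removed = "C2H3NO",
                                     tolerance = tolerance,
                                     label = "sulfinic acid on carbamidomethyl-Cys"),
        mmf_cys = deltaMassSpec(added = "C5H6O4", removed = "C7H7N",
                                tolerance = tolerance,
                                label = "monomethyl fumarate on pyridylethyl-Cys")
    )
}

#' Match a mass shift against a specification
#'
#' @param deltaMass numeric vector of observed mass shifts (Da).
#' @param spec a [DeltaMassSpec-class].
#' @return logical vector: `TRUE` where
#'   `|deltaMass - value| <= tolerance` (bounds inclusive).
#' @export
#' @examples
#' spec <- deltaMassSpec(value = 143.06, tolerance = 0.01)
#' matchDelta(c(143.058, 143.08), spec)  # TRUE FALSE
matchDelta <- function(deltaMass, spec) {
    stopifnot(is(spec, "DeltaMassSpec"))
    abs(deltaMass - spec@value) <= spec@tolerance
}

.matchAnyDelta <- function(deltaMass, specs) {
    if (!length(specs)) return(rep(FALSE, length(deltaMass)))
    Reduce(`|`, lapply(specs, function(s) matchDelta(deltaMass, s)))
}

#' Bin mass shifts into a frequency histogram
#'
#' Uniform half-open bins `[edge, edge + width)` over `range`. Values
#' outside the range (including a value exactly at the upper limit) are
#' counted in the overflow tally rather than dropped.
#'
#' @param deltas numeric vector of mass shifts (Da).
#' @param binWidth bin width in Da (default 1).
#' @param range length-2 numeric `(lo, hi)`, default `c(-500, 500)`.
#' @return a [DeltaMassHistogram-class].
#' @export
#' @examples
#' h <- buildHistogram(c(1.2, 1.7, 2.2), binWidth = 1, range = c(0, 3))
#' histCounts(h)  # 0 2 1
buildHistogram <- function(deltas, binWidth = 1, range = c(-500, 500)) {
    stopifnot(binWidth > 0, length(range) == 2L, range[1L] < range[2L])
    breaks <- seq(range[1L], range[2L], by = binWidth)
    if (breaks[length(breaks)] < range[2L])
        breaks <- c(breaks, range[2L])
    inside <- deltas >= range[1L] & deltas < range[2L]
    idx <- findInterval(deltas[inside], breaks, rightmost.closed = FALSE)
    counts <- tabulate(idx, nbins = length(breaks) - 1L)
    new("DeltaMassHistogram", breaks = breaks, counts = as.integer(counts),
        overflow = sum(!inside))
}

#' Spearman similarity of two mass-shift histograms
#'
#' Rank-correlates the per-bin counts of two histograms built over
#' identical bins (via [stats::cor.test()], Spearman method with
#' average-rank tie handling). If either count vector is constant the
#' correlation is undefined and reported as such rather than as a
#' number.
#'
#' @param h1,h2 [DeltaMassHistogram-class] objects with identical breaks.
#' @return list with elements `rho` (numeric, `NA` when undefined),
#'   `defined` (logical), `nBins` and `pValue` (`NA` when undefined).
#' @export
#' @examples
#' h <- buildHistogram(c(1.5, 1.6, 2.5), binWidth = 1, range = c(0, 4))
#' histogramSimilarity(h, h)$rho  # 1
histogramSimilarity <- function(h1, h2) {
    stopifnot(is(h1, "DeltaMassHistogram"), is(h2, "DeltaMassHistogram"))
    if (!isTRUE(all.equal(h1@breaks, h2@breaks)))
        stop("histograms must share identical bin edges")
    x <- as.numeric(h1@counts)
    y <- as.numeric(h2@counts)
    if (length(unique(x)) < 2L || length(unique(y)) < 2L)
        return(list(rho = NA_real_, defined = FALSE, nBins = length(x),
                    pValue = NA_real_))
    ct <- suppressWarnings(
        stats::cor.test(x, y, method = "spearman", exact = FALSE))
    list(rho = unname(ct$estimate), defined = TRUE, nBins = length(x),
         pValue = ct$p.value)
}

#' Parse a target mass-shift specification string
#'
#' Grammar (used on the command line and in config files):
#' \preformatted{
#'   label:+143.06±0.01
#'   label:+143.06+-0.01
#'   label:add=C6H7NO2+H2O,remove=C2H3NO,tol=0.01
#' }
#' The first form is a literal value with tolerance (`±` and `+-` are
#' interchangeable; tolerance defaults to 0.01 Da when omitted). The
#' second derives the value from compositions; `remove=` and `tol=` are
#' optional.
#'
#' @param text one specification string.
#' @return a [DeltaMassSpec-class].
#' @export
#' @examples
#' parseTargetSpec("hydrolysed-nesyl:+143.06+-0.01")
#' parseTargetSpec("nesyl-cys:add=C6H7NO2,remove=C2H3NO,tol=0.01")
parseTargetSpec <- function(text) {
    stopifnot(is.character(text), length(text) == 1L)
    colon <- regexpr(":", text, fixed = TRUE)
    if (colon < 0L) stop("target spec must be 'label:<spec>': ", text)
    label <- substr(text, 1L, colon - 1L)
    body <- substring(text, colon + 1L)
    if (!nzchar(label) || !nzchar(body))
        stop("target spec must be 'label:<spec>': ", text)
    if (grepl("=", body, fixed = TRUE)) {
        fields <- strsplit(body, ",", fixed = TRUE)[[1L]]
        kv <- strsplit(fields, "=", fixed = TRUE)
        if (any(lengths(kv) != 2L))
            stop("malformed composition spec: ", body)
        keys <- vapply(kv, `[`, "", 1L)
        vals <- vapply(kv, `[`, "", 2L)
        bad <- setdiff(keys, c("add", "remove", "tol"))
        if (length(bad))
            stop("unknown key(s) in target spec: ", paste(bad, collapse = ", "))
        tol <- if ("tol" %in% keys) as.numeric(vals[keys == "tol"][1L]) else 0.01
        deltaMassSpec(tolerance = tol, label = label,
                      added = if ("add" %in% keys) vals[keys == "add"][1L],
                      removed = if ("remove" %in% keys) vals[keys == "remove"][1L])
    } else {
        body2 <- gsub("±", "+-", body)
        parts <- strsplit(body2, "+-", fixed = TRUE)[[1L]]
        value <- suppressWarnings(as.numeric(parts[1L]))
        if (is.na(value)) stop("malformed value in target spec: ", body)
        tol <- if (length(parts) > 1L) suppressWarnings(as.numeric(parts[2L]))
               else 0.01
        if (is.na(tol)) stop("malformed tolerance in target spec: ", body)
        deltaMassSpec(value = value, tolerance = tol, label = label)
    }
}
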