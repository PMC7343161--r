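#' @include AllClasses.R masses.R
NULL

#' Build a filter configuration
#'
#' @param proteinId accession of the protein of interest.
#' @param maxAbsDeltaMass mass-shift window half-width in Da (default
#'   500, inclusive on both bounds); `Inf` disables the rule.
#' @param maxDpPEP posterior-error-probability ceiling (default 0.01);
#'   1 disables the rule; peptides with no PEP are never rejected by it.
#' @param dropDecoys drop decoy DPs (default TRUE).
#' @param backgroundExclusions list of [DeltaMassSpec-class]; DPs whose
#'   mass shift matches any of them are rejected (default none).
#' @param requireUniqueProtein reject DPs shared with other proteins
#'   (default FALSE: shared peptides, e.g. between haemoglobin chains,
#'   survive and are disambiguated downstream).
#' @return a [FilterConfig-class].
#' @export
#' @examples
#' filterConfig("P02768", maxAbsDeltaMass = 500, maxDpPEP = 0.01)
filterConfig <- function(proteinId, maxAbsDeltaMass = 500, maxDpPEP = 0.01,
                         dropDecoys = TRUE, backgroundExclusions = list(),
                         requireUniqueProtein = FALSE) {
    new("FilterConfig", proteinId = proteinId,
        maxAbsDeltaMass = maxAbsDeltaMass, maxDpPEP = maxDpPEP,
        dropDecoys = dropDecoys, backgroundExclusions = backgroundExclusions,
        requireUniqueProtein = requireUniqueProtein)
}

#' Read a filter configuration from a key-value file
#'
#' Plain `key = value` lines (`#` comments allowed). Recognised keys:
#' `protein_id`, `max_abs_delta_mass`, `max_dp_pep`, `drop_decoys`
#' (true/false), `require_unique_protein`, and repeatable
#' `background_exclusion` lines in [parseTargetSpec()] grammar.
#'
#' @param path config file.
#' @return a [FilterConfig-class].
#' @export
readFilterConfig <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(sub("#.*$", "", lines))
    lines <- lines[nzchar(lines)]
    kv <- regmatches(lines, regexec("^([A-Za-z_]+)[[:space:]]*=[[:space:]]*(.*)$",
                                    lines))
    if (any(lengths(kv) != 3L))
        stop("malformed config line: ", lines[which(lengths(kv) != 3L)[1L]])
    keys <- vapply(kv, `[`, "", 2L)
    vals <- vapply(kv, `[`, "", 3L)
    get1 <- function(key, default) if (key %in% keys) vals[keys == key][1L]
                                   else default
    asFlag <- function(x) tolower(x) %in% c("true", "yes", "1", "on")
    if (!"protein_id" %in% keys) stop("config must set protein_id")
    filterConfig(
        proteinId = get1("protein_id", NA_character_),
        maxAbsDeltaMass = as.numeric(get1("max_abs_delta_mass", "500")),
        maxDpPEP = as.numeric(get1("max_dp_pep", "0.01")),
        dropDecoys = asFlag(get1("drop_decoys", "true")),
        requireUniqueProtein = asFlag(get1("require_unique_protein", "false")),
        backgroundExclusions = lapply(vals[keys == "background_exclusion"],
                                      parseTargetSpec))
}

.emptyDPSet <- function() {
    new("DependentPeptideSet", DataFrame(
        baseSequence = character(),
        deltaMass = numeric(),
        probabilities = NumericList(),
        proteins = CharacterList(),
        rawFile = character(),
        retentionTime = numeric(),
        charge = numeric(),
        intensity = numeric(),
        pep = numeric()))
}

#' Filter a feature table down to the DPs of one protein
#'
#' Applies the filter battery in order: (1) keep dependent-peptide rows
#' only; (2) drop decoys (if `dropDecoys`); (3) drop DPs whose PEP
#' exceeds `maxDpPEP` (absent PEP never rejects); (4) keep DPs listing
#' the protein of interest (and only it, if `requireUniqueProtein`);
#' (5) keep `|delta m| <= maxAbsDeltaMass` (inclusive); (6) drop DPs
#' matching any background-exclusion spec. Survivor order is preserved
#' and a per-rule rejection tally is recorded in
#' `metadata(result)$rejections` and emitted as a message.
#'
#' @param features a [FeatureSet-class] from [readAllPeptides()].
#' @param config a [FilterConfig-class].
#' @param verbose emit the tally as a message (default TRUE).
#' @return a [DependentPeptideSet-class]; probability strings are parsed
#'   into per-residue vectors (all-zero when no string was reported).
#' @export
filterDependentPeptides <- function(features, config, verbose = TRUE) {
    stopifnot(is(config, "FilterConfig"))
    if (is(features, "DependentPeptideSet"))
        return(.refilterDPSet(features, config, verbose))
    stopifnot(is(features, "FeatureSet"))
    n <- nrow(features)
    tally <- c(not_dp = 0L, decoy = 0L, pep = 0L, protein = 0L,
               window = 0L, background = 0L)
    alive <- rep(TRUE, n)

    reject <- function(alive, bad, rule) {
        bad <- alive & bad
        tally[rule] <<- tally[rule] + sum(bad)
        alive & !bad
    }

    alive <- reject(alive, features$featureType != "dependent_peptide",
                    "not_dp")
    if (config@dropDecoys)
        alive <- reject(alive, features$dpDecoy %in% TRUE, "decoy")
    pep <- features$dpPEP
    alive <- reject(alive, !is.na(pep) & pep > config@maxDpPEP, "pep")
    hasProt <- vapply(features$proteins, function(p)
        config@proteinId %in% p, TRUE)
    if (config@requireUniqueProtein)
        hasProt <- hasProt & lengths(features$proteins) == 1L
    alive <- reject(alive, !hasProt, "protein")
    dm <- features$dpMassDifference
    alive <- reject(alive, !is.na(dm) & abs(dm) > config@maxAbsDeltaMass,
                    "window")
    if (length(config@backgroundExclusions))
        alive <- reject(alive,
                        !is.na(dm) & .matchAnyDelta(dm, config@backgroundExclusions),
                        "background")

    keep <- which(alive)
    if (verbose)
        message("filterDependentPeptides: ", length(keep), "/", n,
                " survive; rejected ",
                paste(names(tally), tally, sep = ":", collapse = " "))

    if (!length(keep)) {
        out <- .emptyDPSet()
        metadata(out)$rejections <- tally
        metadata(out)$config <- config
        return(out)
    }
    sel <- features[keep, , drop = FALSE]
    profiles <- mapply(function(str, base) {
        if (is.na(str)) return(numeric(nchar(base)))
        prof <- parseLocalisationProbabilities(str)
        if (prof@sequence != base)
            stop("probability string sequence '", prof@sequence,
                 "' disagrees with DP base sequence '", base, "'")
        prof@probabilities
    }, sel$dpProbabilities, sel$dpBaseSequence, SIMPLIFY = FALSE)
    out <- new("DependentPeptideSet", DataFrame(
        baseSequence = sel$dpBaseSequence,
        deltaMass = sel$dpMassDifference,
        probabilities = NumericList(unname(profiles)),
        proteins = sel$proteins,
        rawFile = sel$rawFile,
        retentionTime = sel$retentionTime,
        charge = sel$charge,
        intensity = sel$intensity,
        pep = sel$dpPEP))
    metadata(out)$rejections <- tally
    metadata(out)$config <- config
    out
}

# Re-apply the battery to an already-filtered set (decoys are gone by
# then; the remaining rules make the filter idempotent on its output).
.refilterDPSet <- function(dps, config, verbose = TRUE) {
    tally <- c(not_dp = 0L, decoy = 0L, pep = 0L, protein = 0L,
               window = 0L, background = 0L)
    alive <- rep(TRUE, nrow(dps))
    reject <- function(alive, bad, rule) {
        bad <- alive & bad
        tally[rule] <<- tally[rule] + sum(bad)
        alive & !bad
    }
    alive <- reject(alive, !is.na(dps$pep) & dps$pep > config@maxDpPEP, "pep")
    hasProt <- vapply(dps$proteins, function(p) config@proteinId %in% p, TRUE)
    if (config@requireUniqueProtein)
        hasProt <- hasProt & lengths(dps$proteins) == 1L
    alive <- reject(alive, !hasProt, "protein")
    alive <- reject(alive, abs(dps$deltaMass) > config@maxAbsDeltaMass,
                    "window")
    if (length(config@backgroundExclusions))
        alive <- reject(alive,
                        .matchAnyDelta(dps$deltaMass,
                                       config@backgroundExclusions),
                        "background")
    out <- dps[alive, , drop = FALSE]
    if (verbose)
        message("filterDependentPeptides: ", nrow(out), "/", nrow(dps),
                " survive; rejected ",
                paste(names(tally), tally, sep = ":", collapse = " "))
    metadata(out)$rejections <- tally
    metadata(out)$config <- config
    out
}
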