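#' @include AllClasses.R io.R masses.R
#' @importFrom stats runif rbinom rlnorm
NULL

#' Configuration for the synthetic fixture generator
#'
#' Describes a simulated experiment: a random protein digested into
#' tryptic-like peptides, analysed as treated and untreated replicates.
#' Planted modifications are site-specific, appear only in treated
#' samples (each treated replicate detects them with `detectProb`), and
#' carry localisation-probability strings concentrating mass on the
#' true site. Background modifications share their identity (same
#' sequence, same jittered mass shift) across all samples and appear in
#' each sample with probability `backgroundRate`, emulating the
#' replicate-to-replicate stochasticity of data-dependent acquisition.
#' Mass shifts are jittered uniformly within half the spec tolerance so
#' tolerance matching is exercised without boundary flakiness.
#'
#' @param proteinLength residues (default 300).
#' @param peptideLength length-2 range of tryptic segment lengths
#'   (default `c(7, 20)`).
#' @param missedCleavageFraction fraction of adjacent segment pairs also
#'   emitted as missed-cleavage peptides (default 0.2).
#' @param nTreated,nUntreated replicate counts (defaults 2 and 2).
#' @param planted list of `list(site =, spec =, detectProb =)` entries;
#'   `spec` a [DeltaMassSpec-class], `site` a 1-based protein position.
#' @param background list of `list(spec =, n =)` entries: `n` distinct
#'   background DPs per spec (at most one per tryptic peptide, so that
#'   background keys stay distinct under tolerance matching), shared
#'   across all samples.
#' @param backgroundRate per-sample detection probability of each
#'   background DP (default 0.9).
#' @param decoyRate decoy DP rows as a fraction of true DP rows
#'   (default 0.05).
#' @param pepMax PEP values are drawn uniformly on `(0, pepMax)`
#'   (default 0.009, inside the standard 0.01 filter ceiling).
#' @param locNoise probability mass leaked from the true site to its
#'   neighbouring residues (default 0).
#' @param seed integer seed; the generator is deterministic given it.
#' @return a `FixtureConfig` list (class `"FixtureConfig"`).
#' @export
fixtureConfig <- function(proteinLength = 300L,
                          peptideLength = c(7L, 20L),
                          missedCleavageFraction = 0.2,
                          nTreated = 2L, nUntreated = 2L,
                          planted = list(), background = list(),
                          backgroundRate = 0.9, decoyRate = 0.05,
                          pepMax = 0.009, locNoise = 0, seed = 1L) {
    stopifnot(proteinLength >= 20L,
              length(peptideLength) == 2L,
              peptideLength[1L] >= 2L,
              peptideLength[1L] <= peptideLength[2L],
              missedCleavageFraction >= 0, missedCleavageFraction <= 1,
              nTreated >= 0L, nUntreated >= 0L,
              backgroundRate >= 0, backgroundRate <= 1,
              decoyRate >= 0, decoyRate <= 1,
              pepMax > 0, pepMax <= 1,
              locNoise >= 0, locNoise < 1)
    for (pl in planted) {
        stopifnot(is.list(pl), is(pl$spec, "DeltaMassSpec"))
        if (pl$site < 1L || pl$site > proteinLength)
            stop("planted site ", pl$site, " outside protein (length ",
                 proteinLength, ")")
        if (is.null(pl$detectProb)) pl$detectProb <- 1
        stopifnot(pl$detectProb >= 0, pl$detectProb <= 1)
    }
    for (bg in background)
        stopifnot(is.list(bg), is(bg$spec, "DeltaMassSpec"), bg$n >= 0)
    structure(list(proteinLength = as.integer(proteinLength),
                   peptideLength = as.integer(peptideLength),
                   missedCleavageFraction = missedCleavageFraction,
                   nTreated = as.integer(nTreated),
                   nUntreated = as.integer(nUntreated),
                   planted = planted, background = background,
                   backgroundRate = backgroundRate, decoyRate = decoyRate,
                   pepMax = pepMax, locNoise = locNoise,
                   seed = as.integer(seed)),
              class = "FixtureConfig")
}

#' Catalogue of common background mass shifts
#'
#' Ten modifications that dominate the background of typical search
#' results (sample-handling artefacts and ubiquitous in-vivo marks):
#' oxidation, deamidation, methylation, formylation, acetylation,
#' dimethylation, ammonia loss, water loss, phosphorylation and
#' carbamylation. Used to populate the shared background of synthetic
#' fixtures.
#'
#' @param tolerance matching tolerance in Da applied to every spec.
#' @return named list of [DeltaMassSpec-class].
#' @export
#' @examples
#' sapply(backgroundCatalogue(), specValue)
backgroundCatalogue <- function(tolerance = 0.01) {
    vals <- c(oxidation = 15.9949, deamidation = 0.9840,
              methylation = 14.0157, formylation = 27.9949,
              acetylation = 42.0106, dimethylation = 28.0313,
              `ammonia loss` = -17.0265, `water loss` = -18.0106,
              phosphorylation = 79.9663, carbamylation = 43.0058)
    mapply(function(v, l) deltaMassSpec(value = v, tolerance = tolerance,
                                        label = l),
           vals, names(vals), SIMPLIFY = FALSE)
}

# Random protein with K/R placed so that tryptic segments fall in the
# configured length range; position 1 is kept non-K/R.
.simulateProtein <- function(len, pepLen) {
    inner <- c("A", "D", "E", "F", "G", "H", "I", "L", "M", "N",
               "P", "Q", "S", "T", "V", "W", "Y", "C")
    res <- sample(inner, len, replace = TRUE)
    cuts <- integer()
    pos <- 0L
    repeat {
        step <- sample(seq(pepLen[1L], pepLen[2L]), 1L)
        pos <- pos + step
        if (pos >= len) break
        cuts <- c(cuts, pos)
    }
    res[cuts] <- sample(c("K", "R"), length(cuts), replace = TRUE)
    res[len] <- sample(c("K", "R"), 1L)
    list(residues = paste(res, collapse = ""), cuts = c(cuts, len))
}

.trypticPeptides <- function(proteinInfo, pepLen, missedFraction) {
    bounds <- c(0L, proteinInfo$cuts)
    segs <- data.frame(start = head(bounds, -1L) + 1L, end = bounds[-1L])
    pep <- function(s, e) substring(proteinInfo$residues, s, e)
    out <- data.frame(start = segs$start, end = segs$end)
    if (nrow(segs) > 1L && missedFraction > 0) {
        join <- which(runif(nrow(segs) - 1L) < missedFraction)
        if (length(join))
            out <- rbind(out, data.frame(start = segs$start[join],
                                         end = segs$end[join + 1L]))
    }
    out <- out[out$end - out$start + 1L >= pepLen[1L], , drop = FALSE]
    out$sequence <- pep(out$start, out$end)
    out[order(out$start, out$end), , drop = FALSE]
}

.jitterDelta <- function(spec) {
    spec@value + runif(1L, -spec@tolerance / 2, spec@tolerance / 2)
}

.probString <- function(sequence, siteOffset, locNoise) {
    n <- nchar(sequence)
    stopifnot(siteOffset >= 1L, siteOffset <= n)
    p <- numeric(n)
    p[siteOffset] <- 1 - locNoise
    if (locNoise > 0) {
        nb <- setdiff(c(siteOffset - 1L, siteOffset + 1L), c(0L, n + 1L))
        if (length(nb)) p[nb] <- locNoise / length(nb)
    }
    p <- round(p, 3)
    annotateProbabilities(new("LocalisationProfile", sequence = sequence,
                              probabilities = p))
}

.dpRow <- function(rawFile, proteinId, base, delta, probString, pepMax,
                   decoy = FALSE) {
    data.frame(rawFile = rawFile, sequence = NA_character_,
               proteins = proteinId, dpBaseSequence = base,
               dpMassDifference = delta, dpProbabilities = probString,
               dpPEP = round(runif(1L, 1e-4, pepMax), 5),
               dpDecoy = decoy,
               retentionTime = round(runif(1L, 20, 120), 2),
               charge = sample(2:4, 1L),
               intensity = round(rlnorm(1L, 14, 1)),
               stringsAsFactors = FALSE)
}

#' Generate a synthetic treated/untreated fixture
#'
#' Writes a FASTA file and one default-dialect `allPeptides.txt` per
#' replicate into `dir`, together with a ground-truth table. The output
#' is deterministic given `config$seed` (recorded as a `# seed:` header
#' comment in each table). Base-hit rows cover every tryptic peptide in
#' every sample; planted modifications appear only in treated samples;
#' background modifications keep one key across all samples.
#'
#' @param config a [fixtureConfig()] object.
#' @param dir output directory (created if missing).
#' @param proteinId accession written to the FASTA header and Proteins
#'   column (default "SYN1").
#' @return list with `fasta`, `treated` and `untreated` file paths,
#'   `proteinId`, and `truth` (a data.frame with one row per planted or
#'   background modification: sequence, deltaMass, site, label, kind,
#'   and per-sample presence flags).
#' @export
generateFixture <- function(config, dir = tempfile("fixture"),
                            proteinId = "SYN1") {
    stopifnot(inherits(config, "FixtureConfig"))
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    set.seed(config$seed)

    protInfo <- .simulateProtein(config$proteinLength, config$peptideLength)
    peptides <- .trypticPeptides(protInfo, config$peptideLength,
                                 config$missedCleavageFraction)
    fastaPath <- file.path(dir, "protein.fasta")
    writeLines(c(paste0(">sp|", proteinId, "|SYNTHETIC synthetic protein",
                        " seed=", config$seed),
                 protInfo$residues), fastaPath)

    # resolve each planted site to a containing tryptic peptide
    plantedTab <- NULL
    for (pl in config$planted) {
        hit <- which(peptides$start <= pl$site & peptides$end >= pl$site)
        if (!length(hit))
            stop("planted site ", pl$site,
                 " is not covered by any generated peptide")
        k <- hit[1L]
        detectProb <- if (is.null(pl$detectProb)) 1 else pl$detectProb
        plantedTab <- rbind(plantedTab, data.frame(
            sequence = peptides$sequence[k],
            start = peptides$start[k],
            site = pl$site,
            deltaMass = .jitterDelta(pl$spec),
            label = pl$spec@label,
            detectProb = detectProb,
            stringsAsFactors = FALSE))
    }

    # shared-identity background pool
    bgTab <- NULL
    for (bg in config$background) {
        if (bg$n < 1L) next
        # one DP per (peptide, spec): sampling without replacement keeps
        # background keys distinct under tolerance matching
        if (bg$n > nrow(peptides))
            stop("background spec '", bg$spec@label, "' asks for ", bg$n,
                 " DPs but only ", nrow(peptides), " peptides exist; ",
                 "spread the background over more specs")
        ks <- sample(nrow(peptides), bg$n, replace = FALSE)
        bgTab <- rbind(bgTab, data.frame(
            sequence = peptides$sequence[ks],
            start = peptides$start[ks],
            site = NA_integer_,
            deltaMass = vapply(seq_len(bg$n), function(i)
                .jitterDelta(bg$spec), 0),
            label = bg$spec@label,
            siteOffset = vapply(ks, function(k)
                sample(nchar(peptides$sequence[k]), 1L), 0L),
            stringsAsFactors = FALSE))
    }

    samples <- c(
        if (config$nTreated)
            paste0("treated_", seq_len(config$nTreated)),
        if (config$nUntreated)
            paste0("untreated_", seq_len(config$nUntreated)))
    treatedIdx <- grep("^treated", samples)

    presence <- matrix(FALSE, nrow = 0L, ncol = length(samples))
    truth <- NULL
    files <- character(length(samples))
    names(files) <- samples

    # decide presence up-front so ground truth and files agree
    plantedPresence <- matrix(FALSE, nrow = NROW(plantedTab),
                              ncol = length(samples))
    if (NROW(plantedTab))
        for (r in seq_len(nrow(plantedTab)))
            for (s in treatedIdx)
                plantedPresence[r, s] <-
                    runif(1L) < plantedTab$detectProb[r]
    bgPresence <- matrix(FALSE, nrow = NROW(bgTab), ncol = length(samples))
    if (NROW(bgTab))
        bgPresence[] <- runif(length(bgPresence)) < config$backgroundRate

    decoyPool <- c("LGEYGFQNALIVR", "FKDLGEEHFK", "VPQVSTPTLVEVSR",
                   "YLYEIARR", "QTALVELLK", "AEFVEVTK")

    for (s in seq_along(samples)) {
        rawFile <- samples[s]
        rows <- list()
        for (k in seq_len(nrow(peptides)))
            rows[[length(rows) + 1L]] <- data.frame(
                rawFile = rawFile, sequence = peptides$sequence[k],
                proteins = proteinId, dpBaseSequence = NA_character_,
                dpMassDifference = NA_real_,
                dpProbabilities = NA_character_, dpPEP = NA_real_,
                dpDecoy = FALSE,
                retentionTime = round(runif(1L, 20, 120), 2),
                charge = sample(2:4, 1L),
                intensity = round(rlnorm(1L, 15, 1)),
                stringsAsFactors = FALSE)
        if (NROW(plantedTab))
            for (r in which(plantedPresence[, s]))
                rows[[length(rows) + 1L]] <- .dpRow(
                    rawFile, proteinId, plantedTab$sequence[r],
                    plantedTab$deltaMass[r],
                    .probString(plantedTab$sequence[r],
                                plantedTab$site[r] - plantedTab$start[r] + 1L,
                                config$locNoise),
                    config$pepMax)
        if (NROW(bgTab))
            for (r in which(bgPresence[, s]))
                rows[[length(rows) + 1L]] <- .dpRow(
                    rawFile, proteinId, bgTab$sequence[r],
                    bgTab$deltaMass[r],
                    .probString(bgTab$sequence[r], bgTab$siteOffset[r],
                                config$locNoise),
                    config$pepMax)
        nDP <- sum(vapply(rows, function(x) !is.na(x$dpBaseSequence[1L]),
                          TRUE))
        nDecoys <- round(config$decoyRate * nDP)
        for (d in seq_len(nDecoys))
            rows[[length(rows) + 1L]] <- .dpRow(
                rawFile, paste0("REV__", proteinId),
                sample(decoyPool, 1L), round(runif(1L, -400, 400), 4),
                NA_character_, config$pepMax, decoy = TRUE)
        # a couple of unidentified features for realism
        for (u in 1:2)
            rows[[length(rows) + 1L]] <- data.frame(
                rawFile = rawFile, sequence = NA_character_,
                proteins = NA_character_, dpBaseSequence = NA_character_,
                dpMassDifference = NA_real_,
                dpProbabilities = NA_character_, dpPEP = NA_real_,
                dpDecoy = FALSE,
                retentionTime = round(runif(1L, 20, 120), 2),
                charge = sample(1:3, 1L),
                intensity = round(rlnorm(1L, 12, 1)),
                stringsAsFactors = FALSE)
        tab <- do.call(rbind, rows)
        fs <- new("FeatureSet", DataFrame(
            rawFile = tab$rawFile,
            featureType = ifelse(!is.na(tab$dpBaseSequence),
                                 "dependent_peptide",
                                 ifelse(!is.na(tab$sequence), "base_hit",
                                        "unidentified")),
            sequence = tab$sequence,
            proteins = CharacterList(lapply(tab$proteins, function(p)
                if (is.na(p)) character() else p)),
            dpBaseSequence = tab$dpBaseSequence,
            dpMassDifference = tab$dpMassDifference,
            dpProbabilities = tab$dpProbabilities,
            dpPEP = tab$dpPEP,
            dpDecoy = tab$dpDecoy,
            retentionTime = tab$retentionTime,
            charge = tab$charge,
            intensity = tab$intensity))
        files[s] <- file.path(dir, paste0("allPeptides_", rawFile, ".txt"))
        writeAllPeptides(fs, files[s],
                         comments = paste0("seed: ", config$seed))
    }

    mkTruth <- function(tab, pres, kind) {
        if (!NROW(tab)) return(NULL)
        out <- data.frame(sequence = tab$sequence,
                          deltaMass = tab$deltaMass, site = tab$site,
                          label = tab$label, kind = kind,
                          stringsAsFactors = FALSE)
        colnames(pres) <- samples
        cbind(out, as.data.frame(pres))
    }
    truth <- rbind(mkTruth(plantedTab, plantedPresence, "planted"),
                   mkTruth(bgTab[, setdiff(colnames(bgTab), "siteOffset"),
                                 drop = FALSE],
                           bgPresence, "background"))

    list(fasta = fastaPath,
         treated = unname(files[grep("^treated", samples)]),
         untreated = unname(files[grep("^untreated", samples)]),
         proteinId = proteinId, truth = truth, dir = dir)
}
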