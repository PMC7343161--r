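#' @include AllClasses.R
#' @importFrom Biostrings readAAStringSet AAString matchPattern
#' @importFrom utils read.delim write.table
NULL

#' Read the protein of interest from a FASTA file
#'
#' Selects the first record whose header contains `identifier` as a
#' substring (so both UniProt `sp|ACC|NAME` and PDB-style headers work);
#' with `exact = TRUE` the identifier must match a whole `|`- or
#' whitespace-delimited header token. Whitespace is removed from the
#' sequence and residues are uppercased.
#'
#' @param path FASTA file (possibly multi-record).
#' @param identifier accession or other header substring.
#' @param exact require an exact header-token match.
#' @param numberingNote free-text note recording the numbering
#'   convention of this sequence (e.g. "mature sequence, no initiator
#'   Met"); carried on the returned object and never altered downstream.
#' @return a [ProteinSequence-class].
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">sp|TEST1|TEST_BOVIN demo", "MKWV", "TFIS"), fa)
#' readProteinFasta(fa, "TEST1")
readProteinFasta <- function(path, identifier, exact = FALSE,
                             numberingNote = "") {
    if (!file.exists(path)) stop("FASTA file not found: ", path)
    seqs <- readAAStringSet(path)
    if (!length(seqs)) stop("no sequences in FASTA file: ", path)
    headers <- names(seqs)
    hit <- if (exact) {
        tokens <- strsplit(headers, "[|[:space:]]+")
        which(vapply(tokens, function(tk) identifier %in% tk, TRUE))
    } else {
        grep(identifier, headers, fixed = TRUE)
    }
    if (!length(hit))
        stop("protein not found: '", identifier, "'. Available headers: ",
             paste(headers, collapse = "; "))
    res <- toupper(gsub("[[:space:]*]", "", as.character(seqs[[hit[1L]]])))
    if (!nzchar(res))
        stop("empty sequence for identifier '", identifier, "'")
    new("ProteinSequence", identifier = identifier, residues = res,
        numberingNote = numberingNote)
}

#' Default MaxQuant column dialect
#'
#' Maps semantic field names to `allPeptides.txt` column headers.
#' Defaults follow MaxQuant 1.6; column names drift between versions,
#' so any entry can be overridden.
#'
#' @param ... named overrides, e.g. `dpBaseSequence = "DP base sequence"`.
#' @return named character vector (semantic field -> column header).
#' @export
#' @examples
#' mqDialect()
mqDialect <- function(...) {
    d <- c(rawFile = "Raw file",
           sequence = "Sequence",
           proteins = "Proteins",
           dpBaseSequence = "DP Base Sequence",
           dpMassDifference = "DP Mass Difference",
           dpProbabilities = "DP Probabilities",
           dpPEP = "DP PEP",
           dpDecoy = "DP Decoy",
           retentionTime = "Retention time",
           charge = "Charge",
           intensity = "Intensity")
    overrides <- c(...)
    if (length(overrides)) {
        unknown <- setdiff(names(overrides), names(d))
        if (length(unknown))
            stop("unknown dialect field(s): ", paste(unknown, collapse = ", "))
        d[names(overrides)] <- overrides
    }
    d
}

.numericColumn <- function(x, column) {
    x <- trimws(x)
    x[x %in% c("", "NaN", "NA")] <- NA_character_
    if (any(grepl(",", x, fixed = TRUE)))
        stop("locale-formatted decimals (',') in column '", column,
             "'; files must use '.' as the decimal separator")
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad))
        stop("malformed numeric cell in column '", column, "', row ",
             bad[1L], ": '", x[bad[1L]], "'")
    out
}

.charColumn <- function(x) {
    x <- trimws(as.character(x))
    x[!nzchar(x)] <- NA_character_
    x
}

#' Read a MaxQuant allPeptides.txt table
#'
#' Reads the tab-separated per-feature table into a typed
#' [FeatureSet-class]. Rows with a non-empty DP base sequence are typed
#' `dependent_peptide`; rows with a non-empty `Sequence` are `base_hit`;
#' everything else is `unidentified`. Missing cells become `NA`, never
#' zero. Lines starting with `#` are skipped (fixture files record their
#' generator seed that way).
#'
#' @param path tab-separated UTF-8 file with a header row.
#' @param dialect column-name mapping from [mqDialect()].
#' @return a [FeatureSet-class].
#' @export
readAllPeptides <- function(path, dialect = mqDialect()) {
    if (!file.exists(path)) stop("file not found: ", path)
    raw <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                      check.names = FALSE, colClasses = "character",
                      comment.char = "#", na.strings = character(),
                      fileEncoding = "UTF-8")
    missing <- setdiff(unname(dialect), colnames(raw))
    if (length(missing))
        stop("required column(s) missing: ", paste(missing, collapse = ", "))
    col <- function(field) raw[[dialect[[field]]]]
    proteins <- .charColumn(col("proteins"))
    df <- DataFrame(
        rawFile = .charColumn(col("rawFile")),
        sequence = .charColumn(col("sequence")),
        proteins = CharacterList(lapply(proteins, function(p)
            if (is.na(p)) character() else strsplit(p, ";", fixed = TRUE)[[1L]])),
        dpBaseSequence = .charColumn(col("dpBaseSequence")),
        dpMassDifference = .numericColumn(col("dpMassDifference"),
                                          dialect[["dpMassDifference"]]),
        dpProbabilities = .charColumn(col("dpProbabilities")),
        dpPEP = .numericColumn(col("dpPEP"), dialect[["dpPEP"]]),
        dpDecoy = .charColumn(col("dpDecoy")) %in% c("+", "1", "yes", "TRUE"),
        retentionTime = .numericColumn(col("retentionTime"),
                                       dialect[["retentionTime"]]),
        charge = .numericColumn(col("charge"), dialect[["charge"]]),
        intensity = .numericColumn(col("intensity"), dialect[["intensity"]]))
    df$featureType <- ifelse(
        !is.na(df$dpBaseSequence) & !is.na(df$dpMassDifference),
        "dependent_peptide",
        ifelse(!is.na(df$sequence), "base_hit", "unidentified"))
    new("FeatureSet", df[, .FEATURE_COLS])
}

#' Write a FeatureSet back to allPeptides.txt form
#'
#' Inverse of [readAllPeptides()] under the same dialect: absent values
#' become empty cells, decoy flags become `"+"`, multi-protein cells are
#' `;`-joined. Used by the fixture generator and for round-trip checks.
#'
#' @param features a [FeatureSet-class].
#' @param path output file.
#' @param dialect column-name mapping from [mqDialect()].
#' @param comments optional character vector written as leading `#` lines.
#' @return `path`, invisibly.
#' @export
writeAllPeptides <- function(features, path, dialect = mqDialect(),
                             comments = character()) {
    stopifnot(is(features, "FeatureSet"))
    fmtNum <- function(x) ifelse(is.na(x), "",
                                 format(x, trim = TRUE, scientific = FALSE,
                                        digits = 15))
    fmtChr <- function(x) ifelse(is.na(x), "", x)
    out <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
        a = fmtChr(features$rawFile),
        b = fmtChr(features$sequence),
        c = vapply(features$proteins, paste, "", collapse = ";"),
        d = fmtChr(features$dpBaseSequence),
        e = fmtNum(features$dpMassDifference),
        f = fmtChr(features$dpProbabilities),
        g = fmtNum(features$dpPEP),
        h = ifelse(features$dpDecoy, "+", ""),
        i = fmtNum(features$retentionTime),
        j = fmtNum(features$charge),
        k = fmtNum(features$intensity))
    colnames(out) <- unname(dialect[c("rawFile", "sequence", "proteins",
        "dpBaseSequence", "dpMassDifference", "dpProbabilities", "dpPEP",
        "dpDecoy", "retentionTime", "charge", "intensity")])
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    if (length(comments)) writeLines(paste0("# ", comments), con)
    write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Parse an annotated localisation-probability string
#'
#' Parses strings of the form `"AAC(0.95)DK(0.05)R"` in which a residue
#' may be followed by its modification-site probability in parentheses.
#' Residues without an annotation carry probability 0.
#'
#' @param annotated the annotated peptide string; `NA` or `""` is not
#'   accepted (callers handle absent strings).
#' @return a [LocalisationProfile-class].
#' @export
#' @examples
#' probabilities(parseLocalisationProbabilities("PEPT(1)IDE"))
parseLocalisationProbabilities <- function(annotated) {
    stopifnot(is.character(annotated), length(annotated) == 1L,
              !is.na(annotated))
    chars <- strsplit(annotated, "")[[1L]]
    seqChars <- character()
    probs <- numeric()
    i <- 1L
    n <- length(chars)
    while (i <= n) {
        ch <- chars[i]
        if (grepl("^[A-Za-z]$", ch)) {
            seqChars <- c(seqChars, toupper(ch))
            probs <- c(probs, 0)
            i <- i + 1L
        } else if (ch == "(") {
            if (!length(seqChars))
                stop("annotation before any residue at character ", i,
                     " in '", annotated, "'")
            close <- i
            while (close <= n && chars[close] != ")") close <- close + 1L
            if (close > n)
                stop("unbalanced parenthesis at character ", i, " in '",
                     annotated, "'")
            num <- paste(chars[(i + 1L):(close - 1L)], collapse = "")
            p <- suppressWarnings(as.numeric(num))
            if (is.na(p))
                stop("non-numeric annotation '", num, "' at character ", i,
                     " in '", annotated, "'")
            if (p < 0 || p > 1)
                stop("probability ", p, " outside [0, 1] at character ", i,
                     " in '", annotated, "'")
            probs[length(probs)] <- p
            i <- close + 1L
        } else {
            stop("unexpected character '", ch, "' at character ", i,
                 " in '", annotated, "'")
        }
    }
    new("LocalisationProfile",
        sequence = paste(seqChars, collapse = ""), probabilities = probs)
}

#' Re-annotate a localisation profile as a probability string
#'
#' Inverse of [parseLocalisationProbabilities()]: residues with nonzero
#' probability get a parenthesised annotation.
#'
#' @param profile a [LocalisationProfile-class].
#' @return the annotated string.
#' @export
annotateProbabilities <- function(profile) {
    stopifnot(is(profile, "LocalisationProfile"))
    chars <- strsplit(profile@sequence, "")[[1L]]
    ann <- ifelse(profile@probabilities > 0,
                  paste0("(", format(profile@probabilities, trim = TRUE,
                                     scientific = FALSE, digits = 15), ")"),
                  "")
    paste0(chars, ann, collapse = "")
}
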