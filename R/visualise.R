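#' @include AllClasses.R mapping.R masses.R
#' @importFrom xml2 xml_new_root xml_add_child write_xml
NULL

# SVG scaffolding: plots are emitted as structured SVG whose elements
# carry stable class attributes ("dp-rect", "hist-bar", "dp-strip",
# "prob-cell", "site-annotation", "baseline solid", "baseline dashed"),
# so figure content is testable by parsing, not by pixels.

.svgOpen <- function(width, height) {
    xml_new_root("svg", xmlns = "http://www.w3.org/2000/svg",
                 width = as.character(width), height = as.character(height),
                 viewBox = paste(0, 0, width, height))
}

.svgWrite <- function(doc, path) {
    ok <- tryCatch({ write_xml(doc, path); TRUE },
                   error = function(e) e)
    if (!isTRUE(ok))
        stop("cannot write graphic to '", path, "': ",
             conditionMessage(ok))
    invisible(path)
}

.num <- function(x) sprintf("%.3f", x)

# Draw the protein baseline: dashed overall, solid where covered.
.drawBaseline <- function(doc, coverage, xmap, y) {
    n <- length(coverage)
    runs <- rle(coverage)
    pos <- 1L
    for (k in seq_along(runs$lengths)) {
        from <- pos
        to <- pos + runs$lengths[k] - 1L
        attrs <- list(x1 = .num(xmap(from - 0.5)), y1 = .num(y),
                      x2 = .num(xmap(to + 0.5)), y2 = .num(y),
                      stroke = "black", "stroke-width" = "1")
        if (runs$values[k]) {
            attrs$class <- "baseline solid"
        } else {
            attrs$class <- "baseline dashed"
            attrs$`stroke-dasharray` <- "4,3"
        }
        do.call(xml_add_child, c(list(doc, "line"), attrs))
        pos <- to + 1L
    }
    invisible(doc)
}

.axisText <- function(doc, x, y, label, class = "axis-label") {
    xml_add_child(doc, "text", x = .num(x), y = .num(y), class = class,
                  "font-size" = "10", label)
}

#' DP localisation plot
#'
#' Renders the survey figure: the protein as a horizontal baseline
#' (dashed, becoming solid over covered regions), and one rectangle per
#' dependent peptide and mapped interval, spanning the interval
#' horizontally with signed height proportional to the mass shift
#' (positive shifts extend above the baseline, negative below) and a
#' partially transparent grey border. Unmapped DPs are skipped with a
#' message.
#'
#' @param protein a [ProteinSequence-class].
#' @param dps a localised [DependentPeptideSet-class].
#' @param coverage logical coverage mask from [computeCoverage()];
#'   `NULL` draws an all-dashed baseline.
#' @param outPath output SVG file.
#' @param width,height canvas size in pixels.
#' @return `outPath`, invisibly.
#' @export
plotLocalisation <- function(protein, dps, coverage = NULL, outPath,
                             width = 800, height = 400) {
    stopifnot(is(protein, "ProteinSequence"),
              is(dps, "DependentPeptideSet"),
              "intervals" %in% colnames(dps))
    n <- nchar(protein@residues)
    if (is.null(coverage)) coverage <- logical(n)
    stopifnot(length(coverage) == n)
    margin <- 45
    xmap <- function(pos) margin + (pos - 0.5) / n * (width - 2 * margin)
    y0 <- height / 2
    dmMax <- max(1, abs(dps$deltaMass), na.rm = TRUE)
    yscale <- (height / 2 - margin) / dmMax

    doc <- .svgOpen(width, height)
    .drawBaseline(doc, coverage, xmap, y0)
    nUnmapped <- 0L
    for (i in seq_len(nrow(dps))) {
        iv <- dps$intervals[[i]]
        if (!length(iv)) { nUnmapped <- nUnmapped + 1L; next }
        h <- dps$deltaMass[i] * yscale
        for (k in seq_along(iv)) {
            x1 <- xmap(start(iv)[k] - 0.5)
            x2 <- xmap(end(iv)[k] + 0.5)
            yTop <- if (h >= 0) y0 - h else y0
            xml_add_child(doc, "rect", class = "dp-rect",
                          x = .num(x1), y = .num(yTop),
                          width = .num(x2 - x1), height = .num(abs(h)),
                          fill = "none", stroke = "grey",
                          "stroke-opacity" = "0.5",
                          "data-delta-mass" = .num(dps$deltaMass[i]))
        }
    }
    if (nUnmapped)
        message("plotLocalisation: ", nUnmapped, " unmapped DP(s) skipped")
    .axisText(doc, width / 2, height - 8, "position in protein sequence")
    .axisText(doc, 12, y0, "Δm (Da)")
    for (tick in pretty(c(1, n)))
        if (tick >= 1 && tick <= n)
            .axisText(doc, xmap(tick), y0 + 14, as.character(tick),
                      class = "axis-tick")
    .svgWrite(doc, outPath)
}

#' Mass-shift frequency histogram plot
#'
#' One bar per bin with a nonzero count; the overflow tally (values
#' outside the histogram range) is annotated on the figure whenever it
#' is nonzero.
#'
#' @param histogram a [DeltaMassHistogram-class].
#' @param outPath output SVG file.
#' @param width,height canvas size in pixels.
#' @return `outPath`, invisibly.
#' @export
plotHistogram <- function(histogram, outPath, width = 500, height = 300) {
    stopifnot(is(histogram, "DeltaMassHistogram"))
    margin <- 40
    brk <- histogram@breaks
    cnt <- histogram@counts
    lo <- brk[1L]
    hi <- brk[length(brk)]
    xmap <- function(v) margin + (v - lo) / (hi - lo) * (width - 2 * margin)
    cMax <- max(1L, cnt)
    ymap <- function(c) (height - margin) - c / cMax * (height - 2 * margin)

    doc <- .svgOpen(width, height)
    xml_add_child(doc, "line", class = "axis",
                  x1 = .num(xmap(lo)), y1 = .num(ymap(0)),
                  x2 = .num(xmap(hi)), y2 = .num(ymap(0)),
                  stroke = "black")
    for (b in which(cnt > 0L)) {
        x1 <- xmap(brk[b])
        x2 <- xmap(brk[b + 1L])
        xml_add_child(doc, "rect", class = "hist-bar",
                      x = .num(x1), y = .num(ymap(cnt[b])),
                      width = .num(x2 - x1),
                      height = .num(ymap(0) - ymap(cnt[b])),
                      fill = "steelblue",
                      "data-count" = as.character(cnt[b]))
    }
    if (histogram@overflow > 0L)
        .axisText(doc, width - margin, margin,
                  paste0(histogram@overflow, " value(s) outside range"),
                  class = "overflow-note")
    .axisText(doc, width / 2, height - 6, "Δm (Da)")
    .axisText(doc, 10, height / 2, "frequency")
    .svgWrite(doc, outPath)
}

#' Pack dependent peptides into a lane canvas
#'
#' First-fit packing in input order: each DP is etched (as a run of
#' ones) into the lowest lane in which all cells over all of its
#' intervals are free, and its localisation probabilities are deposited
#' into the matching cells of the probability matrix. DPs that fit into
#' no lane go to the overflow list (the matrices were full) — placed
#' plus overflow always partition the input.
#'
#' @param dps a localised [DependentPeptideSet-class].
#' @param proteinLength number of columns.
#' @param capacity number of lanes (>= 1).
#' @return a [ProbabilityCanvas-class].
#' @export
packCanvas <- function(dps, proteinLength, capacity = 40L) {
    stopifnot(is(dps, "DependentPeptideSet"),
              "intervals" %in% colnames(dps))
    capacity <- as.integer(capacity)
    if (is.na(capacity) || capacity < 1L) stop("capacity must be >= 1")
    occ <- matrix(0L, nrow = capacity, ncol = proteinLength)
    prob <- matrix(0, nrow = capacity, ncol = proteinLength)
    placed <- integer()
    lane <- integer()
    overflow <- integer()
    for (i in seq_len(nrow(dps))) {
        iv <- dps$intervals[[i]]
        if (!length(iv)) { overflow <- c(overflow, i); next }
        cols <- unique(unlist(lapply(seq_along(iv), function(k)
            start(iv)[k]:end(iv)[k])))
        free <- which(rowSums(occ[, cols, drop = FALSE]) == 0)
        if (!length(free)) { overflow <- c(overflow, i); next }
        r <- free[1L]
        occ[r, cols] <- 1L
        p <- dps$probabilities[[i]]
        for (k in seq_along(iv))
            prob[r, start(iv)[k]:end(iv)[k]] <- p
        placed <- c(placed, i)
        lane <- c(lane, r)
    }
    new("ProbabilityCanvas", occupancy = occ, probability = prob,
        placed = placed, lane = lane, overflow = overflow,
        capacity = capacity)
}

#' Probability localisation plot
#'
#' Renders DPs matching an expected mass shift as coloured strips,
#' lane-packed via [packCanvas()], with per-cell shading proportional to
#' the localisation probability (darker = more probable). Every protein
#' site carrying a nonzero probability in a placed DP is annotated with
#' its residue letter and position. DPs that fit into no lane are
#' reported with a warning.
#'
#' @param protein a [ProteinSequence-class].
#' @param dps a localised [DependentPeptideSet-class]; callers
#'   pre-filter to the DPs matching `spec` via [matchDelta()] — rows
#'   not matching are rejected here.
#' @param spec the [DeltaMassSpec-class] being visualised.
#' @param capacity lane count (default 40).
#' @param outPath output SVG file.
#' @param coverage optional logical coverage mask for the baseline.
#' @param width,height canvas size in pixels.
#' @return list with `path` and the [ProbabilityCanvas-class]
#'   (invisibly).
#' @export
plotProbabilityLocalisation <- function(protein, dps, spec, capacity = 40L,
                                        outPath, coverage = NULL,
                                        width = 800, height = 500) {
    stopifnot(is(protein, "ProteinSequence"),
              is(dps, "DependentPeptideSet"), is(spec, "DeltaMassSpec"))
    if (nrow(dps) && !all(matchDelta(dps$deltaMass, spec)))
        stop("all DPs must match the spec; pre-filter with matchDelta()")
    n <- nchar(protein@residues)
    canvas <- packCanvas(dps, n, capacity)
    if (length(canvas@overflow))
        warning("plotProbabilityLocalisation: ", length(canvas@overflow),
                " DP(s) not shown because the matrices were full (rows ",
                paste(canvas@overflow, collapse = ", "), ")")

    margin <- 45
    xmap <- function(pos) margin + (pos - 0.5) / n * (width - 2 * margin)
    cellW <- (width - 2 * margin) / n
    laneH <- max(4, (height - 3 * margin) / max(1L, canvas@capacity))
    ymap <- function(r) height - margin - 20 - r * laneH
    yBase <- height - margin - 10

    doc <- .svgOpen(width, height)
    if (is.null(coverage)) coverage <- logical(n)
    .drawBaseline(doc, coverage, xmap, yBase)
    resChars <- strsplit(protein@residues, "")[[1L]]
    annotated <- logical(n)
    for (j in seq_along(canvas@placed)) {
        i <- canvas@placed[j]
        r <- canvas@lane[j]
        iv <- dps$intervals[[i]]
        p <- dps$probabilities[[i]]
        for (k in seq_along(iv)) {
            s <- start(iv)[k]; e <- end(iv)[k]
            xml_add_child(doc, "rect", class = "dp-strip",
                          x = .num(xmap(s - 0.5)), y = .num(ymap(r)),
                          width = .num(xmap(e + 0.5) - xmap(s - 0.5)),
                          height = .num(laneH * 0.85),
                          fill = "#fee8c8", stroke = "grey",
                          "stroke-width" = "0.5",
                          "data-row" = as.character(i),
                          "data-lane" = as.character(r))
            for (off in which(p > 0)) {
                pos <- s + off - 1L
                xml_add_child(doc, "rect", class = "prob-cell",
                              x = .num(xmap(pos - 0.5)), y = .num(ymap(r)),
                              width = .num(cellW),
                              height = .num(laneH * 0.85),
                              fill = "#7f0000",
                              "fill-opacity" = .num(p[off]),
                              "data-probability" = .num(p[off]),
                              "data-position" = as.character(pos))
                annotated[pos] <- TRUE
            }
        }
    }
    for (pos in which(annotated))
        .axisText(doc, xmap(pos), yBase + 14,
                  paste0(resChars[pos], pos), class = "site-annotation")
    .axisText(doc, width / 2, height - 6, "position in protein sequence")
    .axisText(doc, margin, margin / 2,
              sprintf("%s: Δm %+0.2f ± %g Da",
                      if (nzchar(spec@label)) spec@label else "target",
                      roundHalfUp(spec@value, 2), spec@tolerance),
              class = "title")
    .svgWrite(doc, outPath)
    invisible(list(path = outPath, canvas = canvas))
}
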