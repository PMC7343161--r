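library(xml2)

svgElems <- function(path, class) {
    doc <- read_xml(path)
    xml_find_all(doc, sprintf("//*[@class='%s']", class))
}

test_that("localisation plot draws one rectangle per DP interval", {
    prot <- toyProtein("MKACDEFKGHIKLMNPQRSTVWYK")
    dps <- makeDPs(c("ACDEFK", "GHIK", "MNPQR"), c(125.05, -25.03, 143.06))
    loc <- localiseDependentPeptides(dps, prot, verbose = FALSE)
    out <- withr::local_tempfile(fileext = ".svg")
    cover <- computeCoverage(prot, c("MKACDEFK", "MNPQRSTVWYK"))
    plotLocalisation(prot, loc, cover, out)
    rects <- svgElems(out, "dp-rect")
    expect_length(rects, 3L)
    # total rectangles equal the summed interval count
    expect_identical(length(rects), sum(lengths(loc$intervals)))
    # negative mass shift: rectangle top sits at the baseline
    dm <- as.numeric(xml_attr(rects, "data-delta-mass"))
    yTop <- as.numeric(xml_attr(rects, "y"))
    h <- as.numeric(xml_attr(rects, "height"))
    baseline <- yTop[dm < 0][1]
    expect_true(all(abs(yTop[dm >= 0] + h[dm >= 0] - baseline) < 1e-6))
    # dashed and solid baseline segments both present
    expect_gt(length(svgElems(out, "baseline solid")), 0L)
    expect_gt(length(svgElems(out, "baseline dashed")), 0L)
})

test_that("localisation plot tolerates an empty DP set", {
    prot <- toyProtein("MKACDEFK")
    loc <- localiseDependentPeptides(makeDPs(character(), numeric()), prot,
                                     verbose = FALSE)
    out <- withr::local_tempfile(fileext = ".svg")
    expect_no_error(plotLocalisation(prot, loc, NULL, out))
    expect_length(svgElems(out, "dp-rect"), 0L)
})

test_that("unwritable output paths raise an error", {
    prot <- toyProtein("MKACDEFK")
    loc <- localiseDependentPeptides(makeDPs(character(), numeric()), prot,
                                     verbose = FALSE)
    expect_error(plotLocalisation(prot, loc, NULL,
                                  "/nonexistent-dir/x/y.svg"),
                 "cannot write")
})

test_that("histogram plot has one bar per nonzero bin plus overflow note", {
    h <- buildHistogram(c(1.2, 1.7, 2.2, 99), binWidth = 1, range = c(0, 3))
    out <- withr::local_tempfile(fileext = ".svg")
    plotHistogram(h, out)
    bars <- svgElems(out, "hist-bar")
    expect_length(bars, 2L)
    expect_identical(sort(as.integer(xml_attr(bars, "data-count"))),
                     c(1L, 2L))
    expect_length(svgElems(out, "overflow-note"), 1L)

    empty <- buildHistogram(numeric(), binWidth = 1, range = c(0, 3))
    out2 <- withr::local_tempfile(fileext = ".svg")
    expect_no_error(plotHistogram(empty, out2))
    expect_length(svgElems(out2, "hist-bar"), 0L)
    expect_length(svgElems(out2, "overflow-note"), 0L)
})

test_that("canvas packing partitions input into placed and overflow", {
    set.seed(77)
    aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    prot <- toyProtein(paste(sample(aas, 60, replace = TRUE), collapse = ""))
    for (trial in 1:15) {
        n <- sample(1:12, 1)
        starts <- sample(50, n, replace = TRUE)
        lens <- sample(4:9, n, replace = TRUE)
        dps <- makeDPs(substring(residues(prot), starts, starts + lens),
                       runif(n, -100, 100))
        loc <- localiseDependentPeptides(dps, prot, verbose = FALSE)
        capacity <- sample(1:5, 1)
        canvas <- packCanvas(loc, nchar(prot), capacity)
        expect_setequal(c(placedIndices(canvas), overflowIndices(canvas)),
                        seq_len(n))
        # no two placed DPs share a (lane, position) cell
        expect_true(all(canvas@occupancy %in% c(0L, 1L)))
        occupiedCells <- sum(canvas@occupancy)
        claimedCells <- sum(vapply(placedIndices(canvas), function(i)
            length(unique(unlist(lapply(seq_along(loc$intervals[[i]]),
                function(k) IRanges::start(loc$intervals[[i]])[k]:
                    IRanges::end(loc$intervals[[i]])[k])))), 0))
        expect_equal(occupiedCells, claimedCells)
    }
})

test_that("two overlapping DPs at capacity one drop exactly one with a warning", {
    prot <- toyProtein("MKACDEFKGHIK")
    dps <- makeDPs(c("ACDEFK", "DEFKGH"), c(143.058, 143.061),
                   probs = list(c(0, 1, 0, 0, 0, 0), c(1, 0, 0, 0, 0, 0)))
    loc <- localiseDependentPeptides(dps, prot, verbose = FALSE)
    spec <- deltaMassSpec(value = 143.06, tolerance = 0.01)
    out <- withr::local_tempfile(fileext = ".svg")
    expect_warning(
        res <- plotProbabilityLocalisation(prot, loc, spec, capacity = 1,
                                           outPath = out),
        "matrices were full")
    expect_length(placedIndices(res$canvas), 1L)
    expect_length(overflowIndices(res$canvas), 1L)
    expect_identical(placedIndices(res$canvas), 1L)  # first-fit input order
})

test_that("non-overlapping DPs share a single lane", {
    prot <- toyProtein("MKACDEFKGHIKLMNPQR")
    dps <- makeDPs(c("MKAC", "GHIK"), c(143.06, 143.06),
                   probs = list(c(0, 0, 0, 1), c(0, 1, 0, 0)))
    loc <- localiseDependentPeptides(dps, prot, verbose = FALSE)
    canvas <- packCanvas(loc, nchar(prot), capacity = 1)
    expect_identical(placedIndices(canvas), c(1L, 2L))
    expect_identical(laneOf(canvas), c(1L, 1L))
})

test_that("probability plot shades cells and annotates nonzero sites", {
    prot <- toyProtein("MKACDEFKGHIKLMNPQR")
    # identical sequence + mass shift, different retention times: the
    # putative diastereoisomer pair must appear as two distinct strips
    dps <- makeDPs(c("ACDEFK", "ACDEFK"), c(143.058, 143.058),
                   rt = c(41.2, 55.8),
                   probs = list(c(0, 0.7, 0.3, 0, 0, 0),
                                c(0, 0.7, 0.3, 0, 0, 0)))
    loc <- localiseDependentPeptides(dps, prot, verbose = FALSE)
    spec <- deltaMassSpec(value = 143.06, tolerance = 0.01)
    out <- withr::local_tempfile(fileext = ".svg")
    res <- plotProbabilityLocalisation(prot, loc, spec, capacity = 5,
                                       outPath = out)
    strips <- svgElems(out, "dp-strip")
    expect_length(strips, 2L)
    expect_identical(sort(unique(xml_attr(strips, "data-lane"))),
                     c("1", "2"))
    cells <- svgElems(out, "prob-cell")
    expect_length(cells, 4L)  # two nonzero sites per strip
    # shading is monotone in probability
    op <- as.numeric(xml_attr(cells, "fill-opacity"))
    pr <- as.numeric(xml_attr(cells, "data-probability"))
    expect_identical(order(op), order(pr))
    ann <- svgElems(out, "site-annotation")
    expect_length(ann, 2L)  # two distinct protein sites carry mass
    expect_setequal(xml_text(ann), c("C4", "D5"))
})

test_that("DPs not matching the spec are rejected by the probability plot", {
    prot <- toyProtein("MKACDEFK")
    dps <- makeDPs("ACDEF", 100, probs = list(c(1, 0, 0, 0, 0)))
    loc <- localiseDependentPeptides(dps, prot, verbose = FALSE)
    spec <- deltaMassSpec(value = 143.06, tolerance = 0.01)
    expect_error(plotProbabilityLocalisation(prot, loc, spec,
                                             outPath = tempfile()),
                 "matchDelta")
    expect_error(packCanvas(loc, nchar(prot), capacity = 0), "capacity")
})
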