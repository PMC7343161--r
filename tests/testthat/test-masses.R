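test_that("composition masses match hand-summed monoisotopic values", {
    # oracle: elementwise sums over the standard monoisotopic table
    H <- 1.0078250319; C <- 12; N <- 14.0030740052; O <- 15.9949146221
    expect_equal(compositionMass("H2O"), 2 * H + O, tolerance = 1e-9)
    expect_equal(round(compositionMass("H2O"), 4), 18.0106)
    expect_equal(compositionMass("C6H7NO2"), 6 * C + 7 * H + N + 2 * O,
                 tolerance = 1e-9)
    expect_equal(round(compositionMass("C6H7NO2"), 4), 125.0477)
    expect_identical(compositionMass(""), 0)  # empty composition
    expect_error(compositionMass("Xx2"), "unknown element")
})

test_that("formula parsing handles counts, defaults and sums", {
    expect_identical(parseFormula("C6H7NO2"),
                     c(C = 6L, H = 7L, N = 1L, O = 2L))
    expect_identical(parseFormula("C6H7NO2+H2O"),
                     c(C = 6L, H = 9L, N = 1L, O = 3L))
    expect_identical(parseFormula(c(C = 2, H = 3, N = 1, O = 1)),
                     c(C = 2L, H = 3L, N = 1L, O = 1L))
    expect_error(parseFormula("C6?"), "cannot parse")
})

test_that("composition mass is additive over formula sums", {
    set.seed(3)
    elems <- c("C", "H", "N", "O", "S", "P")
    for (rep in 1:20) {
        a <- sample(0:8, 6); names(a) <- elems
        b <- sample(0:8, 6); names(b) <- elems
        expect_equal(compositionMass(a + b),
                     compositionMass(a) + compositionMass(b),
                     tolerance = 1e-9)
    }
})

test_that("expected mass shifts reproduce the documented adduct values", {
    # intact N-ethylsuccinimidyl (NEM Michael adduct)
    expect_equal(roundHalfUp(specValue(deltaMassSpec(added = "C6H7NO2")), 2),
                 125.05)
    # hydrolysed NESyl
    expect_equal(roundHalfUp(specValue(
        deltaMassSpec(added = "C6H7NO2+H2O")), 2), 143.06)
    # cancellation of the carbamidomethyl fixed modification on Cys
    expect_equal(roundHalfUp(specValue(
        deltaMassSpec(added = "C6H7NO2", removed = "C2H3NO")), 2), 68.03)
    expect_equal(roundHalfUp(specValue(
        deltaMassSpec(added = "C6H7NO2+H2O", removed = "C2H3NO")), 2), 86.04)
    # cysteine sulfinic acid against a carbamidomethylated base
    expect_equal(roundHalfUp(specValue(
        deltaMassSpec(added = "O2", removed = "C2H3NO")), 2), -25.03)
})

test_that("expected_delta_mass is antisymmetric in added and removed", {
    set.seed(8)
    elems <- c("C", "H", "N", "O", "S")
    for (rep in 1:10) {
        a <- sample(0:6, 5); names(a) <- elems
        r <- sample(0:6, 5); names(r) <- elems
        if (all(a == 0) && all(r == 0)) next
        f <- expectedDeltaMass(a[a > 0], r[r > 0])
        g <- expectedDeltaMass(r[r > 0], a[a > 0])
        expect_equal(specValue(f), -specValue(g), tolerance = 1e-9)
    }
})

test_that("half-up display rounding differs from banker's where it matters", {
    expect_equal(roundHalfUp(0.125, 2), 0.13)
    expect_equal(roundHalfUp(-0.125, 2), -0.13)
    expect_equal(roundHalfUp(125.045, 2), 125.05)
})

test_that("matchDelta uses a symmetric inclusive tolerance", {
    spec <- deltaMassSpec(value = 143.06, tolerance = 0.01)
    expect_true(matchDelta(143.058, spec))
    expect_false(matchDelta(143.08, spec))
    expect_true(matchDelta(143.06 + 0.01, spec))  # inclusive bound
    expect_true(matchDelta(143.06 - 0.01, spec))
    expect_identical(matchDelta(c(143.06, 150), spec), c(TRUE, FALSE))
})

test_that("spec values built from compositions verify against themselves", {
    expect_error(new("DeltaMassSpec", value = 100,
                     added = parseFormula("H2O"), removed = integer()),
                 "disagrees")
    s <- deltaMassSpec(added = "C2H3NO", label = "carbamidomethyl")
    expect_s4_class(s, "DeltaMassSpec")
    expect_output(show(s), "carbamidomethyl")
})

test_that("histograms bin half-open and tally overflow", {
    h <- buildHistogram(c(1.2, 1.7, 2.2), binWidth = 1, range = c(0, 3))
    expect_identical(histCounts(h), c(0L, 2L, 1L))
    expect_identical(histOverflow(h), 0L)

    e <- buildHistogram(numeric(), binWidth = 1, range = c(0, 3))
    expect_identical(histCounts(e), c(0L, 0L, 0L))

    # a value exactly at the upper limit overflows (half-open bins)
    b <- buildHistogram(c(0, 2.999, 3, -0.1), binWidth = 1, range = c(0, 3))
    expect_identical(sum(histCounts(b)), 2L)
    expect_identical(histOverflow(b), 2L)
    # bin edges are half-open at the left edge of the next bin
    edge <- buildHistogram(c(1, 1 - 1e-9), binWidth = 1, range = c(0, 3))
    expect_identical(histCounts(edge), c(1L, 1L, 0L))
})

test_that("histogram similarity is Spearman with a defined-ness flag", {
    h1 <- buildHistogram(c(0.5, 1.5, 1.6, 2.5, 2.6, 2.7), binWidth = 1,
                         range = c(0, 4))
    expect_equal(histogramSimilarity(h1, h1)$rho, 1)

    up <- new("DeltaMassHistogram", breaks = 0:4,
              counts = c(1L, 2L, 3L, 4L), overflow = 0L)
    down <- new("DeltaMassHistogram", breaks = 0:4,
                counts = c(4L, 3L, 2L, 1L), overflow = 0L)
    expect_equal(histogramSimilarity(up, down)$rho, -1)

    flat <- new("DeltaMassHistogram", breaks = 0:4,
                counts = rep(2L, 4), overflow = 0L)
    sim <- histogramSimilarity(up, flat)
    expect_false(sim$defined)
    expect_true(is.na(sim$rho))

    h2 <- buildHistogram(1, binWidth = 1, range = c(0, 3))
    expect_error(histogramSimilarity(h1, h2), "identical bin edges")
})

test_that("target spec strings parse in both grammars", {
    s1 <- parseTargetSpec("hydro:+143.06+-0.01")
    expect_equal(specValue(s1), 143.06)
    expect_equal(specTolerance(s1), 0.01)
    expect_identical(specLabel(s1), "hydro")

    s2 <- parseTargetSpec("neg:-25.03")
    expect_equal(specValue(s2), -25.03)
    expect_equal(specTolerance(s2), 0.01)  # default tolerance

    s3 <- parseTargetSpec("nesyl-cys:add=C6H7NO2,remove=C2H3NO,tol=0.02")
    expect_equal(roundHalfUp(specValue(s3), 2), 68.03)
    expect_equal(specTolerance(s3), 0.02)

    s4 <- parseTargetSpec("w:add=H2O")
    expect_equal(roundHalfUp(specValue(s4), 2), 18.01)

    expect_error(parseTargetSpec("no-colon"), "label")
    expect_error(parseTargetSpec("x:add=C6,bogus=1"), "unknown key")
    expect_error(parseTargetSpec("x:+abc"), "malformed")
})

test_that("built-in modifications carry consistent compositions", {
    mods <- builtinModifications()
    expect_equal(roundHalfUp(specValue(mods$nesyl), 2), 125.05)
    expect_equal(roundHalfUp(specValue(mods$water), 2), 18.01)
    expect_equal(roundHalfUp(specValue(mods$nesyl_hydrolysed), 2), 143.06)
    expect_equal(roundHalfUp(specValue(mods$nesyl_cys), 2), 68.03)
    expect_equal(roundHalfUp(specValue(mods$nesyl_hydrolysed_cys), 2), 86.04)
    expect_equal(roundHalfUp(specValue(mods$cys_sulfinic), 2), -25.03)
    expect_equal(roundHalfUp(specValue(mods$mmf_cys), 2), 24.97)
    expect_identical(round(specValue(mods$pyridylethyl)), 105)
    # hydrolysed NESyl = NESyl + water, exactly
    expect_equal(specValue(mods$nesyl_hydrolysed),
                 specValue(mods$nesyl) + specValue(mods$water),
                 tolerance = 1e-9)
})
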