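# Shared specs for fixture tests: the target adduct is well separated
# from the two background modification masses.
targetSpec <- function() deltaMassSpec(added = "C6H7NO2+H2O",
                                       label = "hydrolysed NESyl")
bgSpecs <- function() list(
    list(spec = deltaMassSpec(value = 15.9949, tolerance = 0.01,
                              label = "oxidation"), n = 15),
    list(spec = deltaMassSpec(value = 0.984, tolerance = 0.01,
                              label = "deamidation"), n = 10))

test_that("the generator is deterministic given its seed", {
    cfg <- fixtureConfig(planted = list(list(site = 50, spec = targetSpec(),
                                             detectProb = 1)),
                         background = bgSpecs(), seed = 99)
    fx1 <- generateFixture(cfg, dir = withr::local_tempdir())
    fx2 <- generateFixture(cfg, dir = withr::local_tempdir())
    expect_identical(readLines(fx1$fasta), readLines(fx2$fasta))
    for (k in seq_along(fx1$treated))
        expect_identical(readLines(fx1$treated[k]),
                         readLines(fx2$treated[k]))
    for (k in seq_along(fx1$untreated))
        expect_identical(readLines(fx1$untreated[k]),
                         readLines(fx2$untreated[k]))
    # a different seed changes the output
    fx3 <- generateFixture(fixtureConfig(planted = cfg$planted,
                                         background = cfg$background,
                                         seed = 100),
                           dir = withr::local_tempdir())
    expect_false(identical(readLines(fx1$treated[1]),
                           readLines(fx3$treated[1])))
})

test_that("fixture files parse with the default dialect", {
    cfg <- fixtureConfig(planted = list(list(site = 50, spec = targetSpec(),
                                             detectProb = 1)),
                         background = bgSpecs(), decoyRate = 0.2, seed = 4)
    fx <- generateFixture(cfg, dir = withr::local_tempdir())
    fs <- readAllPeptides(fx$treated[1])
    expect_s4_class(fs, "FeatureSet")
    expect_true(any(fs$featureType == "dependent_peptide"))
    expect_true(any(fs$featureType == "base_hit"))
    expect_true(any(fs$featureType == "unidentified"))
    expect_true(any(fs$dpDecoy))
    prot <- readProteinFasta(fx$fasta, fx$proteinId)
    expect_s4_class(prot, "ProteinSequence")
    # base peptides tile the protein completely
    peps <- observedPeptides(fs, fx$proteinId, include = "base")
    expect_true(all(computeCoverage(prot, peps)))
})

test_that("a modification-free config yields base and decoy-free DP rows only", {
    cfg <- fixtureConfig(seed = 12)
    fx <- generateFixture(cfg, dir = withr::local_tempdir())
    fs <- readAllPeptides(fx$treated[1])
    expect_identical(sum(fs$featureType == "dependent_peptide"), 0L)
    expect_null(fx$truth)
})

test_that("planted keys appear in treated files only, per ground truth", {
    cfg <- fixtureConfig(planted = list(list(site = 50, spec = targetSpec(),
                                             detectProb = 1),
                                        list(site = 120, spec = targetSpec(),
                                             detectProb = 1)),
                         background = bgSpecs(), seed = 21)
    fx <- generateFixture(cfg, dir = withr::local_tempdir())
    truth <- fx$truth[fx$truth$kind == "planted", ]
    expect_identical(nrow(truth), 2L)
    expect_true(all(truth$treated_1 & truth$treated_2))
    expect_false(any(truth$untreated_1 | truth$untreated_2))
    for (f in fx$treated) {
        fs <- readAllPeptides(f)
        dp <- fs[fs$featureType == "dependent_peptide", ]
        expect_true(all(keyInSet(truth$sequence, truth$deltaMass,
                                 makeDPs(dp$dpBaseSequence,
                                         dp$dpMassDifference), 0.011)))
    }
    for (f in fx$untreated) {
        fs <- readAllPeptides(f)
        dp <- fs[fs$featureType == "dependent_peptide", ]
        expect_false(any(keyInSet(truth$sequence, truth$deltaMass,
                                  makeDPs(dp$dpBaseSequence,
                                          dp$dpMassDifference), 0.011)))
    }
})

test_that("an uncoverable planted site is rejected by name", {
    # peptides shorter than the minimum length are unobservable; a site
    # inside such a fragment cannot be planted
    cfg <- fixtureConfig(proteinLength = 40L, peptideLength = c(18L, 20L),
                         planted = list(list(site = 39, spec = targetSpec(),
                                             detectProb = 1)),
                         seed = 2)
    # protein of 40 with cuts every 18-20 leaves a short C-terminal
    # stub; site 39 sits in it for this seed
    expect_error(generateFixture(cfg, dir = withr::local_tempdir()),
                 "site 39")
    expect_error(fixtureConfig(planted = list(list(site = 500,
                                                   spec = targetSpec())),
                               proteinLength = 300),
                 "outside protein")
})

test_that("full detection and zero noise give perfect end-to-end recovery", {
    sites <- c(35, 70, 150, 230)
    cfg <- fixtureConfig(
        planted = lapply(sites, function(s)
            list(site = s, spec = targetSpec(), detectProb = 1)),
        background = bgSpecs(), locNoise = 0, seed = 31)
    fx <- generateFixture(cfg, dir = withr::local_tempdir())
    prot <- readProteinFasta(fx$fasta, fx$proteinId)
    fc <- filterConfig(fx$proteinId)
    tr <- lapply(fx$treated, function(f)
        filterDependentPeptides(readAllPeptides(f), fc, verbose = FALSE))
    un <- lapply(fx$untreated, function(f)
        filterDependentPeptides(readAllPeptides(f), fc, verbose = FALSE))
    cc <- constantConjoin(tr, un)
    hits <- cc[matchDelta(cc$deltaMass, targetSpec()), , drop = FALSE]
    truth <- fx$truth[fx$truth$kind == "planted", ]
    # exactly the planted keys survive constant conjunction
    expect_identical(nrow(hits), length(sites))
    expect_true(all(keyInSet(truth$sequence, truth$deltaMass, hits, 0.011)))
    loc <- localiseDependentPeptides(hits, prot, verbose = FALSE)
    called <- sort(unlist(lapply(seq_len(nrow(loc)), function(i)
        bestSites(loc, i))))
    expect_identical(called, sort(as.integer(truth$site)))
})

test_that("localisation noise leaks mass to neighbours but keeps the maximum", {
    cfg <- fixtureConfig(planted = list(list(site = 50, spec = targetSpec(),
                                             detectProb = 1)),
                         locNoise = 0.2, seed = 8)
    fx <- generateFixture(cfg, dir = withr::local_tempdir())
    fs <- readAllPeptides(fx$treated[1])
    dp <- which(fs$featureType == "dependent_peptide")[1]
    prof <- parseLocalisationProbabilities(fs$dpProbabilities[dp])
    expect_equal(sum(probabilities(prof)), 1, tolerance = 0.01)
    expect_equal(max(probabilities(prof)), 0.8)
    expect_gte(sum(probabilities(prof) > 0), 2L)
})

test_that("constant-conjunction survival of planted keys follows p squared", {
    spec <- targetSpec()
    p <- 0.6
    nSites <- 8
    sites <- seq(30, 30 + 25 * (nSites - 1), by = 25)
    surv <- integer()
    for (seed in 1:12) {
        cfg <- fixtureConfig(
            planted = lapply(sites, function(s)
                list(site = s, spec = spec, detectProb = p)),
            nUntreated = 0L, seed = seed)
        fx <- generateFixture(cfg, dir = withr::local_tempdir())
        truth <- fx$truth
        surv <- c(surv, sum(truth$treated_1 & truth$treated_2))
    }
    n <- length(surv) * nSites
    phat <- sum(surv) / n
    se <- sqrt(p^2 * (1 - p^2) / n)
    expect_lt(abs(phat - p^2), 4 * se)
})
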