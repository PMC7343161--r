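Package: dpvis
Title: Filtering, Enrichment and Visualisation of Dependent-Peptide
    Search Results
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-processing toolkit for dependent-peptide (DP) searches
    of covalently modified proteins. Reads MaxQuant allPeptides.txt
    tables and protein FASTA files, filters DPs for a protein of
    interest, localises them onto the protein sequence by sliding-window
    substring search, enriches treatment-specific DPs by 'conjoined' and
    'constantly conjoined' set logic over treated/untreated replicates,
    computes expected mass shifts from elemental compositions (including
    cancellation of fixed modifications such as carbamidomethylation),
    surveys mass-shift distributions as histograms with Spearman
    similarity, pinpoints hypothesised modifications by localisation
    probability, and renders DP localisation plots, mass-shift
    histograms and probability localisation plots as structured SVG.
    A seeded synthetic-fixture generator emulates treated/untreated
    replicate search outputs with planted site-specific modifications
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    Biostrings,
    xml2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
biocViews: Proteomics, MassSpectrometry, Software, Visualization
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'masses.R'
    'io.R'
    'synthetic.R'
    'mapping.R'
    'visualise.R'
    'enrichment.R'
    'filtering.R'
    'cli.R'
    'dpvis-package.R'
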