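---
title: "Methods: dependent-peptide filtering, enrichment and visualisation"
author: "dpvis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dependent-peptide filtering, enrichment and visualisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpvis)
```

## The problem and the model

A dependent-peptide (DP) search identifies a chromatographic feature by
partial agreement of its fragment spectrum with that of an identified
"base" peptide. The precursor mass difference between the two, Δm (Da,
signed), is evidence of a covalent modification, and the search engine
distributes a localisation probability over the residues of the base
sequence. The central modelling assumption of everything in this
package is therefore:

> a DP is characterised by the pair (base sequence, Δm), and Δm equals
> the mass of a chemical transformation *only after* fixed
> modifications shared between DP and base peptide are accounted for.

Three consequences drive the design. First, DPs are compared as keys —
identical base sequence, Δm within a symmetric tolerance — never as
spectra. Second, expected Δm values are computed from elemental
compositions as `mass(added) − mass(removed)`, where `removed` carries
a fixed modification that is present on the base peptide but replaced
in the DP (for example carbamidomethyl, +C2H3NO, on cysteine). Third,
position 1 of the protein is its N-terminal residue, and the numbering
convention of the supplied sequence (mature versus full-length) is
recorded as free text on the `ProteinSequence` and never altered:
silently renumbering shifts every reported site by one.

## The filter battery

`filterDependentPeptides()` applies six rules in a fixed order, each
individually disableable, and reports a per-rule rejection tally so
that the provenance of every removed row is visible:

| rule | default | rationale |
|---|---|---|
| keep DP rows only | always | base hits and unidentified features are not DPs |
| drop decoys | on | reverse-database matches carry no information about the protein |
| PEP ceiling | 0.01 | posterior error probability of the base identification; an absent PEP never rejects (missing evidence is logged, not punished) |
| protein membership | required | DPs shared between homologous proteins survive by default and are disambiguated downstream, because dropping shared peptides early loses real sites |
| mass window | \|Δm\| ≤ 500 Da | clarity: the bulk of interpretable chemistry sits inside ±500 Da; the bound is inclusive on both sides so a shift of exactly −500.0 is not lost to a rounding convention |
| background exclusion | empty | optional list of Δm specs to strip known artefacts |

The battery is idempotent (re-filtering its own output changes
nothing), monotone under threshold tightening, and the survivor count
plus tally always equals the input count — these are tested as
properties, not examples.

## Enrichment set logic

Treatment-specific modifications are separated from background by set
difference over replicates:

* **conjoined**: DPs of a treated analysis whose key matches nothing in
  an untreated analysis;
* **constantly conjoined**: DPs whose key matches something in *every*
  treated replicate and nothing in *any* untreated replicate. The
  surviving record is taken from treated replicate 1, so counts refer
  to analysis 1.

Key matching uses a symmetric inclusive tolerance, default **0.01 Da**,
evaluated pairwise against the comparison list. Tolerance matching is
not transitive, and clustering the keys first would manufacture
transitivity that the data do not have; the pairwise definition is the
one whose membership predicate can be asserted exactly in tests.
Retention time is deliberately not part of the key — co-eluting
diastereoisomer pairs with identical sequence and Δm are genuinely the
same key — but an optional retention-time window (`rtTolerance`) exists
for chemistries where separating them matters.

Enrichment is quantified as
`fold = pct(after) / pct(before)` where pct is the percentage of DPs
matching any target Δm spec. When no pre-enrichment DP matches, the
fold is reported as undefined (`foldDefined = FALSE`), never as a
number: a 0/0 here is an absence of evidence, not infinity.

## Mass arithmetic

Monoisotopic atomic masses are embedded at ≥ 6 decimal places; every
comparison uses full precision. Display rounds half away from zero to
2 decimal places, which matches how shift values are conventionally
printed (banker's rounding would print +125.045 as +125.04). The
built-in table covers N-ethylmaleimide chemistry (NESyl +125.05 Da,
hydrolysed NESyl +143.06 Da, and their carbamidomethyl-cancelled
cysteine forms +68.03 / +86.04 Da), cysteine sulfinic acid against a
carbamidomethylated base (−25.03 Da), and monomethyl fumarate against a
pyridylethylated base (+24.97 Da).

Histograms use uniform half-open bins `[edge, edge + width)`, default
1 Da over [−500, 500]. The width is a visualisation choice, not a
statistical one, and is configurable; values outside the range go to an
overflow tally rather than disappearing. Histogram similarity is
Spearman rank correlation of the per-bin counts
(`stats::cor.test`, average-rank ties). A constant count vector has no
rank ordering, so the correlation is reported as undefined rather than
`NA`-crashing downstream code.

## Localisation and site calls

Peptides are located on the protein by exact substring search
(`Biostrings::matchPattern`), reporting *all* occurrences including
overlapping ones. DPs mapping twice are flagged ambiguous and excluded
from site calls (a probability vector cannot be lifted into protein
coordinates twice at once); DPs mapping nowhere are flagged unmapped.
Both stay in the object and are logged.

`bestSites()` returns the positions attaining the maximum localisation
probability. Ties are ordered by an optional residue-class priority
list — for N-ethylmaleimide chemistry `c("C", "K", "H")`, the
nucleophiles the reagent actually attacks — then N-terminal-most first,
and tied sites are never dropped. The default priority is empty because
site plausibility is reagent-specific knowledge the caller has and the
package does not.

## The probability canvas

Probability localisation plots pack DPs into a matrix of lanes
(default capacity **40**): each DP is etched as a run of ones into the
lowest lane where all of its positions are free (first-fit in input
order), and its probabilities are deposited into a parallel matrix that
drives the shading (darker = more probable). A DP that fits into no
lane goes to an explicit overflow list and triggers a warning — the
plot must say what it is not showing. `placed + overflow = input` holds
for every capacity and input, and is tested as a property. Output is
structured SVG whose elements carry stable class attributes
(`dp-rect`, `hist-bar`, `dp-strip`, `prob-cell`, `site-annotation`), so
tests assert figure *content* (counts, placement, monotone shading) and
never pixels; colours and opacities are configuration surface.

## What the synthetic generator emulates — and what it does not

`generateFixture()` writes a FASTA plus per-replicate
`allPeptides.txt` files that parse with the default MaxQuant 1.6
dialect. It emulates the study design the set logic needs:

* a random protein whose K/R placement yields tryptic segments within a
  configured length range (default 7–20 residues), fully tiled by
  base-hit rows, with a configurable missed-cleavage fraction
  (default 0.2);
* **planted** site-specific modifications appearing only in treated
  samples, each treated replicate detecting them with probability
  `detectProb`; probability strings concentrate mass on the true site,
  with `locNoise` leaking mass to neighbouring residues;
* **background** modifications with one key shared across all samples
  (same peptide, same jittered Δm), drawn per sample with probability
  `backgroundRate` (default 0.9). The rate is below 1 deliberately:
  replicate-to-replicate detection stochasticity is what
  data-dependent acquisition actually produces, and it is the property
  that makes constant conjunction strictly stronger than single-pair
  conjunction. Background keys are kept distinct by sampling at most
  one peptide per background spec; `backgroundCatalogue()` supplies ten
  common artefact shifts to spread larger backgrounds over.
* Δm values are jittered uniformly within half the spec tolerance, so
  tolerance matching is exercised away from its boundary; decoy rows
  (default 5% of DP rows) and a few unidentified features are added;
  PEP values are drawn inside the default filter ceiling.

It does **not** simulate spectra, intensity structure, retention-time
chemistry, chimeric identifications, or search-engine scoring. Passing
tests on fixtures therefore demonstrate that the *set logic, mass
arithmetic, mapping and rendering* are correct given well-formed search
output; they say nothing about MaxQuant's own false-discovery behaviour
on real data, which is upstream of this package's scope.

## Numerical and degenerate-input choices

* Decimal parsing accepts `.` only; a locale-formatted file is rejected
  with a diagnostic rather than silently misread.
* Missing cells become absent values, never zeros (a PEP of 0 and an
  absent PEP mean opposite things).
* An empty filter result, an empty DP list for a plot, and an all-zero
  probability profile are all legal inputs with defined outputs (empty
  set, baseline-only figure, empty site list).
* The generator is deterministic given a single integer seed, recorded
  as a `# seed:` comment line in each table; the reader skips `#`
  lines.

## Problem sizes

The shipped tests and the acceptance script use a 300-residue protein,
two treated and two untreated replicates, 10 planted modifications over
200 shared background DPs, and 1000 randomized set-logic trials (in
batches of 100 independent key universes per call). These sizes give
every property enough room to fail while keeping a full run in well
under a minute on a single core; they are not estimates of any real
experiment's scale.

## Known limitations

* Proteome-wide and isoform-aware mapping are out of scope: one protein
  of interest per run, exact substring matching only.
* Δm values are not annotated against modification databases; the
  package pinpoints hypothesised shifts, it does not name unknown ones.
* Enrichment is presence/absence set logic; intensity-based
  differential abundance would be needed for modifications that are
  merely *more* abundant after treatment.
* The filter battery approximates commonly used criteria and is fully
  configurable; it does not re-estimate the search engine's DP false
  discovery rate.
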