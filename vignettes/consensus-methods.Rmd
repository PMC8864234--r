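---
title: "Consensus analysis of ethnobotanical surveys: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus analysis of ethnobotanical surveys: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ethnoconsensus)
```

## The data model

An ethnobotanical survey in this package is three long-format tables plus a
mapping. The **use report** is the atomic unit: one row of `use_reports.csv`
is one informant citing one species for one ailment. This granularity is
load-bearing — it is what makes ΣUᵢ (total reports per species) exceed FC
(distinct citing informants) when an informant uses one plant against
several complaints, and it is the unit in which the consensus numerator Nur
is counted. Multi-valued plant parts, preparations and routes are stored in
a single cell with `;` as inner separator; they are split only where a
tabulation needs them.

The index denominator *N* is the number of **included** informants.
Respondents who did not complete an interview are retained in the informant
table with `included = FALSE` for demographic bookkeeping, but a use report
from an excluded informant is a validation error, not a soft warning: the
denominator and the numerators must refer to the same panel.

Species names are compared as authority-stripped binomials.
`canonicalize_name()` removes markup, collapses whitespace, drops the
author citation and preserves one infraspecific rank (`var.`, `subsp.`,
`f.`). It is idempotent, so canonical names can be re-canonicalized freely.
No live nomenclature service is consulted — name resolution beyond string
canonicalization (synonymy, spelling variants) is the user's
responsibility, which keeps every run reproducible.

## Indices and their conventions

For species *s*: UV = ΣUᵢ/N, FC = distinct citing informants,
RFC = FC/N. Two invariants hold by construction and are enforced in tests:
`UV ≥ RFC` (each citing informant contributes at least one report) and
`ΣUᵢ ≥ FC`.

For an ICPC category with Nur mapped use reports on Nt distinct taxa:

$$F_{ic} = \frac{N_{ur} - N_t}{N_{ur} - 1}$$

Two definitional choices deserve a note:

* **Nt counts taxa, not respondents.** Survey write-ups sometimes gloss Nt
  as "the number of respondents that mentioned a species". The formula's
  standard reading — and the only one that reproduces published consensus
  tables from their printed (Nur, Nt) pairs — is the number of distinct
  taxa cited for the category, and that is what this package computes.
* **Degenerate denominator.** A category with a single use report has
  Nur − 1 = 0. It is reported as `fic_degenerate_value` (default 0):
  one report is no evidence of agreement. The default matches how
  single-report categories are printed in published tables; the value is
  config-exposed for users who prefer `NA`.

Fic is strictly decreasing in Nt at fixed Nur, and strictly increasing in
Nur at fixed Nt ≥ 2 (at Nt = 1 it is identically 1 for any Nur > 1 — a
category served by a single taxon is perfect consensus no matter how often
it is cited).

**Rounding.** Display values are rounded half-up (ties away from zero) to
2 decimals by default, because that is the convention of the field's index
tables; base R's banker's rounding disagrees with printed values on exact
ties such as 18/80 = 0.225. A small epsilon (≈1.5e−8) absorbs binary
representation error; values that close to a tie boundary are far below
the resolution of count-ratio data. Raw unrounded values are always kept
alongside the display values, and all comparisons and orderings use the raw
values.

**Tabulations.** Parts, preparations and routes are tabulated per species
with multi-counting: each *distinct* value a species was recorded with
counts once, so the denominator is the number of (species, value) pairs,
not the number of species. Families count once per species;
knowledge sources are multi-counted per informant. Counts always sum to the
table's denominator exactly; percentages are display-rounded only.

## The three-step consensus reading

`interpret_consensus()` encodes the standard interpretation: (1) keep
categories with Fic at or above a threshold — these are the ailments on
which the community agrees; (2) flag categories whose Nur exceeds a second
threshold as common local diseases; (3) within each retained category, rank
plants by category-restricted FC. No numeric thresholds are canonical in
the literature; the defaults (`fic_threshold = 0.8`, `nur_threshold = 50`)
retain the categories such analyses typically single out at the survey's
scale, and both are arguments. Ties are broken lexicographically by
canonical name so the report is a pure function of its inputs.

## Literature cross-referencing

A `reference_flora` is a canonicalized species set with an optional
species → use-term map. Overlap is exact set intersection, with the
percentage over the survey species count. Shared use requires a controlled
vocabulary: published catalogues record free-text efficacies, so the
package asks the user to map both the survey ailments and the reference
uses into one vocabulary (the ICPC ailment map works directly) and counts
a species as shared only when its survey use-set intersects its use-set in
*every* listed reference. Novel species are those absent from all
reference species lists; novel uses are (species, use) pairs found in no
reference use map, with the pairs belonging to novel species kept but
flagged, mirroring the field's convention of reporting new medicinal
species separately from new uses of known ones. Matching is at binomial
level; infraspecific fallback is deliberately not silent — names must be
canonicalized the same way on both sides.

## Co-use association rules

Baskets are per-informant deduplicated species sets (one basket per
included informant, empty baskets retained so the basket count is N). For
every ordered pair (A, B): support is the number of informants citing
both, confidence is support divided by the count of A. Only pairs are
mined — the co-use network is pairwise, and the exact integer identity
`confidence(A→B)·count(A) = support` is preserved before any rounding.
Support counts informants, not report rows: co-use is a property of a
person's repertoire, not of report multiplicity. Default thresholds
(`min_support = 2`, `min_confidence = 0.5`) are arguments, as no published
values exist for them. The implementation is a dense incidence-matrix
cross-product, and it is tested for exact equality against a brute-force
pair-enumeration oracle on a thousand randomized small fixtures.

## The synthetic survey generator

`generate_survey()` exists so that every stage can be tested, with known
ground truth, without any field data. Its defaults are fixed at the shape
of the Kinmen survey and are not tuned per run:

* **Panel**: 80 included informants (plus 8 excluded emitted with no
  reports), 45/80 female, elderly-skewed age bands, low-education-skewed
  schooling, five townships with the survey's relative sizes, oral
  transmission dominating knowledge sources.
* **Knowledge**: the number of distinct species an informant cites is
  zero-truncated Poisson, parameterized by its *mean* (the rate is solved
  from λ/(1−e^(−λ)) = target), with per-gender targets of 6 (women) and
  4 (men). Parameterizing by the mean makes stratum knowledge-rate
  estimates unbiased, which the recovery tests exploit.
* **Flora**: 83 species in 48 families, family sizes Zipf-like (a few
  large families, many singletons), red-list statuses on 34/83 species in
  the observed profile (EN 1 : VU 2 : NT 1 : LC 13 : DD 1 : NA 16).
* **Consensus**: species are partitioned into category pools sized by the
  published taxa profile; each category draws a species-choice probability
  vector from a symmetric Dirichlet with a per-category concentration.
  That single dial maps onto Fic: low concentration → a few taxa dominate
  → high Fic. The vector is drawn once per survey and shared by all
  informants — consensus is a population-level property. The default
  concentration gradient (0.15 up to 2.5 across the twelve categories)
  spans strong to weak consensus as field data do.
* **Reports**: each (informant, species) citation expands into
  1 + Poisson(0.1) use reports for distinct ailments of the category, so
  ΣUᵢ modestly exceeds FC, as observed. Parts/preparations/routes are
  fixed per species from categorical laws matching the published
  frequency profiles, occasionally multi-valued.

All randomness flows from the single seed; the caller's RNG state is saved
and restored, and one seed yields byte-identical CSV output across runs.

What the generator does *not* emulate: informant-level correlation between
demographics and category preferences, seasonal or spatial collection
structure, free-text ailment noise (synthetic ailments are already
controlled vocabulary), and name-spelling errors. Tests passing on
synthetic data therefore validate the *computations* and their invariants,
not the field realism of any particular survey.

## Problem sizes and test design

The test suite checks, among others: exact reproduction of the 24
published per-species index rows and all 12 category Fic values from their
printed marginals (one row is a documented paper-internal rounding
inconsistency: a 0.225 tie printed as 0.22 in the table and 0.23 in the
text; half-up reproduces the text value and the tests treat that row
accordingly); rule mining against an exhaustive oracle over 1,000 random
basket sets of at most 10 informants × 8 species; the UV ≥ RFC and Fic
formula/monotonicity invariants over 10,000 randomized small datasets; and
parameter recovery — a concentrated category out-ranks a diffuse one in
Fic in ≥ 99 of 100 replicates at 80 informants (concentrations 0.05
vs 50 over equal 60-taxon pools), and the 6 : 4 female/male knowledge rate
is recovered as a ratio in [1.4, 1.6] at 2,000 informants. These sizes
keep the default suite to a few minutes while leaving the Monte-Carlo
margins wide.

## Known limitations

* Name matching is purely lexical; synonyms and misspellings must be
  resolved upstream (an explicit design choice for reproducibility).
* Shared-use agreement is only as good as the controlled-vocabulary
  mapping supplied; mapping free-text efficacies is curation work the
  package cannot automate.
* The association network is descriptive: support/confidence are
  co-citation statistics, not estimates of pharmacological interaction,
  and no significance filtering is applied.
* Demographic summaries are descriptive; the package deliberately fits no
  inferential models to them.
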