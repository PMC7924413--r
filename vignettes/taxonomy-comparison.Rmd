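---
title: "Comparing versions of biological taxonomies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing versions of biological taxonomies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxodiff)
```

## The curation problem

Biological taxonomies are expert-maintained hierarchies of ranked taxa
(kingdom down to species) in which species carry binomial names with
authorship — the author and year identify the taxonomic judgment under
which a name was published. Because different authorities revise groups
independently, curators routinely face two versions T1 and T2 of the
same classification and must reconcile them: find the concepts present
in both (congruences), the corrections (splits, merges, moves,
renames), and the additions and exclusions. taxodiff provides the
machinery for this workflow: a flat-table data model with validation
and query helpers, a change model with typed relations, a synthetic
variant generator with known ground truth, a diff engine that recovers
changes from name and synonym evidence, four comparison layouts with a
shared colour code, and the nonparametric statistics used to evaluate
comparison methods in within-subject studies.

Changes are modelled at species rank only. Revisions overwhelmingly
act at the lowest ranks, and restricting relations to species keeps
the change semantics crisp: a split is one species to several, a merge
several to one, moves re-classify a species under another genus,
renames correct an epithet, additions and exclusions touch one side
only. Exactly seven relation types exist; "all" is a filter, not a
type. Congruences are materialized as explicit relations so that the
coverage rule — every species of either version sits in exactly one
relation — is checkable rather than implied.

## The data model and its rules

A taxonomy is a forest stored as a tibble with opaque per-version
identifiers, parent links, ranks, names, authorship and ordered
synonym lists. Construction rejects schema defects (duplicate ids,
unknown ranks, unresolvable parents, cycles); softer structural rules
are reported by `validate_taxonomy()` as data, so defective inputs can
be triaged. Two deliberate permissions: ranks may be skipped (a
species directly under a family is legal, as in real checklist
exports) but never inverted, and child order is always input order —
curators navigate lists as given, so no alphabetisation is applied
anywhere, and file round trips preserve order exactly.

Identifiers are version-local. The concept key used for matching is
the normalized (name, author, year) triple, not the id: authorship
equality is plain string comparison after case folding and whitespace
collapsing, with no nomenclatural parsing. A lenient name-only key is
available for real-world data with inconsistent attribution.

## The synthetic study setup

`build_seed()` manufactures a ranked taxonomy with pseudo-Latin names:
one kingdom-to-order chain, then families, genera and species. The
defaults (66 species in 20 genera and 8 families, about a hundred
nodes) mirror the scale of the small amphibian checklist excerpt that
motivated the design — large enough to contain every change type,
small enough to inspect by eye. Epithets are globally unique by
construction; this is what makes the generator's evidence unambiguous,
because no accidental name collision can masquerade as a congruence.

`generate_variant()` derives a destination version by injecting a
requested mix of changes — counts, or percentages of the species pool
resolved by round-half-up — with at most one change per species, which
prevents self-contradictory evidence. Semantics worth spelling out,
since each was a genuinely open choice:

* **Splits** give every product a fresh epithet; the source survives
  only as a synonym. Letting one product keep the original name would
  make splits locally indistinguishable from a congruence plus
  additions.
* **Merge survivors** are chosen uniformly at random among the
  sources; nomenclatural priority is out of scope.
* **Merges are congeneric** — sources are drawn from a single genus.
  Joining species of one genus is the typical revision; it also keeps
  the agglomerated layout's ordering well defined.
* **Moves** relocate across existing genera only, updating the genus
  part of the binomial and keeping the epithet.
* **Renames** mutate the epithet in place by one to three
  single-character edits (`mutate_epithet()`), the footprint of a typo
  correction.
* Genera emptied by exclusions are kept by default so the upper
  hierarchy stays comparable; `prune_empty_genera` drops them, since
  published variant datasets visibly differ in node counts.

Every run is a pure function of the seed taxonomy and the
specification's RNG seed, byte for byte.

## Change detection

`diff_taxonomies()` classifies species by name-key matches and synonym
citations. The association rule is symmetric: two species are linked
when their accepted keys are equal or when *either* one cites the
other's accepted name as a synonym. One-sided citation (only the newer
version records synonyms) is the common case, but symmetry buys a
clean algebraic property — swapping the arguments maps every relation
to its dual (split to merge, added to excluded) — which the test suite
checks, and it costs nothing when the evidence is one-sided.

Classification: equal keys with the same parent genus are congruent,
with a different parent a move; a one-to-one synonym link with the
same parent is a rename, with a different parent and the same epithet
a move; one-to-many links are splits, many-to-one merges. A
simultaneous epithet and placement change would be a compound change,
which the data model forbids; rather than guess a precedence, the diff
attaches an explicit conflict to the comparison and leaves the taxa
out of the relations — the output always either satisfies the coverage
rules or says exactly why not. The same applies when split and merge
evidence implicate the same taxon.

On generator output the diff recovers the emitted ground truth
exactly; this round trip, run over a hundred random seeds of 20–100
species with random within-capacity change mixes, is the package's
principal correctness property.

## Layouts and colour

All four layouts share one colour code — blue congruences, pink
splits, orange merges, light green moves, light brownish purple
renames, green additions, red exclusions — with fixed default hex
values, since the tradition names colours but not coordinates. The
per-type toggle filter behaves identically everywhere.

* **Edge drawing** juxtaposes the two indented lists and draws one
  typed edge per (origin, destination) pair of each two-sided
  relation. Congruence edges, when toggled on, are ordinary edges;
  additions and exclusions have no second endpoint and become node
  marks on their own side.
* **Matrix** puts T1 on the rows and T2 on the columns; each pair
  becomes a typed cell, additions and exclusions marks on their own
  axis. Congruent pairs produce blue cells — an interpretation, since
  a congruence encoding for matrices is not fixed by tradition.
  Column labels are drawn horizontally and abbreviated; vertical
  labels are notoriously unpopular with users.
* **Agglomeration** interleaves both versions into one list. Shared
  rows (matched higher taxa and congruent species) appear once;
  origin-side rows take the light variant of the type hue and
  destination-side rows the dark variant, where "light" is the base
  hue raised by 25 HSL lightness points. Destination rows are placed
  directly after their related origin rows under the shared ancestor,
  and the construction guarantees that reading only origin rows gives
  exactly the T1 order and only destination rows the T2 order.
  Filtering blanks colour annotations but never removes rows, so the
  list stays a complete inventory.
* **Animation** moves taxa from the T1 column (`x = 0`) to the T2
  column (`x = 1`) with linear easing. Splits fork and merges join at
  the midpoint of the relation's schedule — the origin track vanishes
  there and the products appear; both the fork time and the linear
  easing are chosen for testability, and the timeline's boundary
  conditions (t = 0 on the T1 layout, t = 1 on the T2 layout) are
  asserted in tests. Playback is simultaneous or one relation at a
  time.

Rendering produces plain SVG (one line per edge, one rect per cell,
one text per row) so documents can be parsed and counted; animations
additionally serialize to a JSON timeline.

## Evaluation statistics

For method-evaluation studies where N participants work under k
conditions, the package implements Cochran's Q for binary outcomes,

$$Q = (k-1)\,\frac{k\sum_j C_j^2 - \big(\sum_j C_j\big)^2}
                  {k\sum_i R_i - \sum_i R_i^2},$$

the tie-corrected Friedman rank statistic for ordinal ratings, and
Dunn's pairwise post hoc with Bonferroni correction (adjusted p =
min(1, m·raw) over m = k(k−1)/2 pairs — Bonferroni, not Holm, to match
the convention of the studies this supports). Both omnibus statistics
are referred to chi-square with k−1 degrees of freedom. Rows in which
all conditions agree carry no information; when only such rows exist
the denominators vanish and the statistics are defined as 0 with p = 1,
keeping the functions total.

Asymptotic p-values at N around 12 are borderline, so permutation and
exact-enumeration modes are provided. The right agreement notion
between the asymptotic and exact answers at desk scale deserves a
note: the permutation null of a 6×3 binary or 4×3 ordinal matrix is
highly discrete, with point masses above 0.3 at the observed
statistic, so a pointwise comparison of p-values is meaningless by
construction. The tests therefore check that the asymptotic p lies in
the exact distribution's jump interval [P(T > obs), P(T ≥ obs)],
widened by 0.05 for Monte-Carlo and chi-square approximation error — a
bound chosen from the approximation behaviour at these sizes before
the tests were frozen.

`effectiveness_summary()` aggregates per-exercise correct counts into
totals and round-half-up integer percentages, and
`response_matrix_from_totals()` rebuilds a binary matrix from printed
per-condition totals — exact whenever all but one column are
saturated, which is what makes published single-exercise statistics
reconstructible. `rating_location()` reports plain medians,
grouped/interpolated medians and means side by side, because published
"median" columns for 1–5 ratings sometimes show values a plain integer
median cannot attain; reporting all three labelled honestly beats
guessing.

## Worked example

```{r example, eval = FALSE}
seed <- build_seed(seed_spec(n_species = 66, n_genera = 20,
                             n_families = 8, rng_seed = 7))
spec <- generator_spec(split = 6, merge = 7, move = 6, rename = 7,
                       added = 6, excluded = 4, rng_seed = 11)
variant <- generate_variant(seed, spec)
recovered <- diff_taxonomies(seed, variant$destination)
summarize_changes(recovered)
dunn_bonferroni(response_matrix_from_totals(c(5, 12, 12, 12), 12))
```

## Problem sizes and limitations

The property suites run on synthetic taxonomies of 20–100 species
(about 30–140 nodes); a hundred generator–diff round trips at that
scale, the full 128-subset filter sweep over four comparisons, and the
statistics oracles (10,000 within-row permutation resamples; full
enumeration of the 1,296 rank configurations of a 4×3 matrix) complete
in a couple of minutes on one core. These sizes are the package's own
choice of test conditions: they match the small-checklist scale the
design targets, and every algorithm here is linear or near-linear in
the node count, so nothing qualitative changes at 10⁴ nodes beyond
rendering practicality.

What passing tests do and do not show: the generator emulates clean
curation data — globally unique epithets, complete authorship, exact
synonym bookkeeping, one change per species. Real exports have
misspelled authors, missing years, reused epithets across genera,
compound changes and undocumented renames; on such data the diff
degrades conservatively (unmatched species become exclusions plus
additions, compound evidence becomes explicit conflicts) but the exact
round-trip guarantee applies only to evidence-complete input. Fuzzy
name matching, partial taxon-concept relations (RCC-5 style),
higher-rank changes and multi-way (more than two version) merges are
out of scope.
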