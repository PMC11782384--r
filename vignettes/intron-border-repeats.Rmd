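---
title: "Detecting direct repeats at intron-exon borders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting direct repeats at intron-exon borders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intronDR)
```

## The question and the model

Mobile genetic elements that insert into a staggered double-strand break
leave a signature behind: error-prone repair duplicates the target site, so
the insert ends up flanked by a pair of short, similar, same-orientation
sequence copies — a direct repeat (DR). If introns were acquired by
insertion events of this kind, a DR pair should be detectable near the two
ends of an intron: one copy in the neighbourhood of the 5' exon/intron
border and one near the 3' intron/exon border, even after substitutions and
indels have accumulated in the copies since the insertion.

`intronDR` operationalizes that search. For each annotated intron it
extracts a window of up to 40 bp on each side of each border (80 bp per
border), finds the best direct repeat with one copy per window under an
explicit retention criterion, classifies where each copy sits relative to
its border, and evaluates how surprising such a match would be in random
sequence.

## The retention criterion

A candidate repeat is a gapped alignment of one segment from each window,
described as a column sequence over *match*, *mismatch*, *gap5* (gap in the
5' copy) and *gap3*. The rules, exposed via `search_params()`:

* **Length** `L` counts match and mismatch columns only; gap columns are
  excluded from both the length and the similarity denominator. Similarity
  is `matches / L`. This convention keeps a single integer length for gapped
  repeats and makes the integer percent identities of short repeats come out
  as ratios of small integers (e.g. 8 matches in 11 columns is 73%).
* **`min_length = 4`**: repeats of 3 bp and shorter are never reported; in
  an 80-bp window a 3-mer match is essentially guaranteed by chance.
* **`min_similarity = 0.70`**.
* **`max_linker = 2`**: runs of one or two non-identical columns
  (mismatches and/or gaps) are allowed only as *linkers* joining identical
  blocks. Terminal columns must be matches.
* **`min_flank_block = 2`**: a linker must link two identical regions; we
  read "region" as at least two matched columns, the weakest reading under
  which a linker still links something.
* **`max_length = 40`**: half the combined search span; the criterion needs
  some cap and no natural one larger than the window exists.

`find_best_dr()` returns the optimum under a total order: greatest `L`,
then greatest similarity, then smallest summed copy-to-border distance,
then smallest 5' copy start, then smallest 3' copy start. Length before
similarity mirrors a longest-first search ("the longest region of
similarity at least 70%"); proximity to the border as the next key reflects
the biological expectation that insertion-derived repeats sit at the
borders. These five keys still do not pin down a unique alignment (two
optima can share spans and scores and differ only in linker composition),
so two further deterministic keys are applied: smaller copy5/copy3 span
ends, then the lexicographically smallest column sequence (match <
mismatch < gap5 < gap3). The result is fully deterministic for fixed
inputs.

The implementation is a branch-and-bound over column sequences in C++;
`brute_force_oracle()` is an independent pure-R exhaustive enumeration of
every start pair and every valid column sequence, guarded to windows of at
most 25 bases and `max_length` 16. Equality of the two on randomized window
pairs is asserted in the test suite (580 pairs across parameter settings)
and recomputed by the acceptance script (500 pairs); `validate_alignment()`
replays any alignment against the windows as a universal postcondition.

## Coordinates, borders and classification

Internally all coordinates are 0-based half-open; GFF3, GenBank and the
annotation TSV are 1-based inclusive and converted at the boundary.
Borders are between-base positions: the 5' border sits between the last
5'-exon base and the first intron base. A repeat copy is classed `BORDER`
only when it straddles its border (at least one base on each side); a copy
ending exactly at the border belongs to the side it lies on. The distance
`d` is the count of bases strictly between the copy and the border, so
straddling and abutting copies both have `d = 0` and the "at the border"
bin is exactly `d = 0` — no tolerance is applied.

The placement pair `(loc5, loc3)` takes nine values. Three of them leave
the spliced product's length unchanged (`border/border`, `intron/exon`,
`exon/intron`), three imply a repeat separation shorter than the intron
(`border/intron`, `intron/border`, `intron/intron`) and three a longer one
(`exon/border`, `border/exon`, `exon/exon`, the classic flanking
target-site-duplication geometry). The exact geometric quantity
`delta = (copy3_start - border3) - (copy5_start - border5)` is reported
alongside; when both copies have `d = 0` its sign (0 / negative / positive)
agrees with the categorical relation, a property the tests check over all
nine placements.

Windows are clipped at gene ends and never masked: in a multi-intron gene a
window may overlap a neighbouring exon or intron and its content is taken
verbatim. Clipping keeps `border_pos` within the window by construction.
Minus-strand GFF3 features are reverse-complemented at read time (flagged
`strand_flipped`), so all analysis runs in transcribed orientation.

## The null model

For a repeat of length `n` the table produced by `probability_table()`
reports `(w - n + 1) / 4^n` with `w = 80`: the per-position probability of
a fixed `n`-mer is `1 / 4^n`, and multiplying by the number of start
positions gives the expected number of matching positions. This is an
expected count — equivalently a union bound on, and for `n >= 7` within 5%
of, the exact occurrence probability `1 - (1 - 4^-n)^(w - n + 1)`. The
package reports the tabulated expected-count form (display-rounded
half-up to nine decimals, with values below 5e-10 shown as
`< 0.000000001`) and asserts the bound and the 5% gap in its tests.
`4^n` is computed exactly: every power of four is a power of two and hence
exactly representable as a double at these magnitudes.

Two Monte-Carlo estimators complement the table.
`empirical_fixed_word_probability()` estimates the fixed-word occurrence
probability directly and is checked against exhaustive enumeration at tiny
sizes and against the closed form at `n = 7, w = 80`.
`criterion_false_positive_rate()` applies the full search criterion to
independent random window pairs; it quantifies how permissive the
criterion is. This number is worth taking seriously: with the default
parameters on 80-bp windows, chance linker-chains reaching the length and
similarity thresholds are common, so a high hit rate on real introns is
only interpretable against this chance level — which is exactly why the
analytic table conditions on repeat *length*, where the chance probability
collapses for `n >= 7`.

A GC-content parameter is exposed on both estimators but defaults to 0.5,
the equal-frequency null.

## The synthetic generator

`plant_intron()` emulates the kind of record the pipeline consumes:
`exon5 + intron + exon3` on an i.i.d. background, `GT`/`AG` imposed at the
intron ends (planted copies may overwrite the consensus — splice signals
are biological context here, never detection input), one repeat copy
planted at each configured border offset, and the 3' copy degraded by
per-base substitutions (always to a different base) and single-base indels.
Substitutions and indels are applied to one copy only; one-sided mutation
is enough to control the realized copy similarity and keeps the truth
bookkeeping exact. Indels shift downstream coordinates; the annotated
intron span and the recorded truth spans account for the shift. Expected
copy similarity under substitutions alone is `1 - sub_rate`; default rates
(`sub_rate = 0.2`, `indel_rate = 0.01`) therefore target the ~80% mean
copy identity typical of reported border repeats, and `dr_len = 11`
matches the most common reported repeat length.

After planting, the background is re-rolled (up to 50 attempts) until the
two border windows share no exact `dr_len`-mer outside the planted copies.
The screen is deliberately exact-match only: screening against every
70%-similar gapped competitor would be intractable, and the recovery tests
do not rely on it — they condition on `brute_force_oracle()` confirming
the planted pair optimal on the (clipped) windows. Two recovery facts are
asserted: under an exact-match-only criterion the planted pair is always
recovered exactly (the screen makes it the unique optimum), and under the
default permissive criterion the reported repeat is at least as long as
the planted one, with length, category and relation equal to truth in
every oracle-confirmed case.

`generate_cohort()` allocates metadata groups deterministically by largest
remainder from a composition table (default: a broad survey-like mix over
intron types and genomic locations) and draws placements from the nine
canonical modes (`placement_offsets()`).

What the generator does *not* emulate: real exon/intron base composition,
splice-site sequence context beyond `GT`/`AG`, repeat drift in both copies,
twintron nesting, or annotation error. Tests passing on synthetic cohorts
therefore demonstrate the pipeline's internal correctness — coordinate
bookkeeping, search optimality, classification geometry — not that any
particular biological dataset will yield a given repeat frequency.

## Aggregation conventions

`length_distribution()` counts one repeat length per intron (one retained
pair per intron), while `distance_distribution()` pools both copies (two
distance observations per intron); the two conventions are what make
per-intron length tallies and per-copy placement tallies total correctly.
Standard deviations are population (n denominator) throughout — they serve
as descriptive spread, not inferential estimates. Percentages are kept
exact in the returned tables and rounded to one decimal only at display.
No multiple-testing correction and no between-group tests are performed.

## Validation sizes

The shipped checks use: 580 randomized oracle-equivalence window pairs in
the unit suite and 500 (length 20) in the acceptance script; 100,000
Monte-Carlo trials for the fixed-word probability; 200 zero-noise planted
genes (repeat length 12, the nine placement modes cycled) for recovery,
scanned at flank 12 so the windows fit the oracle's tractability guard;
200 drifted replicates at `sub_rate = 0.2` for the recovered-similarity
check; and the published 207-entry repeat-length tally shipped in
`inst/extdata/dr_length_tally.tsv` for the aggregate-statistics check.

## Known limitations

* The search reports exactly one repeat pair per intron; alternates and
  near-ties are not emitted.
* Only direct repeats are sought; inverted (reverse-complement) repeats are
  out of scope.
* The GenBank reader handles simple-span intron features only; compound
  `join()` locations are rejected by design.
* With the default permissive criterion, reported repeat lengths on real
  or synthetic data can exceed a "true" underlying duplication because
  linker-chains extend into flanking sequence; interpretation should lean
  on the null model rather than on raw lengths alone.
* Paper-scale summary statistics (mean repeat length, distance fractions,
  category percentages over a curated intron collection) depend on that
  collection; the package recomputes the published per-length tally it
  ships but cannot reconstruct record-level results without the underlying
  sequences.
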