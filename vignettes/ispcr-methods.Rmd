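---
title: "In silico PCR and barcode quality indices: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In silico PCR and barcode quality indices: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ispcr)
```

This vignette is the package's account of what it computes, the
assumptions behind each step, and the choices made where the design was
genuinely open. The README shows the workflow; here we explain it.

## The amplification model

In silico PCR treats a primer pair as a pattern query against a sequence
database. A record is amplified when:

1. the forward primer matches a window of the sequence (either strand),
2. the reverse complement of the reverse primer matches a window
   starting at or after the end of the forward window (the two primer
   footprints may not overlap), and
3. the insert — the substring strictly between the footprints — has a
   length inside `[min_insert_len, max_insert_len]`.

Matching is **substitutions-only**: a primer anneals along its full
length or not at all, so the alignment between primer and template is
ungapped and the number of "mismatched positions" is well defined.
Thermodynamics is deliberately out of scope: a mismatch count is a
crude but monotone proxy for annealing stability, and the protected
3' zone captures the one qualitative effect that dominates real PCR —
polymerase extension fails from an unpaired 3' terminus.

Both primer and template may contain IUPAC degenerate symbols. Two
symbols are compatible when their base sets intersect (`R` vs `G`: yes;
`R` vs `Y`: no). The same intersection rule applies to degenerate
symbols in the *template* (an `N` in a record matches any primer
position). The rule is symmetric and easy to test; the alternative —
treating template ambiguity codes as always-mismatching — would make
coverage estimates depend on sequencing artifacts in the database, which
is the less useful behaviour for primer evaluation.

Every valid pairing of sites is reported, including nested and
overlapping alternatives: the model imposes orientation and distance
constraints and nothing else. No "shortest product wins" heuristic is
applied, because any such heuristic would build an amplification-bias
model by stealth; consumers can filter the hit table themselves.

## Tunable parameters

| parameter | default | units | why this value |
|---|---|---|---|
| `max_mismatches` (k) | 2 | positions/primer | stringent setting corresponding to amplification at a rather high annealing temperature; raising k emulates relaxed cycling conditions |
| `exact_suffix_len` | 3 | 3'-terminal positions | mismatches at the extension end abolish amplification; 3 bases is the conventional protected zone |
| `min_insert_len` | 0 | nt | no lower bound: short diagnostic fragments are legitimate |
| `max_insert_len` | 2000 | nt | generous upper bound — barcoding inserts run ≤ ~700 nt; a bound is required for site pairing to be meaningful |
| `kmax` (profiles) | 8 | positions | wide enough that essentially every vertebrate-style template finds its best window; the cumulative curve then shows how coverage responds to relaxing k |

Reported lengths carry **both** conventions: `insert_len` excludes the
primer footprints (the convention under which the classic 658-bp COI
"Folmer fragment" is quoted) and `product_len` includes them. Carrying
both removes any ambiguity about which convention a downstream
comparison uses.

## The matcher

The engine is a Wu–Manber/bitap scan: one 64-bit word per mismatch
level, so a pattern of length ≤ 63 is searched in O(text × k) word
operations regardless of degeneracy. Per-position mismatch prohibition
is implemented by masking the "spend a mismatch here" transition at
protected positions; the 3'-suffix rule is the default instantiation of
that general mechanism (`protected =` accepts any position set — the
reverse-complemented reverse primer, for instance, has its protected
zone at the *start* of the scanned pattern). Patterns longer than 63 nt
fall back to a naive scan with the identical contract; published
barcode primers are ≤ 27 nt, so the fallback exists for contract
totality, not speed.

`brute_force_find()` — the literal sliding-window definition — is a
permanent part of the API, not test scaffolding. The central invariant
of the package is `find_matches() ≡ brute_force_find()` on arbitrary
inputs, and the test suite asserts it on thousands of randomized
instances per run, alongside the analytic properties (budget
monotonicity, saturation, degenerate-position neutrality).

All coordinates, internal and exported, are 1-based inclusive — the R
and Bioconductor convention. Adopting a second, 0-based convention
internally was considered and rejected: a single convention in a
1-based host language is the cheapest defence against off-by-one drift.

## The indices

**Coverage** `Bc = amplified taxa / total taxa` is evaluated at a
caller-chosen rank. Records whose lineage has no node at that rank are
excluded from numerator *and* denominator (and counted in the result):
a record annotated only at genus level can neither hit nor miss at
species rank.

**Resolution** is computed from the taxon/individual/barcode structure:
`E` maps each taxon to its amplified individuals, `Img` each individual
to its distinct barcode strings, `E'` is the region's barcode universe.
A taxon `t` is unambiguous iff the owners of `Ω(t) = Img(E(t)) ∩ E'`
are exactly `E(t)`. Three decisions matter here:

* `E(t)` contains **only amplified** individuals. Including unamplified
  conspecifics would make every partly-amplified taxon automatically
  ambiguous, conflating resolution with coverage.
* Barcode identity is **exact string equality** after uppercasing, in
  forward-primer orientation. Set-compatible comparison of degenerate
  symbols would make "shares a barcode" intransitive, and orientation
  normalization prevents a hit on the opposite strand from looking like
  a distinct barcode. Consequence: an `N` in an extracted barcode is a
  literal character, so a sequencing ambiguity can split a barcode pair
  that is biologically identical. This is a documented limitation.
* The **> 10 species rule** is a reporting flag (`sufficient_data`),
  not a refusal: with ten or fewer amplified species a resolution
  estimate is too noisy to rank primer pairs, but the value itself is
  still well defined and returned.

Reference databases are conventionally thinned to **one randomly chosen
sequence per species** (`one_per_species()`, explicit seed, private RNG
stream) so that heavily sequenced model organisms do not dominate the
denominator; `clade_filter()` restricts an evaluation to one clade for
per-clade comparisons.

## The synthetic community generator

`generate_community()` exists so the entire evaluation workflow is
testable offline with *exact* expected values. It emulates the one
structural feature of a reference database that the indices respond to:
which species amplify, at how many mismatches, and which species share
barcodes. Per species it plants one forward and one reverse site with
exactly the requested mismatch counts (positions drawn among
unprotected, non-degenerate primer positions; mismatching bases drawn
outside the primer symbol's base set), an insert either private or
byte-identical within a declared shared group, and uniform-random
A/C/G/T background.

Two devices make the ground truth analytic rather than probabilistic:

* **Accidental-site rejection**: each assembled template is re-scanned
  with both primers on both strands at `check_k` (default 4)
  mismatches, suffix rule off, and resampled unless exactly the planted
  windows appear. The guarantee is therefore exact for every budget
  `k ≤ check_k`; it cannot extend to arbitrary k (at k = pattern length
  every window matches), which is why `check_k` is an explicit design
  bound of the generator.
* **Insert distinctness**: private inserts are resampled until pairwise
  distinct and distinct from every group insert, so "shares a barcode"
  holds exactly for the declared groups.

What the generator does **not** emulate: realistic base composition,
substitution models or rate heterogeneity, within-species variation
(one record per species), length variation of real barcodes beyond the
configured range, indels between primer sites, or sequencing ambiguity
codes (a flagless default; degenerate symbols never appear in
fixtures). Passing the recovery tests therefore demonstrates the
*bookkeeping* — matching, pairing, orientation, taxonomy traversal, set
algebra — is exact; it says nothing about how well a mismatch count
predicts amplification of real templates, which is a property of PCR,
not of this code.

Default study conditions in the tests and the acceptance script: 12
species (2 families × 2 genera × 3 species), inserts 40–80 nt, flanks
20 nt, one shared trio, a dropout species and planted mismatches up to
check_k = 4 — small enough that the full differential suite (10⁴ random
matcher instances, 10³ random amplifier templates, 50 seeded
communities) runs in about a minute, large enough that every index
takes a non-trivial value at every rank.

## Mismatch profiles

`mismatch_profile()` reports, per record, the minimum mismatch count of
one primer over all windows of both strands, plus the cumulative
fraction of records at or below each count. Two conventions are fixed
here: the protected-suffix rule is **off** by default (the profile
measures raw primer–template divergence; a flag restores the rule), and
the cumulative fraction is relative to **all** records, not only those
with a site within `kmax` — so the curve's plateau below 1 directly
reads as the fraction of the database that remains unamplifiable at the
scanned budgets.

## Degenerate inputs and edge cases

* Gap and unknown characters (`-`, `*`, `.`) are rejected at parse
  time, never silently skipped — skipping would shift every downstream
  coordinate.
* `U` is folded to `T` and case is normalized on input; one canonical
  alphabet everywhere downstream.
* Zero-length inserts are legal when `min_insert_len = 0` (the two
  footprints abut); overlapping footprints are never paired.
* A record with no hits, an empty database, an empty barcode table: all
  produce empty-but-well-formed results, never errors. Division-less
  definitions (`Bc`, `Bs` with zero denominators) return `NA` with a
  flag.
* Ranks are free strings compared case-insensitively; no rank ordering
  is assumed, so exotic taxdump ranks pass through untouched.

## Known limitations

Substitutions-only matching cannot represent primers that tolerate a
bulge; mismatch counts are unweighted (a G–T wobble counts the same as
a C–C clash); amplification efficiency, primer cocktails and
template competition are out of scope; and barcode identity by literal
string equality is conservative in the presence of ambiguity codes, as
discussed above.
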