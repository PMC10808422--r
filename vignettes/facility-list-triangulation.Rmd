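---
title: "Triangulating multi-source health facility lists"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triangulating multi-source health facility lists}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faclink)
```

## The problem

A master facility list — one geolocated row per health facility in a
country — rarely exists where it is needed most. What does exist is a set
of overlapping partial lists: survey sampling frames compiled in different
years, an emergency-operations database, externally curated geodata, and
regional spreadsheets. The same health post appears in five of them under
"PS Nemataba", "Nemataba Poste de Santé" and "Nemataba", sometimes as a
health hut (it was upgraded in 2017), with three coordinate pairs spread
over 800 m and one outright wrong. `faclink` consolidates such lists into
a single deduplicated, geolocated facility list while keeping every
conflict visible.

This vignette documents the model and its assumptions, the parameters that
matter, the synthetic data the package validates itself against, and the
design decisions taken where the workflow was genuinely open.

## Pipeline and assumptions

The pipeline is: per-source standardization → name normalization →
within-source deduplication → pooling → within-region fuzzy matching →
transitive-closure clustering → (optional) replay of manual review
decisions → group-level resolution (type, GPS, conflicts) → consolidated
facility list (CFL) plus reports.

Three assumptions shape it:

* **Region labels are reliable enough to block on.** Candidate pairs are
  only formed between records whose canonicalized region matches
  (case-, accent- and separator-insensitively) one of Senegal's 14 regions
  — or, for unrecognized labels, the verbatim string. Records with a
  missing region are never matched automatically; only review decisions
  can place them. A facility filed under the wrong region will therefore
  not be merged automatically — a deliberate trade of recall for
  precision and runtime.
* **Names carry the identity signal.** Matching runs on a normalized name
  with facility-type tokens removed, because the type is modelled
  separately (it legitimately changes over time, the identity does not).
* **Sources are snapshots with dates.** Type conflicts are resolved by
  source recency; undated sources are treated as oldest.

## Name normalization

`normalize_name()` applies, in order: accent transliteration and removal
of any character outside `[a-z0-9 ]`; lowercasing; removal of
facility-type tokens ("PS", "Case de Santé", "CHR", ...) at token
boundaries, longest token first; acronym expansion ("St." → "saint");
conversion of a standalone *terminal* roman numeral ("Facility iii" →
"facility 3"); and whitespace collapse. Destructive steps run first so the
later token matching sees a canonical alphabet. Accented letters are
transliterated, not deleted — deleting would corrupt French orthography
("Santé" → "Sant"). Roman-numeral conversion is restricted to a terminal
token in i–xx so that names containing "vi" or "di" internally are never
touched. Type tokens are removed anywhere in the name (not only as
prefixes), since sources disagree on where they attach; each removal is
recoverable from the original name kept on every record.

After type-token removal, leading and trailing French filler words
(de, du, la, ...) are stripped. This is a package design choice: it makes
"Hôpital de Fatick" and "CS Fatick" share the match name "fatick", which
mirrors how list compilers actually treat these as the *same-name,
different-type* ambiguity pattern (see below). A name consisting only of
type tokens normalizes to the empty string; such records are flagged,
never dropped.

The token vocabulary and acronym map ship as an editable
`normalization_lexicon()`, because any real deployment grows both lists.

## Matching

Similarity is Jaro–Winkler with the standard published constants
p = 0.1 and prefix cap ℓmax = 4 (configurable; the workflow itself fixes
only the threshold). The package treats the threshold as a *distance*:
a pair is a candidate when d = 1 − sim ≤ 0.2, i.e. similarity ≥ 0.8.
Accepted pairs are clustered by single-linkage transitive closure
(connected components via `igraph`): if A matches B and B matches C, then
{A, B, C} is one facility group even when A–C alone is weaker. That is
deliberately recall-friendly — the workflow this models always pairs the
automatic step with manual verification, and `apply_review_decisions()`
replays split/merge corrections idempotently on top of the automatic
clustering.

Group identifiers are deterministic (region slug + zero-padded index,
ordered by region, then lexicographic minimum match name, then source
order), so re-running on shuffled input reproduces identical `match_id`s.

## GPS assignment and geospatial verification

When several sources contribute coordinates to one group, one pair is
chosen by an ordered source-preference hierarchy — by default
COUS, then the non-2017 SPA frames (2016, 2015, 2014 in that order), then
SPA 2017, ESRI, HDX, and Maina et al. — reflecting trust in
government-associated sources over external compilations. The hierarchy
is configuration, not code; sources absent from it rank last in
configuration order. Whether "(2016, 2015, 2014)" is a preference order or
a mere enumeration is ambiguous; it is implemented as a preference order
and is configurable tier-internally. Coordinates are never averaged:
discordant points usually mean one source is wrong, and an average is
wrong everywhere.

Two distance rules, both strict inequalities on the all-pairs maximum
Haversine distance (sphere radius 6371 km): groups spreading > 1 km are
flagged for review; among groups with ≥ 2 *distinct* coordinate sets
(distinct after 5-decimal rounding, ≈ 1 m), a spread > 2 km counts as
discordant in the validation summary. The 1 km rule is applied to all
member pairs, not only the preferred-vs-rest comparisons, because a single
bad non-preferred point is still worth review.

## Facility-type resolution and ambiguity patterns

Types live on the upgrade ladder hut < post < center < hospital. A group
reporting several ladder types takes the type of its most recent dated
source, noted as an upgrade or downgrade — upgrades (health hut → health
post) are the common real-world cause. Conflicts with no date information,
or involving off-ladder types ("autre"), resolve to the majority type,
ties to the higher level, always with a note. `data_flagged` is 1 exactly
when `data_notes` is non-empty, so every automatic resolution stays
visible.

Three recurring ambiguity patterns are flagged, never auto-resolved:

1. *Same name, different type, same region* — possibly one upgraded
   facility; cross-noted, unless the assigned coordinates are more than
   1 km apart, in which case the groups are noted as name-sharing but
   geographically distinct.
2. *Same name and type, different department/health district* — kept
   separate and noted; departments (45) and health districts (77–79) are
   different administrative systems and their discordance is recorded,
   not reconciled.
3. *Near-threshold pairs* (distance in (0.2, 0.3]) — collected into a
   review report for human screening, mirroring the "similar but
   different enough" failure mode of edit-distance matching.

## The synthetic registry

`simulate_registry()` draws a ground-truthed universe and K overlapping
noisy sources, emulating the documented error modes: partial and
overlapping coverage (per-source inclusion probability), type-token
attachment to names, accent loss/addition, acronym contraction, roman
numeral toggling, single-character typos, type upgrades reported
asymmetrically by sources dated before/after the upgrade year, isotropic
metre-scale GPS jitter (applied in metres, converted to degrees at the
local latitude, so the 1 km rule behaves realistically), GPS missingness,
and exact within-source duplicates.

Reference conditions (the defaults, chosen once): 500 facilities over 14
regions, type mix ≈ 2% hospitals / 5% health centers / 50% health posts /
43% health huts (the national proportions of the consolidated Senegal
list), 5 sources with inclusion probability 0.75, GPS probability 0.7,
jitter sd 150 m, typo probability 0.04, accent noise 0.15, type-prefix
attachment 0.5, acronym contraction 0.3, roman toggling 0.3, upgrade
probability 0.1, within-source duplicate probability 0.01. These are mild,
plausible rates for administrative lists; jitter of 100–200 m matches
handheld-GPS-plus-transcription error, and the inclusion rate yields the
sparse-overlap structure (most facilities seen by 3–4 of 5 sources) that
makes hierarchical GPS assignment meaningful.

Facility names are built from generic Senegalese toponym fragments (no
real facility names). Within a region, names are constructed to be
separable: unique prefix fragments first and a minimum pairwise
Jaro–Winkler distance of 0.28 where possible. This is an explicit
modelling choice: real within-region facility names are mostly
distinguishable, and entity resolution on a universe whose identities are
not separable in principle measures the universe, not the linker. The
fallback passes (separation only, then any unused combination) only
engage for region sizes beyond the default scale.

What the generator does **not** emulate — and hence what green tests do
not certify about real data: truly adversarial name collisions (two
different facilities legitimately sharing one name in one region),
systematic cross-source copying of errors, region misassignment,
department/district recoding over time, and the human verification rounds
that real consolidations rely on. Measured F1 on synthetic data is an
upper bound on real-data performance.

The seeded generator is fully deterministic: the universe consumes the
seed, source emission consumes seed + 1, both through R's default RNG.

## Evaluation

`pairwise_linkage_metrics()` scores predicted groups against ground truth
by pair counting: precision = correctly co-grouped pairs / predicted
co-grouped pairs (1 when nothing is paired), recall analogously over true
pairs (1 when none exist), F1 their harmonic mean (0 when both are 0).
Pairwise metrics are primary because review workflows operate on pairs; a
cluster-level exact-match rate is reported alongside. `threshold_sweep()`
re-runs the full pipeline per threshold and asserts the single-linkage
monotonicity of recall.

Under the reference conditions (seed 1) the pipeline reaches F1 ≈ 0.996
with recall 1; that value is pinned as a regression guard in the test
suite. A noise-free, full-inclusion registry is recovered exactly
(precision = recall = 1, one group per true facility).

One distributional note: with per-axis jitter sd σ on both of two
observations of one facility, their separation is Rayleigh with scale
σ√2, so the fraction of pairs separated by more than r is
exp(−r²/(4σ²)) — at σ = 500 m, 36.8% exceed 1 km. The test suite verifies
the generator against this closed form.

## Numerical and degenerate-input choices

* Coordinates are rounded to 5 decimal places (≈ 1 m) on output and
  before distinct-GPS counting; parsing accepts comma decimals; malformed
  or out-of-range coordinates become missing with a warning, never an
  error, while a missing mapped column is fatal.
* All internal orderings (group ids, tie-breaks, source lists) use
  C-locale/radix sorting, so results are locale-independent.
* Ties: duplicate records within a source prefer the one with
  coordinates, then the lowest row index; two coordinate rows from one
  source inside one group take the lower row index and flag the group;
  modal values (group name, region, department) break ties
  lexicographically.
* Empty inputs are legal everywhere: zero sources pool to an empty list,
  an empty CFL yields empty reports, a group with < 2 geolocated members
  has no pairwise distance (`NA`), and a region with no multi-GPS groups
  reports discordance as `NA` rather than 0.
* Problem sizes in the test suite were chosen for tight feedback: unit
  tests run registries of 40–250 facilities with 3–4 sources; the
  acceptance checks run the 500-facility, 5-source reference simulation,
  exhaustive string-metric verification up to length 4 over a 3-letter
  alphabet plus a seeded sample of longer strings, and 1,000-group
  brute-force checks of the GPS hierarchy.

## Known limitations

* Blocking is strictly by region; a record filed under the wrong region
  can only be merged via a review decision.
* No phonetic or embedding-based matching; edit similarity misses
  "similar but different" spellings that sound alike, which is exactly
  what the near-threshold review report is for.
* Facility openings, closures and renamings over time are out of scope:
  the CFL is a snapshot consolidation, not a facility history.
* The department/health-district discordance is recorded but not
  reconciled.
* Great-circle distance uses a sphere, not the WGS84 ellipsoid; at
  facility scales the difference (< 0.5%) is far below GPS noise.
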