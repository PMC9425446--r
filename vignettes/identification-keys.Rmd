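---
title: "Identification keys from descriptive matrices: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identification keys from descriptive matrices: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyclave)
```

## The problem

Identifying a specimen with a classical dichotomous key means answering a
fixed sequence of either/or questions: a single unobservable character (a
dissected mouthpart, a worn elytral margin) can block the whole
determination. Matrix-based ("multi-access") keys decouple the questions
from any fixed order: the knowledge base scores every taxon for every
character, the user reports whatever characters are observable, and the
engine eliminates taxa whose scored states contradict the observations.

`polyclave` implements both sides of this workflow on a common data model:
a multi-access engine with character ranking, a generator for single-access
keys, and an interpreter for hand-written dichotomous keys, so that the two
artefacts — matrix and key — can be checked against each other
mechanically. The worked knowledge base covers the 14 species of the ground
beetle tribe Platynini (Coleoptera, Carabidae) recorded from or near the
southern Levant.

## The data model

A **character** is either categorical, with an ordered list of discrete
states, or numerical, with a unit. A taxon's **observation** for a
character has one of three statuses:

* *scored* — a non-empty subset of the states (more than one state =
  polymorphism, e.g. color morphs), or a closed interval `[lo, hi]` for a
  numerical character;
* *unknown* — nothing usable is recorded;
* *inapplicable* — the character does not apply to the taxon.

Unknown and inapplicable are kept apart in storage because they mean
different things scientifically, but they behave identically in every
computation: both are compatible with any observation and both drop out of
discrimination scoring. Many descriptive platforms collapse the two on
export, so conflating them in the algorithms (not in the storage) loses
nothing.

A specimen **profile** maps characters to answers: a set of states
(normally a singleton — the multi-state form is used when a whole taxon
description is replayed against a key) or a measured point. A taxon is
*compatible* with a profile when every answered character either is
unknown/inapplicable for the taxon, shares at least one state with it, or
(numerical) the point falls inside the taxon's closed interval. Boundary
values match: intervals are closed on both ends, so a 8.0 mm measurement is
consistent with a species scored 5.5–8.0 mm. Elimination
(`filter_taxa()`) keeps exactly the compatible taxa; it is monotone (more
answers never bring a taxon back) and order-independent.

## Discriminatory power

Interactive key platforms rank the remaining characters by how much they
help, but the ranking metrics in field use are generally unpublished. We
therefore define a deterministic, matrix-only index and document it: the
**pairwise-separation index** of character `c` over the remaining taxon set
`R` is

```
power(c, R) = #{ {i, j} ⊆ R : c separates i and j } / #{ {i, j} ⊆ R : both scored }
```

where a pair is *separated* when the two state sets are disjoint
(categorical) or the two intervals are disjoint (numerical), and pairs with
an unknown/inapplicable member are excluded from both counts (0 when no
scored pair exists). The index is 0 for characters that cannot split the
current candidates and 1 for characters that split every scored pair. On
the packaged matrix, the upper-side pubescence character separates the 2
hairy from the 12 glabrous species and nothing else: 24 of the 91 possible
pairs, power 24/91 ≈ 0.26.

## Ranking policies

`ranking_options()` composes the question order from up to four keys;
the final tie-break is always declaration order in the knowledge base, which
makes every ranking deterministic:

| policy | primary | then |
|---|---|---|
| `power` (default) | power, descending | — |
| `fewer_states` | state count, ascending | power, descending |
| `most_states` | state count, descending | power, descending |

With `use_weights = TRUE`, the character weight (weak = 1, medium = 2,
strong = 3) is inserted immediately after the primary criterion. Numerical
characters count as two states in the state-count criteria, because the key
generator binarises them (below). Characters already answered, and
characters with zero power, are excluded outright.

The `most_states` policy formalises the strategy of starting with the most
finely divided character (here the 13-state coloration of the upper side);
`fewer_states` formalises the opposite preference, often favoured for
lay users because few-state characters are easier to answer confidently.

## Decision counts

`decision_profile()` measures how many questions each taxon needs under a
policy, with an idealised simulated user: at each step the top-ranked
suggestion is answered with the taxon's own scored observation (polymorphic
cells answer with the full state set, numerical cells with the full
interval); if the taxon is unknown for the suggested character the user
skips to the next suggestion — one cannot answer what one cannot see. The
session ends at a singleton (resolved) or when no answerable character
discriminates (unresolved).

On the packaged matrix every species resolves, in 2–4 decisions under
`most_states` and 3–9 under `fewer_states`; no species is faster under
`fewer_states`. This reproduces the qualitative behaviour expected of such
matrices — a many-state coloration character splits the candidates so finely
that one to few questions suffice, while prioritising small characters
lengthens sessions — with the caveat that the absolute counts depend on our
published-information-only transcription (below) and on our ranking index,
not on any platform's proprietary one.

## Single-access key generation

`build_single_access_key()` recursively asks, for the current taxon set,
the top-ranked character, and branches:

* categorical: one branch per state observed among the scored taxa, in
  declared state order. A polymorphic taxon appears under **every** branch
  whose state it carries — this is exactly why generated keys list variable
  species at two or three leaves. Taxa unknown for the character are copied
  to every branch.
* numerical: intervals are merged into maximal covered blocks; each gap
  between blocks becomes a threshold and each block a branch. Every scored
  interval lies wholly inside one block, so branch predicates are disjoint.
  A character whose intervals leave no gap cannot branch (even if some pair
  is disjoint through a chain of overlaps) and the next-ranked character is
  tried.

Recursion excludes characters already used on the path, so it terminates;
groups that no unused character separates become *unresolved leaves*,
rendered as a bracketed taxon list rather than an error. Identical inputs
yield byte-identical keys.

On the packaged matrix the generated keys are much larger than a
hand-written key (hundreds of numbered steps), and nearly every species
appears at several leaves. This is a direct consequence of the
transcription policy: cells are scored only where the printed sources state
a value, so roughly half the matrix is unknown, and unknown taxa are copied
into every branch they might belong to. A fully scored working matrix — as
a curator would maintain on an interactive platform — collapses most of
this duplication; the printed-source matrix is kept deliberately, because
every scored cell is auditable against its couplet or table row.

## The dichotomous key interpreter

The printed 13-couplet key ships as `platynini_key()`: each lead carries
its printed text plus machine predicates over the matrix characters (the
assertion that actually discriminates at that couplet — pubescence at
couplet 1, mentum tooth at couplet 3, pronotum proportions at couplets
11–13, and so on). A lead is satisfied when every answered predicate holds
with the whole answer set inside the asserted states (numerical: the
answered interval inside the asserted interval). Subset — not overlap —
semantics makes a self-contradictory profile (e.g. hairs both present and
absent) fail both leads and raise an "inconsistent specimen" error naming
the couplet; a profile satisfying both leads raises an "ambiguous" error,
which a well-formed key should make unreachable.

`check_consistency()` closes the loop between the two artefacts: every
taxon's own scored observations must traverse the key to that taxon's lead.
The packaged matrix and key agree for all 14 species; flipping any
discriminating cell is caught. `key_metrics()` reports the conventional
efficiency figures — 13 numbered alternatives, and per-species decision
counts from 2 (the two pubescent species, keyed out at couplet 2) to 9 (the
two species reached through the full couplet chain 1, 3, 5, 8, 9, 10, 11,
12, 13). An "alternative" is counted as one numbered step (a lead pair),
not as one lead.

## Transcription decisions in the packaged matrix

The matrix is transcribed exclusively from printed sources — the key
couplets and the published character overview table — under one rule:
**no printed value, no scored cell**. Each scored cell records its source
in the observation's `source` field, and a test audits that no scored cell
lacks one. Decisions a curator should know about:

* **16 characters.** The overview table lists 15 descriptors; the mentum
  tooth, used by couplet 3 of the printed key, is appended as the 16th.
* **Coloration of the upper side, 13 states.** The published state list is
  not printed; 13 states were synthesized from the couplets' color phrases
  (each distinct phrase one state; range phrases such as "reddish to dark
  brown" scored as polymorphic over the adjacent states).
* **Pronotum proportion, 4 states** binned at width/length ratios 1.1,
  1.2 and 1.3; printed ranges map to every band they intersect, so several
  species are polymorphic here by construction.
* **Pronotum punctation** is applicable to 3 species per the overview
  table, but the couplets name values only for the two *Olisthopus*
  (strong vs weak). The third scored species is not identifiable from the
  printed text; we chose *Atranus ruficollis* (strong), whose pronotum is
  among the four reference figures for this character.
* **Setiferous punctures of the 3rd elytral interval** are applicable to
  12 species (unusable in the two strongly pubescent ones). Printed counts
  exist only at couplet 9; its counter-lead range (2–)3(–4) is applied to
  all eleven non-*viridicupreum* glabrous species.
* **Weights** default to medium for all characters. The original key
  generation weighted four characters strongly and two weakly, but the
  assignment was never identified per character, so the package exposes a
  `weights` override instead of guessing.

## The synthetic-data generator

`random_kb()` emulates the structure of such matrices — categorical
characters with 2–4 states, a share of numerical characters, and
independently drawn polymorphic and unknown cells — and
`sample_specimen()` emulates an observer: one state per polymorphic cell, a
uniform point per interval, characters dropped with `unknown_rate`, answers
replaced by a uniformly chosen wrong value with `noise_rate`. Each call
runs on a private RNG stream under a mandatory seed and leaves the caller's
RNG untouched.

What the generator does **not** model: correlated characters, structured
observer error (confusing adjacent states rather than arbitrary ones),
ontogenetic or geographic variation, and missingness that depends on the
character (in real matrices, "unknown" concentrates in hard-to-observe
characters). Passing the simulation suite therefore demonstrates the
engine's set semantics — containment of the true taxon is exact at noise 0,
and degrades monotonically with noise — not field identification rates.

The test suite sizes its simulations to stay fast while still exercising
the space broadly: 200 random matrices (≤ 8 taxa, ≤ 6 characters) for the
brute-force cross-check of the elimination engine, 20 matrices for key
traversal properties, and 20 noiseless specimens per species of the
packaged matrix for the containment check.

## Known limitations

* The generated single-access keys are correct but not optimal: no
  look-ahead, no expected-depth minimisation.
* Character dependencies (one character only applicable given a state of
  another) are not modelled; inapplicability is per-cell.
* The CSV dialect does not carry per-cell provenance notes; use JSON (or
  the SDD-flavoured XML) for loss-free exchange.
* The SDD export is a documented subset of the standard, sufficient to
  round-trip this package's model, not a general SDD 1.1 reader/writer.
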