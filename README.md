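# polyclave

Multi-access and single-access identification keys from descriptive
character matrices, for taxonomists and biodiversity informaticians who
build, audit, or mechanize species identification tools.

A descriptive knowledge base scores a set of taxa for a set of characters —
categorical states (with polymorphism) or numerical intervals, with
explicit *unknown* and *inapplicable* cells. From that one matrix,
`polyclave` provides:

* a **multi-access (interactive) engine**: answer characters in any order,
  eliminate incompatible taxa, and get ranked suggestions for the next
  character to examine;
* a **single-access key generator** with weighting and
  fewer/most-states-first options, duplicating polymorphic taxa across
  leaves the way real generated keys do;
* a **dichotomous key interpreter**: hand-written couplet keys become
  machine-traversable objects, with per-taxon decision metrics and a
  consistency check of key against matrix;
* **interchange formats**: CSV matrix dialect, loss-free JSON, and an
  SDD-flavoured XML export/import;
* a **synthetic-data module** for seed-reproducible accuracy simulations;
* a command-line tool (`exec/polyclave`) wiring it all together.

Character ranking uses a documented, deterministic **pairwise-separation
index**: for a character *c* and remaining taxa *R*,

    power(c, R) = (# unordered pairs of R that c separates) / (# pairs with both taxa scored)

where a pair is separated iff its state sets (or numerical intervals) are
disjoint; unknown and inapplicable cells drop out of numerator and
denominator alike.

The package ships a complete worked knowledge base — *Platynini, southern
Levant* (Coleoptera, Carabidae): 14 species × 16 characters transcribed
from its printed 13-couplet dichotomous key and character overview table,
with per-cell provenance, alongside the encoded printed key itself
(`platynini_key()`).

## A worked identification

```r
library(polyclave)
kb <- platynini_kb()
kb
#> <knowledge_base> "Platynini, southern Levant": 14 taxa x 16 characters

# start an interactive session, asking many-state characters first
s <- new_session(kb, ranking_options("most_states"))
head(suggest_next(s), 3)
#> [1] "coloration_upperside" "coloration_legs"      "pronotum_proportion"

s <- answer_character(s, "coloration_upperside", "green_coppery_yellow_margin")
remaining_taxa(s)
#> [1] "olisthopus_fuscatus"     "olisthopus_glabricollis"
#> [3] "agonum_marginatum"
```

Only *Agonum marginatum* is scored with that coloration; the two
*Olisthopus* stay because their coloration is unknown in the matrix, and
unknown cells never eliminate. A measurement settles it:

```r
s <- answer_character(s, "body_length", 9.2)   # mm
remaining_taxa(s)
#> [1] "agonum_marginatum"
```

Two answers, one species. The same specimen through the printed
dichotomous key needs four couplets:

```r
traverse_dichotomous(platynini_key(), specimen_profile(
  hairs_upperside = "absent", mentum_tooth = "present",
  pronotum_hind_angles = "rounded_or_obtuse",
  coloration_upperside = "green_coppery_yellow_margin"))
#> <key_traversal> Agonum marginatum in 4 decisions (couplets 1, 3, 5, 8)

key_metrics(platynini_key())
#> <key_metrics> 13 alternatives; decisions 2-9

discriminatory_power(kb, "hairs_upperside")
#> [1] 0.2637363    # = 24/91: 2 hairy x 12 glabrous species
```

From the shell:

```sh
polyclave keystats --dichotomous          # {"alternatives": 13, ...}
polyclave identify --answers answers.json
polyclave buildkey --prefer-fewer-states --use-weights --format text
polyclave simulate --taxa 8 --chars 6 --noise 0.2 --reps 50 --seed 7
```

See `vignettes/identification-keys.Rmd` for the model, the ranking
policies, the key-generation algorithm, and the transcription decisions
behind the packaged matrix.

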