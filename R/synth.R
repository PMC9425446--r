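# Run expr under a private RNG stream seeded with `seed`; the caller's
# global RNG state is untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed))
    stop("an explicit seed is required for reproducibility", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a random knowledge base
#'
#' Synthetic matrices for property testing and simulation: categorical
#' characters with a random number of states, an optional share of numerical
#' characters, and cells that are polymorphic or unknown with the given
#' probabilities. Identical seeds give identical knowledge bases.
#'
#' @param n_taxa Number of taxa (>= 2).
#' @param n_characters Number of characters (>= 1).
#' @param states_range Integer range `c(min, max)` of state counts for
#'   categorical characters.
#' @param p_polymorphic Probability that a scored categorical cell carries
#'   two states instead of one.
#' @param p_unknown Probability that a cell is left unknown.
#' @param p_numerical Share of numerical characters.
#' @param seed Mandatory integer seed.
#' @return A valid [knowledge_base()].
#' @examples
#' kb <- random_kb(5, 4, seed = 1)
#' validate_kb(kb)$valid
#' @export
random_kb <- function(n_taxa, n_characters, states_range = c(2L, 4L),
                      p_polymorphic = 0.1, p_unknown = 0.1,
                      p_numerical = 0.15, seed) {
  stopifnot(n_taxa >= 2L, n_characters >= 1L,
            length(states_range) == 2L, states_range[1] >= 2L,
            states_range[1] <= states_range[2],
            p_polymorphic >= 0, p_polymorphic <= 1,
            p_unknown >= 0, p_unknown <= 1,
            p_numerical >= 0, p_numerical <= 1)
  with_seed(seed, {
    characters <- lapply(seq_len(n_characters), function(i) {
      id <- sprintf("char_%02d", i)
      if (stats::runif(1) < p_numerical) {
        char_def(id, paste("Character", i), "numerical", units = "mm")
      } else {
        k <- sample(seq.int(states_range[1], states_range[2]), 1L)
        sts <- sprintf("s%d", seq_len(k))
        names(sts) <- sts
        char_def(id, paste("Character", i), "categorical", states = sts)
      }
    })
    taxa <- lapply(seq_len(n_taxa), function(j) {
      observations <- list()
      for (ch in characters) {
        if (stats::runif(1) < p_unknown) {
          observations[[ch$char_id]] <- obs_unknown("synthetic")
          next
        }
        observations[[ch$char_id]] <- if (ch$kind == "categorical") {
          k <- if (stats::runif(1) < p_polymorphic && nrow(ch$states) > 1L)
            2L else 1L
          obs_states(sample(state_ids(ch), k), "synthetic")
        } else {
          lo <- round(stats::runif(1, 0, 10), 2)
          obs_range(lo, round(lo + stats::rexp(1, rate = 1), 2), "synthetic")
        }
      }
      taxon_desc(sprintf("taxon_%02d", j), paste("Taxon", j),
                 observations = observations)
    })
    knowledge_base(sprintf("synthetic knowledge base (seed %d)", seed),
                   characters, taxa, notes = "synthetic")
  })
}

#' Sample a synthetic specimen of a taxon
#'
#' Draws a specimen profile from a taxon's scored observations: one state
#' per (possibly polymorphic) categorical cell, a uniform point inside each
#' numerical interval. With probability `unknown_rate` a character is left
#' unanswered (the observer could not see it); with probability `noise_rate`
#' an answered value is replaced by a wrong one (a state the taxon does not
#' carry, or a point outside its interval). Characters the taxon itself is
#' unknown or inapplicable for are never answered.
#'
#' @param kb A [knowledge_base()].
#' @param taxon_id The true taxon.
#' @param noise_rate,unknown_rate Probabilities in `[0, 1]`.
#' @param seed Mandatory integer seed.
#' @return A [specimen_profile()].
#' @examples
#' kb <- platynini_kb()
#' p <- sample_specimen(kb, "agonum_marginatum", seed = 7)
#' "agonum_marginatum" %in% filter_taxa(kb, p)   # always TRUE at noise 0
#' @export
sample_specimen <- function(kb, taxon_id, noise_rate = 0, unknown_rate = 0,
                            seed) {
  tx <- kb_taxon(kb, taxon_id)
  stopifnot(noise_rate >= 0, noise_rate <= 1,
            unknown_rate >= 0, unknown_rate <= 1)
  with_seed(seed, {
    answers <- list()
    for (char_id in names(kb$characters)) {
      obs <- tx$observations[[char_id]]
      if (!is_scored(obs)) next
      if (stats::runif(1) < unknown_rate) next
      ch <- kb$characters[[char_id]]
      if (ch$kind == "categorical") {
        value <- sample(obs$states, 1L)
        if (stats::runif(1) < noise_rate) {
          wrong <- setdiff(state_ids(ch), obs$states)
          if (length(wrong)) value <- sample(wrong, 1L)
        }
        answers[[char_id]] <- value
      } else {
        value <- stats::runif(1, obs$range[1], obs$range[2])
        if (stats::runif(1) < noise_rate) {
          span <- max(obs$range[2] - obs$range[1], 1)
          value <- if (stats::runif(1) < 0.5) obs$range[1] - stats::runif(1, 0, span)
            else obs$range[2] + stats::runif(1, 0, span)
        }
        answers[[char_id]] <- value
      }
    }
    specimen_profile(.answers = answers)
  })
}

#' Monte-Carlo identification accuracy
#'
#' Repeatedly samples synthetic specimens of every taxon with
#' [sample_specimen()] and checks containment: does the multi-access filter
#' keep the true taxon among the remaining candidates? At noise 0 the rate
#' is 1 by construction; under noise it measures the engine's sensitivity to
#' wrongly observed characters.
#'
#' @param kb A valid [knowledge_base()].
#' @param noise_rate,unknown_rate Passed to [sample_specimen()].
#' @param reps Specimens per taxon.
#' @param seed Mandatory integer seed (each specimen draws a sub-seed from
#'   one stream, so results are reproducible).
#' @return A list with `accuracy` (containment rate over all draws),
#'   `n_draws`, and `per_taxon` (named rates).
#' @export
simulate_identification <- function(kb, noise_rate = 0, unknown_rate = 0,
                                    reps = 20L, seed) {
  assert_valid_kb(kb)
  sub_seeds <- with_seed(seed,
    sample.int(.Machine$integer.max, length(kb$taxa) * reps))
  hits <- matrix(NA, nrow = reps, ncol = length(kb$taxa),
                 dimnames = list(NULL, names(kb$taxa)))
  k <- 0L
  for (taxon_id in names(kb$taxa)) {
    for (r in seq_len(reps)) {
      k <- k + 1L
      prof <- sample_specimen(kb, taxon_id, noise_rate = noise_rate,
                              unknown_rate = unknown_rate,
                              seed = sub_seeds[k])
      hits[r, taxon_id] <- taxon_id %in% filter_taxa(kb, prof)
    }
  }
  list(accuracy = mean(hits), n_draws = length(hits),
       per_taxon = colMeans(hits))
}
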