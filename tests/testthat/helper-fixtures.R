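# Small hand-built knowledge bases and an independent brute-force
# compatibility oracle used by the property tests.

# Three beetles, two binary characters and one numerical character.
toy_kb <- function() {
  knowledge_base(
    "toy",
    characters = list(
      char_def("wings", "Wing development", "categorical",
               states = c(full = "full", reduced = "reduced")),
      char_def("color", "Color", "categorical",
               states = c(red = "red", blue = "blue", green = "green")),
      char_def("length", "Length", "numerical", units = "mm")),
    taxa = list(
      taxon_desc("t1", "Taxon one", observations = list(
        wings = obs_states("full"),
        color = obs_states(c("red", "blue")),
        length = obs_range(2, 4))),
      taxon_desc("t2", "Taxon two", observations = list(
        wings = obs_states("reduced"),
        color = obs_states("blue"),
        length = obs_range(5, 7))),
      taxon_desc("t3", "Taxon three", observations = list(
        wings = obs_states("full"),
        color = obs_unknown(),
        length = obs_range(3.5, 6)))))
}

# Brute-force reference for filter_taxa: expands every answered state/point
# against every cell with bare set arithmetic, independently of the package's
# compatibility code path.
oracle_filter <- function(kb, profile) {
  keep <- character()
  for (taxon_id in names(kb$taxa)) {
    tx <- kb$taxa[[taxon_id]]
    ok <- TRUE
    for (char_id in names(profile)) {
      obs <- tx$observations[[char_id]]
      if (obs$status != "scored") next
      ch <- kb$characters[[char_id]]
      ans <- profile[[char_id]]
      if (ch$kind == "categorical") {
        overlap <- 0L
        for (a in as.character(ans)) for (s in obs$states)
          if (identical(a, s)) overlap <- overlap + 1L
        if (overlap == 0L) ok <- FALSE
      } else {
        a <- as.numeric(ans)
        if (length(a) == 1L) a <- c(a, a)
        # enumerate: does any point of the answer lie in the cell interval?
        inside <- !(a[2] < obs$range[1]) && !(a[1] > obs$range[2])
        if (!inside) ok <- FALSE
      }
      if (!ok) break
    }
    if (ok) keep <- c(keep, taxon_id)
  }
  keep
}

# A random legal profile over a knowledge base (answers arbitrary states /
# points, not necessarily drawn from any taxon).
random_profile <- function(kb, n_answers, seed) {
  set.seed(seed)
  chars <- sample(names(kb$characters), min(n_answers, length(kb$characters)))
  answers <- list()
  for (char_id in chars) {
    ch <- kb$characters[[char_id]]
    answers[[char_id]] <- if (ch$kind == "categorical")
      sample(ch$states$state_id, sample(1:2, 1))
    else round(runif(1, 0, 12), 2)
  }
  specimen_profile(.answers = answers)
}
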