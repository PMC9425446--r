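#' Specimen profiles
#'
#' A specimen profile is the user-side observation vector of the interactive
#' key: a partial mapping from character ids to answers. A categorical answer
#' is a non-empty set of state ids (a single selection is a singleton set);
#' a numerical answer is a measured point, or an interval `c(lo, hi)` when a
#' whole description (e.g. a taxon's own scoring) is replayed against a key.
#'
#' @param ... Named answers, e.g.
#'   `specimen_profile(hairs_upperside = "present", body_length = 6.1)`.
#' @param .answers Alternatively, a named list of answers.
#' @return An object of class `specimen_profile`.
#' @export
specimen_profile <- function(..., .answers = NULL) {
  answers <- if (is.null(.answers)) list(...) else .answers
  if (length(answers) &&
      (is.null(names(answers)) || any(!nzchar(names(answers)))))
    stop("profile answers must be named by character id", call. = FALSE)
  if (anyDuplicated(names(answers)))
    stop("duplicate character ids in profile", call. = FALSE)
  structure(answers, class = "specimen_profile")
}

#' @export
print.specimen_profile <- function(x, ...) {
  cat("<specimen_profile> ", length(x), " answered character(s)\n", sep = "")
  for (ch in names(x))
    cat("  ", ch, " = ", paste(x[[ch]], collapse = " | "), "\n", sep = "")
  invisible(x)
}

# Check one answer against the character it addresses; returns the answer
# normalised (categorical: character vector of state ids; numerical: numeric
# interval of length 2).
check_answer <- function(kb, char_id, answer) {
  ch <- kb_char(kb, char_id)
  if (ch$kind == "categorical") {
    answer <- as.character(answer)
    if (length(answer) == 0L)
      stop("empty answer for character '", char_id, "'", call. = FALSE)
    bad <- setdiff(answer, state_ids(ch))
    if (length(bad))
      stop("unknown state id(s) for character '", char_id, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
    unique(answer)
  } else {
    answer <- as.numeric(answer)
    if (!length(answer) %in% 1:2 || anyNA(answer))
      stop("numerical answer for '", char_id,
           "' must be a point or an interval c(lo, hi)", call. = FALSE)
    if (length(answer) == 1L) answer <- c(answer, answer)
    if (answer[1] > answer[2])
      stop("numerical answer for '", char_id, "' has lo > hi", call. = FALSE)
    answer
  }
}

#' Is a taxon description compatible with a specimen profile?
#'
#' A taxon remains a candidate as long as every answered character agrees
#' with its description: cells scored unknown or inapplicable are compatible
#' with anything; a categorical answer agrees when it shares at least one
#' state with the taxon's (possibly polymorphic) state set; a numerical point
#' agrees when it falls inside the taxon's closed interval (an interval
#' answer, when it overlaps it). An empty profile is vacuously compatible
#' with every taxon.
#'
#' @param kb A [knowledge_base()].
#' @param taxon A taxon id or a `taxon_description`.
#' @param profile A [specimen_profile()].
#' @return `TRUE` or `FALSE`.
#' @export
compatible <- function(kb, taxon, profile) {
  tx <- if (inherits(taxon, "taxon_description")) taxon else kb_taxon(kb, taxon)
  for (char_id in names(profile)) {
    ans <- check_answer(kb, char_id, profile[[char_id]])
    obs <- tx$observations[[char_id]]
    if (is.null(obs) || !is_scored(obs)) next  # unknown/inapplicable: always ok
    if (kb_char(kb, char_id)$kind == "categorical") {
      if (!any(ans %in% obs$states)) return(FALSE)
    } else {
      if (ans[2] < obs$range[1] || ans[1] > obs$range[2]) return(FALSE)
    }
  }
  TRUE
}

#' Eliminate incompatible taxa
#'
#' The elimination step of the multi-access key: returns exactly the taxa
#' compatible with the profile, in knowledge-base order.
#'
#' @inheritParams compatible
#' @return Character vector of taxon ids.
#' @examples
#' kb <- platynini_kb()
#' filter_taxa(kb, specimen_profile(hairs_upperside = "present"))
#' @export
filter_taxa <- function(kb, profile) {
  keep <- vapply(kb$taxa, compatible, logical(1), kb = kb, profile = profile)
  names(kb$taxa)[keep]
}

# Does a character separate a pair of taxa? Only scored-vs-scored pairs can
# be separated: disjoint state sets (categorical) or disjoint closed
# intervals (numerical). Returns NA when either cell is not scored.
pair_separated <- function(ch, obs1, obs2) {
  if (!is_scored(obs1) || !is_scored(obs2)) return(NA)
  if (ch$kind == "categorical")
    !any(obs1$states %in% obs2$states)
  else
    obs1$range[2] < obs2$range[1] || obs2$range[2] < obs1$range[1]
}

#' Discriminatory power of a character
#'
#' Pairwise-separation index over the remaining taxa: the fraction of
#' unordered taxon pairs, among those where both taxa are scored for the
#' character, that the character separates (disjoint state sets, or disjoint
#' closed intervals). Unknown and inapplicable cells drop out of both the
#' numerator and the denominator; a character with no scored pair has
#' power 0. The index is 0 when the character cannot split the remaining
#' taxa at all and 1 when it splits every scored pair.
#'
#' @param kb A [knowledge_base()].
#' @param char_id Character id.
#' @param remaining Taxon ids still in play (default: all taxa). At least two.
#' @return A number in `[0, 1]`.
#' @export
discriminatory_power <- function(kb, char_id, remaining = names(kb$taxa)) {
  if (length(remaining) < 2L)
    stop("discriminatory power needs at least two remaining taxa",
         call. = FALSE)
  ch <- kb_char(kb, char_id)
  obs <- lapply(remaining, function(t) kb_taxon(kb, t)$observations[[char_id]])
  n <- length(obs)
  sep <- 0L; scored_pairs <- 0L
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    s <- pair_separated(ch, obs[[i]], obs[[j]])
    if (is.na(s)) next
    scored_pairs <- scored_pairs + 1L
    if (s) sep <- sep + 1L
  }
  if (scored_pairs == 0L) 0 else sep / scored_pairs
}

#' Options controlling character ranking
#'
#' The composite ordering used by [rank_characters()], [suggest_next()] and
#' [build_single_access_key()]:
#'
#' * `policy = "power"` (default): discriminatory power, descending.
#' * `policy = "fewer_states"`: state count ascending (numerical characters
#'   count as two, via their binarisation in the key generator), then power.
#' * `policy = "most_states"`: state count descending, then power. This is
#'   the "start with the character with the most states" strategy that makes
#'   a many-state coloration character the first question.
#'
#' With `use_weights = TRUE` the character weight (descending) is inserted
#' immediately after the primary criterion. The final tie-break is always
#' declaration order in the knowledge base.
#'
#' @param policy Ranking policy, see above.
#' @param use_weights Insert the 1/2/3 character weight into the ordering?
#' @return An object of class `ranking_options`.
#' @export
ranking_options <- function(policy = c("power", "fewer_states", "most_states"),
                            use_weights = FALSE) {
  policy <- match.arg(policy)
  stopifnot(is.logical(use_weights), length(use_weights) == 1L)
  structure(list(policy = policy, use_weights = use_weights),
            class = "ranking_options")
}

# Core ranking over an explicit remaining set, excluding given characters.
# Characters with zero power are dropped: they cannot help identification.
rank_characters_impl <- function(kb, remaining, exclude = character(),
                                 options = ranking_options()) {
  cand <- setdiff(names(kb$characters), exclude)
  if (length(remaining) < 2L || length(cand) == 0L) return(character())
  power <- vapply(cand, discriminatory_power, numeric(1),
                  kb = kb, remaining = remaining)
  cand <- cand[power > 0]
  power <- power[power > 0]
  if (length(cand) == 0L) return(character())
  nstates <- vapply(cand, function(id) n_effective_states(kb$characters[[id]]),
                    integer(1))
  weight <- vapply(cand, function(id) kb$characters[[id]]$weight, integer(1))
  decl <- match(cand, names(kb$characters))
  keys <- switch(options$policy,
    power        = list(-power),
    fewer_states = list(nstates, -power),
    most_states  = list(-nstates, -power))
  if (options$use_weights) keys <- append(keys, list(-weight), after = 1L)
  keys <- c(keys, list(decl))
  cand[do.call(order, keys)]
}

#' Rank characters by usefulness for the next question
#'
#' Orders the characters a user should consider next, given what has already
#' been answered: answered characters and characters that cannot separate any
#' pair of the remaining taxa are excluded, the rest are sorted by the
#' composite ordering of [ranking_options()].
#'
#' @param kb A [knowledge_base()].
#' @param profile Answers given so far (default: none). The remaining taxa
#'   are derived from it via [filter_taxa()].
#' @param options A [ranking_options()] object.
#' @return Character vector of character ids, best first.
#' @examples
#' kb <- platynini_kb()
#' head(rank_characters(kb, options = ranking_options("most_states")), 3)
#' @export
rank_characters <- function(kb, profile = specimen_profile(),
                            options = ranking_options()) {
  remaining <- filter_taxa(kb, profile)
  if (length(remaining) < 2L)
    stop("character ranking needs at least two remaining taxa", call. = FALSE)
  rank_characters_impl(kb, remaining, exclude = names(profile),
                       options = options)
}
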