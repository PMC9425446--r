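#' Interactive identification sessions
#'
#' A session is the stateful form of the multi-access key: characters are
#' answered in any order, each answer eliminates incompatible taxa, and the
#' engine suggests which character to look at next. The remaining taxa after
#' any sequence of answers depend only on the set of answers, not on their
#' order.
#'
#' @param kb A valid [knowledge_base()].
#' @param options A [ranking_options()] controlling [suggest_next()].
#' @return `new_session()` returns an object of class
#'   `identification_session`.
#' @examples
#' s <- new_session(platynini_kb())
#' s <- answer_character(s, "hairs_upperside", "present")
#' remaining_taxa(s)
#' suggest_next(s)
#' @export
new_session <- function(kb, options = ranking_options()) {
  assert_valid_kb(kb)
  stopifnot(inherits(options, "ranking_options"))
  structure(list(kb = kb, options = options, answers = list(),
                 remaining = names(kb$taxa)),
            class = "identification_session")
}

#' @rdname new_session
#' @param session An `identification_session`.
#' @param char_id Character to answer; answering the same character twice is
#'   an error.
#' @param answer The observation: state id(s) for a categorical character, a
#'   point or interval for a numerical one.
#' @export
answer_character <- function(session, char_id, answer) {
  stopifnot(inherits(session, "identification_session"))
  if (char_id %in% names(session$answers))
    stop("character '", char_id, "' was already answered", call. = FALSE)
  answer <- check_answer(session$kb, char_id, answer)
  session$answers[[char_id]] <- answer
  session$remaining <- filter_taxa(session$kb, session_profile(session))
  session
}

#' @rdname new_session
#' @export
session_profile <- function(session) {
  specimen_profile(.answers = session$answers)
}

#' @rdname new_session
#' @export
remaining_taxa <- function(session) session$remaining

#' Suggest the next characters to examine
#'
#' Ranks the still-unanswered, still-discriminating characters for the
#' session's remaining taxa under the session's [ranking_options()]. With a
#' single remaining taxon there is nothing left to ask and the list is
#' empty.
#'
#' @param session An `identification_session`.
#' @return Character vector of character ids, best first.
#' @export
suggest_next <- function(session) {
  stopifnot(inherits(session, "identification_session"))
  if (length(session$remaining) < 2L) return(character())
  rank_characters_impl(session$kb, session$remaining,
                       exclude = names(session$answers),
                       options = session$options)
}

#' @export
print.identification_session <- function(x, ...) {
  cat("<identification_session> ", length(x$answers), " answer(s), ",
      length(x$remaining), " taxa remaining\n", sep = "")
  invisible(x)
}

#' Decisions needed to identify each taxon
#'
#' Simulates, for every taxon, an idealised user running an interactive
#' session: at each step the top suggestion is answered with the taxon's own
#' scored observation (full state set for polymorphic cells, full interval
#' for numerical ones); characters the taxon is unknown or inapplicable for
#' are skipped to the next suggestion. The session ends when the remaining
#' set is exactly the taxon (resolved) or when no answerable character
#' discriminates any further (unresolved: the taxon is indistinguishable
#' from the rest of its group under this matrix).
#'
#' @param kb A valid [knowledge_base()].
#' @param options A [ranking_options()]; the policy determines the question
#'   order, so it determines the counts.
#' @return A data frame with columns `taxon_id`, `decisions` (number of
#'   answered characters when the session ended) and `resolved`.
#' @examples
#' dp <- decision_profile(platynini_kb(), ranking_options("most_states"))
#' range(dp$decisions[dp$resolved])
#' @export
decision_profile <- function(kb, options = ranking_options()) {
  assert_valid_kb(kb)
  rows <- lapply(names(kb$taxa), function(taxon_id) {
    truth <- kb$taxa[[taxon_id]]$observations
    answered <- list()
    remaining <- names(kb$taxa)
    repeat {
      if (identical(remaining, taxon_id)) break
      sugg <- rank_characters_impl(kb, remaining,
                                   exclude = names(answered),
                                   options = options)
      sugg <- sugg[vapply(sugg, function(ch) is_scored(truth[[ch]]),
                          logical(1))]
      if (length(sugg) == 0L) break
      ch <- sugg[[1]]
      obs <- truth[[ch]]
      answered[[ch]] <-
        if (kb$characters[[ch]]$kind == "categorical") obs$states
        else obs$range
      remaining <- filter_taxa(kb, specimen_profile(.answers = answered))
    }
    data.frame(taxon_id = taxon_id, decisions = length(answered),
               resolved = identical(remaining, taxon_id),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
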