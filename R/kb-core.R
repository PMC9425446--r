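#' Define a character (descriptor)
#'
#' A character is one observable feature of the taxa in a knowledge base:
#' either categorical, with an ordered list of discrete states, or numerical,
#' with a measurement unit. Characters carry a three-level weight
#' (weak = 1, medium = 2, strong = 3) used by the ranking options of the
#' interactive engine and the key generator.
#'
#' @param char_id Opaque identifier, unique within a knowledge base.
#' @param name Human-readable character name.
#' @param kind `"categorical"` or `"numerical"`.
#' @param states For categorical characters, the ordered states: either a
#'   character vector of state ids, or a named character vector
#'   `c(state_id = "label", ...)`, or a data frame with columns `state_id`
#'   and `label`. Must be empty for numerical characters.
#' @param units Measurement unit (numerical characters only), e.g. `"mm"`.
#' @param weight Integer 1 (weak), 2 (medium, default) or 3 (strong).
#' @param group Optional free-text grouping tag (e.g. `"pronotum"`).
#' @return An object of class `character_def`.
#' @examples
#' char_def("hairs_upperside", "Hairs on upper side", "categorical",
#'          states = c(present = "present", absent = "absent"))
#' char_def("body_length", "Body length", "numerical", units = "mm")
#' @export
char_def <- function(char_id, name, kind = c("categorical", "numerical"),
                     states = NULL, units = "", weight = 2L, group = "") {
  kind <- match.arg(kind)
  stopifnot(is.character(char_id), length(char_id) == 1L, nzchar(char_id),
            is.character(name), length(name) == 1L)
  weight <- as.integer(weight)
  if (length(weight) != 1L || is.na(weight) || !weight %in% 1:3)
    stop("'weight' must be 1 (weak), 2 (medium) or 3 (strong)", call. = FALSE)
  states <- as_state_table(states)
  if (kind == "categorical") {
    if (nrow(states) == 0L)
      stop("categorical character '", char_id, "' needs a non-empty state list",
           call. = FALSE)
    if (anyDuplicated(states$state_id))
      stop("duplicate state ids in character '", char_id, "'", call. = FALSE)
    if (nzchar(units))
      stop("'units' is only meaningful for numerical characters", call. = FALSE)
  } else {
    if (nrow(states) > 0L)
      stop("numerical character '", char_id, "' must not declare states",
           call. = FALSE)
  }
  structure(
    list(char_id = char_id, name = name, kind = kind, states = states,
         units = units, weight = weight, group = group),
    class = "character_def"
  )
}

as_state_table <- function(states) {
  if (is.null(states))
    return(data.frame(state_id = character(), label = character(),
                      stringsAsFactors = FALSE))
  if (is.data.frame(states)) {
    stopifnot(all(c("state_id", "label") %in% names(states)))
    return(data.frame(state_id = as.character(states$state_id),
                      label = as.character(states$label),
                      stringsAsFactors = FALSE))
  }
  ids <- if (is.null(names(states))) as.character(states) else names(states)
  data.frame(state_id = ids, label = as.character(states),
             stringsAsFactors = FALSE)
}

#' Observations: how a taxon is scored for one character
#'
#' Each cell of the matrix is one observation with a status:
#' `scored` (carrying a value), `unknown`, or `inapplicable`. A scored
#' categorical value is a non-empty subset of the character's states (more
#' than one state = polymorphism); a scored numerical value is a closed
#' interval `[lo, hi]` (a single measurement is the degenerate interval
#' `lo == hi`). Unknown and inapplicable cells are compatible with any
#' specimen observation and are excluded from discriminatory-power scoring.
#'
#' @param states Character vector of state ids the taxon exhibits.
#' @param lo,hi Interval bounds, `lo <= hi`.
#' @param source Free-text provenance note for the scored value (e.g. the
#'   literature couplet or table row it was transcribed from).
#' @return An object of class `observation`.
#' @examples
#' obs_states(c("present"))
#' obs_range(5.5, 8)            # body length 5.5-8 mm
#' obs_unknown()
#' @export
obs_states <- function(states, source = "") {
  states <- as.character(states)
  if (length(states) == 0L || anyNA(states) || !all(nzchar(states)))
    stop("a scored categorical observation needs at least one state id",
         call. = FALSE)
  structure(list(status = "scored", states = unique(states), range = NULL,
                 source = source),
            class = "observation")
}

#' @rdname obs_states
#' @export
obs_range <- function(lo, hi = lo, source = "") {
  lo <- as.numeric(lo); hi <- as.numeric(hi)
  if (anyNA(c(lo, hi)) || length(lo) != 1L || length(hi) != 1L || lo > hi)
    stop("numerical observation needs a closed interval with lo <= hi",
         call. = FALSE)
  structure(list(status = "scored", states = NULL, range = c(lo, hi),
                 source = source),
            class = "observation")
}

#' @rdname obs_states
#' @export
obs_unknown <- function(source = "") {
  structure(list(status = "unknown", states = NULL, range = NULL,
                 source = source),
            class = "observation")
}

#' @rdname obs_states
#' @export
obs_inapplicable <- function(source = "") {
  structure(list(status = "inapplicable", states = NULL, range = NULL,
                 source = source),
            class = "observation")
}

is_scored <- function(obs) identical(obs$status, "scored")

#' Describe a taxon
#'
#' One item of the knowledge base: a taxon with its scored observations.
#' Characters not listed in `observations` are filled in as unknown when the
#' taxon is assembled into a [knowledge_base()].
#'
#' @param taxon_id Opaque identifier, unique within a knowledge base.
#' @param name Scientific name.
#' @param in_region Does the taxon occur in the region the knowledge base
#'   covers? Taxa kept in the matrix for completeness (e.g. species that may
#'   occur just outside the study region) carry `FALSE`.
#' @param observations Named list of [obs_states()]/[obs_range()]/
#'   [obs_unknown()]/[obs_inapplicable()] values, named by character id.
#' @param notes Free text.
#' @return An object of class `taxon_description`.
#' @export
taxon_desc <- function(taxon_id, name, in_region = TRUE,
                       observations = list(), notes = "") {
  stopifnot(is.character(taxon_id), length(taxon_id) == 1L, nzchar(taxon_id),
            is.character(name), length(name) == 1L,
            is.logical(in_region), length(in_region) == 1L, !is.na(in_region),
            is.list(observations))
  if (length(observations) &&
      (is.null(names(observations)) || any(!nzchar(names(observations)))))
    stop("'observations' must be named by character id", call. = FALSE)
  ok <- vapply(observations, inherits, logical(1), what = "observation")
  if (!all(ok))
    stop("all observations must be built with obs_states()/obs_range()/",
         "obs_unknown()/obs_inapplicable()", call. = FALSE)
  structure(
    list(taxon_id = taxon_id, name = name, in_region = in_region,
         observations = observations, notes = notes),
    class = "taxon_description"
  )
}

#' Assemble a knowledge base
#'
#' The knowledge base is the unit every other function operates on: an
#' ordered list of characters, an ordered list of taxa, and one observation
#' per (taxon, character) cell. Missing cells are filled as unknown;
#' observations for undeclared characters are a structural error reported by
#' [validate_kb()].
#'
#' @param title Title of the knowledge base.
#' @param characters List of [char_def()] objects (declaration order is
#'   meaningful: it is the final tie-break of character ranking).
#' @param taxa List of [taxon_desc()] objects.
#' @param notes Free-text provenance notes.
#' @return An object of class `knowledge_base`.
#' @seealso [validate_kb()], [platynini_kb()] for a complete worked example.
#' @export
knowledge_base <- function(title, characters, taxa, notes = "") {
  stopifnot(is.character(title), length(title) == 1L,
            is.list(characters), is.list(taxa))
  if (!all(vapply(characters, inherits, logical(1), what = "character_def")))
    stop("'characters' must be a list of char_def objects", call. = FALSE)
  if (!all(vapply(taxa, inherits, logical(1), what = "taxon_description")))
    stop("'taxa' must be a list of taxon_desc objects", call. = FALSE)
  names(characters) <- vapply(characters, `[[`, character(1), "char_id")
  names(taxa) <- vapply(taxa, `[[`, character(1), "taxon_id")
  # fill unscored cells as unknown so every description is total, and store
  # observations in character declaration order (canonical for all formats)
  for (t in names(taxa)) {
    missing <- setdiff(names(characters), names(taxa[[t]]$observations))
    for (m in missing) taxa[[t]]$observations[[m]] <- obs_unknown()
    known <- intersect(names(characters), names(taxa[[t]]$observations))
    extra <- setdiff(names(taxa[[t]]$observations), names(characters))
    taxa[[t]]$observations <- taxa[[t]]$observations[c(known, extra)]
  }
  structure(list(title = title, characters = characters, taxa = taxa,
                 notes = notes),
            class = "knowledge_base")
}

kb_char <- function(kb, char_id) {
  ch <- kb$characters[[char_id]]
  if (is.null(ch))
    stop("unknown character id: '", char_id, "'", call. = FALSE)
  ch
}

kb_taxon <- function(kb, taxon_id) {
  tx <- kb$taxa[[taxon_id]]
  if (is.null(tx))
    stop("unknown taxon id: '", taxon_id, "'", call. = FALSE)
  tx
}

state_ids <- function(ch) ch$states$state_id

#' Number of states a character contributes to ranking
#'
#' Categorical characters count their declared states; numerical characters
#' count as two, because key generation binarises them at gaps between taxon
#' intervals.
#' @noRd
n_effective_states <- function(ch) {
  if (ch$kind == "categorical") nrow(ch$states) else 2L
}

#' @export
print.character_def <- function(x, ...) {
  cat("<character_def> ", x$char_id, ": ", x$name, " [", x$kind, "]", sep = "")
  if (x$kind == "categorical")
    cat(", ", nrow(x$states), " states", sep = "")
  else if (nzchar(x$units))
    cat(" (", x$units, ")", sep = "")
  cat(", weight", x$weight, "\n")
  invisible(x)
}

#' @export
print.knowledge_base <- function(x, ...) {
  cat("<knowledge_base> \"", x$title, "\": ", length(x$taxa), " taxa x ",
      length(x$characters), " characters\n", sep = "")
  invisible(x)
}

#' @export
print.taxon_description <- function(x, ...) {
  scored <- sum(vapply(x$observations, is_scored, logical(1)))
  cat("<taxon_description> ", x$taxon_id, " (", x$name, "), ",
      scored, "/", length(x$observations), " characters scored",
      if (!x$in_region) ", outside region" else "", "\n", sep = "")
  invisible(x)
}
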