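#' Validate a knowledge base
#'
#' Structural checks (errors) and completeness diagnostics (warnings).
#' Errors make the knowledge base unusable by the other modules: duplicate
#' character/taxon/state ids, empty character or taxon lists, observations
#' for undeclared characters, or cell values that do not fit their character
#' (states outside the declared list, intervals on categorical characters and
#' vice versa). Warnings flag scientific weaknesses that do not prevent use:
#' characters unknown for every taxon, characters that separate no pair of
#' taxa, and taxon pairs no character separates (indistinguishable in this
#' matrix).
#'
#' @param kb A [knowledge_base()].
#' @return An object of class `kb_validation` with elements `errors`
#'   (character vector), `warnings` (list with `all_unknown_characters`,
#'   `non_separating_characters`, `indistinguishable_pairs`), and `valid`
#'   (`TRUE` iff no errors).
#' @examples
#' rep <- validate_kb(platynini_kb())
#' rep$valid
#' @export
validate_kb <- function(kb) {
  stopifnot(inherits(kb, "knowledge_base"))
  errors <- character()
  err <- function(...) errors <<- c(errors, paste0(...))

  char_ids <- names(kb$characters)
  taxon_ids <- names(kb$taxa)
  if (length(char_ids) == 0L) err("knowledge base declares no characters")
  if (length(taxon_ids) == 0L) err("knowledge base contains no taxa")
  if (anyDuplicated(char_ids))
    err("duplicate character ids: ",
        paste(unique(char_ids[duplicated(char_ids)]), collapse = ", "))
  if (anyDuplicated(taxon_ids))
    err("duplicate taxon ids: ",
        paste(unique(taxon_ids[duplicated(taxon_ids)]), collapse = ", "))

  for (tx in kb$taxa) {
    extra <- setdiff(names(tx$observations), char_ids)
    if (length(extra))
      err("taxon '", tx$taxon_id, "' scores undeclared character(s): ",
          paste(extra, collapse = ", "))
    missing <- setdiff(char_ids, names(tx$observations))
    if (length(missing))
      err("taxon '", tx$taxon_id, "' lacks observations for: ",
          paste(missing, collapse = ", "))
    for (char_id in intersect(names(tx$observations), char_ids)) {
      obs <- tx$observations[[char_id]]
      ch <- kb$characters[[char_id]]
      if (!inherits(obs, "observation")) {
        err("taxon '", tx$taxon_id, "', character '", char_id,
            "': not an observation object")
        next
      }
      if (!is_scored(obs)) next
      if (ch$kind == "categorical") {
        if (is.null(obs$states)) {
          err("taxon '", tx$taxon_id, "', character '", char_id,
              "': categorical cell without states")
        } else {
          bad <- setdiff(obs$states, state_ids(ch))
          if (length(bad))
            err("taxon '", tx$taxon_id, "', character '", char_id,
                "': undeclared state(s) ", paste(bad, collapse = ", "))
        }
      } else if (is.null(obs$range)) {
        err("taxon '", tx$taxon_id, "', character '", char_id,
            "': numerical cell without interval")
      }
    }
  }

  warnings <- list(all_unknown_characters = character(),
                   non_separating_characters = character(),
                   indistinguishable_pairs = list())
  if (length(errors) == 0L) {
    for (char_id in char_ids) {
      scored <- vapply(kb$taxa, function(tx)
        is_scored(tx$observations[[char_id]]), logical(1))
      if (!any(scored))
        warnings$all_unknown_characters <-
          c(warnings$all_unknown_characters, char_id)
      else if (length(taxon_ids) >= 2L &&
               discriminatory_power(kb, char_id) == 0)
        warnings$non_separating_characters <-
          c(warnings$non_separating_characters, char_id)
    }
    n <- length(taxon_ids)
    if (n >= 2L) {
      for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
        separated <- FALSE
        for (char_id in char_ids) {
          s <- pair_separated(kb$characters[[char_id]],
                              kb$taxa[[i]]$observations[[char_id]],
                              kb$taxa[[j]]$observations[[char_id]])
          if (isTRUE(s)) { separated <- TRUE; break }
        }
        if (!separated)
          warnings$indistinguishable_pairs <-
            c(warnings$indistinguishable_pairs,
              list(c(taxon_ids[i], taxon_ids[j])))
      }
    }
  }

  structure(list(errors = errors, warnings = warnings,
                 valid = length(errors) == 0L),
            class = "kb_validation")
}

#' @export
print.kb_validation <- function(x, ...) {
  cat("<kb_validation> ", if (x$valid) "valid" else "INVALID", "\n", sep = "")
  for (e in x$errors) cat("  error: ", e, "\n", sep = "")
  w <- x$warnings
  if (length(w$all_unknown_characters))
    cat("  warning: all-unknown characters: ",
        paste(w$all_unknown_characters, collapse = ", "), "\n", sep = "")
  if (length(w$non_separating_characters))
    cat("  warning: characters separating no pair: ",
        paste(w$non_separating_characters, collapse = ", "), "\n", sep = "")
  for (p in w$indistinguishable_pairs)
    cat("  warning: indistinguishable taxa: ", p[1], " / ", p[2], "\n",
        sep = "")
  invisible(x)
}

# Stop unless the knowledge base passes structural validation.
assert_valid_kb <- function(kb) {
  rep <- validate_kb(kb)
  if (!rep$valid)
    stop("invalid knowledge base:\n  ",
         paste(rep$errors, collapse = "\n  "), call. = FALSE)
  invisible(kb)
}

#' Noiseless profile of a taxon
#'
#' Replays a taxon's own scored observations as a specimen profile:
#' polymorphic cells answer with their full state set, numerical cells with
#' their full interval; unknown and inapplicable cells are left unanswered.
#' Used by the consistency checks between a knowledge base and a key.
#'
#' @param kb A [knowledge_base()].
#' @param taxon_id Taxon id.
#' @return A [specimen_profile()].
#' @export
noiseless_profile <- function(kb, taxon_id) {
  tx <- kb_taxon(kb, taxon_id)
  answers <- list()
  for (char_id in names(kb$characters)) {
    obs <- tx$observations[[char_id]]
    if (!is_scored(obs)) next
    answers[[char_id]] <-
      if (kb$characters[[char_id]]$kind == "categorical") obs$states
      else obs$range
  }
  specimen_profile(.answers = answers)
}
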