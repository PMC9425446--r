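#' Build blocks of a dichotomous key
#'
#' A dichotomous key is an ordered set of numbered couplets; each couplet
#' offers two contrasting leads; each lead carries the printed text, a set of
#' machine-readable predicates over knowledge-base characters, and a target:
#' another couplet or a taxon. `pred_states()`/`pred_range()` build the
#' predicates, `key_lead()` one lead, `key_couplet()` one couplet and
#' `dichotomous_key()` the whole key.
#'
#' @param char_id Character id the predicate tests.
#' @param states State ids the lead asserts (categorical characters).
#' @param lo,hi Closed interval the lead asserts (numerical characters).
#' @param text Printed lead text.
#' @param predicates List of predicates; a lead is satisfied when every
#'   predicate holds for the profile (see [traverse_dichotomous()]).
#' @param couplet Target couplet number (exclusive with `taxon`).
#' @param taxon Target taxon id (exclusive with `couplet`).
#' @param label Display name for a taxon target (defaults to the id).
#' @param parenthesized Is the taxon listed in parentheses (e.g. expected
#'   but not yet recorded in the region)?
#' @param number Couplet number.
#' @param lead1,lead2 The two [key_lead()]s.
#' @param couplets List of [key_couplet()]s; couplet 1 is the entry point.
#' @param title Optional key title.
#' @return Objects of class `key_pred`, `key_lead`, `key_couplet`,
#'   `dichotomous_key` respectively.
#' @export
pred_states <- function(char_id, states) {
  stopifnot(is.character(char_id), length(char_id) == 1L,
            is.character(states), length(states) >= 1L)
  structure(list(char_id = char_id, states = unique(states), range = NULL),
            class = "key_pred")
}

#' @rdname pred_states
#' @export
pred_range <- function(char_id, lo, hi = lo) {
  stopifnot(is.character(char_id), length(char_id) == 1L,
            is.numeric(lo), is.numeric(hi), lo <= hi)
  structure(list(char_id = char_id, states = NULL, range = c(lo, hi)),
            class = "key_pred")
}

#' @rdname pred_states
#' @export
key_lead <- function(text, predicates = list(), couplet = NULL, taxon = NULL,
                     label = taxon, parenthesized = FALSE) {
  if (is.null(couplet) == is.null(taxon))
    stop("a lead targets either a couplet or a taxon, exactly one",
         call. = FALSE)
  if (!all(vapply(predicates, inherits, logical(1), what = "key_pred")))
    stop("'predicates' must be built with pred_states()/pred_range()",
         call. = FALSE)
  target <- if (!is.null(couplet))
    list(kind = "couplet", couplet = as.integer(couplet))
  else
    list(kind = "taxon", taxon = taxon, label = label,
         parenthesized = isTRUE(parenthesized))
  structure(list(text = text, predicates = predicates, target = target),
            class = "key_lead")
}

#' @rdname pred_states
#' @export
key_couplet <- function(number, lead1, lead2) {
  stopifnot(inherits(lead1, "key_lead"), inherits(lead2, "key_lead"))
  structure(list(number = as.integer(number), leads = list(lead1, lead2)),
            class = "key_couplet")
}

#' @rdname pred_states
#' @export
dichotomous_key <- function(couplets, title = "") {
  if (!all(vapply(couplets, inherits, logical(1), what = "key_couplet")))
    stop("'couplets' must be a list of key_couplet objects", call. = FALSE)
  numbers <- vapply(couplets, `[[`, integer(1), "number")
  if (anyDuplicated(numbers))
    stop("duplicate couplet numbers", call. = FALSE)
  names(couplets) <- as.character(numbers)
  # referenced couplets must exist
  for (cp in couplets) for (ld in cp$leads)
    if (ld$target$kind == "couplet" &&
        !as.character(ld$target$couplet) %in% names(couplets))
      stop("couplet ", cp$number, " points to missing couplet ",
           ld$target$couplet, call. = FALSE)
  structure(list(couplets = couplets, title = title),
            class = "dichotomous_key")
}

#' @export
print.dichotomous_key <- function(x, ...) {
  cat("<dichotomous_key> ", length(x$couplets), " couplets",
      if (nzchar(x$title)) paste0(" (", x$title, ")"), "\n", sep = "")
  invisible(x)
}

lead_satisfied <- function(lead, profile, couplet_number) {
  for (p in lead$predicates) {
    ans <- profile[[p$char_id]]
    if (is.null(ans))
      stop("profile does not answer character '", p$char_id,
           "' needed at couplet ", couplet_number, call. = FALSE)
    if (!is.null(p$states)) {
      ans <- as.character(ans)
      if (!length(ans) || !all(ans %in% p$states)) return(FALSE)
    } else {
      ans <- as.numeric(ans)
      if (length(ans) == 1L) ans <- c(ans, ans)
      if (ans[1] < p$range[1] || ans[2] > p$range[2]) return(FALSE)
    }
  }
  TRUE
}

#' Run a specimen through a dichotomous key
#'
#' Follows the key from couplet 1, at each couplet taking the unique lead
#' whose predicates are all satisfied by the profile. A categorical predicate
#' is satisfied when the whole answer set lies within the lead's asserted
#' states; a numerical predicate when the answered point (or interval) lies
#' within the asserted interval. A profile that satisfies neither lead is an
#' inconsistent specimen; satisfying both leads is an ambiguity in the key.
#' Both raise an error naming the couplet.
#'
#' @param key A [dichotomous_key()].
#' @param profile A [specimen_profile()]; it must answer every character the
#'   traversal needs.
#' @return A list of class `key_traversal` with `taxon` (id), `label`,
#'   `path` (couplet numbers visited) and `decisions` (`length(path)`).
#' @examples
#' kb <- platynini_kb()
#' traverse_dichotomous(platynini_key(),
#'                      noiseless_profile(kb, "orthotrichus_cymindoides"))
#' @export
traverse_dichotomous <- function(key, profile) {
  stopifnot(inherits(key, "dichotomous_key"))
  current <- 1L
  path <- integer()
  repeat {
    cp <- key$couplets[[as.character(current)]]
    if (is.null(cp))
      stop("key has no couplet ", current, call. = FALSE)
    path <- c(path, cp$number)
    if (length(path) > length(key$couplets))
      stop("cycle detected in key at couplet ", cp$number, call. = FALSE)
    sat <- vapply(cp$leads, lead_satisfied, logical(1),
                  profile = profile, couplet_number = cp$number)
    if (sum(sat) == 0L)
      stop("inconsistent specimen: no lead of couplet ", cp$number,
           " is satisfied", call. = FALSE)
    if (sum(sat) > 1L)
      stop("ambiguous specimen: both leads of couplet ", cp$number,
           " are satisfied", call. = FALSE)
    tgt <- cp$leads[[which(sat)]]$target
    if (tgt$kind == "taxon")
      return(structure(list(taxon = tgt$taxon, label = tgt$label,
                            path = path, decisions = length(path)),
                       class = "key_traversal"))
    current <- tgt$couplet
  }
}

#' @export
print.key_traversal <- function(x, ...) {
  cat("<key_traversal> ", x$label, " in ", x$decisions,
      " decisions (couplets ", paste(x$path, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Check a dichotomous key against a knowledge base
#'
#' Regression guard between the two renderings of the same taxonomic
#' knowledge: for every taxon of the knowledge base, its noiseless profile
#' (its own scored observations) is run through the key; the taxon must
#' arrive at its own lead. Traversal errors (inconsistent/ambiguous, missing
#' answers) count as mismatches and are reported verbatim.
#'
#' @param key A [dichotomous_key()].
#' @param kb A valid [knowledge_base()] containing every taxon the key
#'   targets.
#' @return A list of class `key_consistency` with `n_checked`, `mismatches`
#'   (data frame with columns `taxon_id` and `outcome`) and `ok`.
#' @export
check_consistency <- function(key, kb) {
  assert_valid_kb(kb)
  bad_id <- character(); bad_out <- character()
  for (taxon_id in names(kb$taxa)) {
    res <- tryCatch(
      traverse_dichotomous(key, noiseless_profile(kb, taxon_id)),
      error = function(e) conditionMessage(e))
    outcome <- if (is.character(res)) res
      else if (identical(res$taxon, taxon_id)) NA_character_
      else paste0("arrived at '", res$taxon, "'")
    if (!is.na(outcome)) {
      bad_id <- c(bad_id, taxon_id); bad_out <- c(bad_out, outcome)
    }
  }
  structure(list(n_checked = length(kb$taxa),
                 mismatches = data.frame(taxon_id = bad_id, outcome = bad_out,
                                         stringsAsFactors = FALSE),
                 ok = length(bad_id) == 0L),
            class = "key_consistency")
}

#' @export
print.key_consistency <- function(x, ...) {
  cat("<key_consistency> ", x$n_checked, " taxa checked, ",
      nrow(x$mismatches), " mismatch(es)\n", sep = "")
  if (nrow(x$mismatches)) print(x$mismatches)
  invisible(x)
}

#' The printed dichotomous key for Platynini of the southern Levant
#'
#' The 13-couplet dichotomous identification key matching [platynini_kb()],
#' with the printed lead texts and machine predicates over the knowledge
#' base's characters. The predicates encode, for each lead, the character
#' assertions that discriminate at that couplet (e.g. couplet 1 splits on
#' the pubescence of the upper side; couplets 11-13 on pronotum
#' proportions).
#'
#' @return A [dichotomous_key()] with 13 couplets.
#' @examples
#' key <- platynini_key()
#' key_metrics(key)$alternatives  # 13
#' @export
platynini_key <- function() {
  ps <- pred_states; pr <- pred_range
  dichotomous_key(title = "Platynini of the southern Levant", couplets = list(
    key_couplet(1,
      key_lead(paste("Upper side with numerous hairs, especially on pronotum",
                     "and elytra"),
               list(ps("hairs_upperside", "present")), couplet = 2),
      key_lead(paste("Upper side without hairs, only regular setae",
                     "(supraorbital setae, series umbilicata, etc.)"),
               list(ps("hairs_upperside", "absent")), couplet = 3)),
    key_couplet(2,
      key_lead(paste("Pronotum cordiform, almost as long as wide. Hind angles",
                     "of pronotum obtuse, somewhat upwards bent. Apical margin",
                     "of elytra evenly rounded. Reddish to dark brown, head",
                     "sometimes darker and pronotum brightened. 5.5-8.0 mm"),
               list(ps("pronotum_proportion", "about_as_long_as_wide")),
               taxon = "atranus_ruficollis", label = "Atranus ruficollis"),
      key_lead(paste("Pronotum clearly wider than long. Hind angles completely",
                     "rounded. Apical margin of elytra sinuous, with small",
                     "tooth at end of suture. Body dark brown, antennae and",
                     "legs and margins of pronotum and elytra reddish brown.",
                     "9-12 mm"),
               list(ps("pronotum_proportion", "clearly_wider")),
               taxon = "orthotrichus_cymindoides",
               label = "Orthotrichus cymindoides")),
    key_couplet(3,
      key_lead(paste("Labrum clearly convex; apical margin rounded; mandibles",
                     "shorter, ca. 2x as long as labrum. Mentum without",
                     "tooth"),
               list(ps("mentum_tooth", "absent")), couplet = 4),
      key_lead(paste("Labrum flat or slightly convex; apical margin almost",
                     "straight (sometimes slightly convex or concave);",
                     "mandibles longer, in most species > 2.5x as long as",
                     "labrum. Mentum with tooth"),
               list(ps("mentum_tooth", "present")), couplet = 5)),
    key_couplet(4,
      key_lead(paste("Pronotum wider, ca. 1.3x wider than long; lateral bead",
                     "broader, punctation stronger. At least part of first 3",
                     "antennomeres dark. Setiferous punctures of 3rd elytral",
                     "stria large and adjacent intervals clearly depressed.",
                     "With or without pronounced depression of 5th stria and",
                     "adjacent intervals in apical third of elytra.",
                     "5.0-6.5 mm"),
               list(ps("pronotum_punctation", "strong")),
               taxon = "olisthopus_fuscatus", label = "Olisthopus fuscatus"),
      key_lead(paste("Pronotum longer, ca. 1.2x wider than long; lateral bead",
                     "slender, punctation weaker. At least first 3",
                     "antennomeres yellowish brown. Setiferous punctures of",
                     "3rd elytral stria small, and adjacent intervals not",
                     "extraordinarily depressed. Without depression of 5th",
                     "stria and adjacent intervals in apical third of elytra.",
                     "5-6.5 mm"),
               list(ps("pronotum_punctation", "weak")),
               taxon = "olisthopus_glabricollis",
               label = "Olisthopus glabricollis")),
    key_couplet(5,
      key_lead(paste("Hind angles of pronotum ca. rectangular, sometimes",
                     "produced in sharp denticle, sometimes bases of pronotum",
                     "somewhat convex. Upper side colorful either with blue to",
                     "violet metallic luster or head and pronotum with green",
                     "or blue metallic luster and elytra matt brown with",
                     "darkening in central and apical part"),
               list(ps("pronotum_hind_angles", "rectangular")), couplet = 6),
      key_lead(paste("Hind angles of pronotum entirely rounded or obtuse,",
                     "sometimes slightly produced into minute denticle"),
               list(ps("pronotum_hind_angles", "rounded_or_obtuse")),
               couplet = 8)),
    key_couplet(6,
      key_lead(paste("Head and pronotum with green or bluish green metallic",
                     "luster, elytra matt brown with darkening in central and",
                     "apical part. Hind angles of pronotum without seta.",
                     "5.0-7.0 mm"),
               list(ps("coloration_upperside",
                       "forebody_green_elytra_matt_brown")),
               taxon = "anchomenus_dorsalis_infuscatus",
               label = "Anchomenus dorsalis infuscatus"),
      key_lead(paste("Head, pronotum and elytra with blue to violet luster.",
                     "Hind angles of pronotum with seta. Longer than 8.5 mm"),
               list(ps("coloration_upperside", "blue_to_violet")),
               couplet = 7)),
    key_couplet(7,
      key_lead(paste("First antennomere in apical part enlarged, behind a",
                     "small constriction (\"trumpet-shaped\"). Pronotum",
                     "1.26-1.38 wider than long. 9.0-10.5 mm"),
               list(ps("first_antennomere", "trumpet_shaped")),
               taxon = "anchomenus_alcedo", label = "Anchomenus alcedo"),
      key_lead(paste("First antennomere regularly shaped, in apical part",
                     "neither with a constriction nor widened at apex.",
                     "Pronotum 1.16-1.27 wider than long. 8.7-10.3 mm"),
               list(ps("first_antennomere", "regular")),
               taxon = "anchomenus_bellus", label = "Anchomenus bellus",
               parenthesized = TRUE)),
    key_couplet(8,
      key_lead(paste("Upper side green and/or coppery; with broad yellow",
                     "elytral margin; yellow coloration on pronotal margin",
                     "narrower. 8.5-10.5 mm"),
               list(ps("coloration_upperside", "green_coppery_yellow_margin")),
               taxon = "agonum_marginatum", label = "Agonum marginatum"),
      key_lead(paste("Upper side variable, from black and brown to vivid",
                     "metallic luster, but without yellow margin on elytra or",
                     "pronotum"),
               list(ps("coloration_upperside", c(
                 "reddish_brown", "dark_brown", "black",
                 "dark_brown_reddish_margins",
                 "forebody_green_elytra_matt_brown", "blue_to_violet",
                 "elytra_green_forebody_reddish_coppery", "elytra_brownish",
                 "vivid_metallic_green", "bronze", "dark_brown_to_black",
                 "brown_faint_green_luster"))),
               couplet = 9)),
    key_couplet(9,
      key_lead(paste("Third elytral intervals with (5-) 6 (-7) setiferous",
                     "punctures. Upper side with metallic luster, mostly",
                     "elytra green and forebody (head, pronotum) reddish or",
                     "coppery, rarely black. 8-10 mm"),
               list(pr("setiferous_punctures_3rd_interval", 5, 7)),
               taxon = "agonum_viridicupreum", label = "Agonum viridicupreum"),
      key_lead(paste("Third elytral intervals with (2-) 3 (-4) setiferous",
                     "punctures. Upper side of different color"),
               list(pr("setiferous_punctures_3rd_interval", 2, 4)),
               couplet = 10)),
    key_couplet(10,
      key_lead(paste("Elytra brownish, femora reddish to pale brown; tibiae",
                     "darker. Apex of 3rd antennal segment with additional",
                     "(sometimes only few) small hairs beside regular erect",
                     "setae. 7-9.5 mm"),
               list(ps("coloration_upperside", "elytra_brownish")),
               taxon = "agonum_sordidum", label = "Agonum sordidum"),
      key_lead(paste("Elytra with metallic luster or black or dark brown to",
                     "black. Apex of 3rd antennal segment only with regular",
                     "setae"),
               list(ps("coloration_upperside", c(
                 "vivid_metallic_green", "bronze", "black",
                 "dark_brown_to_black", "brown_faint_green_luster"))),
               couplet = 11)),
    key_couplet(11,
      key_lead(paste("Larger species (> 8.5 mm) with small and wide pronotum",
                     "(mostly more than 1.3x wider than long). Microsculpture",
                     "of elytra isodiametric and strongly developed, also in",
                     "males. Vivid metallic green or bronze, rarely black.",
                     "With depression in 5th stria and adjacent intervals of",
                     "apical third of elytra. 8.5-11.5 mm"),
               list(ps("pronotum_proportion", "clearly_wider")),
               taxon = "agonum_rugicolle", label = "Agonum rugicolle"),
      key_lead(paste("Smaller species up to 9.0 mm with larger and slender",
                     "pronotum (mostly < 1.3x wider than long). Microsculpture",
                     "of elytra isodiametric, but less developed. Never",
                     "vividly metallic colored, elytra dark brown to black,",
                     "completely without or with slight metallic luster"),
               list(ps("pronotum_proportion",
                       c("about_as_long_as_wide", "slightly_wider",
                         "moderately_wider"))),
               couplet = 12)),
    key_couplet(12,
      key_lead(paste("Pronotum wider, 1.2 to 1.3x wider than long, lateral",
                     "margin continuously rounded between maximum width and",
                     "hind angles. Coloration dark brown to black, first",
                     "antennal segments and tibiae, sometimes femora brown.",
                     "Without any metallic luster. Without or with slight",
                     "depression of 5th stria and adjacent intervals in apical",
                     "third of elytra. 7-8.5 mm"),
               list(ps("pronotum_proportion", "moderately_wider")),
               taxon = "agonum_nigrum", label = "Agonum nigrum"),
      key_lead(paste("Pronotum narrower, < 1.2x wider than long, lateral",
                     "margin from maximum width towards hind angles slightly",
                     "straight or slightly concave. Coloration similar, but",
                     "legs and antennae homogeneously paler or darker brown.",
                     "Without or only a slight metallic hue on whole upper",
                     "side or forebody (head, pronotum). Without or with a",
                     "clearly visible depression of 5th stria and adjacent",
                     "intervals in apical third of elytra"),
               list(ps("pronotum_proportion",
                       c("about_as_long_as_wide", "slightly_wider"))),
               couplet = 13)),
    key_couplet(13,
      key_lead(paste("Pronotum 1.1 to 1.2x wider than long, lateral margin",
                     "from maximum width towards hind angles straight or very",
                     "slightly concave, hind angles less rounded, fore angles",
                     "pronounced. Without depression of 5th stria and adjacent",
                     "intervals in apical third of elytra. Legs and antennae",
                     "shorter. Almost dark brown to black, tibiae sometimes",
                     "paler, without or with faint metallic luster.",
                     "7.5-9.0 mm"),
               list(ps("pronotum_proportion", "slightly_wider")),
               taxon = "agonum_mesostictum", label = "Agonum mesostictum"),
      key_lead(paste("Pronotum <= 1.1x wider than long, lateral margin from",
                     "maximum width towards hind angles straight, hind angles",
                     "more rounded, fore angles stronger rounded. Clearly",
                     "visible depression of 5th stria and adjacent intervals",
                     "in apical third of elytra. Legs and antennae longer.",
                     "Elytra, first 3 antennal segments and legs brown, upper",
                     "side with faint green metallic luster. 8.5-9 mm"),
               list(ps("pronotum_proportion", "about_as_long_as_wide")),
               taxon = "agonum_monachum_syriacum",
               label = "Agonum monachum syriacum"))
  ))
}
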