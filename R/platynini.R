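#' The "Platynini, southern Levant" knowledge base
#'
#' A complete worked knowledge base for the 14 species of the ground beetle
#' tribe Platynini (Coleoptera, Carabidae) recorded from, or expected near,
#' the southern Levant: 16 characters (14 categorical, 2 numerical) scored
#' from the printed dichotomous key shipped as [platynini_key()] and from the
#' published character overview of the matching Xper3 knowledge base.
#'
#' Scoring is deliberately conservative: a cell carries a value only where
#' the printed couplets or the character overview table state one, and every
#' scored cell records its source couplet/table row in the observation's
#' `source` field; everything else is `"?"` (unknown). Thirteen species occur
#' in the southern Levant; *Anchomenus bellus* (listed in parentheses in the
#' printed key, possibly occurring in Northwest Syria) is kept in the matrix
#' with `in_region = FALSE`.
#'
#' Character weights default to medium. The published key generation weighted
#' four characters strongly and two weakly, but the assignment was not
#' identified per character; use `weights` to supply your own.
#'
#' @param weights Optional named integer vector of weight overrides
#'   (1 = weak, 2 = medium, 3 = strong), named by character id.
#' @return A [knowledge_base()] with 14 taxa and 16 characters.
#' @examples
#' kb <- platynini_kb()
#' kb
#' filter_taxa(kb, specimen_profile(hairs_upperside = "present"))
#' @export
platynini_kb <- function(weights = NULL) {
  characters <- list(
    char_def("body_length", "Body length", "numerical", units = "mm",
             group = "habitus"),
    char_def("coloration_upperside",
             "Coloration of upper side (head, pronotum, elytra)",
             "categorical", group = "coloration", states = c(
      reddish_brown = "reddish brown",
      dark_brown = "dark brown",
      black = "black",
      dark_brown_reddish_margins =
        "dark brown, margins of pronotum and elytra reddish brown",
      forebody_green_elytra_matt_brown = paste(
        "head and pronotum with green or bluish green metallic luster,",
        "elytra matt brown with darkening in central and apical part"),
      blue_to_violet = "blue to violet metallic luster",
      green_coppery_yellow_margin =
        "green and/or coppery with broad yellow elytral margin",
      elytra_green_forebody_reddish_coppery =
        "elytra green, forebody reddish or coppery",
      elytra_brownish = "elytra brownish",
      vivid_metallic_green = "vivid metallic green",
      bronze = "bronze",
      dark_brown_to_black = "dark brown to black",
      brown_faint_green_luster = "brown with faint green metallic luster")),
    char_def("metallic_luster", "Metallic luster of upper side", "categorical",
             group = "coloration",
             states = c(absent = "absent", faint = "faint", vivid = "vivid")),
    char_def("coloration_legs", "Coloration of legs", "categorical",
             group = "coloration", states = c(
      reddish_brown = "reddish brown",
      pale_brown_tibiae_darker =
        "femora reddish to pale brown, tibiae darker",
      brown = "brown",
      dark_tibiae_paler = "dark, tibiae (sometimes femora) paler brown")),
    char_def("first_antennomere", "First antennomere", "categorical",
             group = "head", states = c(
      trumpet_shaped =
        "apically enlarged behind a small constriction (trumpet-shaped)",
      regular = "regularly shaped")),
    char_def("labrum", "Labrum", "categorical", group = "head", states = c(
      convex_apex_rounded = "clearly convex, apical margin rounded",
      flat_apex_straight =
        "flat or slightly convex, apical margin almost straight")),
    char_def("mandibles", "Mandibles", "categorical", group = "head",
             states = c(
      short_2x_labrum = "shorter, ca. 2x as long as labrum",
      long_over_2_5x_labrum = "longer, > 2.5x as long as labrum")),
    char_def("pronotum_hind_angles", "Pronotum hind angles", "categorical",
             group = "pronotum", states = c(
      rectangular = "ca. rectangular, sometimes produced in sharp denticle",
      rounded_or_obtuse = "entirely rounded or obtuse")),
    char_def("pronotum_lateral_margin", "Pronotum lateral margin",
             "categorical", group = "pronotum", states = c(
      continuously_rounded =
        "continuously rounded between maximum width and hind angles",
      straight = "straight from maximum width towards hind angles",
      slightly_concave =
        "slightly concave from maximum width towards hind angles")),
    char_def("pronotum_proportion", "Pronotum proportion (width/length)",
             "categorical", group = "pronotum", states = c(
      about_as_long_as_wide = "about as long as wide (<= 1.1x)",
      slightly_wider = "slightly wider than long (1.1-1.2x)",
      moderately_wider = "moderately wider than long (1.2-1.3x)",
      clearly_wider = "clearly wider than long (> 1.3x)")),
    char_def("pronotum_punctation", "Pronotum punctation", "categorical",
             group = "pronotum",
             states = c(strong = "strong", weak = "weak")),
    char_def("hairs_upperside", "Hairs on upper side (pronotum, elytra)",
             "categorical", group = "habitus", states = c(
      present = "numerous hairs present",
      absent = "without hairs, only regular setae")),
    char_def("setiferous_punctures_3rd_interval",
             "3rd elytral interval, number of setiferous punctures",
             "numerical", units = "count", group = "elytra"),
    char_def("stria5_apical_depression",
             "5th elytral stria and adjacent intervals (apical third)",
             "categorical", group = "elytra", states = c(
      depressed = "depressed", not_depressed = "not depressed")),
    char_def("elytra_apical_margin", "Apical margin of elytra", "categorical",
             group = "elytra", states = c(
      evenly_rounded = "evenly rounded",
      sinuous_with_tooth = "sinuous, with small tooth at end of suture")),
    char_def("mentum_tooth", "Mentum tooth", "categorical", group = "head",
             states = c(present = "with tooth", absent = "without tooth"))
  )

  if (!is.null(weights)) {
    bad <- setdiff(names(weights),
                   vapply(characters, `[[`, character(1), "char_id"))
    if (length(bad))
      stop("weight override for unknown character(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    for (i in seq_along(characters)) {
      id <- characters[[i]]$char_id
      if (id %in% names(weights)) {
        w <- as.integer(weights[[id]])
        if (!w %in% 1:3) stop("weights must be 1, 2 or 3", call. = FALSE)
        characters[[i]]$weight <- w
      }
    }
  }

  st <- obs_states; rg <- obs_range; unk <- obs_unknown

  # Shared cells printed once for a whole branch of the key.
  labrum_flat <- st("flat_apex_straight", "couplet 3, lead 2")
  mand_long <- st("long_over_2_5x_labrum", "couplet 3, lead 2")
  mentum_yes <- st("present", "couplet 3, lead 2")
  angles_rect <- st("rectangular", "couplet 5, lead 1")
  angles_round <- st("rounded_or_obtuse", "couplet 5, lead 2")
  setif_few <- rg(2, 4, "couplet 9, lead 2; character overview table")
  hairless <- st("absent", "couplet 1, lead 2")

  taxa <- list(
    taxon_desc("atranus_ruficollis", "Atranus ruficollis", observations = list(
      body_length = rg(5.5, 8.0, "couplet 2, lead 1"),
      coloration_upperside = st(c("reddish_brown", "dark_brown"),
                                "couplet 2, lead 1"),
      pronotum_proportion = st("about_as_long_as_wide", "couplet 2, lead 1"),
      pronotum_hind_angles = st("rounded_or_obtuse",
                                "couplet 2, lead 1 (obtuse)"),
      pronotum_punctation = st("strong",
                               "pronotum reference figure (punctation)"),
      elytra_apical_margin = st("evenly_rounded", "couplet 2, lead 1"),
      hairs_upperside = st("present", "couplet 1, lead 1"))),
    taxon_desc("orthotrichus_cymindoides", "Orthotrichus cymindoides",
               observations = list(
      body_length = rg(9, 12, "couplet 2, lead 2"),
      coloration_upperside = st("dark_brown_reddish_margins",
                                "couplet 2, lead 2"),
      coloration_legs = st("reddish_brown", "couplet 2, lead 2"),
      pronotum_proportion = st("clearly_wider", "couplet 2, lead 2"),
      pronotum_hind_angles = st("rounded_or_obtuse",
                                "couplet 2, lead 2 (completely rounded)"),
      elytra_apical_margin = st("sinuous_with_tooth", "couplet 2, lead 2"),
      hairs_upperside = st("present", "couplet 1, lead 1"))),
    taxon_desc("olisthopus_fuscatus", "Olisthopus fuscatus",
               observations = list(
      body_length = rg(5.0, 6.5, "couplet 4, lead 1"),
      labrum = st("convex_apex_rounded", "couplet 3, lead 1"),
      mandibles = st("short_2x_labrum", "couplet 3, lead 1"),
      mentum_tooth = st("absent", "couplet 3, lead 1"),
      pronotum_proportion = st(c("moderately_wider", "clearly_wider"),
                               "couplet 4, lead 1 (ca. 1.3x)"),
      pronotum_punctation = st("strong", "couplet 4, lead 1"),
      stria5_apical_depression = st(c("depressed", "not_depressed"),
                                    "couplet 4, lead 1 (with or without)"),
      setiferous_punctures_3rd_interval = setif_few,
      hairs_upperside = hairless)),
    taxon_desc("olisthopus_glabricollis", "Olisthopus glabricollis",
               observations = list(
      body_length = rg(5, 6.5, "couplet 4, lead 2"),
      labrum = st("convex_apex_rounded", "couplet 3, lead 1"),
      mandibles = st("short_2x_labrum", "couplet 3, lead 1"),
      mentum_tooth = st("absent", "couplet 3, lead 1"),
      pronotum_proportion = st(c("slightly_wider", "moderately_wider"),
                               "couplet 4, lead 2 (ca. 1.2x)"),
      pronotum_punctation = st("weak", "couplet 4, lead 2"),
      stria5_apical_depression = st("not_depressed", "couplet 4, lead 2"),
      setiferous_punctures_3rd_interval = setif_few,
      hairs_upperside = hairless)),
    taxon_desc("anchomenus_dorsalis_infuscatus",
               "Anchomenus dorsalis infuscatus", observations = list(
      body_length = rg(5.0, 7.0, "couplet 6, lead 1"),
      coloration_upperside = st("forebody_green_elytra_matt_brown",
                                "couplet 6, lead 1"),
      metallic_luster = st("vivid", "couplet 6, lead 1"),
      labrum = labrum_flat, mandibles = mand_long, mentum_tooth = mentum_yes,
      pronotum_hind_angles = angles_rect,
      setiferous_punctures_3rd_interval = setif_few,
      hairs_upperside = hairless)),
    taxon_desc("anchomenus_alcedo", "Anchomenus alcedo", observations = list(
      body_length = rg(9.0, 10.5, "couplet 7, lead 1"),
      coloration_upperside = st("blue_to_violet", "couplet 6, lead 2"),
      metallic_luster = st("vivid", "couplet 6, lead 2"),
      first_antennomere = st("trumpet_shaped", "couplet 7, lead 1"),
      labrum = labrum_flat, mandibles = mand_long, mentum_tooth = mentum_yes,
      pronotum_hind_angles = angles_rect,
      pronotum_proportion = st(c("moderately_wider", "clearly_wider"),
                               "couplet 7, lead 1 (1.26-1.38)"),
      setiferous_punctures_3rd_interval = setif_few,
      hairs_upperside = hairless)),
    taxon_desc("anchomenus_bellus", "Anchomenus bellus", in_region = FALSE,
               notes = "may occur in Northwest Syria; in parentheses in the printed key",
               observations = list(
      body_length = rg(8.7, 10.3, "couplet 7, lead 2"),
      coloration_upperside = st("blue_to_violet", "couplet 6, lead 2"),
      metallic_luster = st("vivid", "couplet 6, lead 2"),
      first_antennomere = st("regular", "couplet 7, lead 2"),
      labrum = labrum_flat, mandibles = mand_long, mentum_tooth = mentum_yes,
      pronotum_hind_angles = angles_rect,
      pronotum_proportion = st(c("slightly_wider", "moderately_wider"),
                               "couplet 7, lead 2 (1.16-1.27)"),
      setiferous_punctures_3rd_interval = setif_few,
      hairs_upperside = hairless)),
    taxon_desc("agonum_marginatum", "Agonum marginatum", observations = list(
      body_length = rg(8.5, 10.5, "couplet 8, lead 1"),
      coloration_upperside = st("green_coppery_yellow_margin",
                                "couplet 8, lead 1"),
      labrum = labrum_flat, mandibles = mand_long, mentum_tooth = mentum_yes,
      pronotum_hind_angles = angles_round,
      setiferous_punctures_3rd_interval = setif_few,
      hairs_upperside = hairless)),
    taxon_desc("agonum_viridicupreum", "Agonum viridicupreum",
               observations = list(
      body_length = rg(8, 10, "couplet 9, lead 1"),
      coloration_upperside = st(c("elytra_green_forebody_reddish_coppery",
                                  "black"),
                                "couplet 9, lead 1 (rarely black)"),
      metallic_luster = st("vivid", "couplet 9, lead 1"),
      labrum = labrum_flat, mandibles = mand_long, mentum_tooth = mentum_yes,
      pronotum_hind_angles = angles_round,
      setiferous_punctures_3rd_interval = rg(5, 7, "couplet 9, lead 1"),
      hairs_upperside = hairless)),
    taxon_desc("agonum_sordidum", "Agonum sordidum", observations = list(
      body_length = rg(7, 9.5, "couplet 10, lead 1"),
      coloration_upperside = st("elytra_brownish", "couplet 10, lead 1"),
      metallic_luster = st("absent",
                           "couplet 10 (contrast with counter-lead)"),
      coloration_legs = st("pale_brown_tibiae_darker", "couplet 10, lead 1"),
      labrum = labrum_flat, mandibles = mand_long, mentum_tooth = mentum_yes,
      pronotum_hind_angles = angles_round,
      setiferous_punctures_3rd_interval = setif_few,
      hairs_upperside = hairless)),
    taxon_desc("agonum_rugicolle", "Agonum rugicolle", observations = list(
      body_length = rg(8.5, 11.5, "couplet 11, lead 1"),
      coloration_upperside = st(c("vivid_metallic_green", "bronze", "black"),
                                "couplet 11, lead 1 (rarely black)"),
      metallic_luster = st(c("vivid", "absent"),
                           "couplet 11, lead 1 (rarely black)"),
      labrum = labrum_flat, mandibles = mand_long, mentum_tooth = mentum_yes,
      pronotum_hind_angles = angles_round,
      pronotum_proportion = st("clearly_wider",
                               "couplet 11, lead 1 (mostly > 1.3x)"),
      stria5_apical_depression = st("depressed", "couplet 11, lead 1"),
      setiferous_punctures_3rd_interval = setif_few,
      hairs_upperside = hairless)),
    taxon_desc("agonum_nigrum", "Agonum nigrum", observations = list(
      body_length = rg(7, 8.5, "couplet 12, lead 1"),
      coloration_upperside = st("dark_brown_to_black", "couplet 12, lead 1"),
      metallic_luster = st("absent",
                           "couplet 12, lead 1 (without any metallic luster)"),
      coloration_legs = st("dark_tibiae_paler", "couplet 12, lead 1"),
      labrum = labrum_flat, mandibles = mand_long, mentum_tooth = mentum_yes,
      pronotum_hind_angles = angles_round,
      pronotum_lateral_margin = st("continuously_rounded", "couplet 12, lead 1"),
      pronotum_proportion = st("moderately_wider",
                               "couplet 12, lead 1 (1.2-1.3x)"),
      stria5_apical_depression = st(c("depressed", "not_depressed"),
                                    "couplet 12, lead 1 (without or with slight)"),
      setiferous_punctures_3rd_interval = setif_few,
      hairs_upperside = hairless)),
    taxon_desc("agonum_mesostictum", "Agonum mesostictum", observations = list(
      body_length = rg(7.5, 9.0, "couplet 13, lead 1"),
      coloration_upperside = st("dark_brown_to_black", "couplet 13, lead 1"),
      metallic_luster = st(c("absent", "faint"),
                           "couplet 13, lead 1 (without or with faint)"),
      coloration_legs = st("dark_tibiae_paler",
                           "couplet 13, lead 1 (tibiae sometimes paler)"),
      labrum = labrum_flat, mandibles = mand_long, mentum_tooth = mentum_yes,
      pronotum_hind_angles = angles_round,
      pronotum_lateral_margin = st(c("straight", "slightly_concave"),
                                   "couplet 13, lead 1"),
      pronotum_proportion = st("slightly_wider",
                               "couplet 13, lead 1 (1.1-1.2x)"),
      stria5_apical_depression = st("not_depressed", "couplet 13, lead 1"),
      setiferous_punctures_3rd_interval = setif_few,
      hairs_upperside = hairless)),
    taxon_desc("agonum_monachum_syriacum", "Agonum monachum syriacum",
               observations = list(
      body_length = rg(8.5, 9, "couplet 13, lead 2"),
      coloration_upperside = st("brown_faint_green_luster", "couplet 13, lead 2"),
      metallic_luster = st("faint", "couplet 13, lead 2"),
      coloration_legs = st("brown", "couplet 13, lead 2"),
      labrum = labrum_flat, mandibles = mand_long, mentum_tooth = mentum_yes,
      pronotum_hind_angles = angles_round,
      pronotum_lateral_margin = st("straight", "couplet 13, lead 2"),
      pronotum_proportion = st("about_as_long_as_wide",
                               "couplet 13, lead 2 (<= 1.1x)"),
      stria5_apical_depression = st("depressed", "couplet 13, lead 2"),
      setiferous_punctures_3rd_interval = setif_few,
      hairs_upperside = hairless))
  )

  knowledge_base(
    title = "Platynini, southern Levant",
    characters = characters,
    taxa = taxa,
    notes = paste(
      "Transcribed from the printed dichotomous key (13 couplets) and the",
      "published character overview of the Xper3 knowledge base of the same",
      "name. Cells without a printed source are scored unknown.")
  )
}
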