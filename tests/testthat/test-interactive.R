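test_that("a session eliminates taxa step by step", {
  kb <- platynini_kb()
  s <- new_session(kb)
  expect_identical(remaining_taxa(s), names(kb$taxa))

  s <- answer_character(s, "hairs_upperside", "present")
  expect_setequal(remaining_taxa(s),
                  c("atranus_ruficollis", "orthotrichus_cymindoides"))
  expect_error(answer_character(s, "hairs_upperside", "absent"),
               "already answered")

  s <- answer_character(s, "pronotum_proportion", "clearly_wider")
  expect_identical(remaining_taxa(s), "orthotrichus_cymindoides")
  expect_length(s$answers, 2L)          # identified in two decisions
  expect_identical(suggest_next(s), character())

  # an answer matching every remaining taxon eliminates nothing
  s2 <- answer_character(new_session(kb), "mentum_tooth", "present")
  s3 <- answer_character(s2, "labrum", "flat_apex_straight")
  expect_identical(remaining_taxa(s3), remaining_taxa(s2))
})

test_that("the endpoint of a session is order-independent", {
  kb <- platynini_kb()
  answers <- list(stria5_apical_depression = "depressed",
                  pronotum_hind_angles = "rounded_or_obtuse",
                  body_length = 8.7)
  ends <- lapply(list(c(1, 2, 3), c(3, 1, 2), c(2, 3, 1)), function(ord) {
    s <- new_session(kb)
    for (i in ord)
      s <- answer_character(s, names(answers)[i], answers[[i]])
    remaining_taxa(s)
  })
  expect_identical(ends[[1]], ends[[2]])
  expect_identical(ends[[1]], ends[[3]])
})

test_that("suggestions follow the session's ranking policy", {
  kb <- platynini_kb()
  # most-states-first puts the 13-state coloration character on top
  s <- new_session(kb, ranking_options("most_states"))
  expect_identical(suggest_next(s)[1], "coloration_upperside")
  # fewer-states-first starts with a 2-state character
  s <- new_session(kb, ranking_options("fewer_states"))
  first <- suggest_next(s)[1]
  expect_identical(nrow(kb$characters[[first]]$states), 2L)
  # two taxa differing in a single character: that character comes first
  twin_kb <- knowledge_base("pair", list(
      char_def("c1", "Same", "categorical", states = c(a = "a", b = "b")),
      char_def("c2", "Diff", "categorical", states = c(a = "a", b = "b"))),
    list(taxon_desc("x", "X", observations = list(
           c1 = obs_states("a"), c2 = obs_states("a"))),
         taxon_desc("y", "Y", observations = list(
           c1 = obs_states("a"), c2 = obs_states("b")))))
  expect_identical(suggest_next(new_session(twin_kb)), "c2")
})

test_that("decision profiles count questions to identification", {
  # one perfectly separating character: everything resolves in one decision
  kb1 <- knowledge_base("one", list(
      char_def("c1", "C1", "categorical",
               states = c(a = "a", b = "b", c = "c"))),
    list(taxon_desc("x", "X", observations = list(c1 = obs_states("a"))),
         taxon_desc("y", "Y", observations = list(c1 = obs_states("b"))),
         taxon_desc("z", "Z", observations = list(c1 = obs_states("c")))))
  dp <- decision_profile(kb1)
  expect_true(all(dp$resolved))
  expect_true(all(dp$decisions == 1L))

  # indistinguishable taxa are reported unresolved
  kb2 <- knowledge_base("twins", list(
      char_def("c1", "C1", "categorical", states = c(a = "a", b = "b"))),
    list(taxon_desc("x", "X", observations = list(c1 = obs_states("a"))),
         taxon_desc("y", "Y", observations = list(c1 = obs_states("a"))),
         taxon_desc("z", "Z", observations = list(c1 = obs_states("b")))))
  dp2 <- decision_profile(kb2)
  expect_false(dp2$resolved[dp2$taxon_id == "x"])
  expect_false(dp2$resolved[dp2$taxon_id == "y"])
  expect_true(dp2$resolved[dp2$taxon_id == "z"])
})

test_that("decision counts do not depend on taxon declaration order", {
  kb <- platynini_kb()
  kb_rev <- knowledge_base(kb$title, kb$characters, rev(unname(kb$taxa)),
                           notes = kb$notes)
  for (policy in c("most_states", "fewer_states")) {
    dp <- decision_profile(kb, ranking_options(policy))
    dp_rev <- decision_profile(kb_rev, ranking_options(policy))
    m <- match(dp$taxon_id, dp_rev$taxon_id)
    expect_identical(dp$decisions, dp_rev$decisions[m])
    expect_identical(dp$resolved, dp_rev$resolved[m])
  }
})

test_that("every taxon of the packaged base resolves, faster with many-state questions first", {
  kb <- platynini_kb()
  dp_most <- decision_profile(kb, ranking_options("most_states"))
  dp_few <- decision_profile(kb, ranking_options("fewer_states"))
  expect_true(all(dp_most$resolved))
  expect_true(all(dp_few$resolved))
  expect_true(all(dp_most$decisions >= 1L))
  # leading with the most-states character never costs more questions here
  expect_true(all(dp_most$decisions <= dp_few$decisions))
})
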