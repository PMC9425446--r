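test_that("constructors enforce the model invariants", {
  expect_error(char_def("x", "X", "categorical"), "non-empty state list")
  expect_error(char_def("x", "X", "numerical",
                        states = c(a = "a")), "must not declare states")
  expect_error(char_def("x", "X", "categorical",
                        states = c(a = "a", a = "b")), "duplicate state ids")
  expect_error(char_def("x", "X", "categorical", states = c(a = "a"),
                        weight = 5), "weight")
  expect_identical(char_def("x", "X", "categorical",
                            states = c(a = "a"))$weight, 2L)
  expect_error(obs_states(character()), "at least one state")
  expect_error(obs_range(3, 1), "lo <= hi")
  expect_error(specimen_profile(.answers = list(1)), "named")
})

test_that("compatibility implements unknown-tolerant set semantics", {
  kb <- platynini_kb()
  # vacuous conjunction: an empty profile eliminates nothing
  for (t in names(kb$taxa))
    expect_true(compatible(kb, t, specimen_profile()))
  hairy <- specimen_profile(hairs_upperside = "present")
  expect_false(compatible(kb, "agonum_marginatum", hairy))
  expect_true(compatible(kb, "atranus_ruficollis", hairy))
  # unknown cells are compatible with anything
  expect_true(compatible(kb, "atranus_ruficollis",
                         specimen_profile(mentum_tooth = "present")))
  # closed numerical intervals: boundary points match
  expect_true(compatible(kb, "atranus_ruficollis",
                         specimen_profile(body_length = 8.0)))
  expect_false(compatible(kb, "atranus_ruficollis",
                          specimen_profile(body_length = 8.1)))
  expect_error(compatible(kb, "atranus_ruficollis",
                          specimen_profile(no_such = "x")), "unknown character")
  expect_error(compatible(kb, "atranus_ruficollis",
                          specimen_profile(hairs_upperside = "hairy")),
               "unknown state")
})

test_that("filtering reproduces the printed key's first eliminations", {
  kb <- platynini_kb()
  expect_length(filter_taxa(kb, specimen_profile()), 14L)
  expect_setequal(
    filter_taxa(kb, specimen_profile(hairs_upperside = "present")),
    c("atranus_ruficollis", "orthotrichus_cymindoides"))
  expect_identical(
    filter_taxa(kb, specimen_profile(hairs_upperside = "present",
                                     pronotum_proportion = "clearly_wider")),
    "orthotrichus_cymindoides")
  # results come back in knowledge-base order
  expect_identical(filter_taxa(kb, specimen_profile()), names(kb$taxa))
})

test_that("discriminatory power is the pairwise-separation index", {
  kb <- toy_kb()
  # wings splits t2 from t1 and t3, t1/t3 share "full": 2 of 3 pairs
  expect_equal(discriminatory_power(kb, "wings"), 2 / 3)
  # color: t3 unknown, so only the t1/t2 pair is scored, and they overlap
  expect_equal(discriminatory_power(kb, "color"), 0)
  # length: t1/t2 disjoint, the others overlap
  expect_equal(discriminatory_power(kb, "length"), 1 / 3)
  # perfect separator on a pair
  expect_equal(discriminatory_power(kb, "wings", c("t1", "t2")), 1)
  expect_error(discriminatory_power(kb, "wings", "t1"), "at least two")

  # the published pubescence character separates the 2 hairy x 12 glabrous
  # species: 24 of the C(14,2) = 91 pairs
  expect_equal(discriminatory_power(platynini_kb(), "hairs_upperside"),
               24 / 91)
})

test_that("power is invariant under taxon reordering and unknown padding", {
  kb <- platynini_kb()
  remaining <- names(kb$taxa)
  for (char_id in c("hairs_upperside", "pronotum_proportion", "body_length")) {
    p0 <- discriminatory_power(kb, char_id, remaining)
    set.seed(42)
    expect_equal(discriminatory_power(kb, char_id, sample(remaining)), p0)
  }
  # adding an all-unknown taxon changes no scored pair, hence no index
  kb2 <- knowledge_base(kb$title, kb$characters,
                        c(unname(kb$taxa), list(taxon_desc("blank", "Blank"))))
  expect_equal(discriminatory_power(kb2, "hairs_upperside"), 24 / 91)
})

test_that("composite ranking honours policy, weights and declaration order", {
  sts2 <- c(a = "a", b = "b")
  sts3 <- c(a = "a", b = "b", c = "c")
  kb <- knowledge_base("rank", characters = list(
      char_def("many", "Many states", "categorical", states = sts3),
      char_def("weak2", "Two states, weak", "categorical", states = sts2,
               weight = 1L),
      char_def("strong2", "Two states, strong", "categorical", states = sts2,
               weight = 3L),
      char_def("constant", "Non-separating", "categorical", states = sts2)),
    taxa = list(
      taxon_desc("t1", "T1", observations = list(
        many = obs_states("a"), weak2 = obs_states("a"),
        strong2 = obs_states("a"), constant = obs_states("a"))),
      taxon_desc("t2", "T2", observations = list(
        many = obs_states("b"), weak2 = obs_states("b"),
        strong2 = obs_states("b"), constant = obs_states("a")))))

  # all separating characters have power 1; zero-power ones are dropped
  r <- rank_characters(kb)
  expect_false("constant" %in% r)
  expect_identical(r[1], "many")         # declaration order breaks the tie

  # fewer-states: both 2-state characters precede the 3-state one
  r <- rank_characters(kb, options = ranking_options("fewer_states"))
  expect_identical(r, c("weak2", "strong2", "many"))
  # weights slot in right after the primary criterion
  r <- rank_characters(kb, options = ranking_options("fewer_states",
                                                     use_weights = TRUE))
  expect_identical(r, c("strong2", "weak2", "many"))
  r <- rank_characters(kb, options = ranking_options("most_states",
                                                     use_weights = TRUE))
  expect_identical(r[1], "many")

  # answered characters are excluded
  r <- rank_characters(kb, specimen_profile(many = c("a", "b")))
  expect_false("many" %in% r)

  # a perfectly separating character leads under the default policy
  kb_toy <- toy_kb()
  expect_identical(rank_characters(kb_toy, options = ranking_options())[1],
                   "wings")
})

test_that("validation flags structural errors and completeness warnings", {
  expect_true(validate_kb(platynini_kb())$valid)
  expect_length(validate_kb(platynini_kb())$warnings$indistinguishable_pairs,
                0L)

  # no taxa at all is a structural error
  kb0 <- knowledge_base("empty", list(char_def("c", "C", "categorical",
                                               states = c(a = "a"))), list())
  expect_false(validate_kb(kb0)$valid)
  expect_match(validate_kb(kb0)$errors, "no taxa", all = FALSE)

  # twins are flagged as indistinguishable
  twin <- list(
    taxon_desc("x", "X", observations = list(c1 = obs_states("a"))),
    taxon_desc("y", "Y", observations = list(c1 = obs_states("a"))))
  kbt <- knowledge_base("twins", list(char_def("c1", "C1", "categorical",
    states = c(a = "a", b = "b"))), twin)
  rep <- validate_kb(kbt)
  expect_true(rep$valid)
  expect_identical(rep$warnings$indistinguishable_pairs, list(c("x", "y")))
  expect_identical(rep$warnings$non_separating_characters, "c1")

  # a character no taxon is scored for
  kbu <- knowledge_base("unk", list(
    char_def("c1", "C1", "categorical", states = c(a = "a", b = "b")),
    char_def("c2", "C2", "categorical", states = c(a = "a", b = "b"))),
    list(taxon_desc("x", "X", observations = list(c1 = obs_states("a"))),
         taxon_desc("y", "Y", observations = list(c1 = obs_states("b")))))
  expect_identical(validate_kb(kbu)$warnings$all_unknown_characters, "c2")

  # scoring an undeclared state is an error
  kbe <- knowledge_base("bad", list(char_def("c1", "C1", "categorical",
    states = c(a = "a"))),
    list(taxon_desc("x", "X", observations = list(c1 = obs_states("zzz"))),
         taxon_desc("y", "Y")))
  expect_false(validate_kb(kbe)$valid)
  expect_match(validate_kb(kbe)$errors, "undeclared state", all = FALSE)
})

test_that("filtering agrees with the brute-force oracle on random matrices", {
  for (i in 1:30) {
    kb <- random_kb(n_taxa = sample(2:8, 1), n_characters = sample(1:6, 1),
                    states_range = c(2L, 4L), p_polymorphic = 0.3,
                    p_unknown = 0.3, seed = 1000 + i)
    profile <- random_profile(kb, n_answers = sample(1:4, 1), seed = 2000 + i)
    expect_identical(filter_taxa(kb, profile), oracle_filter(kb, profile))
  }
})

test_that("elimination is monotone and self-identification always holds", {
  for (i in 1:20) {
    kb <- random_kb(n_taxa = 6, n_characters = 5, p_polymorphic = 0.2,
                    p_unknown = 0.2, seed = 3000 + i)
    q <- random_profile(kb, n_answers = 4, seed = 4000 + i)
    for (k in seq_len(length(q) - 1L)) {
      p <- specimen_profile(.answers = unclass(q)[seq_len(k)])
      expect_true(all(filter_taxa(kb, q) %in% filter_taxa(kb, p)))
    }
    # a noiseless profile of a taxon never eliminates that taxon
    for (taxon_id in names(kb$taxa))
      expect_true(taxon_id %in%
                    filter_taxa(kb, noiseless_profile(kb, taxon_id)))
  }
})
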