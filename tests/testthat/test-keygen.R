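test_that("a binary split of two taxa yields a one-step key", {
  kb <- knowledge_base("pair", list(
      char_def("c1", "C1", "categorical", states = c(a = "a", b = "b"))),
    list(taxon_desc("x", "X", observations = list(c1 = obs_states("a"))),
         taxon_desc("y", "Y", observations = list(c1 = obs_states("b")))))
  key <- build_single_access_key(kb)
  m <- key_metrics(key)
  expect_identical(m$alternatives, 1L)
  expect_true(all(m$decisions == 1))
  expect_length(m$duplicated_taxa, 0L)
  expect_error(build_single_access_key(
    knowledge_base("one", kb$characters, kb$taxa[1])), "at least two taxa")
})

test_that("taxa unknown for the splitting character are copied to every branch", {
  kb <- knowledge_base("copy", list(
      char_def("c1", "C1", "categorical", states = c(a = "a", b = "b"))),
    list(taxon_desc("x", "X", observations = list(c1 = obs_states("a"))),
         taxon_desc("y", "Y", observations = list(c1 = obs_states("b"))),
         taxon_desc("u", "U", observations = list(c1 = obs_unknown()))))
  key <- build_single_access_key(kb)
  expect_identical(key$root$char_id, "c1")
  for (b in key$root$branches) {
    leaf_taxa <- if (b$target$kind == "taxa") b$target$taxa else character()
    expect_true("u" %in% leaf_taxa)
  }
  m <- key_metrics(key)
  expect_identical(m$duplicated_taxa, "u")
  # the unresolved pairs {x,u} and {y,u} are reported, not dropped
  expect_length(m$unresolved_groups, 2L)
})

test_that("polymorphic taxa appear under each of their states", {
  kb <- knowledge_base("poly", list(
      char_def("c1", "C1", "categorical",
               states = c(a = "a", b = "b", c = "c")),
      char_def("c2", "C2", "categorical", states = c(a = "a", b = "b"))),
    list(taxon_desc("x", "X", observations = list(
           c1 = obs_states(c("a", "b")), c2 = obs_states("a"))),
         taxon_desc("y", "Y", observations = list(
           c1 = obs_states("b"), c2 = obs_states("b"))),
         taxon_desc("z", "Z", observations = list(
           c1 = obs_states("c"), c2 = obs_states("b")))))
  key <- build_single_access_key(kb)   # c1 has the higher power, so it roots
  expect_identical(key$root$char_id, "c1")
  expect_length(key$root$branches, 3L)
  m <- key_metrics(key)
  expect_identical(m$duplicated_taxa, "x")
})

test_that("numerical characters branch at coverage gaps", {
  kb <- knowledge_base("num", list(
      char_def("len", "Length", "numerical", units = "mm")),
    list(taxon_desc("x", "X", observations = list(len = obs_range(1, 3))),
         taxon_desc("y", "Y", observations = list(len = obs_range(2, 4))),
         taxon_desc("z", "Z", observations = list(len = obs_range(6, 8)))))
  key <- build_single_access_key(kb)
  expect_length(key$root$branches, 2L)  # blocks [1,4] and [6,8]
  m <- key_metrics(key)
  # x and y overlap and no other character exists: one unresolved leaf
  expect_length(m$unresolved_groups, 1L)
  expect_setequal(m$unresolved_groups[[1]], c("x", "y"))
  expect_identical(m$decisions[["z"]], 1)
})

test_that("generated keys reach every taxon, duplicating variable species", {
  kb <- platynini_kb()
  key <- build_single_access_key(kb, ranking_options("fewer_states",
                                                     use_weights = TRUE))
  m <- key_metrics(key)
  expect_setequal(names(m$decisions), names(kb$taxa))
  # lower bound on numbered steps for a key with this branching factor
  max_branch <- 0L
  walk <- function(n) {
    if (n$kind != "node") return(invisible())
    max_branch <<- max(max_branch, length(n$branches))
    for (b in n$branches) walk(b$target)
  }
  walk(key$root)
  expect_gte(m$alternatives,
             ceiling((length(kb$taxa) - 1) / (max_branch - 1)))
  # species polymorphic for some character turn up at more than one leaf
  polymorphic <- names(kb$taxa)[vapply(kb$taxa, function(tx)
    any(vapply(tx$observations, function(o)
      !is.null(o$states) && length(o$states) > 1L, logical(1))), logical(1))]
  expect_gt(length(intersect(m$duplicated_taxa, polymorphic)), 0L)
  # identical input gives a byte-identical key
  key2 <- build_single_access_key(kb, ranking_options("fewer_states",
                                                      use_weights = TRUE))
  expect_identical(render_key_text(key2), render_key_text(key))
})

test_that("generated keys lead each taxon's own profile to a leaf holding it", {
  for (i in 1:20) {
    kb <- random_kb(n_taxa = sample(3:7, 1), n_characters = sample(2:6, 1),
                    p_polymorphic = 0.25, p_unknown = 0.25, seed = 5000 + i)
    key <- build_single_access_key(kb)
    for (taxon_id in names(kb$taxa))
      expect_true(taxon_id %in%
                    key_candidates(key, noiseless_profile(kb, taxon_id)))
  }
})

test_that("the printed key has 13 steps and 2 to 9 decisions per species", {
  m <- key_metrics(platynini_key())
  expect_identical(m$alternatives, 13L)
  expect_identical(min(m$decisions), 2)
  expect_identical(max(m$decisions), 9)
  expect_length(m$decisions, 14L)       # every species keyed out exactly once
  expect_length(m$duplicated_taxa, 0L)
})

test_that("traversal follows the unique satisfied lead", {
  kb <- platynini_kb()
  key <- platynini_key()
  res <- traverse_dichotomous(
    key, noiseless_profile(kb, "orthotrichus_cymindoides"))
  expect_identical(res$taxon, "orthotrichus_cymindoides")
  expect_identical(res$decisions, 2L)
  res <- traverse_dichotomous(key, noiseless_profile(kb, "agonum_mesostictum"))
  expect_identical(res$taxon, "agonum_mesostictum")
  expect_identical(res$path[length(res$path)], 13L)

  # self-contradictory observation: neither lead holds at couplet 1
  expect_error(
    traverse_dichotomous(key, specimen_profile(
      hairs_upperside = c("present", "absent"))),
    "inconsistent specimen.*couplet 1")
  # missing answers are named
  expect_error(
    traverse_dichotomous(key, specimen_profile(hairs_upperside = "absent")),
    "does not answer.*mentum_tooth.*couplet 3")
})

test_that("key and matrix agree on every taxon", {
  kb <- platynini_kb()
  key <- platynini_key()
  cc <- check_consistency(key, kb)
  expect_true(cc$ok)
  expect_identical(cc$n_checked, 14L)

  # flipping one state is caught
  kb_bad <- kb
  kb_bad$taxa$agonum_marginatum$observations$coloration_upperside <-
    obs_states("elytra_brownish", "deliberate flip")
  cc_bad <- check_consistency(key, kb_bad)
  expect_false(cc_bad$ok)
  expect_true("agonum_marginatum" %in% cc_bad$mismatches$taxon_id)

  expect_error(
    check_consistency(key, knowledge_base("empty", kb$characters, list())),
    "no taxa")
})

test_that("rendered keys parse back to the same structure", {
  key <- platynini_key()
  txt <- render_key_text(key)
  first <- strsplit(txt, "\n")[[1]][1]
  expect_match(first, "^1\t")
  expect_match(first, "Upper side with numerous hairs")
  expect_match(txt, "\\(\\*\\*Anchomenus bellus\\*\\*\\)")  # parenthesized taxon
  reparsed <- parse_key_text(txt)
  expect_identical(render_key_text(reparsed), txt)
  m <- key_metrics(reparsed)
  expect_identical(m$alternatives, 13L)
  expect_identical(unname(range(m$decisions)), c(2, 9))

  # a generated key renders with one numbered step per node
  kb <- knowledge_base("pair", list(
      char_def("c1", "C1", "categorical", states = c(a = "a", b = "b"))),
    list(taxon_desc("x", "X", observations = list(c1 = obs_states("a"))),
         taxon_desc("y", "Y", observations = list(c1 = obs_states("b")))))
  sk <- build_single_access_key(kb)
  txt_sk <- render_key_text(sk)
  expect_length(strsplit(txt_sk, "\n")[[1]], 2L)
  expect_match(strsplit(txt_sk, "\n")[[1]][1], "^1\t")
  expect_identical(render_key_text(parse_key_text(txt_sk)), txt_sk)
})
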