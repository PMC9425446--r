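test_that("the cell grammar round-trips every kind of cell", {
  cat3 <- char_def("c", "C", "categorical",
                   states = c(a = "a", b = "b", c = "c"))
  num <- char_def("n", "N", "numerical", units = "mm")
  cells_cat <- c("?", "NA", "a", "b|c", "a|b|c")
  for (cell in cells_cat)
    expect_identical(format_cell(parse_cell(cell, cat3)), cell)
  cells_num <- c("?", "NA", "3.5", "2..4", "-1.25..0.5")
  for (cell in cells_num)
    expect_identical(format_cell(parse_cell(cell, num)), cell)
  # and for arbitrary observations the other way around
  for (i in 1:25) {
    set.seed(i)
    obs <- obs_states(sample(c("a", "b", "c"), sample(1:3, 1)))
    expect_identical(parse_cell(format_cell(obs), cat3)$states, obs$states)
    lo <- round(runif(1, -5, 5), 2)
    obs <- obs_range(lo, lo + round(runif(1, 0, 3), 2))
    expect_identical(parse_cell(format_cell(obs), num)$range, obs$range)
  }
  expect_error(parse_cell("zzz", cat3, "row 't1', column 'c'"),
               "undeclared state.*row 't1', column 'c'")
  expect_error(parse_cell("4..2", num), "lo > hi")
  expect_error(parse_cell("abc", num), "malformed numerical")
})

test_that("JSON and CSV round-trip a knowledge base", {
  kb <- platynini_kb()
  fj <- withr::local_tempfile(fileext = ".json")
  save_kb(kb, fj)
  expect_identical(load_kb(fj), kb)

  # CSV keeps declared states, weights and every matrix cell; per-cell
  # provenance notes and free-text notes are JSON-only by design
  fc <- withr::local_tempfile(fileext = ".csv")
  save_kb(kb, fc)
  kb2 <- load_kb(fc)
  expect_identical(names(kb2$taxa), names(kb$taxa))
  expect_identical(names(kb2$characters), names(kb$characters))
  expect_identical(lapply(kb2$characters, `[[`, "states"),
                   lapply(kb$characters, `[[`, "states"))
  for (t in names(kb$taxa)) {
    expect_identical(kb2$taxa[[t]]$in_region, kb$taxa[[t]]$in_region)
    for (ch in names(kb$characters))
      expect_identical(format_cell(kb2$taxa[[t]]$observations[[ch]]),
                       format_cell(kb$taxa[[t]]$observations[[ch]]))
  }

  # json -> csv -> json preserves the matrix cell for cell
  kb3 <- load_kb(fj)
  fc2 <- withr::local_tempfile(fileext = ".csv")
  save_kb(kb3, fc2)
  fj2 <- withr::local_tempfile(fileext = ".json")
  save_kb(load_kb(fc2), fj2)
  kb4 <- load_kb(fj2)
  for (t in names(kb$taxa))
    for (ch in names(kb$characters))
      expect_identical(format_cell(kb4$taxa[[t]]$observations[[ch]]),
                       format_cell(kb$taxa[[t]]$observations[[ch]]))
})

test_that("loading rejects malformed input with a useful message", {
  kb <- platynini_kb()
  fc <- withr::local_tempfile(fileext = ".csv")
  save_kb(kb, fc)
  lines <- readLines(fc)
  i <- grep("atranus_ruficollis", lines, fixed = TRUE)[1]
  lines[i] <- sub("present", "fuzzy", lines[i])
  writeLines(lines, fc)
  expect_error(load_kb(fc), "fuzzy.*atranus_ruficollis.*hairs_upperside")

  # duplicate taxon ids
  fj <- withr::local_tempfile(fileext = ".json")
  x <- jsonlite::fromJSON(save_kb(kb, fj), simplifyVector = FALSE)
  x$taxa[[2]]$taxon_id <- x$taxa[[1]]$taxon_id
  jsonlite::write_json(x, fj, auto_unbox = TRUE)
  expect_error(load_kb(fj), "duplicate taxon ids")

  # an empty taxon list is a structural error
  x <- jsonlite::fromJSON(save_kb(kb, fj), simplifyVector = FALSE)
  x$taxa <- list()
  jsonlite::write_json(x, fj, auto_unbox = TRUE)
  expect_error(load_kb(fj), "no taxa")
})

test_that("SDD-flavoured XML export is well-formed and loss-free", {
  kb <- platynini_kb()
  fx <- withr::local_tempfile(fileext = ".xml")
  export_sdd_xml(kb, fx)
  doc <- xml2::read_xml(fx)   # read_xml itself rejects malformed XML
  expect_length(xml2::xml_find_all(doc, "//TaxonNames/TaxonName"), 14L)
  expect_length(xml2::xml_find_all(doc, "//CodedDescriptions/CodedDescription"),
                14L)
  expect_length(xml2::xml_find_all(doc, "//Characters/*"), 16L)
  # unknown cells are explicitly marked
  expect_gt(length(xml2::xml_find_all(doc, "//Status[@code='unknown']")), 0L)
  expect_identical(import_sdd_xml(fx), kb)

  # a descriptorless knowledge base still exports valid XML
  kb0 <- knowledge_base("bare", list(),
                        list(taxon_desc("t", "T")))
  fx0 <- withr::local_tempfile(fileext = ".xml")
  export_sdd_xml(kb0, fx0)
  doc0 <- xml2::read_xml(fx0)
  expect_length(xml2::xml_find_all(doc0, "//Characters/*"), 0L)
})

test_that("the packaged knowledge base matches its construction and carries provenance", {
  kb <- platynini_kb()
  expect_length(kb$taxa, 14L)
  expect_length(kb$characters, 16L)

  # the shipped extdata files are exactly the constructed knowledge base
  fj <- system.file("extdata", "platynini_levant.json", package = "polyclave")
  expect_identical(load_kb(fj), kb)

  # transcription audit: every scored cell names its printed source
  for (tx in kb$taxa)
    for (ch in names(kb$characters)) {
      obs <- tx$observations[[ch]]
      if (obs$status == "scored")
        expect_true(nzchar(obs$source),
                    label = paste0("source of ", tx$taxon_id, " / ", ch))
    }

  # weight overrides reach the characters
  kbw <- platynini_kb(weights = c(hairs_upperside = 3, body_length = 1))
  expect_identical(kbw$characters$hairs_upperside$weight, 3L)
  expect_identical(kbw$characters$body_length$weight, 1L)
  expect_error(platynini_kb(weights = c(nope = 2)), "unknown character")
})
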