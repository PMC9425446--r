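#' Matrix cell grammar
#'
#' The CSV interchange dialect stores one observation per cell:
#' * categorical states separated by `|` (e.g. `present`, `s1|s3`),
#' * numerical values as a point (`6.5`) or closed interval (`5.5..8`),
#' * `?` for unknown, `NA` for inapplicable.
#'
#' `parse_cell()` and `format_cell()` are exact inverses on valid cells.
#'
#' @param text Cell text.
#' @param ch The [char_def()] the cell belongs to.
#' @param where Context string used in error messages (row/column).
#' @param obs An [obs_states()]-family observation.
#' @return `parse_cell()` an `observation`; `format_cell()` a string.
#' @export
parse_cell <- function(text, ch, where = "") {
  text <- trimws(text)
  ctx <- if (nzchar(where)) paste0(" (", where, ")") else ""
  if (text == "?") return(obs_unknown())
  if (text == "NA") return(obs_inapplicable())
  if (ch$kind == "categorical") {
    states <- strsplit(text, "|", fixed = TRUE)[[1]]
    states <- trimws(states)
    if (length(states) == 0L || any(!nzchar(states)))
      stop("malformed categorical cell '", text, "'", ctx, call. = FALSE)
    bad <- setdiff(states, state_ids(ch))
    if (length(bad))
      stop("undeclared state(s) ", paste(bad, collapse = ", "),
           " in cell '", text, "'", ctx, call. = FALSE)
    obs_states(states)
  } else {
    parts <- strsplit(text, "..", fixed = TRUE)[[1]]
    if (!length(parts) %in% 1:2)
      stop("malformed numerical cell '", text, "'", ctx, call. = FALSE)
    vals <- suppressWarnings(as.numeric(parts))
    if (anyNA(vals))
      stop("malformed numerical cell '", text, "'", ctx, call. = FALSE)
    if (length(vals) == 1L) vals <- c(vals, vals)
    if (vals[1] > vals[2])
      stop("numerical cell '", text, "' has lo > hi", ctx, call. = FALSE)
    obs_range(vals[1], vals[2])
  }
}

#' @rdname parse_cell
#' @export
format_cell <- function(obs) {
  switch(obs$status,
    unknown = "?",
    inapplicable = "NA",
    scored = if (!is.null(obs$states)) paste(obs$states, collapse = "|")
      else if (obs$range[1] == obs$range[2]) format_num(obs$range[1])
      else paste0(format_num(obs$range[1]), "..", format_num(obs$range[2]))
  )
}

#' Read and write knowledge bases
#'
#' Two documented on-disk formats:
#'
#' * **json** — complete: characters with declared states, weights and
#'   groups, taxa with per-cell status, values and provenance `source`
#'   notes. Loss-free round trip.
#' * **csv** — a matrix table (one row per taxon, one column per character,
#'   cells in the [parse_cell()] grammar) preceded by `#`-prefixed header
#'   lines (`#title:` and one `#character:` line per descriptor carrying
#'   id, kind, name, declared states, units, weight, group as
#'   tab-separated `key=value` fields). Round trips everything except
#'   per-cell provenance notes and free-text notes.
#'
#' `load_kb()` validates structurally and stops on errors (duplicate ids,
#' malformed cells — named by row and column —, empty taxon lists).
#'
#' @param path File path.
#' @param format `"json"` or `"csv"`; default guessed from the extension.
#' @param kb A [knowledge_base()].
#' @return `load_kb()` a [knowledge_base()]; `save_kb()` the path,
#'   invisibly.
#' @examples
#' f <- tempfile(fileext = ".json")
#' save_kb(platynini_kb(), f)
#' kb <- load_kb(f)
#' length(kb$taxa)
#' @export
load_kb <- function(path, format = c("auto", "json", "csv")) {
  format <- resolve_format(match.arg(format), path)
  kb <- if (format == "json") kb_from_json_list(
    jsonlite::fromJSON(path, simplifyVector = FALSE))
  else load_kb_csv(path)
  assert_valid_kb(kb)
}

#' @rdname load_kb
#' @export
save_kb <- function(kb, path, format = c("auto", "json", "csv")) {
  stopifnot(inherits(kb, "knowledge_base"))
  format <- resolve_format(match.arg(format), path)
  if (format == "json") {
    jsonlite::write_json(kb_to_json_list(kb), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
  } else {
    save_kb_csv(kb, path)
  }
  invisible(path)
}

resolve_format <- function(format, path) {
  if (format != "auto") return(format)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("json", "csv")) ext
  else stop("cannot guess format from extension '", ext,
            "'; pass format=", call. = FALSE)
}

# ---- JSON ------------------------------------------------------------------

kb_to_json_list <- function(kb) {
  list(
    title = kb$title,
    notes = kb$notes,
    characters = lapply(unname(kb$characters), function(ch) {
      out <- list(char_id = ch$char_id, name = ch$name, kind = ch$kind,
                  weight = ch$weight, group = ch$group)
      if (ch$kind == "categorical")
        out$states <- lapply(seq_len(nrow(ch$states)), function(i)
          list(state_id = ch$states$state_id[i], label = ch$states$label[i]))
      else out$units <- ch$units
      out
    }),
    taxa = lapply(unname(kb$taxa), function(tx) {
      list(taxon_id = tx$taxon_id, name = tx$name, in_region = tx$in_region,
           notes = tx$notes,
           observations = lapply(tx$observations, function(obs) {
             out <- list(status = obs$status)
             if (!is.null(obs$states)) out$states <- as.list(obs$states)
             if (!is.null(obs$range)) out$range <- as.list(obs$range)
             if (nzchar(obs$source)) out$source <- obs$source
             out
           }))
    })
  )
}

json_chr <- function(x, default = "") if (is.null(x)) default else x

kb_from_json_list <- function(x) {
  characters <- lapply(x$characters, function(ch) {
    states <- if (length(ch$states))
      data.frame(state_id = vapply(ch$states, `[[`, character(1), "state_id"),
                 label = vapply(ch$states, `[[`, character(1), "label"),
                 stringsAsFactors = FALSE)
    char_def(ch$char_id, ch$name, ch$kind, states = states,
             units = json_chr(ch$units), weight = json_chr(ch$weight, 2L),
             group = json_chr(ch$group))
  })
  taxa <- lapply(x$taxa, function(tx) {
    observations <- lapply(tx$observations, function(obs) {
      src <- json_chr(obs$source)
      switch(obs$status,
        unknown = obs_unknown(src),
        inapplicable = obs_inapplicable(src),
        scored = if (!is.null(obs$states))
          obs_states(unlist(obs$states), src)
        else obs_range(obs$range[[1]], obs$range[[2]], src),
        stop("unknown observation status '", obs$status, "'", call. = FALSE))
    })
    taxon_desc(tx$taxon_id, tx$name, in_region = isTRUE(tx$in_region),
               observations = observations, notes = json_chr(tx$notes))
  })
  knowledge_base(json_chr(x$title), characters, taxa,
                 notes = json_chr(x$notes))
}

# ---- CSV -------------------------------------------------------------------

csv_reserved <- function(x, what) {
  if (any(grepl("[\t|]", x)) || any(grepl("\\.\\.", x)))
    stop(what, " may not contain tabs, '|' or '..' in the CSV dialect",
         call. = FALSE)
  x
}

save_kb_csv <- function(kb, path) {
  header <- c(paste0("#title: ", gsub("[\r\n]+", " ", kb$title)))
  for (ch in kb$characters) {
    fields <- c(paste0("id=", ch$char_id),
                paste0("kind=", ch$kind),
                paste0("name=", csv_reserved(ch$name, "character names")),
                paste0("weight=", ch$weight))
    if (nzchar(ch$group)) fields <- c(fields, paste0("group=", ch$group))
    if (ch$kind == "categorical") {
      csv_reserved(ch$states$label, "state labels")
      fields <- c(fields, paste0("states=", paste0(
        ch$states$state_id, ":", ch$states$label, collapse = "|")))
    } else if (nzchar(ch$units)) {
      fields <- c(fields, paste0("units=", ch$units))
    }
    header <- c(header, paste0("#character: ", paste(fields, collapse = "\t")))
  }
  mat <- data.frame(taxon_id = names(kb$taxa),
                    name = vapply(kb$taxa, `[[`, character(1), "name"),
                    in_region = vapply(kb$taxa, `[[`, logical(1), "in_region"),
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (char_id in names(kb$characters))
    mat[[char_id]] <- vapply(kb$taxa, function(tx)
      format_cell(tx$observations[[char_id]]), character(1))
  con <- textConnection("csv_body", "w", local = TRUE)
  utils::write.csv(mat, con, row.names = FALSE)
  close(con)
  writeLines(c(header, csv_body), path)
  invisible(path)
}

parse_character_header <- function(line) {
  fields <- strsplit(sub("^#character:\\s*", "", line), "\t", fixed = TRUE)[[1]]
  kv <- list()
  for (f in fields) {
    eq <- regexpr("=", f, fixed = TRUE)
    if (eq < 1L) stop("malformed #character field: ", f, call. = FALSE)
    kv[[substr(f, 1L, eq - 1L)]] <- substr(f, eq + 1L, nchar(f))
  }
  states <- NULL
  if (!is.null(kv$states)) {
    pairs <- strsplit(strsplit(kv$states, "|", fixed = TRUE)[[1]], ":",
                      fixed = TRUE)
    states <- data.frame(
      state_id = vapply(pairs, `[[`, character(1), 1L),
      label = vapply(pairs, function(p)
        if (length(p) > 1L) paste(p[-1], collapse = ":") else p[[1]],
        character(1)),
      stringsAsFactors = FALSE)
  }
  char_def(kv$id, json_chr(kv$name, kv$id), json_chr(kv$kind, "categorical"),
           states = states, units = json_chr(kv$units),
           weight = as.integer(json_chr(kv$weight, "2")),
           group = json_chr(kv$group))
}

load_kb_csv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  title <- sub("^#title:\\s*", "", meta[startsWith(meta, "#title:")][1])
  if (is.na(title)) title <- basename(path)
  characters <- lapply(meta[startsWith(meta, "#character:")],
                       parse_character_header)
  names(characters) <- vapply(characters, `[[`, character(1), "char_id")
  tab <- utils::read.csv(text = paste(body, collapse = "\n"),
                         check.names = FALSE, colClasses = "character")
  need <- c("taxon_id", "name", "in_region")
  if (!all(need %in% names(tab)))
    stop("CSV matrix needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  cell_cols <- setdiff(names(tab), need)
  undeclared <- setdiff(cell_cols, names(characters))
  if (length(undeclared))
    stop("matrix column(s) without #character declaration: ",
         paste(undeclared, collapse = ", "), call. = FALSE)
  taxa <- lapply(seq_len(nrow(tab)), function(i) {
    observations <- list()
    for (char_id in cell_cols)
      observations[[char_id]] <- parse_cell(
        tab[[char_id]][i], characters[[char_id]],
        where = paste0("row '", tab$taxon_id[i], "', column '", char_id, "'"))
    taxon_desc(tab$taxon_id[i], tab$name[i],
               in_region = tolower(tab$in_region[i]) %in% c("true", "t", "1"),
               observations = observations)
  })
  knowledge_base(title, characters, taxa)
}

# ---- SDD-flavoured XML -----------------------------------------------------

#' SDD-flavoured XML interchange
#'
#' Exports a knowledge base as structured-descriptive-data-style XML: a
#' `Dataset` with `Characters` (one `CategoricalCharacter` with
#' `StateDefinition`s, or `QuantitativeCharacter` with a `MeasurementUnit`,
#' per descriptor), `TaxonNames`, and one `CodedDescription` per taxon whose
#' `SummaryData` holds one element per character — `State` references for
#' scored categorical cells, `Measure` Min/Max for numerical ones, and an
#' explicit `Status` marker for unknown and inapplicable cells. Character
#' weight/group, taxon `in_region` and per-cell provenance ride along as
#' attributes, so [import_sdd_xml()] recovers the knowledge base exactly.
#' This is an export-flavoured subset of the SDD standard, not full SDD 1.1.
#'
#' @param kb A [knowledge_base()].
#' @param path Output (input) file path.
#' @return `export_sdd_xml()` the path invisibly; `import_sdd_xml()` a
#'   [knowledge_base()].
#' @examples
#' f <- tempfile(fileext = ".xml")
#' export_sdd_xml(platynini_kb(), f)
#' kb2 <- import_sdd_xml(f)
#' length(kb2$taxa)
#' @export
export_sdd_xml <- function(kb, path) {
  stopifnot(inherits(kb, "knowledge_base"))
  root <- xml2::xml_new_root("Datasets")
  ds <- xml2::xml_add_child(root, "Dataset")
  rep <- xml2::xml_add_child(ds, "Representation")
  xml2::xml_add_child(rep, "Label", kb$title)
  if (nzchar(kb$notes)) xml2::xml_add_child(rep, "Detail", kb$notes)

  chars_node <- xml2::xml_add_child(ds, "Characters")
  for (ch in kb$characters) {
    tag <- if (ch$kind == "categorical") "CategoricalCharacter"
           else "QuantitativeCharacter"
    cn <- xml2::xml_add_child(chars_node, tag, id = ch$char_id,
                              weight = as.character(ch$weight))
    if (nzchar(ch$group)) xml2::xml_set_attr(cn, "group", ch$group)
    crep <- xml2::xml_add_child(cn, "Representation")
    xml2::xml_add_child(crep, "Label", ch$name)
    if (ch$kind == "categorical") {
      sn <- xml2::xml_add_child(cn, "States")
      for (i in seq_len(nrow(ch$states))) {
        sd <- xml2::xml_add_child(sn, "StateDefinition",
                                  id = ch$states$state_id[i])
        srep <- xml2::xml_add_child(sd, "Representation")
        xml2::xml_add_child(srep, "Label", ch$states$label[i])
      }
    } else {
      mu <- xml2::xml_add_child(cn, "MeasurementUnit")
      xml2::xml_add_child(mu, "Label", ch$units)
    }
  }

  tn <- xml2::xml_add_child(ds, "TaxonNames")
  for (tx in kb$taxa) {
    t <- xml2::xml_add_child(tn, "TaxonName", id = tx$taxon_id,
                             in_region = if (tx$in_region) "true" else "false")
    trep <- xml2::xml_add_child(t, "Representation")
    xml2::xml_add_child(trep, "Label", tx$name)
    if (nzchar(tx$notes)) xml2::xml_add_child(trep, "Detail", tx$notes)
  }

  cds <- xml2::xml_add_child(ds, "CodedDescriptions")
  for (tx in kb$taxa) {
    cd <- xml2::xml_add_child(cds, "CodedDescription")
    scope <- xml2::xml_add_child(cd, "Scope")
    xml2::xml_add_child(scope, "TaxonName", ref = tx$taxon_id)
    sd <- xml2::xml_add_child(cd, "SummaryData")
    for (char_id in names(kb$characters)) {
      ch <- kb$characters[[char_id]]
      obs <- tx$observations[[char_id]]
      if (is.null(obs)) obs <- obs_unknown()
      tag <- if (ch$kind == "categorical") "Categorical" else "Quantitative"
      el <- xml2::xml_add_child(sd, tag, ref = char_id)
      if (nzchar(obs$source)) xml2::xml_set_attr(el, "source", obs$source)
      if (!is_scored(obs)) {
        xml2::xml_add_child(el, "Status", code = obs$status)
      } else if (ch$kind == "categorical") {
        for (s in obs$states) xml2::xml_add_child(el, "State", ref = s)
      } else {
        xml2::xml_add_child(el, "Measure", type = "Min",
                            value = format_num(obs$range[1]))
        xml2::xml_add_child(el, "Measure", type = "Max",
                            value = format_num(obs$range[2]))
      }
    }
  }
  xml2::write_xml(root, path)
  invisible(path)
}

xattr <- function(node, name, default = "") {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) default else v
}

#' @rdname export_sdd_xml
#' @export
import_sdd_xml <- function(path) {
  doc <- xml2::read_xml(path)
  ds <- xml2::xml_find_first(doc, "./Dataset")
  title <- xml2::xml_text(
    xml2::xml_find_first(ds, "./Representation/Label"))
  notes <- xml2::xml_find_first(ds, "./Representation/Detail")
  notes <- if (inherits(notes, "xml_missing")) "" else xml2::xml_text(notes)

  characters <- lapply(
    xml2::xml_find_all(ds, "./Characters/*"), function(cn) {
      kind <- if (xml2::xml_name(cn) == "CategoricalCharacter")
        "categorical" else "numerical"
      states <- NULL; units <- ""
      if (kind == "categorical") {
        defs <- xml2::xml_find_all(cn, "./States/StateDefinition")
        states <- data.frame(
          state_id = xml2::xml_attr(defs, "id"),
          label = vapply(defs, function(d) xml2::xml_text(
            xml2::xml_find_first(d, "./Representation/Label")), character(1)),
          stringsAsFactors = FALSE)
      } else {
        units <- xml2::xml_text(
          xml2::xml_find_first(cn, "./MeasurementUnit/Label"))
      }
      char_def(xattr(cn, "id"),
               xml2::xml_text(xml2::xml_find_first(cn, "./Representation/Label")),
               kind, states = states, units = units,
               weight = as.integer(xattr(cn, "weight", "2")),
               group = xattr(cn, "group"))
    })
  names(characters) <- vapply(characters, `[[`, character(1), "char_id")

  name_nodes <- xml2::xml_find_all(ds, "./TaxonNames/TaxonName")
  meta <- list()
  for (t in name_nodes) {
    meta[[xattr(t, "id")]] <- list(
      name = xml2::xml_text(xml2::xml_find_first(t, "./Representation/Label")),
      in_region = identical(xattr(t, "in_region", "true"), "true"),
      notes = {
        d <- xml2::xml_find_first(t, "./Representation/Detail")
        if (inherits(d, "xml_missing")) "" else xml2::xml_text(d)
      })
  }

  taxa <- lapply(xml2::xml_find_all(ds, "./CodedDescriptions/CodedDescription"),
                 function(cd) {
    taxon_id <- xattr(xml2::xml_find_first(cd, "./Scope/TaxonName"), "ref")
    observations <- list()
    for (el in xml2::xml_find_all(cd, "./SummaryData/*")) {
      char_id <- xattr(el, "ref")
      src <- xattr(el, "source")
      status <- xml2::xml_find_first(el, "./Status")
      observations[[char_id]] <- if (!inherits(status, "xml_missing")) {
        if (identical(xattr(status, "code"), "inapplicable"))
          obs_inapplicable(src) else obs_unknown(src)
      } else if (xml2::xml_name(el) == "Categorical") {
        obs_states(xml2::xml_attr(xml2::xml_find_all(el, "./State"), "ref"),
                   src)
      } else {
        ms <- xml2::xml_find_all(el, "./Measure")
        vals <- as.numeric(xml2::xml_attr(ms, "value"))
        names(vals) <- xml2::xml_attr(ms, "type")
        obs_range(vals[["Min"]], vals[["Max"]], src)
      }
    }
    m <- meta[[taxon_id]]
    taxon_desc(taxon_id, m$name, in_region = m$in_region,
               observations = observations, notes = m$notes)
  })
  knowledge_base(title, characters, taxa, notes = notes)
}
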