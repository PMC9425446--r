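#' Generate a single-access key from a knowledge base
#'
#' Recursive top-down construction: at each node the top character of
#' [rank_characters()] (under the given options) is asked, and the current
#' taxon set is split over its observed values. Categorical characters get
#' one branch per state observed among the scored taxa; a polymorphic taxon
#' appears under every branch whose state it carries (this is what makes
#' variable species show up at two or three leaves of such keys), and taxa
#' unknown or inapplicable for the character are copied to every branch.
#' Numerical characters are binarised at the gaps of their interval coverage:
#' each maximal covered block becomes one branch; with no gap the character
#' cannot split and the next-ranked character is tried. Recursion stops at
#' singletons, or at groups no unused character can separate (rendered as an
#' unresolved leaf). Construction is deterministic: the same knowledge base
#' and options give byte-identical keys.
#'
#' @param kb A valid [knowledge_base()] with at least two taxa.
#' @param options A [ranking_options()] object. The combination
#'   `ranking_options("fewer_states", use_weights = TRUE)` mirrors the
#'   "use weights" + "prioritize characters with fewer states" options of
#'   interactive key builders.
#' @return An object of class `single_access_key`.
#' @examples
#' key <- build_single_access_key(platynini_kb(),
#'                                ranking_options("fewer_states"))
#' key_metrics(key)$alternatives
#' @export
build_single_access_key <- function(kb, options = ranking_options()) {
  assert_valid_kb(kb)
  if (length(kb$taxa) < 2L)
    stop("key generation needs at least two taxa", call. = FALSE)
  env <- new.env(parent = emptyenv())
  env$n <- 0L

  build <- function(remaining, used) {
    if (length(remaining) == 1L)
      return(list(kind = "taxa", taxa = remaining, unresolved = FALSE))
    ranked <- rank_characters_impl(kb, remaining, exclude = used,
                                   options = options)
    for (char_id in ranked) {
      parts <- branch_partition(kb, char_id, remaining)
      if (length(parts) >= 2L) {
        env$n <- env$n + 1L
        node <- list(kind = "node", node_id = env$n, char_id = char_id,
                     branches = vector("list", length(parts)))
        for (i in seq_along(parts)) {
          node$branches[[i]] <- list(
            predicate = parts[[i]]$predicate,
            label = parts[[i]]$label,
            target = build(parts[[i]]$taxa, c(used, char_id)))
        }
        return(node)
      }
    }
    list(kind = "taxa", taxa = remaining, unresolved = TRUE)
  }

  root <- build(names(kb$taxa), character())
  structure(list(root = root, n_nodes = env$n, options = options,
                 kb_title = kb$title,
                 taxon_labels = vapply(kb$taxa, `[[`, character(1), "name")),
            class = "single_access_key")
}

# Split a taxon set over one character's observed values. Returns a list of
# branches (predicate, label, taxa) or an empty list when the character
# cannot split the set. Unknown/inapplicable taxa are copied to all branches.
branch_partition <- function(kb, char_id, remaining) {
  ch <- kb$characters[[char_id]]
  obs <- lapply(remaining, function(t) kb$taxa[[t]]$observations[[char_id]])
  scored <- vapply(obs, is_scored, logical(1))
  unknown_taxa <- remaining[!scored]
  if (!any(scored)) return(list())
  if (ch$kind == "categorical") {
    observed <- state_ids(ch)[state_ids(ch) %in%
                                unlist(lapply(obs[scored], `[[`, "states"))]
    if (length(observed) < 2L) return(list())
    lapply(observed, function(s) {
      with_state <- remaining[scored][vapply(obs[scored], function(o)
        s %in% o$states, logical(1))]
      label <- ch$states$label[match(s, ch$states$state_id)]
      list(predicate = structure(list(char_id = char_id, states = s,
                                      range = NULL), class = "key_pred"),
           label = paste0(ch$name, ": ", label),
           taxa = c(with_state, unknown_taxa))
    })
  } else {
    ranges <- do.call(rbind, lapply(obs[scored], `[[`, "range"))
    ord <- order(ranges[, 1], ranges[, 2])
    blocks <- list(); cur <- ranges[ord[1], ]
    for (i in ord[-1]) {
      if (ranges[i, 1] > cur[2]) {            # a gap: close the block
        blocks <- c(blocks, list(cur)); cur <- ranges[i, ]
      } else cur[2] <- max(cur[2], ranges[i, 2])
    }
    blocks <- c(blocks, list(cur))
    if (length(blocks) < 2L) return(list())
    lapply(blocks, function(b) {
      inside <- remaining[scored][ranges[, 1] >= b[1] & ranges[, 2] <= b[2]]
      unit <- if (nzchar(ch$units)) paste0(" ", ch$units) else ""
      list(predicate = structure(list(char_id = char_id, states = NULL,
                                      range = b), class = "key_pred"),
           label = paste0(ch$name, ": ", format_num(b[1]), "-",
                          format_num(b[2]), unit),
           taxa = c(inside, unknown_taxa))
    })
  }
}

# Shortest decimal representation that parses back to the same double.
format_num <- function(x) {
  s <- format(x, digits = 15, trim = TRUE, scientific = FALSE)
  if (as.numeric(s) != x) s <- sprintf("%.17g", x)
  s
}

#' @export
print.single_access_key <- function(x, ...) {
  cat("<single_access_key> ", x$n_nodes, " numbered steps (",
      x$kb_title, ")\n", sep = "")
  invisible(x)
}

# Walk a generated key, returning one row per leaf: taxa and depth in
# numbered nodes (inclusive of the terminal node).
key_leaves <- function(key) {
  out <- list()
  walk <- function(target, depth) {
    if (target$kind == "taxa") {
      out[[length(out) + 1L]] <<- list(taxa = target$taxa, depth = depth,
                                       unresolved = isTRUE(target$unresolved))
    } else {
      for (b in target$branches) walk(b$target, depth + 1L)
    }
  }
  walk(key$root, 0L)
  out
}

#' Candidate taxa for a profile under a generated key
#'
#' Follows every branch of a [build_single_access_key()] key that is
#' compatible with the profile (branches whose predicate shares a state with
#' the answer, or whose interval overlaps it; unanswered characters follow
#' all branches) and returns the union of the taxa at the reached leaves.
#'
#' @param key A `single_access_key`.
#' @param profile A [specimen_profile()].
#' @return Character vector of taxon ids.
#' @export
key_candidates <- function(key, profile) {
  hits <- character()
  walk <- function(target) {
    if (target$kind == "taxa") {
      hits <<- union(hits, target$taxa)
      return(invisible())
    }
    for (b in target$branches) {
      p <- b$predicate
      ans <- profile[[p$char_id]]
      follow <- if (is.null(ans)) TRUE
        else if (!is.null(p$states)) any(as.character(ans) %in% p$states)
        else {
          a <- as.numeric(ans); if (length(a) == 1L) a <- c(a, a)
          a[2] >= p$range[1] && a[1] <= p$range[2]
        }
      if (follow) walk(b$target)
    }
  }
  walk(key$root)
  hits
}

#' Structural metrics of a key
#'
#' The efficiency measures used to compare identification keys:
#' `alternatives` is the number of numbered steps (couplets of a dichotomous
#' key, numbered nodes of a generated key); `decisions` gives, per taxon, the
#' number of numbered steps traversed from the entry point to the taxon's
#' lead, inclusive of the terminal one (for taxa reachable at several leaves,
#' the minimum); `duplicated_taxa` lists taxa appearing at more than one
#' leaf; `unresolved_groups` lists leaves holding more than one taxon.
#'
#' @param key A `dichotomous_key` or `single_access_key`.
#' @return A list of class `key_metrics`.
#' @examples
#' m <- key_metrics(platynini_key())
#' m$alternatives          # 13
#' range(m$decisions)      # 2 and 9
#' @export
key_metrics <- function(key) UseMethod("key_metrics")

#' @export
key_metrics.single_access_key <- function(key) {
  leaves <- key_leaves(key)
  depth <- list()
  for (lf in leaves) for (t in lf$taxa)
    depth[[t]] <- c(depth[[t]], lf$depth)
  decisions <- vapply(depth, min, numeric(1))
  n_leaves_per_taxon <- vapply(depth, length, integer(1))
  structure(list(
    alternatives = key$n_nodes,
    decisions = decisions[order(match(names(decisions), names(depth)))],
    duplicated_taxa = names(n_leaves_per_taxon)[n_leaves_per_taxon > 1L],
    unresolved_groups = lapply(Filter(function(l) l$unresolved, leaves),
                               `[[`, "taxa"),
    n_leaves = length(leaves)),
    class = "key_metrics")
}

#' @export
key_metrics.dichotomous_key <- function(key) {
  depth <- list()
  walk <- function(number, d, seen) {
    if (number %in% seen) stop("cycle at couplet ", number, call. = FALSE)
    cp <- key$couplets[[as.character(number)]]
    for (ld in cp$leads) {
      if (ld$target$kind == "taxon") {
        t <- if (is.null(ld$target$taxon)) ld$target$label else ld$target$taxon
        depth[[t]] <<- c(depth[[t]], d)
      } else walk(ld$target$couplet, d + 1L, c(seen, number))
    }
  }
  entry <- min(vapply(key$couplets, `[[`, integer(1), "number"))
  walk(entry, 1L, integer())
  n_leads <- vapply(depth, length, integer(1))
  structure(list(
    alternatives = length(key$couplets),
    decisions = vapply(depth, min, numeric(1)),
    duplicated_taxa = names(n_leads)[n_leads > 1L],
    unresolved_groups = list(),
    n_leaves = sum(n_leads)),
    class = "key_metrics")
}

#' @export
print.key_metrics <- function(x, ...) {
  cat("<key_metrics> ", x$alternatives, " alternatives; decisions ",
      min(x$decisions), "-", max(x$decisions), sep = "")
  if (length(x$duplicated_taxa))
    cat("; ", length(x$duplicated_taxa), " taxa at >1 leaf", sep = "")
  if (length(x$unresolved_groups))
    cat("; ", length(x$unresolved_groups), " unresolved group(s)", sep = "")
  cat("\n")
  invisible(x)
}

#' Render a key as numbered couplet text
#'
#' Produces the conventional two-column layout: a numbered first lead, the
#' counter-leads marked with an en dash, and targets as either a step number
#' or a bold-marked taxon name (parenthesized taxa keep their parentheses;
#' unresolved groups are rendered as a bracketed list with a warning marker).
#' The output of [parse_key_text()] on this rendering reproduces the key
#' structure (step numbers, lead texts, targets); machine predicates are not
#' part of the printed form.
#'
#' @param key A `dichotomous_key` or `single_access_key`.
#' @return A single character scalar (lines separated by newlines).
#' @examples
#' cat(substr(render_key_text(platynini_key()), 1, 70), "\n")
#' @export
render_key_text <- function(key) UseMethod("render_key_text")

render_target <- function(tgt) {
  if (tgt$kind == "couplet") return(as.character(tgt$couplet))
  lab <- paste0("**", tgt$label, "**")
  if (isTRUE(tgt$parenthesized)) lab <- paste0("(", lab, ")") else lab
}

#' @export
render_key_text.dichotomous_key <- function(key) {
  lines <- character()
  numbers <- sort(vapply(key$couplets, `[[`, integer(1), "number"))
  for (n in numbers) {
    cp <- key$couplets[[as.character(n)]]
    for (i in seq_along(cp$leads)) {
      ld <- cp$leads[[i]]
      head <- if (i == 1L) as.character(cp$number) else "–"
      lines <- c(lines, paste(head, ld$text, render_target(ld$target),
                              sep = "\t"))
    }
  }
  paste(lines, collapse = "\n")
}

#' @export
render_key_text.single_access_key <- function(key) {
  lines <- character()
  labels <- key$taxon_labels
  walk <- function(node) {
    stopifnot(node$kind == "node")
    texts <- vapply(node$branches, `[[`, character(1), "label")
    for (i in seq_along(node$branches)) {
      tgt <- node$branches[[i]]$target
      tgt_txt <- if (tgt$kind == "node") as.character(tgt$node_id)
        else if (length(tgt$taxa) == 1L && !tgt$unresolved)
          paste0("**", labels[[tgt$taxa]], "**")
        else paste0("[", paste0("**", labels[tgt$taxa], "**",
                                collapse = "; "), "] (unresolved)")
      head <- if (i == 1L) as.character(node$node_id) else "–"
      lines <<- c(lines, paste(head, texts[i], tgt_txt, sep = "\t"))
    }
    for (b in node$branches) if (b$target$kind == "node") walk(b$target)
  }
  walk(key$root)
  paste(lines, collapse = "\n")
}

#' Parse rendered couplet text back into a key skeleton
#'
#' Inverse of [render_key_text()] at the structural level: step numbers,
#' lead texts and targets are recovered; machine predicates are not printed
#' and therefore not recovered (the returned key traverses only by text).
#' Rendering the parsed key reproduces the input byte for byte.
#'
#' @param text Character scalar as produced by [render_key_text()].
#' @return A [dichotomous_key()] (possibly with more than two leads per
#'   step for parsed polytomous keys, stored as consecutive leads).
#' @export
parse_key_text <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  couplets <- list()
  current <- NULL
  finish <- function(cur) {
    if (is.null(cur)) return(NULL)
    structure(list(number = cur$number, leads = cur$leads),
              class = "key_couplet")
  }
  parse_target <- function(s) {
    if (grepl("^[0-9]+$", s))
      return(list(kind = "couplet", couplet = as.integer(s)))
    par <- grepl("^\\(", s)
    lab <- gsub("^\\(|\\)$|\\*\\*", "", s)
    lab <- sub("\\] \\(unresolved\\)$", "", sub("^\\[", "", lab))
    list(kind = "taxon", taxon = NULL, label = lab, parenthesized = par)
  }
  for (line in lines) {
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(parts) != 3L)
      stop("malformed key line: ", line, call. = FALSE)
    lead <- structure(list(text = parts[2], predicates = list(),
                           target = parse_target(parts[3])),
                      class = "key_lead")
    if (parts[1] == "–") {
      if (is.null(current))
        stop("counter-lead before any numbered lead", call. = FALSE)
      current$leads <- c(current$leads, list(lead))
    } else {
      cp <- finish(current)
      if (!is.null(cp)) couplets[[as.character(cp$number)]] <- cp
      current <- list(number = as.integer(parts[1]), leads = list(lead))
    }
  }
  cp <- finish(current)
  if (!is.null(cp)) couplets[[as.character(cp$number)]] <- cp
  structure(list(couplets = couplets, title = ""), class = "dichotomous_key")
}
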