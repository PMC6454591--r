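# BEL statement parsing: statement string -> bel_tree.
#
# The grammar accepted is the subset used by the causal-network extraction
# task: `term relation term` with the four supported relation keywords,
# entity terms p()/a()/bp()/path() (also g/r/m), functions such as complex()
# and the activity family, and modification functions pmod()/sub()/trunc()/
# fus() either inside an entity term (surface form) or elevated above it
# (normalized form).  Nested relations (a statement as argument of another)
# are rejected explicitly.

# split `text` at top-level commas (depth 0, outside double quotes)
split_top_commas <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L; in_q <- FALSE; cuts <- integer(0)
  for (i in seq_along(chars)) {
    c <- chars[i]
    if (c == '"') in_q <- !in_q
    else if (!in_q && c == "(") depth <- depth + 1L
    else if (!in_q && c == ")") depth <- depth - 1L
    else if (!in_q && c == "," && depth == 0L) cuts <- c(cuts, i)
  }
  if (!length(cuts)) return(text)
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts - 1L, length(chars))
  vapply(seq_along(starts), function(k)
    paste(chars[seq(starts[k], ends[k])], collapse = ""), "")
}

check_balanced <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L; in_q <- FALSE
  for (i in seq_along(chars)) {
    c <- chars[i]
    if (c == '"') in_q <- !in_q
    if (in_q) next
    if (c == "(") depth <- depth + 1L
    if (c == ")") {
      depth <- depth - 1L
      if (depth < 0L) abort(sprintf("unbalanced parentheses at offset %d", i))
    }
  }
  if (depth != 0L) abort(sprintf("unbalanced parentheses at offset %d", nchar(text)))
  invisible(TRUE)
}

# locate top-level relation keywords (depth 0, whitespace-delimited words)
find_top_relations <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L; in_q <- FALSE
  level <- integer(length(chars))
  for (i in seq_along(chars)) {
    c <- chars[i]
    if (c == '"') in_q <- !in_q
    if (!in_q && c == "(") depth <- depth + 1L
    level[i] <- if (in_q) 1L else depth
    if (!in_q && c == ")") depth <- depth - 1L
  }
  hits <- list()
  for (rel in .bel_relations) {
    for (m in gregexpr(rel, text, fixed = TRUE)[[1]]) {
      if (m < 0) next
      e <- m + nchar(rel) - 1L
      before <- if (m > 1L) chars[m - 1L] else " "
      after <- if (e < length(chars)) chars[e + 1L] else " "
      if (all(level[m:e] == 0L) && grepl("\\s", before) && grepl("\\s", after)) {
        hits[[length(hits) + 1L]] <- list(rel = rel, start = m, end = e)
      }
    }
  }
  # directlyIncreases also matches "Increases" substring? no: fixed match on
  # full keyword with whitespace guards keeps the four distinct.
  hits[order(vapply(hits, `[[`, 0L, "start"))]
}

strip_quotes <- function(x) gsub('"', "", x, fixed = TRUE)

parse_term <- function(text) {
  text <- trimws(text)
  if (!nzchar(text)) abort("empty BEL term")
  m <- regexec("^([A-Za-z][A-Za-z0-9_]*)\\s*\\((.*)\\)$", text)[[1]]
  if (m[1] != -1L) {
    name <- regmatches(text, list(m))[[1]][2]
    inner <- regmatches(text, list(m))[[1]][3]
    args <- split_top_commas(inner)
    if (name %in% .bel_entity_terms) {
      head <- trimws(args[[1]])
      if (!grepl(":", head) && !grepl(.placeholder_rx, head)) {
        abort(sprintf("entity term '%s' lacks a namespace:identifier argument", name))
      }
      ent <- bel_node("entity", strip_quotes(head))
      extra <- lapply(args[-1], parse_term)
      ent$children <- extra
      return(ent)
    }
    if (name %in% c(.bel_functions, .bel_modifications)) {
      return(bel_node("function", name, lapply(args, parse_term)))
    }
    # tolerate unknown call names as generic functions
    return(bel_node("function", name, lapply(args, parse_term)))
  }
  if (grepl(":", text, fixed = TRUE)) {
    return(bel_node("entity", strip_quotes(text)))
  }
  bel_node("parameter", strip_quotes(text))
}

#' Parse a BEL statement into a tree
#'
#' The relation keyword becomes the tree root and its left/right arguments are
#' converted recursively, in their original order, into the root's children.
#'
#' @param text a BEL statement string, e.g.
#'   `"p(HGNC:A) increases p(HGNC:B)"`.
#' @return a [bel_tree()].
#' @export
#' @examples
#' parse_statement("cat(p(HGNC:IL2)) increases complex(p(HGNC:LYN), p(HGNC:IL2RB))")
parse_statement <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  raw <- text
  text <- trimws(text)
  check_balanced(text)
  hits <- find_top_relations(text)
  if (!length(hits)) {
    abort("no supported relation keyword found (expected one of: increases, decreases, directlyIncreases, directlyDecreases)",
          class = "belhier_unsupported_relation")
  }
  if (length(hits) > 1L) {
    abort("nested or multiple top-level relations are not supported",
          class = "belhier_unsupported_relation")
  }
  h <- hits[[1]]
  lhs <- substr(text, 1L, h$start - 1L)
  rhs <- substr(text, h$end + 1L, nchar(text))
  root <- bel_node("relation", h$rel, list(parse_term(lhs), parse_term(rhs)))
  bel_tree(root, source_statement = raw)
}

#' Read sentence/statement pairs
#'
#' Reads a two-column, tab-separated file of `sentence_id<TAB>BEL statement`
#' (one statement per line, UTF-8).  Surrounding quotes on the statement and
#' trailing tab-separated annotations are tolerated.
#'
#' @param path file path.
#' @return a tibble with columns `sentence_id`, `statement`.
#' @export
read_bel_pairs <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tibble(
    sentence_id = vapply(parts, `[[`, "", 1L),
    statement = vapply(parts, function(p) {
      s <- trimws(p[[2]])
      sub('^"(.*)"$', "\\1", s)
    }, "")
  )
}

#' Write sentence/statement pairs
#'
#' @param pairs tibble with `sentence_id`, `statement` columns.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bel_pairs <- function(pairs, path) {
  writeLines(paste(pairs$sentence_id, pairs$statement, sep = "\t"), path,
             useBytes = TRUE)
  invisible(path)
}
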