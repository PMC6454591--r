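# Normalization, unification, preorder serialization with arity markers, and
# rendering back to BEL statement text.

#' Normalize a BEL statement tree
#'
#' Elevates modification functions (`pmod`, `sub`, `trunc`, `fus`) written
#' inside an entity term so that the function becomes the parent of the
#' entity, with the entity followed by the function's parameters as its
#' children: `p(HGNC:AKT1, pmod(P, S, 21))` becomes
#' `pmod(p(HGNC:AKT1), P, S, 21)`.  Keeping functions above entities makes
#' every statement a clean hierarchy for serialization.  Idempotent.
#'
#' @param tree a [bel_tree()] or [bel_node()].
#' @return the normalized object, same class as the input.
#' @export
#' @examples
#' t <- parse_statement("p(HGNC:AKT1, pmod(P, S, 21)) increases p(HGNC:GSK3B)")
#' normalize_statement(t)
normalize_statement <- function(tree) {
  if (inherits(tree, "bel_tree")) {
    return(bel_tree(normalize_node(tree$root), tree$source_statement))
  }
  normalize_node(tree)
}

normalize_node <- function(node) {
  node$children <- lapply(node$children, normalize_node)
  if (node$kind == "entity" && length(node$children)) {
    mods <- node$children
    node$children <- list()
    out <- node
    for (m in mods) {
      if (!(m$kind == "function" && m$label %in% .bel_modifications)) {
        abort(sprintf("unexpected argument '%s' inside entity term '%s'",
                      m$label, node$label))
      }
      out <- bel_node("function", m$label, c(list(out), m$children))
    }
    return(out)
  }
  node
}

#' Unify several BEL trees for one sentence
#'
#' A sentence may carry multiple statements; they are merged under an
#' inserted `"or"` root so a single tree can be aligned with the sentence.
#' A singleton list passes through unchanged, and duplicate statements
#' (exact tree equality after normalization) are collapsed to one.
#'
#' @param trees non-empty list of [bel_tree()] objects for one sentence.
#' @return a single [bel_tree()].
#' @seealso [split_unified()]
#' @export
unify_trees <- function(trees) {
  if (!length(trees)) abort("cannot unify an empty list of trees")
  stopifnot(all(vapply(trees, inherits, TRUE, "bel_tree")))
  # deduplicate identical statements attached to one sentence
  keep <- list()
  for (t in trees) {
    if (!any(vapply(keep, bel_equal, TRUE, t))) keep <- c(keep, list(t))
  }
  if (length(keep) == 1L) return(keep[[1]])
  bel_tree(bel_node("or", "or", lapply(keep, `[[`, "root")))
}

#' Split a unified tree back into individual statements
#'
#' Removes an `"or"` root, returning each child as its own tree; a plain
#' relation tree is returned as a singleton list.
#'
#' @param tree a [bel_tree()].
#' @return list of [bel_tree()] objects.
#' @export
split_unified <- function(tree) {
  stopifnot(inherits(tree, "bel_tree"))
  if (tree$root$kind != "or") return(list(tree))
  lapply(tree$root$children, bel_tree)
}

#' Build the placeholder map of a tree
#'
#' Assigns typed placeholders (`GENE_k`, `CHEM_k`, `BP_k`, `DIS_k`) to the
#' distinct entities of a tree in order of first mention (preorder), numbering
#' restarting at 1 within each type.
#'
#' @param tree a [bel_tree()] or [bel_node()].
#' @return named character vector: entity label -> placeholder.
#' @export
bel_placeholders <- function(tree) {
  labels <- unique(bel_entity_labels(tree))
  out <- character(0)
  counts <- c(GENE = 0L, CHEM = 0L, BP = 0L, DIS = 0L)
  for (lab in labels) {
    if (grepl(.placeholder_rx, lab)) {
      out[lab] <- lab
      next
    }
    ty <- entity_type(lab)
    counts[ty] <- counts[ty] + 1L
    out[lab] <- paste0(ty, "_", counts[ty])
  }
  out
}

#' Serialize a BEL tree to its node sequence
#'
#' Preorder traversal in which every internal node (relation, function or
#' `"or"`) is rendered as `label@n` with `n` its child count, entity leaves
#' are rendered as typed placeholders, and parameter leaves verbatim.  The
#' arity markers make the sequence uniquely invertible by
#' [deserialize_sequence()].
#'
#' @param tree a normalized (optionally unified) [bel_tree()].
#' @param placeholder_map named character vector entity label -> placeholder;
#'   defaults to [bel_placeholders()] of the tree.
#' @return character vector of node tokens (class `node_sequence`).
#' @export
#' @examples
#' t <- parse_statement(
#'   "a(CHEBI:castanospermine) decreases complex(p(MGI:Asgr2), p(MGI:Pdia3))")
#' serialize_tree(t)
serialize_tree <- function(tree, placeholder_map = NULL) {
  if (is.null(placeholder_map)) placeholder_map <- bel_placeholders(tree)
  node <- if (inherits(tree, "bel_tree")) tree$root else tree
  ser <- function(n) {
    if (n$kind %in% c("relation", "function", "or")) {
      return(c(sprintf("%s@%d", n$label, length(n$children)),
               unlist(lapply(n$children, ser))))
    }
    if (n$kind == "entity") {
      ph <- unname(placeholder_map[n$label])
      if (length(ph) != 1L || is.na(ph)) {
        abort(sprintf("entity '%s' missing from placeholder map", n$label))
      }
      return(ph)
    }
    n$label  # parameter
  }
  structure(ser(node), class = "node_sequence")
}

#' Reconstruct a BEL tree from a node sequence
#'
#' Consumes preorder tokens with their declared child counts (`label@n`).
#' Placeholder and `namespace:identifier` tokens become entity leaves, other
#' bare tokens parameter leaves.
#'
#' @param seq character vector of node tokens.
#' @return a [bel_tree()].
#' @export
deserialize_sequence <- function(seq) {
  seq <- as.character(seq)
  if (!length(seq)) abort("empty node sequence", class = "belhier_malformed_sequence")
  pos <- 0L
  take <- function() {
    pos <<- pos + 1L
    if (pos > length(seq)) {
      abort("malformed node sequence: ran out of tokens (arity overflow)",
            class = "belhier_malformed_sequence")
    }
    seq[pos]
  }
  build <- function() {
    tok <- take()
    m <- regexec("^(.*)@([0-9]+)$", tok)[[1]]
    if (m[1] != -1L) {
      parts <- regmatches(tok, list(m))[[1]]
      label <- parts[2]; n <- as.integer(parts[3])
      kind <- if (label %in% .bel_relations) "relation"
              else if (tolower(label) == "or") "function"  # placeholder, fixed below
              else "function"
      node <- bel_node(if (tolower(label) == "or") "or" else kind,
                       if (tolower(label) == "or") "or" else label,
                       lapply(seq_len(n), function(i) build()))
      return(node)
    }
    if (grepl(.placeholder_rx, tok) || grepl(":", tok, fixed = TRUE)) {
      return(bel_node("entity", tok))
    }
    bel_node("parameter", tok)
  }
  root <- build()
  if (pos < length(seq)) {
    abort(sprintf("malformed node sequence: %d leftover token(s) after the root tree",
                  length(seq) - pos),
          class = "belhier_malformed_sequence")
  }
  if (!root$kind %in% c("relation", "or")) {
    abort("node sequence does not start with a relation or 'or' node",
          class = "belhier_malformed_sequence")
  }
  bel_tree(root)
}

# push elevated modification functions back inside their entity term
# (inverse of normalize_statement); processed bottom-up
demote_mods <- function(node) {
  node$children <- lapply(node$children, demote_mods)
  if (node$kind == "function" && node$label %in% .bel_modifications &&
      length(node$children) >= 1L && node$children[[1]]$kind == "entity") {
    target <- node$children[[1]]
    params <- node$children[-1]
    target$children <- c(target$children,
                         list(bel_node("function", node$label, params)))
    return(target)
  }
  node
}

quote_if_needed <- function(idpart) {
  if (grepl("[^A-Za-z0-9_]", idpart)) paste0('"', idpart, '"') else idpart
}

render_entity_label <- function(label, entities) {
  if (grepl(.placeholder_rx, label)) {
    if (is.null(entities)) {
      # no entity table: render the typed placeholder verbatim
      return(list(term = .bel_type_term[[entity_type(label)]], text = label))
    }
    resolved <- unname(entities[label])
    if (length(resolved) != 1L || is.na(resolved)) {
      abort(sprintf("unresolvable placeholder '%s'", label))
    }
    label <- resolved
  }
  ns <- sub(":.*$", "", label)
  id <- sub("^[^:]*:", "", label)
  term <- .bel_type_term[[entity_type(label)]]
  list(term = term, text = paste0(ns, ":", quote_if_needed(id)))
}

#' Render a BEL tree as a statement string
#'
#' Inverse of parsing: elevated modification functions are moved back inside
#' their entity terms, entity types are normalized to the BEL term functions
#' `p()`, `a()`, `bp()`, `path()`, and arguments are joined with a comma and
#' no space.
#'
#' @param tree a plain (non-`"or"`) [bel_tree()].
#' @param entities optional named character vector mapping placeholders to
#'   `namespace:identifier`; required when the tree's leaves are placeholders.
#' @return a single BEL statement string.
#' @export
render_statement <- function(tree, entities = NULL) {
  node <- if (inherits(tree, "bel_tree")) tree$root else tree
  if (node$kind == "or") {
    abort("cannot render a unified 'or' tree; split it first with split_unified()")
  }
  node <- demote_mods(node)
  rend <- function(n) {
    switch(n$kind,
      relation = {
        if (length(n$children) != 2L) {
          abort(sprintf("relation '%s' must have exactly 2 arguments", n$label))
        }
        paste(rend(n$children[[1]]), n$label, rend(n$children[[2]]))
      },
      entity = {
        info <- render_entity_label(n$label, entities)
        args <- c(info$text, vapply(n$children, rend, ""))
        paste0(info$term, "(", paste(args, collapse = ","), ")")
      },
      "function" = paste0(n$label, "(",
                          paste(vapply(n$children, rend, ""), collapse = ","), ")"),
      parameter = n$label,
      abort(sprintf("cannot render node of kind '%s'", n$kind))
    )
  }
  rend(node)
}

#' Canonicalize statement whitespace
#'
#' Strips spaces after commas and collapses runs of whitespace so statement
#' strings from different dialects compare equal.
#'
#' @param text BEL statement string(s).
#' @return canonical string(s).
#' @export
canonical_bel_text <- function(text) {
  text <- gsub(",\\s+", ",", text)
  text <- gsub("\\s+", " ", text)
  trimws(text)
}
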