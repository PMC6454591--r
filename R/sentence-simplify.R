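# Dependency-based sentence simplification.
#
# A BEL statement is a highly condensed semantic representation of its
# sentence; aligning the whole sentence against the short node sequence
# produces many spurious links.  The sentence is therefore reduced to the
# words of the minimal dependency subtree containing all statement entities,
# emitted in their original order.  Parsing itself is external: trees arrive
# pre-parsed in CoNLL-U (Stanford-style basic dependencies work well because
# prepositions sit on the path between content words).

#' Construct a dependency tree
#'
#' @param heads integer vector, one entry per token: the 1-based index of the
#'   token's head, `0` for the root.
#' @param labels character vector of dependency relation labels.
#' @return object of class `dep_tree`.
#' @export
dep_tree <- function(heads, labels = rep("dep", length(heads))) {
  heads <- as.integer(heads)
  n <- length(heads)
  if (sum(heads == 0L) != 1L) abort("dependency tree must have exactly one root")
  if (any(heads < 0L | heads > n)) abort("head index out of range")
  # cycle check: every node must reach the root
  for (i in seq_len(n)) {
    seen <- logical(n); j <- i
    while (heads[j] != 0L) {
      if (seen[j]) abort("dependency annotation contains a cycle")
      seen[j] <- TRUE
      j <- heads[j]
    }
  }
  structure(list(heads = heads, labels = labels, root = which(heads == 0L)),
            class = "dep_tree")
}

#' @export
print.dep_tree <- function(x, ...) {
  cat(sprintf("<dep_tree> %d tokens, root at %d\n", length(x$heads), x$root))
  invisible(x)
}

#' Read a CoNLL-U file
#'
#' Parses 10-column CoNLL-U; `# sent_id = ...` comments are used as join
#' keys, multiword-token (`1-2`) and empty-node (`1.1`) lines are skipped.
#'
#' @param path file path.
#' @return list of records, each `list(sentence_id, forms, tree)` with `tree`
#'   a [dep_tree()].
#' @export
read_conllu <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  out <- list()
  sent_id <- NA_character_; forms <- character(0)
  heads <- integer(0); labels <- character(0); first_line <- NA_integer_
  flush <- function() {
    if (!length(forms)) return()
    tr <- tryCatch(dep_tree(heads, labels), error = function(e) {
      abort(sprintf("invalid dependency annotation for sentence starting at line %d: %s",
                    first_line, conditionMessage(e)))
    })
    out[[length(out) + 1L]] <<- list(sentence_id = sent_id, forms = forms,
                                     tree = tr)
    sent_id <<- NA_character_; forms <<- character(0)
    heads <<- integer(0); labels <<- character(0); first_line <<- NA_integer_
  }
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (!nzchar(trimws(line))) { flush(); next }
    if (startsWith(line, "#")) {
      m <- regmatches(line, regexec("^#\\s*sent_id\\s*=\\s*(.*)$", line))[[1]]
      if (length(m) == 2L) sent_id <- trimws(m[2])
      next
    }
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) < 8L) abort(sprintf("malformed CoNLL-U line %d", ln))
    if (grepl("[-.]", f[1])) next  # multiword token / empty node
    if (is.na(first_line)) first_line <- ln
    forms <- c(forms, f[2])
    heads <- c(heads, as.integer(f[7]))
    labels <- c(labels, f[8])
  }
  flush()
  out
}

#' Write records to CoNLL-U
#'
#' @param records list as returned by [read_conllu()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_conllu <- function(records, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (rec in records) {
    if (!is.na(rec$sentence_id)) {
      writeLines(paste0("# sent_id = ", rec$sentence_id), con)
    }
    tr <- rec$tree
    for (i in seq_along(rec$forms)) {
      writeLines(paste(i, rec$forms[i], "_", "_", "_", "_",
                       tr$heads[i], tr$labels[i], "_", "_", sep = "\t"), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

# ancestor chain of node i, from i up to the root (inclusive)
.chain <- function(heads, i) {
  out <- i
  while (heads[i] != 0L) {
    i <- heads[i]
    out <- c(out, i)
  }
  out
}

#' Minimal subtree containing a set of tokens
#'
#' Returns the node set of the minimal connected subgraph of the dependency
#' tree containing all targets: the union of the paths from every target to
#' the targets' lowest common ancestor.
#'
#' @param tree a [dep_tree()].
#' @param targets non-empty integer vector of 1-based token indices.
#' @return sorted integer vector of token indices.
#' @export
minimal_subtree <- function(tree, targets) {
  stopifnot(inherits(tree, "dep_tree"))
  targets <- unique(as.integer(targets))
  if (!length(targets)) abort("empty target set")
  n <- length(tree$heads)
  if (any(targets < 1L | targets > n)) abort("target index out of range")
  chains <- lapply(targets, function(t) .chain(tree$heads, t))
  common <- Reduce(intersect, chains)
  # chains end at the root, so `common` is non-empty; the LCA is the first
  # common node along any chain (deepest common ancestor)
  lca <- chains[[1]][min(match(common, chains[[1]]))]
  nodes <- integer(0)
  for (ch in chains) {
    nodes <- union(nodes, ch[seq_len(match(lca, ch))])
  }
  sort(nodes)
}

#' Simplify a sentence to its entity-connecting subtree
#'
#' Emits the tokens of [minimal_subtree()] over the entity placeholder
#' tokens, in their original sentence order.  When `tree` is `NULL` the
#' sentence is returned whole with a warning (simplification degrades to the
#' identity so the pipeline stays total).
#'
#' @param sentence an anonymized [annotated_sentence()].
#' @param tree a [dep_tree()] over the sentence's tokens, or `NULL`.
#' @param entity_tokens integer indices of the entity tokens; defaults to the
#'   placeholder tokens.
#' @return the token tibble restricted to the kept tokens, with an `index`
#'   column of original positions.
#' @export
simplify_sentence <- function(sentence, tree, entity_tokens = NULL) {
  toks <- sentence$tokens
  if (is.null(entity_tokens)) entity_tokens <- which(toks$is_placeholder)
  if (!length(entity_tokens)) abort("no entity tokens to simplify around")
  if (is.null(tree)) {
    warn(sprintf("no dependency tree for sentence '%s'; keeping the full sentence",
                 sentence$sentence_id))
    keep <- seq_len(nrow(toks))
  } else {
    if (length(tree$heads) != nrow(toks)) {
      abort(sprintf("dependency tree has %d tokens but sentence '%s' has %d",
                    length(tree$heads), sentence$sentence_id, nrow(toks)))
    }
    keep <- minimal_subtree(tree, entity_tokens)
  }
  out <- toks[keep, , drop = FALSE]
  out$index <- keep
  out
}
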