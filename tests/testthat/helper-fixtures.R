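# Shared fixtures built in code.

# flat two-entity tree
flat_tree <- function(rel = "increases", a = "HGNC:A", b = "HGNC:B") {
  bel_tree(bel_node("relation", rel,
                    list(bel_node("entity", a), bel_node("entity", b))))
}

# the castanospermine statement from the serialization example
castano_tree <- function() {
  parse_statement(
    "a(CHEBI:castanospermine) decreases complex(p(MGI:Asgr2), p(MGI:Pdia3))")
}

# the "Preincubation with ..." pair: simplified tokens and node sequence
preincubation_pair <- function() {
  list(
    source = c("Preincubation", "with", "CHEM_1", "prevented", "association",
               "of", "GENE_1", "to", "GENE_2"),
    target = c("decreases@2", "CHEM_1", "complex@2", "GENE_1", "GENE_2"),
    tree = bel_tree(bel_node("relation", "decreases", list(
      bel_node("entity", "CHEM_1"),
      bel_node("function", "complex", list(bel_node("entity", "GENE_1"),
                                           bel_node("entity", "GENE_2")))))),
    links = tibble::tibble(source = c(3L, 4L, 5L, 7L, 9L),
                           target = c(2L, 1L, 3L, 4L, 5L))
  )
}

# substitute entity labels via a placeholder map (for round-trip comparisons)
substitute_placeholders <- function(node, map) {
  if (inherits(node, "bel_tree")) {
    return(bel_tree(substitute_placeholders(node$root, map)))
  }
  if (node$kind == "entity") node$label <- map[[node$label]]
  node$children <- lapply(node$children, substitute_placeholders, map = map)
  node
}

# random dependency tree over n nodes (uniform attachment)
random_dep_tree <- function(n) {
  ord <- sample(n)
  heads <- integer(n)
  heads[ord[1]] <- 0L
  if (n > 1L) for (i in 2:n) {
    heads[ord[i]] <- ord[sample(i - 1L, 1L)]
  }
  dep_tree(heads)
}

# independent exhaustive minimal-connected-subgraph search (trees <= ~12
# nodes): smallest node subset containing all targets whose induced subgraph
# is connected
brute_minimal_subtree <- function(tree, targets) {
  n <- length(tree$heads)
  edges <- cbind(which(tree$heads != 0L), tree$heads[tree$heads != 0L])
  connected <- function(nodes) {
    if (length(nodes) <= 1L) return(TRUE)
    keep <- edges[edges[, 1] %in% nodes & edges[, 2] %in% nodes, , drop = FALSE]
    seen <- nodes[1]; frontier <- nodes[1]
    while (length(frontier)) {
      nxt <- unique(c(keep[keep[, 1] %in% frontier, 2],
                      keep[keep[, 2] %in% frontier, 1]))
      frontier <- setdiff(nxt, seen)
      seen <- c(seen, frontier)
    }
    length(seen) == length(nodes)
  }
  best <- NULL
  for (mask in 0:(2^n - 1)) {
    nodes <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    if (!all(targets %in% nodes)) next
    if (!is.null(best) && length(nodes) >= length(best)) next
    if (connected(nodes)) best <- nodes
  }
  sort(best)
}

# independent brute-force window scan for dictionary search (same tie-break
# contract: min distance, then longer window, then leftmost)
brute_dictionary_search <- function(tokens, names, max_span, threshold) {
  best <- NULL
  for (i in seq_along(tokens)) {
    for (j in i:min(length(tokens), i + max_span - 1L)) {
      text <- paste(tokens[i:j], collapse = " ")
      d <- min(vapply(names, function(nm) {
        utils::adist(tolower(text), tolower(nm)) /
          max(nchar(text), nchar(nm))
      }, 0))
      cand <- list(start = i, end = j, distance = d)
      if (is.null(best) ||
          d < best$distance - 1e-12 ||
          (abs(d - best$distance) < 1e-12 &&
           (j - i > best$end - best$start))) {
        best <- cand
      }
    }
  }
  if (best$distance > threshold) return(NULL)
  best
}

# independent per-sentence greedy multiset matcher for score oracle
brute_score <- function(gold, pred, level) {
  ids <- union(gold$sentence_id, pred$sentence_id)
  tp <- 0L; ng <- 0L; np <- 0L
  for (s in ids) {
    gk <- unlist(lapply(gold$statement[gold$sentence_id == s],
                        canonicalize, level = level))
    pk <- unlist(lapply(pred$statement[pred$sentence_id == s],
                        canonicalize, level = level))
    gk <- if (is.null(gk)) character(0) else gk
    pk <- if (is.null(pk)) character(0) else pk
    ng <- ng + length(gk); np <- np + length(pk)
    for (k in gk) {
      hit <- match(k, pk)
      if (!is.na(hit)) { tp <- tp + 1L; pk <- pk[-hit] }
    }
  }
  list(tp = tp, n_gold = ng, n_pred = np)
}
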