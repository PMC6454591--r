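# Layered BIESO tags: from (sentence, tree, alignment) to per-layer tag
# sequences and back.
#
# Layer 1 holds entity placeholders and function parameters; each internal
# node sits one layer above its highest child, and its span is the minimal
# contiguous token interval covering its own aligned word(s) and every token
# covered by its descendants.  Tokens inside a span's interval that belong to
# no lower node are tagged I (contiguous intervals, no O gaps inside spans).
# Tag labels carry no arity marker; arity is recomputed from the recognized
# children at reconstruction.

# three-letter -> one-letter amino acid map used when converting parameter
# tokens back to BEL pmod parameters
.aa3to1 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
             Glu = "E", Gln = "Q", Gly = "G", His = "H", Ile = "I",
             Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
             Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V")

param_class <- function(label) {
  if (grepl("^[0-9]+$", label)) return("NUM")
  if (label == "P") return("P")
  if (label %in% c(.aa_codes, names(.aa3to1))) return("AA")
  "P"
}

#' Assign hierarchy layers to the nodes of a BEL tree
#'
#' Leaves (entities and parameters) sit at layer 1; every internal node sits
#' at `1 + max(children layers)`, so the root carries the maximal layer `L`.
#'
#' @param tree a normalized, optionally unified [bel_tree()].
#' @return list with `layer` (integer vector over preorder node positions)
#'   and `L` (the root layer).
#' @export
assign_layers <- function(tree) {
  nodes <- bel_preorder(tree)
  n <- length(nodes)
  layer <- integer(n)
  # preorder: children of node i occupy a contiguous block after i; compute
  # sizes to find them, then layers bottom-up by recursion
  size <- function(node) 1L + sum(vapply(node$children, size, 0L))
  idx <- 0L
  walk <- function(node) {
    idx <<- idx + 1L
    me <- idx
    if (!length(node$children)) {
      layer[me] <<- 1L
      return(1L)
    }
    kids <- vapply(node$children, walk, 0L)
    layer[me] <<- 1L + max(kids)
    layer[me]
  }
  walk(if (inherits(tree, "bel_tree")) tree$root else tree)
  list(layer = layer, L = max(layer))
}

#' Generate layered BIESO tags for one training instance
#'
#' Bottom-up labeling: each tree node's token span is computed from the word
#' alignment (entities and parameters from their own links; functions and
#' relations from their links plus all descendant tokens) and written as a
#' `B/I/E` block (or `S`) at the node's layer, labeled with the node label.
#' Tokens outside every span are `O`.
#'
#' @param tokens character vector of (simplified) sentence tokens.
#' @param tree the unified, normalized [bel_tree()] whose serialization the
#'   alignment targets.
#' @param alignment link tibble with `source` (token index) and `target`
#'   (preorder node index, i.e. position in [serialize_tree()]'s output).
#' @param strict reject the instance when a function/relation node has no
#'   aligned word of its own (default `TRUE`, the training-corpus behavior);
#'   with `FALSE` such spans are recovered from the descendants alone.
#' @return object of class `layered_tags`: list with `tokens` and `layers`
#'   (list of per-layer character tag vectors, layer 1 first).
#' @export
generate_tags <- function(tokens, tree, alignment, strict = TRUE) {
  nodes <- bel_preorder(tree)
  la <- assign_layers(tree)
  n_tok <- length(tokens)
  reject <- function(msg) abort(msg, class = "belhier_untaggable")
  own <- lapply(seq_along(nodes), function(i)
    sort(alignment$source[alignment$target == i]))
  # spans bottom-up over preorder positions: compute child blocks
  spans <- matrix(NA_integer_, nrow = length(nodes), ncol = 2L)
  idx <- 0L
  walk <- function(node) {
    idx <<- idx + 1L
    me <- idx
    kid_rows <- vapply(node$children, walk, 0L)
    words <- own[[me]]
    if (!length(node$children)) {
      if (!length(words)) {
        reject(sprintf("leaf node '%s' has no aligned token", node$label))
      }
      spans[me, ] <<- range(words)
      return(me)
    }
    if (strict && !length(words)) {
      reject(sprintf("node '%s' has no aligned word", node$label))
    }
    lo <- min(c(words, spans[kid_rows, 1]))
    hi <- max(c(words, spans[kid_rows, 2]))
    spans[me, ] <<- c(lo, hi)
    me
  }
  walk(if (inherits(tree, "bel_tree")) tree$root else tree)
  if (any(spans < 1L | spans > n_tok)) reject("alignment index outside token range")
  # same-layer spans must not overlap
  L <- la$L
  for (k in seq_len(L)) {
    sp <- spans[la$layer == k, , drop = FALSE]
    if (nrow(sp) > 1L) {
      o <- order(sp[, 1])
      sp <- sp[o, , drop = FALSE]
      if (any(sp[-1, 1] <= sp[-nrow(sp), 2])) {
        reject(sprintf("overlapping spans at layer %d", k))
      }
    }
  }
  layers <- replicate(L, rep("O", n_tok), simplify = FALSE)
  for (i in seq_along(nodes)) {
    node <- nodes[[i]]
    k <- la$layer[i]
    s <- spans[i, 1]; e <- spans[i, 2]
    lab <- switch(node$kind,
                  entity = entity_type(node$label),
                  parameter = param_class(node$label),
                  node$label)
    if (s == e) {
      layers[[k]][s] <- paste0("S-", lab)
    } else {
      layers[[k]][s] <- paste0("B-", lab)
      layers[[k]][e] <- paste0("E-", lab)
      layers[[k]][(s + 1L):(e - 1L)] <- paste0("I-", lab)
    }
  }
  structure(list(tokens = tokens, layers = layers), class = "layered_tags")
}

#' @export
print.layered_tags <- function(x, ...) {
  cat("<layered_tags>", length(x$layers), "layer(s) over",
      length(x$tokens), "tokens\n")
  w <- max(nchar(c(x$tokens, unlist(x$layers))))
  fmt <- function(v) paste(formatC(v, width = w), collapse = " ")
  cat(" ", fmt(x$tokens), "\n")
  for (k in seq_along(x$layers)) cat(k, fmt(x$layers[[k]]), "\n")
  invisible(x)
}

#' Extract spans from a BIESO tag sequence, repairing violations
#'
#' Standard deterministic decoding repair: an `I`/`E` without a matching open
#' block opens one (treated as `B`), an unterminated block closes at its last
#' contiguous token, and a label change closes the open block.
#'
#' @param tags character vector of BIESO tags (`"O"` or `prefix-label`).
#' @return tibble with columns `start`, `end`, `label`.
#' @export
bieso_spans <- function(tags) {
  out <- list()
  open_lab <- NULL; open_at <- NA_integer_
  close <- function(end) {
    if (!is.null(open_lab)) {
      out[[length(out) + 1L]] <<- c(open_at, end, open_lab)
    }
    open_lab <<- NULL
  }
  for (i in seq_along(tags)) {
    tg <- tags[i]
    if (tg == "O") { close(i - 1L); next }
    pre <- sub("-.*$", "", tg)
    lab <- sub("^[A-Z]+-", "", tg)
    if (pre == "S") { close(i - 1L); out[[length(out) + 1L]] <- c(i, i, lab) }
    else if (pre == "B") { close(i - 1L); open_lab <- lab; open_at <- i }
    else if (pre == "I") {
      if (is.null(open_lab) || open_lab != lab) { close(i - 1L); open_lab <- lab; open_at <- i }
    } else if (pre == "E") {
      if (!is.null(open_lab) && open_lab == lab) close(i)
      else { close(i - 1L); out[[length(out) + 1L]] <- c(i, i, lab) }
    }
  }
  close(length(tags))
  if (!length(out)) return(tibble(start = integer(0), end = integer(0),
                                  label = character(0)))
  m <- do.call(rbind, out)
  tibble(start = as.integer(m[, 1]), end = as.integer(m[, 2]), label = m[, 3])
}

#' Reconstruct a BEL tree from layered tags
#'
#' Top-down inverse of [generate_tags()]: spans are extracted per layer with
#' BIESO repair; each layer-k span becomes an internal node adopting, in
#' left-to-right order, every not-yet-claimed lower span nested within its
#' interval.  The span surviving at the highest layer becomes the root.
#' Lower spans covered by no higher span are dropped with a warning; all-`O`
#' tags yield `NULL` (no statement).
#'
#' @param tags a [layered_tags][generate_tags()] object (predicted layers are
#'   repaired automatically).
#' @param quiet suppress orphan warnings.
#' @return a [bel_tree()] with placeholder entity leaves, or `NULL`.
#' @export
tags_to_tree <- function(tags, quiet = FALSE) {
  tokens <- tags$tokens
  L <- length(tags$layers)
  items <- list()  # each: list(start, end, node, layer)
  sp1 <- bieso_spans(tags$layers[[1]])
  for (r in seq_len(nrow(sp1))) {
    lab <- sp1$label[r]; s <- sp1$start[r]
    node <- if (lab %in% c("GENE", "CHEM", "BP", "DIS")) {
      bel_node("entity", tokens[s])
    } else {
      tok <- tokens[s]
      val <- if (lab == "NUM") tok
             else if (lab == "P") "P"  # modification-type class is the value
             else if (tok %in% names(.aa3to1)) .aa3to1[[tok]]
             else tok
      bel_node("parameter", val)
    }
    items[[length(items) + 1L]] <- list(start = sp1$start[r], end = sp1$end[r],
                                        node = node, layer = 1L)
  }
  if (L >= 2L) for (k in 2:L) {
    spk <- bieso_spans(tags$layers[[k]])
    if (!nrow(spk)) next
    for (r in order(spk$start)) {
      s <- spk$start[r]; e <- spk$end[r]; lab <- spk$label[r]
      inside <- which(vapply(items, function(it) it$start >= s && it$end <= e, TRUE))
      kids <- items[inside]
      kids <- kids[order(vapply(kids, `[[`, 0L, "start"))]
      kind <- if (lab %in% .bel_relations) "relation"
              else if (tolower(lab) == "or") "or"
              else "function"
      node <- bel_node(kind, if (kind == "or") "or" else lab,
                       lapply(kids, `[[`, "node"))
      items <- c(items[setdiff(seq_along(items), inside)],
                 list(list(start = s, end = e, node = node, layer = k)))
    }
  }
  if (!length(items)) {
    if (!quiet) warn("no relation/function span found; no statement extracted")
    return(NULL)
  }
  layers_left <- vapply(items, `[[`, 0L, "layer")
  if (max(layers_left) == 1L) {
    if (!quiet) warn("no relation/function span found; no statement extracted")
    return(NULL)
  }
  root_i <- which(layers_left == max(layers_left))[1]
  if (length(items) > 1L && !quiet) {
    warn(sprintf("%d span(s) outside every higher span were dropped",
                 length(items) - 1L))
  }
  root <- items[[root_i]]$node
  if (!root$kind %in% c("relation", "or")) {
    if (!quiet) warn(sprintf("top span '%s' is not a relation; no statement extracted",
                             root$label))
    return(NULL)
  }
  bel_tree(root)
}

#' Write layered-tag instances in CoNLL column format
#'
#' One token per line: surface followed by the layer 1..L tags, blank line
#' between sentences.
#'
#' @param instances list of [layered_tags][generate_tags()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tag_conll <- function(instances, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (inst in instances) {
    for (i in seq_along(inst$tokens)) {
      writeLines(paste(c(inst$tokens[i],
                         vapply(inst$layers, `[`, "", i)), collapse = "\t"), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' @rdname write_tag_conll
#' @export
read_tag_conll <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  out <- list(); cur <- list()
  flush <- function() {
    if (!length(cur)) return()
    m <- do.call(rbind, cur)
    layers <- lapply(2:ncol(m), function(j) m[, j])
    out[[length(out) + 1L]] <<- structure(
      list(tokens = m[, 1], layers = layers), class = "layered_tags")
    cur <<- list()
  }
  for (line in lines) {
    if (!nzchar(trimws(line))) { flush(); next }
    cur[[length(cur) + 1L]] <- strsplit(line, "\t", fixed = TRUE)[[1]]
  }
  flush()
  out
}

#' Pad a layered-tags instance with all-O layers up to L
#'
#' Fixed per-layer models need a consistent layer indexing, so shallower
#' instances gain empty upper layers during training.
#'
#' @param tags a `layered_tags` object.
#' @param L target layer count.
#' @return the padded object.
#' @export
pad_layers <- function(tags, L) {
  while (length(tags$layers) < L) {
    tags$layers[[length(tags$layers) + 1L]] <- rep("O", length(tags$tokens))
  }
  tags
}
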