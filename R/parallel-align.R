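# Parallel corpus construction and statistical word alignment.
#
# The simplified sentence is the source language and the serialized BEL node
# sequence the target language.  Lexical translation probabilities are
# estimated by IBM Model 1 expectation maximization with an optional NULL
# target token that absorbs function words.  Pseudo-parallel single-token
# pairs (GENE_1 -> GENE_1) bias the model towards identity links for entity
# placeholders.

.null_token <- "<NULL>"

#' Build a parallel corpus tibble
#'
#' @param pair_id character vector of pair identifiers.
#' @param source list of character vectors (simplified sentence tokens).
#' @param target list of character vectors (serialized node sequences).
#' @param gold optional list of two-column matrices of gold links
#'   (source index, target index; 1-based), for fixtures.
#' @return tibble with class `parallel_corpus`.
#' @export
parallel_corpus <- function(pair_id, source, target, gold = NULL) {
  stopifnot(length(pair_id) == length(source), length(source) == length(target))
  if (any(!lengths(source)) || any(!lengths(target))) {
    abort("both sides of every parallel pair must be non-empty")
  }
  out <- tibble(pair_id = as.character(pair_id), source = source, target = target)
  out$gold <- if (is.null(gold)) rep(list(NULL), nrow(out)) else gold
  class(out) <- c("parallel_corpus", class(out))
  out
}

#' Filter sentence/statement pairs by grounding completeness
#'
#' Keeps exactly the pairs in which every statement entity received a
#' non-ABSENT mention; the rest are dropped and reported in the `dropped`
#' attribute with the offending entities.
#'
#' @param pairs tibble with a `pair_id` column.
#' @param groundings named list (by `pair_id`) of grounding tibbles from
#'   [ground_statement_entities()].
#' @return the retained rows of `pairs`; dropped pair ids (with reasons) in
#'   `attr(, "dropped")`.
#' @export
filter_pairs <- function(pairs, groundings) {
  keep <- logical(nrow(pairs))
  reasons <- character(0)
  for (i in seq_len(nrow(pairs))) {
    g <- groundings[[pairs$pair_id[i]]]
    if (is.null(g)) {
      reasons[pairs$pair_id[i]] <- "no grounding result"
    } else if (any(g$absent)) {
      reasons[pairs$pair_id[i]] <-
        paste("absent entities:", paste(g$entity[g$absent], collapse = ", "))
    } else {
      keep[i] <- TRUE
    }
  }
  out <- pairs[keep, , drop = FALSE]
  attr(out, "dropped") <- reasons
  out
}

#' Augment a corpus with pseudo-parallel placeholder pairs
#'
#' Appends `copies` single-token pairs `(placeholder, placeholder)` for every
#' placeholder type/index occurring anywhere in the corpus, so the aligner's
#' translation table strongly favors identity links for entities.
#'
#' @param corpus a [parallel_corpus()].
#' @param copies pseudo pairs per distinct placeholder (default 50).
#' @return the augmented corpus.
#' @export
augment_pseudo_pairs <- function(corpus, copies = 50L) {
  if (copies == 0L) return(corpus)
  vocab <- unique(c(unlist(corpus$source), unlist(corpus$target)))
  ph <- sort(vocab[grepl(.placeholder_rx, vocab)])
  if (!length(ph)) return(corpus)
  ids <- as.character(t(outer(ph, seq_len(copies),
                              function(p, k) sprintf("pseudo_%s_%03d", p, k))))
  add <- parallel_corpus(ids,
                         source = as.list(rep(ph, each = copies)),
                         target = as.list(rep(ph, each = copies)))
  out <- dplyr::bind_rows(corpus, add)
  class(out) <- c("parallel_corpus", setdiff(class(out), "parallel_corpus"))
  out
}

#' Train an IBM Model 1 word aligner
#'
#' Expectation maximization for the lexical translation table
#' `t(source word | target node)`: uniform initialization over co-occurring
#' pairs, expected-count E-step over all source/target token pairs within
#' each sentence pair (plus an optional NULL target), count-normalizing
#' M-step.  Deterministic given the corpus: pairs are processed in `pair_id`
#' order and no random numbers are drawn; `seed` is recorded in the table
#' metadata for provenance.
#'
#' @param corpus a [parallel_corpus()].
#' @param iterations number of EM iterations (>= 1).
#' @param seed integer recorded with the model.
#' @param use_null add a NULL target token to every pair (default `TRUE`).
#' @param null_weight alignment prior weight of the NULL target relative to
#'   each real target (equivalent to `null_weight` NULL tokens per pair).
#'   Model 1 has no fertility, so with weight 1 frequent function words tend
#'   to garbage-link to co-occurring content nodes; a moderate extra NULL
#'   weight restores the behavior expected of a full alignment toolchain.
#' @return object of class `translation_table`: tibble `t` with columns
#'   `target`, `source`, `prob`; per-iteration corpus log-likelihood in
#'   `loglik`.
#' @export
train_aligner <- function(corpus, iterations = 10L, seed = 1L, use_null = TRUE,
                          null_weight = 2) {
  if (!nrow(corpus)) abort("cannot train an aligner on an empty corpus")
  stopifnot(iterations >= 1L)
  corpus <- corpus[order(corpus$pair_id), , drop = FALSE]
  # expand events: one row per (pair, source position, candidate target type)
  ev_src <- list(); ev_tgt <- list(); ev_gid <- list(); gid0 <- 0L
  for (i in seq_len(nrow(corpus))) {
    s <- corpus$source[[i]]
    t <- unique(corpus$target[[i]])
    if (use_null) t <- c(t, .null_token)
    ns <- length(s); nt <- length(t)
    ev_src[[i]] <- rep(s, each = nt)
    ev_tgt[[i]] <- rep(t, times = ns)
    ev_gid[[i]] <- rep(gid0 + seq_len(ns), each = nt)
    gid0 <- gid0 + ns
  }
  src <- unlist(ev_src); tgt <- unlist(ev_tgt); gid <- unlist(ev_gid)
  key <- paste(tgt, src, sep = "\r")
  ukey <- unique(key)
  ki <- match(key, ukey)
  utgt <- sub("\r.*$", "", ukey)
  usrc <- sub("^[^\r]*\r", "", ukey)
  tgt_row <- match(utgt, unique(utgt))
  # uniform init over each target's co-occurring sources
  row_size <- tabulate(tgt_row)
  tv <- 1 / row_size[tgt_row]
  wev <- ifelse(tgt == .null_token, null_weight, 1)  # NULL alignment prior
  loglik <- numeric(iterations)
  # unique (gid, ki): a source token repeated in one target list is already
  # deduplicated via unique(target); repeated source tokens keep separate gids
  for (it in seq_len(iterations)) {
    p <- wev * tv[ki]
    denom <- rowsum(p, gid)
    loglik[it] <- sum(log(denom))
    pn <- p / denom[gid]
    counts <- rowsum(pn, ki)
    cvec <- numeric(length(ukey))
    cvec[as.integer(rownames(counts))] <- counts[, 1]
    totals <- rowsum(cvec, tgt_row)
    tv <- cvec / totals[tgt_row]
  }
  structure(list(
    t = tibble(target = utgt, source = usrc, prob = tv),
    loglik = loglik, iterations = iterations, seed = seed,
    use_null = use_null, null_weight = null_weight
  ), class = "translation_table")
}

#' @export
print.translation_table <- function(x, ...) {
  cat(sprintf("<translation_table> %d entries, %d targets, %d EM iterations\n",
              nrow(x$t), length(unique(x$t$target)), x$iterations))
  invisible(x)
}

#' Look up translation probabilities
#'
#' @param table a [train_aligner()] result.
#' @param target,source token strings (vectorized, recycled).
#' @return numeric probabilities (0 for unseen pairs).
#' @export
translation_prob <- function(table, target, source) {
  key <- paste(target, source, sep = "\r")
  idx <- match(key, paste(table$t$target, table$t$source, sep = "\r"))
  out <- table$t$prob[idx]
  out[is.na(out)] <- 0
  out
}

#' Extract the word/node alignment of one pair
#'
#' Each source word links to the target node with maximal translation
#' probability within the pair (NULL wins and the word stays unaligned when
#' no target beats the NULL probability); ties break to the leftmost target.
#' Entity placeholder tokens are forced to link to their identical target
#' token whenever one is present.
#'
#' @param source,target character vectors (one pair's two sides).
#' @param table a trained [translation_table][train_aligner()].
#' @return tibble of links with columns `source`, `target` (1-based indices);
#'   unaligned source words simply have no row.
#' @export
extract_alignment <- function(source, target, table) {
  links <- list()
  used_tgt_for <- function(ph) which(target == ph)
  ph_used <- integer(0)
  for (j in seq_along(source)) {
    w <- source[j]
    if (grepl(.placeholder_rx, w) && w %in% target) {
      cand <- setdiff(which(target == w), ph_used)
      i <- if (length(cand)) cand[1] else which(target == w)[1]
      ph_used <- c(ph_used, i)
      links[[length(links) + 1L]] <- c(j, i)
      next
    }
    probs <- translation_prob(table, target, rep(w, length(target)))
    null_p <- if (isTRUE(table$use_null)) {
      (table$null_weight %||% 1) * translation_prob(table, .null_token, w)
    } else 0
    best <- which.max(probs)  # leftmost argmax
    if (length(best) && probs[best] > null_p && probs[best] > 0) {
      links[[length(links) + 1L]] <- c(j, best)
    }
  }
  if (!length(links)) return(tibble(source = integer(0), target = integer(0)))
  m <- do.call(rbind, links)
  tibble(source = as.integer(m[, 1]), target = as.integer(m[, 2]))
}

#' Alignment error rate against gold links
#'
#' All gold links are treated as sure links:
#' `AER = 1 - 2|A n S| / (|A| + |S|)`.
#'
#' @param pred,gold link tibbles/matrices with source and target index
#'   columns.
#' @return a single number in `[0, 1]`.
#' @export
alignment_error_rate <- function(pred, gold) {
  pk <- paste(pred[[1]], pred[[2]], sep = "-")
  gk <- paste(gold[[1]], gold[[2]], sep = "-")
  if (!length(pk) && !length(gk)) return(0)
  1 - 2 * length(intersect(pk, gk)) / (length(pk) + length(gk))
}

#' Read/write Pharaoh alignment files
#'
#' One line per pair of space-separated `i-j` links, 0-based (source index
#' `i`, target index `j`).
#'
#' @param alignments list of link tibbles (1-based, as produced by
#'   [extract_alignment()]).
#' @param path file path.
#' @return `write_pharaoh()` returns `path` invisibly; `read_pharaoh()` a
#'   list of link tibbles (1-based).
#' @export
write_pharaoh <- function(alignments, path) {
  lines <- vapply(alignments, function(a) {
    if (!nrow(a)) return("")
    paste(sprintf("%d-%d", a$source - 1L, a$target - 1L), collapse = " ")
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_pharaoh
#' @export
read_pharaoh <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lapply(lines, function(l) {
    l <- trimws(l)
    if (!nzchar(l)) return(tibble(source = integer(0), target = integer(0)))
    parts <- strsplit(strsplit(l, "\\s+")[[1]], "-", fixed = TRUE)
    tibble(source = vapply(parts, function(p) as.integer(p[1]), 0L) + 1L,
           target = vapply(parts, function(p) as.integer(p[2]), 0L) + 1L)
  })
}
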