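# Multi-level scoring of predicted vs gold BEL statements.
#
# The task's equivalence rules apply to every level's canonical keys:
# increases == directlyIncreases (and the decreases pair), and activity
# functions (cat, kin, tscript, ...) map to the general act().  Matching is
# per sentence: a prediction can only match gold statements of the same
# sentence, and counts are multiset-aware.

.eval_levels <- c("term", "function_secondary", "function",
                  "relation_secondary", "relation", "statement")

# apply the evaluation equivalences to a node tree (copy)
map_eval_node <- function(node) {
  if (node$kind == "relation") {
    node$label <- sub("^directly", "", node$label)
    node$label <- paste0(tolower(substr(node$label, 1, 1)),
                         substr(node$label, 2, nchar(node$label)))
  }
  if (node$kind == "function" && node$label %in% .bel_activities) {
    node$label <- "act"
  }
  node$children <- lapply(node$children, map_eval_node)
  node
}

# canonical rendering of a mapped node in normalized (elevated) form
canon_render <- function(node) {
  switch(node$kind,
    relation = paste(canon_render(node$children[[1]]), node$label,
                     canon_render(node$children[[2]])),
    or = paste0("or(", paste(vapply(node$children, canon_render, ""),
                             collapse = ","), ")"),
    entity = {
      lab <- node$label
      if (grepl(.placeholder_rx, lab)) lab
      else {
        ns <- sub(":.*$", "", lab); id <- sub("^[^:]*:", "", lab)
        paste0(.bel_type_term[[entity_type(lab)]], "(", ns, ":",
               quote_if_needed(id), ")")
      }
    },
    "function" = paste0(node$label, "(",
                        paste(vapply(node$children, canon_render, ""),
                              collapse = ","), ")"),
    parameter = node$label
  )
}

#' Project a statement to a level's evaluation items
#'
#' Returns the multiset of canonical keys of one statement at one level:
#' `term` — entity terms; `function` — each function with its full inner
#' term; `function_secondary` — relaxed function credit, one key per
#' (act-mapped function name, entity in its subtree); `relation_secondary` —
#' relation type with each single argument; `relation` — relation type with
#' both arguments in order; `statement` — the full normalized string.
#'
#' @param statement a [bel_tree()], [bel_node()] or statement string.
#' @param level one of `"term"`, `"function_secondary"`, `"function"`,
#'   `"relation_secondary"`, `"relation"`, `"statement"`.
#' @return character vector of canonical keys (possibly with duplicates).
#' @export
canonicalize <- function(statement, level = .eval_levels) {
  level <- match.arg(level)
  if (is.character(statement)) statement <- normalize_statement(parse_statement(statement))
  node <- if (inherits(statement, "bel_tree")) statement$root else statement
  node <- map_eval_node(normalize_node(node))
  if (node$kind == "or") {
    return(unlist(lapply(node$children, canonicalize, level = level)))
  }
  nodes <- bel_preorder(node)
  switch(level,
    term = vapply(Filter(function(n) n$kind == "entity", nodes), canon_render, ""),
    "function" = vapply(Filter(function(n) n$kind == "function", nodes),
                        canon_render, ""),
    function_secondary = {
      fs <- Filter(function(n) n$kind == "function", nodes)
      unlist(lapply(fs, function(f) {
        ents <- Filter(function(n) n$kind == "entity", bel_preorder(f))
        vapply(ents, function(e) paste0(f$label, "|", canon_render(e)), "")
      }))
    },
    relation_secondary = {
      rels <- Filter(function(n) n$kind == "relation", nodes)
      unlist(lapply(rels, function(r)
        vapply(r$children, function(ch)
          paste0(r$label, "|", canon_render(ch)), "")))
    },
    relation = {
      rels <- Filter(function(n) n$kind == "relation", nodes)
      vapply(rels, function(r)
        paste(r$label, canon_render(r$children[[1]]),
              canon_render(r$children[[2]]), sep = "|"), "")
    },
    statement = canon_render(node)
  )
}

multiset_tp <- function(gold_keys, pred_keys) {
  if (!length(gold_keys) || !length(pred_keys)) return(0L)
  gt <- table(gold_keys); pt <- table(pred_keys)
  common <- intersect(names(gt), names(pt))
  sum(pmin(gt[common], pt[common]))
}

#' Score predicted statements against gold
#'
#' Computes per-level precision, recall and F1 (in percent) with per-sentence
#' multiset matching accumulated corpus-wide.  `F1 = 2PR/(P+R)`, zero when
#' `P + R = 0`; an empty prediction set gives precision 0 by convention.
#'
#' @param gold,pred tibbles with columns `sentence_id` and `statement`
#'   (strings parseable by [parse_statement()]) or `tree` (list of
#'   [bel_tree()]); several rows per sentence are expected when a sentence
#'   has several statements.
#' @param levels evaluation levels to compute (default all six).
#' @return object of class `score_report`: tibble with `level`, `tp`, `fp`,
#'   `fn`, `precision`, `recall`, `f1`.
#' @export
score_statements <- function(gold, pred, levels = .eval_levels) {
  get_trees <- function(df) {
    if ("tree" %in% names(df)) return(df$tree)
    lapply(df$statement, function(s) normalize_statement(parse_statement(s)))
  }
  gt <- get_trees(gold); pt <- get_trees(pred)
  gid <- as.character(gold$sentence_id); pid <- as.character(pred$sentence_id)
  sent <- union(gid, pid)
  rows <- lapply(levels, function(lv) {
    tp <- 0L; n_gold <- 0L; n_pred <- 0L
    for (s in sent) {
      gk <- unlist(lapply(gt[gid == s], canonicalize, level = lv))
      pk <- unlist(lapply(pt[pid == s], canonicalize, level = lv))
      gk <- gk %||% character(0); pk <- pk %||% character(0)
      tp <- tp + multiset_tp(gk, pk)
      n_gold <- n_gold + length(gk); n_pred <- n_pred + length(pk)
    }
    p <- if (n_pred > 0L) 100 * tp / n_pred else 0
    r <- if (n_gold > 0L) 100 * tp / n_gold else 0
    f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
    tibble(level = lv, tp = as.integer(tp), fp = n_pred - as.integer(tp),
           fn = n_gold - as.integer(tp), precision = p, recall = r, f1 = f1)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("score_report", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.score_report <- function(x, ...) {
  cat("BEL statement extraction scores\n")
  cat(sprintf("%-20s %6s %6s %6s %7s %7s %7s\n",
              "Level", "TP", "FP", "FN", "P(%)", "R(%)", "F1(%)"))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("%-20s %6d %6d %6d %7.1f %7.1f %7.1f\n",
                x$level[i], x$tp[i], x$fp[i], x$fn[i],
                x$precision[i], x$recall[i], x$f1[i]))
  }
  invisible(x)
}

#' @export
tidy.score_report <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "score_report")
  out
}

#' @export
glance.score_report <- function(x, ...) {
  st <- x[x$level == "statement", ]
  tibble(statement_precision = st$precision, statement_recall = st$recall,
         statement_f1 = st$f1)
}

#' Plot a score report
#'
#' Grouped bars of precision, recall and F1 per evaluation level.
#'
#' @param object a [score_statements()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @importFrom ggplot2 autoplot ggplot aes geom_col facet_wrap labs
#' @export
autoplot.score_report <- function(object, ...) {
  df <- tidyr_pivot(object)
  ggplot(df, aes(x = .data$level, y = .data$value, fill = .data$metric)) +
    geom_col(position = "dodge") +
    labs(x = "evaluation level", y = "percent", fill = NULL,
         title = "BEL extraction performance by level")
}

# small local pivot (avoids importing tidyr for one call)
tidyr_pivot <- function(x) {
  dplyr::bind_rows(lapply(c("precision", "recall", "f1"), function(m)
    tibble(level = factor(x$level, levels = x$level), metric = m,
           value = x[[m]])))
}

#' Write a score report as TSV
#'
#' @param report a [score_statements()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_score_report <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
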