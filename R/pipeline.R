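# End-to-end glue: train the aligner and the stacked labelers from a corpus
# of (simplified sentence, unified tree) pairs, and extract statements from
# new sentences.

#' Train the full extraction pipeline on a synthetic corpus
#'
#' Builds the parallel corpus, augments it with pseudo-parallel placeholder
#' pairs, trains the IBM Model 1 aligner, extracts word/node alignments,
#' generates layered training tags (instances whose trees cannot be fully
#' aligned are dropped, mirroring the attrition of real corpora) and trains
#' the stacked CRFs.
#'
#' @param corpus a [generate_corpus()] result.
#' @param copies pseudo pairs per placeholder (see [augment_pseudo_pairs()]).
#' @param iterations EM iterations for [train_aligner()].
#' @param seed integer recorded with the models.
#' @param L layer count for [train_hier()] (default: deepest instance).
#' @param c2,maxit CRF hyperparameters.
#' @return list with `model` ([train_hier()] result), `table`
#'   (translation table), `instances`, `n_dropped`.
#' @export
pipeline_train <- function(corpus, copies = 50L, iterations = 10L, seed = 1L,
                           L = NULL, c2 = 1.0, maxit = 150L) {
  pc <- synth_parallel_corpus(corpus)
  table <- train_aligner(augment_pseudo_pairs(pc, copies),
                         iterations = iterations, seed = seed)
  instances <- list(); dropped <- 0L
  for (i in seq_len(nrow(corpus))) {
    al <- extract_alignment(corpus$simplified[[i]], corpus$node_seq[[i]], table)
    inst <- tryCatch(
      generate_tags(corpus$simplified[[i]], corpus$unified[[i]], al),
      belhier_untaggable = function(e) NULL)
    if (is.null(inst)) dropped <- dropped + 1L
    else instances[[length(instances) + 1L]] <- inst
  }
  if (!length(instances)) abort("no alignable training instances")
  model <- train_hier(instances, L = L, c2 = c2, maxit = maxit, seed = seed)
  list(model = model, table = table, instances = instances,
       n_dropped = dropped)
}

#' Extract BEL statements from simplified sentences
#'
#' Predicts layered tags, reconstructs the (possibly unified) tree, splits it
#' and renders each statement with the sentence's entity table.  Sentences
#' from which no well-formed statement can be reconstructed contribute no
#' rows.
#'
#' @param model a [train_hier()] result.
#' @param tokens list of simplified-token character vectors.
#' @param sentence_id character vector of ids (parallel to `tokens`).
#' @param entity_tables list of named placeholder -> `namespace:identifier`
#'   vectors (parallel to `tokens`); `NULL` entries leave placeholders
#'   unresolved.
#' @return tibble with `sentence_id`, `statement`.
#' @export
extract_statements <- function(model, tokens, sentence_id,
                               entity_tables = NULL) {
  rows <- list()
  for (i in seq_along(tokens)) {
    tags <- predict_hier(tokens[[i]], model)
    tree <- tags_to_tree(tags, quiet = TRUE)
    if (is.null(tree)) next
    for (t in split_unified(tree)) {
      stmt <- tryCatch(
        render_statement(t, if (is.null(entity_tables)) NULL else entity_tables[[i]]),
        error = function(e) NULL)
      if (!is.null(stmt)) {
        rows[[length(rows) + 1L]] <- tibble(sentence_id = sentence_id[i],
                                            statement = stmt)
      }
    }
  }
  if (!length(rows)) return(tibble(sentence_id = character(0),
                                   statement = character(0)))
  dplyr::bind_rows(rows)
}

#' Alignment quality of a trained table on a corpus with gold links
#'
#' @param corpus a [generate_corpus()] result.
#' @param table a [train_aligner()] result.
#' @return list with `aer` (alignment error rate over all pairs),
#'   `entity_precision` (fraction of predicted placeholder links that are
#'   gold) and `n_links`.
#' @export
corpus_alignment_quality <- function(corpus, table) {
  n_pred <- 0L; n_gold <- 0L; n_hit <- 0L
  ent_pred <- 0L; ent_hit <- 0L
  for (i in seq_len(nrow(corpus))) {
    src <- corpus$simplified[[i]]
    al <- extract_alignment(src, corpus$node_seq[[i]], table)
    gold <- corpus$gold_alignment[[i]]
    pk <- paste(al$source, al$target, sep = "-")
    gk <- paste(gold$source, gold$target, sep = "-")
    n_pred <- n_pred + length(pk); n_gold <- n_gold + length(gk)
    n_hit <- n_hit + length(intersect(pk, gk))
    is_ph <- grepl(.placeholder_rx, src[al$source])
    ent_pred <- ent_pred + sum(is_ph)
    ent_hit <- ent_hit + sum(pk[is_ph] %in% gk)
  }
  list(aer = 1 - 2 * n_hit / (n_pred + n_gold),
       entity_precision = if (ent_pred) ent_hit / ent_pred else NA_real_,
       n_links = n_pred)
}
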