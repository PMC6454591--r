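# Seeded generator of sentence/statement pairs with gold trees, gold
# alignments, dependency parses and gold layered tags.
#
# Sentences are built from a small template grammar shaped like the task's
# worked examples: "<subject phrase> <relation trigger> <function trigger>
# of <entity> to <entity>", with optional coordinated second clauses,
# off-path distractor modifiers (removable by dependency simplification) and
# on-path function words (left unaligned by the gold alignment, as in real
# pairs).  Trigger lexicons reuse the motifs of the printed examples
# ("prevented" -> decreases, "association" -> complex, "elevated" ->
# increases), so fixtures read like the corpus they emulate.  The generator
# emulates the statistical structure of those pairs, not realistic
# biomedical language: sentence lengths, vocabulary size and ambiguity are
# all far below corpus scale.

.synth_fillers <- c("markedly", "significantly", "strongly", "rapidly",
                    "partially", "notably")
.synth_wrappers <- list(c("Preincubation", "with"), c("Treatment", "with"),
                        c("Exposure", "to"))

#' Synthetic corpus configuration
#'
#' @param n_pairs number of sentence/statement pairs.
#' @param seed integer seed; the seed fully determines the corpus.
#' @param n_genes,n_chems,n_bps,n_dis entity vocabulary sizes per type.
#' @param rel_triggers named list relation -> trigger words.
#' @param fn_triggers named list function -> trigger words (`complex` is
#'   binary, `cat` and `deg` unary).
#' @param p_function probability that a statement includes a function layer.
#' @param p_or probability of a two-statement (coordinated) sentence.
#' @param p_distractor probability of each off-path filler modifier slot
#'   being filled.
#' @param p_noise probability that a trigger word is corrupted (replaced by
#'   a filler word), emulating trigger/statement mismatch.
#' @param p_wrapper probability of an on-path unaligned subject phrase
#'   ("Preincubation with ...").
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(n_pairs = 100L, seed = 1L,
                         n_genes = 30L, n_chems = 12L, n_bps = 8L, n_dis = 4L,
                         rel_triggers = list(
                           increases = c("elevated", "induced", "enhanced", "upregulated"),
                           decreases = c("prevented", "inhibited", "reduced", "suppressed"),
                           directlyIncreases = c("activated"),
                           directlyDecreases = c("blocked")),
                         fn_triggers = list(
                           complex = c("association", "binding", "interaction"),
                           cat = c("catalysis", "activity"),
                           deg = c("degradation")),
                         p_function = 0.5, p_or = 0.1, p_distractor = 0.3,
                         p_noise = 0.05, p_wrapper = 0.3) {
  probs <- c(p_function, p_or, p_distractor, p_noise, p_wrapper)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (n_genes < 4L || n_chems < 1L || n_bps < 1L || n_dis < 1L) {
    abort("entity vocabularies are too small (need >= 4 genes and >= 1 of each other type)")
  }
  structure(list(n_pairs = as.integer(n_pairs), seed = as.integer(seed),
                 n_genes = n_genes, n_chems = n_chems, n_bps = n_bps,
                 n_dis = n_dis, rel_triggers = rel_triggers,
                 fn_triggers = fn_triggers, p_function = p_function,
                 p_or = p_or, p_distractor = p_distractor,
                 p_noise = p_noise, p_wrapper = p_wrapper),
            class = "synth_config")
}

#' Low-noise study configuration
#'
#' The configuration used for parameter-recovery runs: single-statement
#' sentences (3 layers at most), moderate distractor rate, 2% trigger
#' corruption.
#'
#' @param n_pairs,seed see [synth_config()].
#' @return a `synth_config`.
#' @export
synth_config_low_noise <- function(n_pairs, seed) {
  synth_config(n_pairs = n_pairs, seed = seed,
               p_function = 0.5, p_or = 0, p_distractor = 0.3,
               p_noise = 0.02, p_wrapper = 0.3)
}

# entity pools: surface name doubles as identifier suffix
synth_entity_pool <- function(config) {
  list(
    GENE = tibble(type = "GENE", ns = "HGNC",
                  id = sprintf("SG%d", seq_len(config$n_genes)),
                  surface = sprintf("SG%d", seq_len(config$n_genes))),
    CHEM = tibble(type = "CHEM", ns = "CHEBI",
                  id = sprintf("SC%d", seq_len(config$n_chems)),
                  surface = sprintf("SC%d", seq_len(config$n_chems))),
    BP = tibble(type = "BP", ns = "GOBP",
                id = sprintf("SB%d", seq_len(config$n_bps)),
                surface = sprintf("SB%d", seq_len(config$n_bps))),
    DIS = tibble(type = "DIS", ns = "MESHD",
                 id = sprintf("SD%d", seq_len(config$n_dis)),
                 surface = sprintf("SD%d", seq_len(config$n_dis)))
  )
}

#' Entity dictionary for a synthetic configuration
#'
#' One symbol row plus one lowercase synonym row per entity, in the
#' dictionary TSV schema used by [ground_statement_entities()].
#'
#' @param config a [synth_config()].
#' @return tibble with `namespace`, `identifier`, `name`.
#' @export
synth_dictionary <- function(config) {
  pool <- dplyr::bind_rows(synth_entity_pool(config))
  dplyr::bind_rows(
    tibble(namespace = pool$ns, identifier = pool$id, name = pool$surface),
    tibble(namespace = pool$ns, identifier = pool$id, name = tolower(pool$surface))
  )
}

# one generated pair; returns NULL never (every pair is complete by
# construction)
synth_pair <- function(config, pool, pair_id) {
  cfg <- config
  tok <- list()   # each: list(word, key, head, node)
  add <- function(word, key, head, node = NA_character_) {
    tok[[length(tok) + 1L]] <<- list(word = word, key = key, head = head,
                                     node = node)
  }
  maybe_corrupt <- function(word) {
    if (stats::runif(1) < cfg$p_noise) sample(.synth_fillers, 1L) else word
  }
  used <- character(0)
  draw_entity <- function(types, weights) {
    repeat {
      ty <- sample(types, 1L, prob = weights)
      row <- pool[[ty]][sample(nrow(pool[[ty]]), 1L), ]
      key <- paste0(row$ns, ":", row$id)
      if (!key %in% used) { used <<- c(used, key); return(row) }
    }
  }
  # clause builder; returns the statement description for tree building
  clause <- function(cid, parent_key) {
    rel <- sample(names(cfg$rel_triggers), 1L,
                  prob = c(0.4, 0.4, 0.1, 0.1))
    rtrig <- maybe_corrupt(sample(cfg$rel_triggers[[rel]], 1L))
    shape <- if (stats::runif(1) < cfg$p_function) {
      sample(c("B", "C"), 1L)
    } else "A"
    k <- function(x) paste0(cid, x)
    wrap <- shape %in% c("A", "B") && stats::runif(1) < cfg$p_wrapper
    subj <- draw_entity(c("GENE", "CHEM"), c(0.6, 0.4))
    if (wrap) {
      w <- .synth_wrappers[[sample(length(.synth_wrappers), 1L)]]
      add(w[1], k("w1"), parent_key)      # replaced below: head must be trigger
      add(w[2], k("w2"), k("w1"))
    }
    subj_head <- if (wrap) k("w2") else k("tr")
    if (shape == "C") {
      fn <- sample(c("cat", "deg"), 1L)
      ftrig <- maybe_corrupt(sample(cfg$fn_triggers[[fn]], 1L))
      add(ftrig, k("ft"), k("tr"), node = k("FN"))
      add("of", k("of"), k("ft"))
      add(subj$surface, k("s"), k("of"), node = k("S"))
    } else {
      if (stats::runif(1) < cfg$p_distractor) {
        add(sample(.synth_fillers, 1L), k("d1"), k("s"))
      }
      add(subj$surface, k("s"), subj_head, node = k("S"))
    }
    if (stats::runif(1) < cfg$p_distractor) {
      add(sample(.synth_fillers, 1L), k("d2"), k("tr"))
    }
    add(rtrig, k("tr"), parent_key, node = k("REL"))
    objs <- list()
    if (shape == "B") {
      fn <- "complex"
      ftrig <- maybe_corrupt(sample(cfg$fn_triggers$complex, 1L))
      add(ftrig, k("ft"), k("tr"), node = k("FN"))
      add("of", k("of"), k("ft"))
      o1 <- draw_entity("GENE", 1)
      o2 <- draw_entity("GENE", 1)
      add(o1$surface, k("o1"), k("of"), node = k("O1"))
      # connector between the two complex arguments varies, as prepositions
      # do in real text
      add(sample(c("to", "with", "and"), 1L), k("to"), k("o1"))
      add(o2$surface, k("o2"), k("to"), node = k("O2"))
      objs <- list(o1, o2)
    } else {
      obj <- draw_entity(c("GENE", "BP", "DIS"), c(0.6, 0.3, 0.1))
      if (stats::runif(1) < cfg$p_distractor) {
        add(sample(.synth_fillers, 1L), k("d3"), k("o"))
      }
      add(obj$surface, k("o"), k("tr"), node = k("O"))
      objs <- list(obj)
    }
    list(cid = cid, shape = shape, rel = rel,
         fn = if (shape == "A") NA_character_ else fn,
         subj = subj, objs = objs)
  }
  # wrapper head fix: w1 hangs off the clause trigger (nsubj chain)
  two <- stats::runif(1) < cfg$p_or
  c1 <- clause("c1_", "ROOT")
  clauses <- list(c1)
  if (two) {
    add("and", "and", "c1_tr", node = "ORNODE")
    c2 <- clause("c2_", "and")
    clauses <- c(clauses, list(c2))
  }
  words <- vapply(tok, `[[`, "", "word")
  keys <- vapply(tok, `[[`, "", "key")
  heads_key <- vapply(tok, `[[`, "", "head")
  node_keys_tok <- vapply(tok, `[[`, "", "node")
  # wrapper tokens were added with the clause parent as head; re-point w1 at
  # the clause trigger so the wrapper sits on the subject path
  for (cl in clauses) {
    w1 <- paste0(cl$cid, "w1")
    if (w1 %in% keys) heads_key[keys == w1] <- paste0(cl$cid, "tr")
  }
  heads <- ifelse(heads_key == "ROOT", 0L, match(heads_key, keys))
  dep <- dep_tree(as.integer(heads))

  raw_text <- paste(words, collapse = " ")
  ent_idx <- which(grepl("_(s|o|o1|o2)$", keys) & !is.na(node_keys_tok))
  ent_rows <- list()
  for (cl in clauses) {
    ents <- c(list(cl$subj), cl$objs)
    slot <- c("S", if (length(cl$objs) == 2L) c("O1", "O2") else "O")
    for (i in seq_along(ents)) {
      key <- paste0(cl$cid, tolower(slot[i]))
      pos <- which(keys == key)
      ent_rows[[length(ent_rows) + 1L]] <-
        tibble(token_start = pos, token_end = pos, type = ents[[i]]$type,
               entity = paste0(ents[[i]]$ns, ":", ents[[i]]$id))
    }
  }
  mentions <- dplyr::arrange(dplyr::bind_rows(ent_rows), .data$token_start)
  sent <- anonymize(annotated_sentence(pair_id, raw_text,
                                       tokens = tokenize(raw_text),
                                       mentions = mentions))
  ph_of <- stats::setNames(sent$mentions$placeholder, sent$mentions$entity)
  entity_table <- stats::setNames(sent$mentions$entity, sent$mentions$placeholder)

  # statement trees with placeholder leaves
  build_tree <- function(cl) {
    leaf <- function(e) bel_node("entity", ph_of[[paste0(e$ns, ":", e$id)]])
    subj_node <- leaf(cl$subj)
    if (cl$shape == "C") subj_node <- bel_node("function", cl$fn, list(subj_node))
    obj_node <- if (cl$shape == "B") {
      bel_node("function", "complex", lapply(cl$objs, leaf))
    } else leaf(cl$objs[[1]])
    bel_tree(bel_node("relation", cl$rel, list(subj_node, obj_node)))
  }
  trees <- lapply(clauses, build_tree)
  unified <- unify_trees(trees)
  # preorder node keys of the unified tree
  clause_node_keys <- function(cl) {
    paste0(cl$cid, switch(cl$shape,
      A = c("REL", "S", "O"),
      B = c("REL", "S", "FN", "O1", "O2"),
      C = c("REL", "FN", "S", "O")))
  }
  preorder_keys <- if (two) {
    c("ORNODE", clause_node_keys(clauses[[1]]), clause_node_keys(clauses[[2]]))
  } else clause_node_keys(clauses[[1]])
  node_seq <- serialize_tree(unified,
                             stats::setNames(names(entity_table), names(entity_table)))
  stopifnot(length(node_seq) == length(preorder_keys))

  simp <- simplify_sentence(sent, dep)
  gold_links <- list()
  for (j in seq_len(nrow(simp))) {
    nk <- node_keys_tok[simp$index[j]]
    if (!is.na(nk)) {
      gold_links[[length(gold_links) + 1L]] <-
        c(j, match(nk, preorder_keys))
    }
  }
  m <- do.call(rbind, gold_links)
  gold_alignment <- tibble(source = as.integer(m[, 1]), target = as.integer(m[, 2]))
  gold_tags <- generate_tags(simp$surface, unified, gold_alignment)

  list(pair_id = pair_id, sentence = sent, dep = dep, trees = trees,
       unified = unified, node_seq = as.character(node_seq),
       simplified = simp$surface, gold_alignment = gold_alignment,
       gold_tags = gold_tags, entity_table = entity_table,
       has_function = any(!is.na(vapply(clauses, `[[`, "", "fn"))),
       n_statements = length(clauses))
}

#' Generate a synthetic sentence/statement corpus
#'
#' Fully seeded: the same configuration produces byte-identical corpora.
#' Every generated pair is complete (all entities present in the sentence,
#' every function/relation node covered by exactly one gold alignment link),
#' so every pair passes [filter_pairs()] by construction.
#'
#' @param config a [synth_config()].
#' @return a tibble of class `synth_corpus`, one row per pair, with list
#'   columns `sentence` ([annotated_sentence()], anonymized), `dep`
#'   ([dep_tree()]), `trees` (gold [bel_tree()] list), `unified`, `node_seq`,
#'   `simplified` (tokens), `gold_alignment`, `gold_tags`, `entity_table`,
#'   and plain columns `pair_id`, `has_function`, `n_statements`.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  pool <- synth_entity_pool(config)
  pairs <- lapply(seq_len(config$n_pairs), function(i)
    synth_pair(config, pool, sprintf("synth_%05d", i)))
  out <- tibble(
    pair_id = vapply(pairs, `[[`, "", "pair_id"),
    sentence = lapply(pairs, `[[`, "sentence"),
    dep = lapply(pairs, `[[`, "dep"),
    trees = lapply(pairs, `[[`, "trees"),
    unified = lapply(pairs, `[[`, "unified"),
    node_seq = lapply(pairs, `[[`, "node_seq"),
    simplified = lapply(pairs, `[[`, "simplified"),
    gold_alignment = lapply(pairs, `[[`, "gold_alignment"),
    gold_tags = lapply(pairs, `[[`, "gold_tags"),
    entity_table = lapply(pairs, `[[`, "entity_table"),
    has_function = vapply(pairs, `[[`, TRUE, "has_function"),
    n_statements = vapply(pairs, `[[`, 0L, "n_statements")
  )
  class(out) <- c("synth_corpus", class(out))
  out
}

#' Parallel corpus of a synthetic corpus
#'
#' Simplified sentences as source, serialized node sequences as target, gold
#' links attached for evaluation.
#'
#' @param corpus a [generate_corpus()] result.
#' @return a [parallel_corpus()].
#' @export
synth_parallel_corpus <- function(corpus) {
  parallel_corpus(corpus$pair_id, corpus$simplified, corpus$node_seq,
                  gold = corpus$gold_alignment)
}

#' Gold statements of a synthetic corpus
#'
#' Renders every gold tree with its sentence's entity table.
#'
#' @param corpus a [generate_corpus()] result.
#' @return tibble with `sentence_id`, `statement`.
#' @export
synth_gold_statements <- function(corpus) {
  rows <- list(tibble(sentence_id = character(0), statement = character(0)))
  for (i in seq_len(nrow(corpus))) {
    for (t in corpus$trees[[i]]) {
      rows[[length(rows) + 1L]] <- tibble(
        sentence_id = corpus$pair_id[i],
        statement = render_statement(t, corpus$entity_table[[i]]))
    }
  }
  dplyr::bind_rows(rows)
}

#' Write a synthetic corpus as a fixture bundle
#'
#' Emits plain-text files: `statements.tsv` (sentence_id, rendered BEL
#' statement), `sentences.tsv` (sentence_id, anonymized sentence text),
#' `parses.conllu`, `alignments.pharaoh` (gold links over
#' simplified/serialized pairs), `tags.conll` (gold layered tags) and
#' `parallel.tsv` (pair_id, simplified tokens, node sequence).
#'
#' @param corpus a [generate_corpus()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixture_bundle <- function(corpus, dir) {
  ok <- dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) abort(sprintf("cannot create directory '%s'", dir))
  write_bel_pairs(synth_gold_statements(corpus), file.path(dir, "statements.tsv"))
  writeLines(vapply(seq_len(nrow(corpus)), function(i)
    paste(corpus$pair_id[i],
          paste(corpus$sentence[[i]]$tokens$surface, collapse = " "),
          sep = "\t"), ""),
    file.path(dir, "sentences.tsv"), useBytes = TRUE)
  write_conllu(lapply(seq_len(nrow(corpus)), function(i)
    list(sentence_id = corpus$pair_id[i],
         forms = corpus$sentence[[i]]$tokens$surface,
         tree = corpus$dep[[i]])),
    file.path(dir, "parses.conllu"))
  write_pharaoh(corpus$gold_alignment, file.path(dir, "alignments.pharaoh"))
  write_tag_conll(corpus$gold_tags, file.path(dir, "tags.conll"))
  writeLines(vapply(seq_len(nrow(corpus)), function(i)
    paste(corpus$pair_id[i],
          paste(corpus$simplified[[i]], collapse = " "),
          paste(corpus$node_seq[[i]], collapse = " "), sep = "\t"), ""),
    file.path(dir, "parallel.tsv"), useBytes = TRUE)
  invisible(dir)
}
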