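# Grounding statement entities in the sentence.
#
# The corpus gives only entity identifiers, not their text positions, so each
# statement entity must be located in the sentence.  Three cascaded passes
# maximize entity recall: (1) an NER hook consuming precomputed mention files
# from external recognizers, (2) identifier renormalization into the task
# namespaces, (3) dictionary search by normalized edit distance for whatever
# is still unaligned.  An entity that cannot be located is ABSENT, which
# later causes the sentence/statement pair to be filtered out.

#' Read an entity dictionary
#'
#' Tab-separated file with one name per row:
#' `namespace<TAB>identifier<TAB>name` (symbol and synonyms each on their own
#' row).
#'
#' @param path TSV path.
#' @return tibble with columns `namespace`, `identifier`, `name`.
#' @export
read_entity_dictionary <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE,
                          col.names = c("namespace", "identifier", "name"))
  as_tibble(df)
}

#' Renormalize an externally recognized identifier
#'
#' Gene/protein identifiers are consistent across Entrez, HGNC and MGI, so
#' they pass through unchanged.  Chemical identifiers are converted to CHEBI
#' through a user-supplied name table; a chemical without a CHEBI mapping is
#' discarded.  Disease identifiers linked to OMIM are discarded (no feasible
#' conversion to MESH); MESH diseases pass through.
#'
#' @param identifier identifier string from the NER hook.
#' @param source_db database tag, e.g. `"Entrez"`, `"HGNC"`, `"MGI"`,
#'   `"MESH"`, `"CHEBI"`, `"OMIM"`.
#' @param entity_type `"GENE"`, `"CHEM"` or `"DIS"`.
#' @param chebi_map named character vector: normalized chemical name ->
#'   CHEBI identifier.
#' @param name normalized chemical name used for the CHEBI lookup.
#' @return list with fields `identifier` (`NA` when discarded), `discarded`
#'   and `reason`.
#' @export
renormalize_identifier <- function(identifier, source_db, entity_type,
                                   chebi_map = NULL, name = NULL) {
  ok <- function(id) list(identifier = id, discarded = FALSE, reason = NA_character_)
  drop <- function(why) list(identifier = NA_character_, discarded = TRUE, reason = why)
  if (entity_type == "GENE") return(ok(identifier))
  if (entity_type == "DIS") {
    if (toupper(source_db) == "OMIM") return(drop("OMIM disease identifiers cannot be converted to MESH"))
    return(ok(identifier))
  }
  if (entity_type == "CHEM") {
    if (toupper(source_db) == "CHEBI") return(ok(identifier))
    key <- tolower(if (is.null(name)) identifier else name)
    hit <- unname(chebi_map[key])
    if (length(hit) != 1L || is.na(hit)) return(drop("no CHEBI mapping for chemical name"))
    return(ok(hit))
  }
  ok(identifier)
}

#' Find the best dictionary match in a token sequence
#'
#' Scans every contiguous window of at most `max_span` tokens and returns the
#' window whose concatenated text minimizes the normalized Levenshtein
#' distance to any of the entry's names (case-insensitive; distance divided
#' by the longer string length).  Ties are broken by smaller distance, then
#' longer window, then leftmost position.  Returns `NULL` (ABSENT) when no
#' window is within `threshold`.
#'
#' @param tokens character vector of token surfaces.
#' @param names character vector of entry names (symbol + synonyms).
#' @param max_span maximum window length in tokens.
#' @param threshold maximum accepted normalized distance.
#' @return `NULL`, or a list with `start`, `end` (1-based inclusive token
#'   indices) and `distance`.
#' @export
dictionary_search <- function(tokens, names, max_span = 6L, threshold = 0.2) {
  stopifnot(length(names) >= 1L)
  n <- length(tokens)
  if (!n) return(NULL)
  wins <- list()
  for (i in seq_len(n)) {
    for (j in i:min(n, i + max_span - 1L)) {
      wins[[length(wins) + 1L]] <- c(i, j)
    }
  }
  texts <- vapply(wins, function(w)
    paste(tokens[w[1]:w[2]], collapse = " "), "")
  d <- utils::adist(tolower(texts), tolower(names))
  norm <- pmax(nchar(texts), matrix(nchar(names), nrow = length(texts),
                                    ncol = length(names), byrow = TRUE))
  nd <- apply(d / norm, 1L, min)
  lens <- vapply(wins, function(w) w[2] - w[1] + 1L, 0L)
  starts <- vapply(wins, `[`, 0, 1L)
  ord <- order(nd, -lens, starts)
  best <- ord[1]
  if (nd[best] > threshold) return(NULL)
  list(start = wins[[best]][1], end = wins[[best]][2], distance = nd[best])
}

#' Ground every entity of a statement in its sentence
#'
#' Cascades NER-hook mentions (renormalized into the task namespaces) and
#' dictionary search.  Every distinct entity leaf of the statement receives
#' exactly one row; ABSENT entities have `NA` spans and mark the pair for
#' filtering.
#'
#' @param sentence an [annotated_sentence()].
#' @param statement a [bel_tree()] (normalized).
#' @param dictionary tibble from [read_entity_dictionary()].
#' @param ner_mentions optional tibble of precomputed NER-hook mentions for
#'   this sentence: columns `token_start`, `token_end`, `type`, `db`,
#'   `identifier` (see [read_ner_mentions()]).
#' @param chebi_map named chemical-name -> CHEBI table for renormalization.
#' @param max_span,threshold dictionary-search parameters.
#' @return tibble with columns `entity`, `type`, `token_start`, `token_end`,
#'   `method` (`"ner"`/`"dictionary"`/`NA`), `distance`, `absent`.
#' @export
ground_statement_entities <- function(sentence, statement, dictionary,
                                      ner_mentions = NULL, chebi_map = NULL,
                                      max_span = 6L, threshold = 0.2) {
  entities <- unique(bel_entity_labels(statement))
  rows <- vector("list", length(entities))
  toks <- sentence$tokens$surface
  for (k in seq_along(entities)) {
    ent <- entities[k]
    ns <- sub(":.*$", "", ent)
    id <- sub("^[^:]*:", "", ent)
    ty <- entity_type(ent)
    found <- NULL
    if (!is.null(ner_mentions) && nrow(ner_mentions)) {
      for (i in seq_len(nrow(ner_mentions))) {
        rn <- renormalize_identifier(ner_mentions$identifier[i],
                                     ner_mentions$db[i],
                                     ner_mentions$type[i],
                                     chebi_map = chebi_map)
        if (!rn$discarded && rn$identifier == id &&
            ner_mentions$type[i] == ty) {
          found <- list(start = ner_mentions$token_start[i],
                        end = ner_mentions$token_end[i],
                        method = "ner", distance = 0)
          break
        }
      }
    }
    if (is.null(found)) {
      names_k <- dictionary$name[dictionary$namespace == ns &
                                 dictionary$identifier == id]
      if (length(names_k)) {
        hit <- dictionary_search(toks, sort(names_k), max_span = max_span,
                                 threshold = threshold)
        if (!is.null(hit)) {
          found <- list(start = hit$start, end = hit$end,
                        method = "dictionary", distance = hit$distance)
        }
      }
    }
    rows[[k]] <- tibble(
      entity = ent, type = ty,
      token_start = if (is.null(found)) NA_integer_ else as.integer(found$start),
      token_end = if (is.null(found)) NA_integer_ else as.integer(found$end),
      method = if (is.null(found)) NA_character_ else found$method,
      distance = if (is.null(found)) NA_real_ else found$distance,
      absent = is.null(found)
    )
  }
  dplyr::bind_rows(rows)
}

#' Read an NER-hook mention file
#'
#' TSV columns: `sentence_id`, `token_start`, `token_end`, `type`, `db`,
#' `identifier`.  External recognizers are never executed by this package;
#' their output is consumed through this file format.
#'
#' @param path TSV path.
#' @return tibble of mentions.
#' @export
read_ner_mentions <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE,
                          col.names = c("sentence_id", "token_start",
                                        "token_end", "type", "db", "identifier"))
  as_tibble(df)
}
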