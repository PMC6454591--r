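# Sentence tokenization and entity anonymization.
#
# Tokenization is whitespace-based plus three rules aimed at dictionary
# search and pmod() parameter recognition rather than news-style text:
#   1. a comma followed by a space ends a token (the comma becomes its own
#      token); a comma followed by a letter or digit stays attached, since it
#      is usually part of a biomedical entity name ("1,204" stays whole);
#   2. hyphenated compounds ending in "ed"/"ing" split at the hyphen, because
#      the participle usually carries the relationship ("progesterone-induced");
#   3. amino-acid residue abbreviations fused with numbers split into the
#      letter and digit parts ("Ser727" -> "Ser" "727"), feeding pmod()
#      parameters.  The letter part must be a one/three-letter amino-acid
#      code, so ordinary alphanumerics like "p53" are not shredded.

.aa_codes <- c(
  LETTERS[!LETTERS %in% c("B", "J", "O", "U", "X", "Z")],
  "Ala", "Arg", "Asn", "Asp", "Cys", "Glu", "Gln", "Gly", "His", "Ile",
  "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp", "Tyr", "Val"
)

# split one whitespace-delimited chunk into pieces with relative 0-based
# offsets into the chunk
split_chunk <- function(chunk) {
  pieces <- list(list(s = chunk, off = 0L))
  # rule 1: trailing comma (followed by space / end-of-sentence) splits off
  step <- function(pieces, fn) {
    out <- list()
    for (p in pieces) out <- c(out, fn(p))
    out
  }
  comma_rule <- function(p) {
    out <- list()
    s <- p$s; off <- p$off
    while (grepl(",$", s) && nchar(s) > 1L) {
      out <- c(list(list(s = ",", off = off + nchar(s) - 1L)), out)
      s <- substr(s, 1L, nchar(s) - 1L)
    }
    c(list(list(s = s, off = off)), out)
  }
  hyphen_rule <- function(p) {
    s <- p$s
    if (!grepl("-", s, fixed = TRUE) || !grepl("(ed|ing)$", s)) return(list(p))
    parts <- strsplit(s, "", fixed = TRUE)[[1]]
    cuts <- which(parts == "-")
    bounds <- sort(unique(c(0L, cuts - 1L, cuts, length(parts))))
    out <- list(); last <- 0L
    for (b in bounds[-1]) {
      seg <- substr(s, last + 1L, b)
      if (nzchar(seg)) out <- c(out, list(list(s = seg, off = p$off + last)))
      last <- b
    }
    out
  }
  residue_rule <- function(p) {
    m <- regexec("^([A-Za-z]+)([0-9]+)$", p$s)[[1]]
    if (m[1] == -1L) return(list(p))
    parts <- regmatches(p$s, list(m))[[1]]
    if (!parts[2] %in% .aa_codes) return(list(p))
    list(list(s = parts[2], off = p$off),
         list(s = parts[3], off = p$off + nchar(parts[2])))
  }
  pieces <- step(pieces, comma_rule)
  pieces <- step(pieces, hyphen_rule)
  step(pieces, residue_rule)
}

#' Tokenize a biomedical sentence
#'
#' Whitespace tokenization plus the three domain rules described in the
#' package vignette: sentence-final commas split off, hyphenated participles
#' split at the hyphen (the hyphen kept as its own token), and amino-acid
#' residue abbreviations split from their position numbers.
#'
#' @param text a single sentence.
#' @return a tibble with columns `surface`, `start`, `end` (0-based,
#'   half-open character offsets into `text`), `stem` and `is_placeholder`.
#' @export
#' @examples
#' tokenize("STAT1 phosphorylation at Ser727")$surface
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  m <- gregexpr("\\S+", text)[[1]]
  out <- list()
  for (i in seq_along(m)) {
    chunk <- substr(text, m[i], m[i] + attr(m, "match.length")[i] - 1L)
    for (p in split_chunk(chunk)) {
      out <- c(out, list(tibble(
        surface = p$s,
        start = m[i] - 1L + p$off,
        end = m[i] - 1L + p$off + nchar(p$s)
      )))
    }
  }
  tok <- dplyr::bind_rows(out)
  tok$stem <- stem_words(tok$surface)
  tok$is_placeholder <- grepl(.placeholder_rx, tok$surface)
  tok
}

#' Stem words with a light suffix-stripping stemmer
#'
#' A deterministic suffix stripper covering the inflections that matter for
#' trigger-word features (plurals, -ed/-ing participles, -ation/-ion
#' nominalizations).  Placeholder tokens pass through unchanged.
#'
#' @param words character vector.
#' @return character vector of stems.
#' @export
stem_words <- function(words) {
  vapply(words, function(w) {
    if (grepl(.placeholder_rx, w)) return(w)
    s <- tolower(w)
    rules <- list(
      c("izations$", "ize"), c("ization$", "ize"), c("ations$", "ate"),
      c("ation$", "ate"), c("ingly$", ""), c("edly$", ""),
      c("ings$", ""), c("ing$", ""), c("ied$", "y"), c("ies$", "y"),
      c("ed$", ""), c("es$", ""), c("ly$", ""), c("ss$", "ss"), c("s$", "")
    )
    for (r in rules) {
      if (grepl(r[1], s) && nchar(sub(r[1], r[2], s)) >= 3L) {
        s <- sub(r[1], r[2], s)
        break
      }
    }
    # undouble a final consonant left by -ed/-ing stripping (stopped -> stop)
    if (grepl("([b-df-hj-np-tv-z])\\1$", s)) s <- substr(s, 1L, nchar(s) - 1L)
    s
  }, "", USE.NAMES = FALSE)
}

#' Construct an annotated sentence
#'
#' @param sentence_id identifier joining the sentence to its statements and
#'   dependency parse.
#' @param raw_text original sentence text.
#' @param tokens token tibble from [tokenize()] (computed if omitted).
#' @param mentions tibble with columns `token_start`, `token_end` (1-based,
#'   inclusive token indices), `type` (`GENE`/`CHEM`/`BP`/`DIS`) and `entity`
#'   (`namespace:identifier`); zero-row tibble if none.
#' @return object of class `annotated_sentence`.
#' @export
annotated_sentence <- function(sentence_id, raw_text, tokens = NULL,
                               mentions = empty_mentions()) {
  if (is.null(tokens)) tokens <- tokenize(raw_text)
  structure(list(sentence_id = sentence_id, raw_text = raw_text,
                 tokens = tokens, mentions = mentions),
            class = "annotated_sentence")
}

#' @rdname annotated_sentence
#' @export
empty_mentions <- function() {
  tibble(token_start = integer(0), token_end = integer(0),
         type = character(0), entity = character(0))
}

#' @export
print.annotated_sentence <- function(x, ...) {
  cat("<annotated_sentence>", x$sentence_id, "\n ",
      paste(x$tokens$surface, collapse = " "), "\n")
  if (nrow(x$mentions)) {
    cat(sprintf("  %d mention(s): %s\n", nrow(x$mentions),
                paste(x$mentions$entity, collapse = ", ")))
  }
  invisible(x)
}

#' Anonymize entity mentions as typed placeholders
#'
#' Collapses every mention's token span to a single placeholder token
#' (`GENE_k`, `CHEM_k`, `BP_k`, `DIS_k`), numbering densely per type in order
#' of first occurrence; repeated mentions of the same entity reuse the same
#' placeholder.  The original tokens are kept in an `anonymize_map` attribute
#' so [de_anonymize()] can restore them.
#'
#' @param sentence an [annotated_sentence()] whose mentions are typed and
#'   non-overlapping.
#' @return the anonymized `annotated_sentence`; its `mentions` gain a
#'   `placeholder` column and its tokens are the collapsed sequence.
#' @export
anonymize <- function(sentence) {
  stopifnot(inherits(sentence, "annotated_sentence"))
  men <- sentence$mentions
  if (!nrow(men)) return(sentence)
  men <- men[order(men$token_start), , drop = FALSE]
  if (any(men$token_start[-1] <= men$token_end[-nrow(men)])) {
    abort("overlapping mentions; resolve overlaps before anonymizing")
  }
  if (any(men$token_end > nrow(sentence$tokens)) || any(men$token_start < 1L)) {
    abort("mention span outside token range")
  }
  # assign placeholders: dense per type, repeat entities reuse theirs
  ph <- character(nrow(men))
  seen <- character(0)
  counts <- c(GENE = 0L, CHEM = 0L, BP = 0L, DIS = 0L)
  for (i in seq_len(nrow(men))) {
    key <- paste0(men$type[i], "|", men$entity[i])
    if (key %in% names(seen)) {
      ph[i] <- seen[[key]]
    } else {
      counts[men$type[i]] <- counts[men$type[i]] + 1L
      ph[i] <- paste0(men$type[i], "_", counts[men$type[i]])
      seen[key] <- ph[i]
      names(seen)[length(seen)] <- key
    }
  }
  men$placeholder <- ph
  old <- sentence$tokens
  new_rows <- list(); map <- list(); new_mentions <- men[0, ]
  i <- 1L; out_idx <- 0L
  while (i <= nrow(old)) {
    hit <- which(men$token_start == i)
    if (length(hit)) {
      h <- hit[1]
      out_idx <- out_idx + 1L
      new_rows[[out_idx]] <- tibble(
        surface = men$placeholder[h],
        start = old$start[men$token_start[h]],
        end = old$end[men$token_end[h]],
        stem = men$placeholder[h],
        is_placeholder = TRUE
      )
      map[[out_idx]] <- old[men$token_start[h]:men$token_end[h], , drop = FALSE]
      m2 <- men[h, ]; m2$token_start <- out_idx; m2$token_end <- out_idx
      new_mentions <- dplyr::bind_rows(new_mentions, m2)
      i <- men$token_end[h] + 1L
    } else {
      out_idx <- out_idx + 1L
      new_rows[[out_idx]] <- old[i, , drop = FALSE]
      map[[out_idx]] <- NULL
      i <- i + 1L
    }
  }
  out <- sentence
  out$tokens <- dplyr::bind_rows(new_rows)
  out$mentions <- new_mentions
  attr(out, "anonymize_map") <- map
  out
}

#' Restore the original token sequence of an anonymized sentence
#'
#' @param sentence an [annotated_sentence()] produced by [anonymize()].
#' @return the sentence with its original tokens and mention spans.
#' @export
de_anonymize <- function(sentence) {
  map <- attr(sentence, "anonymize_map")
  if (is.null(map)) return(sentence)
  rows <- list()
  for (i in seq_len(nrow(sentence$tokens))) {
    if (i <= length(map) && !is.null(map[[i]])) {
      rows[[i]] <- map[[i]]
    } else {
      rows[[i]] <- sentence$tokens[i, , drop = FALSE]
    }
  }
  out <- sentence
  out$tokens <- dplyr::bind_rows(rows)
  out$mentions <- empty_mentions()
  attr(out, "anonymize_map") <- NULL
  out
}

#' Write tokenized sentences as JSONL
#'
#' One JSON object per line: `sentence_id`, `tokens` (surface/start/end) and
#' `mentions`.  Requires the jsonlite package.
#'
#' @param sentences list of [annotated_sentence()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tokens_jsonl <- function(sentences, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    abort("jsonlite is required for JSONL output")
  }
  lines <- vapply(sentences, function(s) {
    jsonlite::toJSON(list(
      sentence_id = s$sentence_id,
      tokens = s$tokens[, c("surface", "start", "end")],
      mentions = s$mentions
    ), auto_unbox = TRUE)
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
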