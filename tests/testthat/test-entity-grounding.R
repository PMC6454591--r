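test_that("renormalization follows the task's namespace rules", {
  expect_false(renormalize_identifier("2534", "HGNC", "GENE")$discarded)
  expect_equal(renormalize_identifier("2534", "Entrez", "GENE")$identifier, "2534")
  omim <- renormalize_identifier("164780", "OMIM", "DIS")
  expect_true(omim$discarded)
  expect_match(omim$reason, "OMIM")
  expect_false(renormalize_identifier("D009369", "MESH", "DIS")$discarded)
  # chemicals go through the name -> CHEBI table
  hit <- renormalize_identifier("D005947", "MESH", "CHEM",
                                chebi_map = c(glucose = "17234"),
                                name = "Glucose")
  expect_equal(hit$identifier, "17234")
  miss <- renormalize_identifier("D000001", "MESH", "CHEM",
                                 chebi_map = c(glucose = "17234"),
                                 name = "unknownium")
  expect_true(miss$discarded)
  # vacuous mapping: any chemical is discarded
  expect_true(renormalize_identifier("X", "MESH", "CHEM",
                                     chebi_map = character(0),
                                     name = "anything")$discarded)
})

test_that("dictionary search finds exact symbols at distance zero", {
  toks <- c("stimulation", "of", "IL2RB", "expression")
  hit <- dictionary_search(toks, "IL2RB")
  expect_equal(hit[c("start", "end")], list(start = 3L, end = 3L))
  expect_equal(hit$distance, 0)
  # case-insensitive
  expect_equal(dictionary_search(toks, "il2rb")$distance, 0)
  # nothing under threshold -> ABSENT
  expect_null(dictionary_search(toks, "completelyunrelatedname"))
})

test_that("dictionary search equals the brute-force window scan", {
  withr::with_seed(73, {
    vocab <- c("alpha", "beta", "gamma", "kinase", "receptor", "acid",
               "cycle", "cell", "factor", "growth")
    for (i in 1:200) {
      toks <- sample(vocab, sample(3:10, 1), replace = TRUE)
      names <- replicate(sample(1:3, 1), paste(
        sample(vocab, sample(1:3, 1), replace = TRUE), collapse = " "))
      got <- dictionary_search(toks, names, max_span = 4L, threshold = 0.5)
      want <- brute_dictionary_search(toks, names, max_span = 4L,
                                      threshold = 0.5)
      if (is.null(want)) {
        expect_null(got)
      } else {
        expect_equal(got[c("start", "end")], want[c("start", "end")])
        expect_equal(got$distance, want$distance, tolerance = 1e-12)
      }
    }
  })
})

test_that("single-substitution synonyms are found at distance 1/len", {
  toks <- c("the", "castenospermine", "treatment")  # one substitution
  hit <- dictionary_search(toks, "castanospermine", threshold = 0.2)
  expect_equal(hit$start, 2L)
  expect_equal(hit$distance, 1 / nchar("castanospermine"))
  want <- brute_dictionary_search(toks, "castanospermine", 6L, 0.2)
  expect_equal(hit$distance, want$distance)
})

test_that("grounding covers every statement entity exactly once", {
  dict <- tibble::tibble(
    namespace = c("HGNC", "HGNC", "CHEBI"),
    identifier = c("LYN", "IL2RB", "42"),
    name = c("lyn", "IL2RB", "aspirin"))
  sent <- annotated_sentence("s1", "lyn binds IL2RB after aspirin")
  stmt <- normalize_statement(parse_statement(
    "a(CHEBI:42) increases complex(p(HGNC:LYN), p(HGNC:IL2RB))"))
  g <- ground_statement_entities(sent, stmt, dict)
  expect_equal(nrow(g), 3L)  # one row per distinct entity leaf
  expect_true(all(!g$absent))
  expect_true(all(g$distance == 0))
  expect_true(all(g$method == "dictionary"))
  # one entity absent from the text
  stmt2 <- normalize_statement(parse_statement(
    "p(HGNC:LYN) increases p(HGNC:MISSING)"))
  g2 <- ground_statement_entities(sent, stmt2, dict)
  expect_equal(sum(g2$absent), 1L)
  expect_equal(g2$entity[g2$absent], "HGNC:MISSING")
  # empty dictionary, no NER hook: everything ABSENT
  g3 <- ground_statement_entities(sent, stmt,
                                  dict[0, , drop = FALSE])
  expect_true(all(g3$absent))
})

test_that("grounding is stable under dictionary row permutation", {
  dict <- tibble::tibble(
    namespace = rep("HGNC", 4),
    identifier = c("A", "A", "B", "B"),
    name = c("alpha factor", "alpha", "beta factor", "beta"))
  sent <- annotated_sentence("s1", "alpha factor binds beta factor")
  stmt <- parse_statement("p(HGNC:A) increases p(HGNC:B)")
  base <- ground_statement_entities(sent, stmt, dict)
  withr::with_seed(5, {
    for (i in 1:10) {
      perm <- dict[sample(nrow(dict)), , drop = FALSE]
      expect_equal(ground_statement_entities(sent, stmt, perm), base)
    }
  })
})

test_that("NER-hook mentions take precedence and renormalize", {
  dict <- tibble::tibble(namespace = character(0), identifier = character(0),
                         name = character(0))
  sent <- annotated_sentence("s1", "lyn binds stuff")
  stmt <- parse_statement("p(HGNC:LYN) increases p(HGNC:B)")
  ner <- tibble::tibble(token_start = 1L, token_end = 1L, type = "GENE",
                        db = "HGNC", identifier = "LYN")
  g <- ground_statement_entities(sent, stmt, dict, ner_mentions = ner)
  expect_equal(g$method[g$entity == "HGNC:LYN"], "ner")
  expect_equal(g$token_start[g$entity == "HGNC:LYN"], 1L)
  expect_true(g$absent[g$entity == "HGNC:B"])
})

test_that("dictionary and NER mention files read back", {
  dpath <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("HGNC\tLYN\tlyn", "CHEBI\t42\taspirin"), dpath)
  d <- read_entity_dictionary(dpath)
  expect_equal(d$identifier, c("LYN", "42"))
  npath <- withr::local_tempfile(fileext = ".tsv")
  writeLines("s1\t1\t1\tGENE\tHGNC\tLYN", npath)
  n <- read_ner_mentions(npath)
  expect_equal(n$sentence_id, "s1")
  expect_equal(n$identifier, "LYN")
})
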