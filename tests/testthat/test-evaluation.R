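test_that("activity functions collapse to act() in canonical keys", {
  expect_equal(canonicalize("kin(p(HGNC:X)) increases p(HGNC:Y)", "function"),
               "act(p(HGNC:X))")
  expect_equal(canonicalize("cat(p(HGNC:X)) increases p(HGNC:Y)", "function"),
               "act(p(HGNC:X))")
  expect_equal(
    canonicalize("tscript(p(HGNC:X)) increases p(HGNC:Y)", "statement"),
    canonicalize("kin(p(HGNC:X)) increases p(HGNC:Y)", "statement"))
})

test_that("direct and indirect relations are treated as equal", {
  a <- canonicalize("p(HGNC:A) directlyIncreases p(HGNC:B)", "relation")
  b <- canonicalize("p(HGNC:A) increases p(HGNC:B)", "relation")
  expect_identical(a, b)
  a <- canonicalize("p(HGNC:A) directlyDecreases p(HGNC:B)", "statement")
  b <- canonicalize("p(HGNC:A) decreases p(HGNC:B)", "statement")
  expect_identical(a, b)
})

test_that("level projections produce the expected item multisets", {
  s <- "cat(p(HGNC:IL2)) increases complex(p(HGNC:LYN), p(HGNC:IL2RB))"
  expect_setequal(canonicalize(s, "term"),
                  c("p(HGNC:IL2)", "p(HGNC:LYN)", "p(HGNC:IL2RB)"))
  expect_setequal(canonicalize(s, "function"),
                  c("act(p(HGNC:IL2))",
                    "complex(p(HGNC:LYN),p(HGNC:IL2RB))"))
  expect_setequal(canonicalize(s, "function_secondary"),
                  c("act|p(HGNC:IL2)", "complex|p(HGNC:LYN)",
                    "complex|p(HGNC:IL2RB)"))
  expect_length(canonicalize(s, "relation_secondary"), 2L)
  expect_length(canonicalize(s, "relation"), 1L)
  expect_match(canonicalize(s, "relation"), "^increases\\|")
})

test_that("statement-level keys are injective outside the stated equivalences", {
  # random trees restricted to the equivalence-free vocabulary: distinct
  # trees must produce distinct statement keys
  rand_plain <- function() {
    ent <- function() bel_node("entity",
                               paste0("HGNC:E", sample(1:20, 1)))
    term <- function(depth) {
      if (depth <= 0L || stats::runif(1) < 0.5) return(ent())
      fn <- sample(c("complex", "deg", "tloc"), 1)
      bel_node("function", fn,
               lapply(seq_len(sample(1:2, 1)), function(i) term(depth - 1L)))
    }
    bel_tree(bel_node("relation", sample(c("increases", "decreases"), 1),
                      list(term(2L), term(2L))))
  }
  withr::with_seed(239, {
    trees <- replicate(150, rand_plain(), simplify = FALSE)
    keys <- vapply(trees, canonicalize, "", level = "statement")
    for (i in seq_along(trees)) {
      same_key <- which(keys == keys[i])
      for (j in same_key) expect_true(bel_equal(trees[[i]], trees[[j]]))
    }
  })
})

test_that("perfect predictions score 100 at every level", {
  gold <- tibble::tibble(
    sentence_id = c("s1", "s1", "s2"),
    statement = c("p(HGNC:A) increases p(HGNC:B)",
                  "kin(p(HGNC:C)) decreases p(HGNC:D)",
                  "a(CHEBI:X) decreases complex(p(HGNC:E), p(HGNC:F))"))
  rep <- score_statements(gold, gold)
  expect_true(all(rep$precision == 100))
  expect_true(all(rep$recall == 100))
  expect_true(all(rep$f1 == 100))
  expect_true(all(rep$fp == 0L) && all(rep$fn == 0L))
})

test_that("empty predictions score zero by convention", {
  gold <- tibble::tibble(sentence_id = "s1",
                         statement = "p(HGNC:A) increases p(HGNC:B)")
  none <- gold[0, ]
  rep <- score_statements(gold, none)
  expect_true(all(rep$precision == 0))
  expect_true(all(rep$recall == 0))
  expect_true(all(rep$f1 == 0))
})

test_that("scores agree with an independent brute-force matcher", {
  pool <- c("p(HGNC:A) increases p(HGNC:B)",
            "p(HGNC:A) directlyIncreases p(HGNC:B)",
            "p(HGNC:B) decreases p(HGNC:A)",
            "kin(p(HGNC:A)) increases p(HGNC:C)",
            "cat(p(HGNC:A)) increases p(HGNC:C)",
            "a(CHEBI:X) decreases complex(p(HGNC:A), p(HGNC:B))",
            "p(HGNC:C) decreases bp(GOBP:Y)")
  withr::with_seed(241, {
    for (trial in 1:20) {
      mk <- function() {
        rows <- list()
        for (s in c("s1", "s2", "s3")) {
          for (k in seq_len(sample(0:3, 1))) {
            rows[[length(rows) + 1L]] <-
              tibble::tibble(sentence_id = s, statement = sample(pool, 1))
          }
        }
        if (!length(rows)) return(tibble::tibble(sentence_id = character(0),
                                                 statement = character(0)))
        dplyr::bind_rows(rows)
      }
      gold <- mk(); pred <- mk()
      rep <- score_statements(gold, pred)
      for (lv in rep$level) {
        want <- brute_score(gold, pred, lv)
        row <- rep[rep$level == lv, ]
        expect_equal(row$tp, want$tp)
        expect_equal(row$tp + row$fn, want$n_gold)
        expect_equal(row$tp + row$fp, want$n_pred)
      }
    }
  })
})

test_that("swapping gold and prediction exchanges precision and recall", {
  gold <- tibble::tibble(
    sentence_id = c("s1", "s1", "s2"),
    statement = c("p(HGNC:A) increases p(HGNC:B)",
                  "p(HGNC:C) decreases p(HGNC:D)",
                  "kin(p(HGNC:E)) increases p(HGNC:F)"))
  pred <- tibble::tibble(
    sentence_id = c("s1", "s2"),
    statement = c("p(HGNC:A) increases p(HGNC:B)",
                  "p(HGNC:E) decreases p(HGNC:F)"))
  ab <- score_statements(gold, pred)
  ba <- score_statements(pred, gold)
  expect_equal(ab$precision, ba$recall)
  expect_equal(ab$recall, ba$precision)
  expect_equal(ab$f1, ba$f1)
})

test_that("true positives are monotone across projection levels", {
  corpus <- generate_corpus(synth_config(60, seed = 251))
  gold <- synth_gold_statements(corpus)
  # perturb: drop some rows and swap some relations
  withr::with_seed(6, {
    pred <- gold[stats::runif(nrow(gold)) > 0.25, , drop = FALSE]
    flip <- stats::runif(nrow(pred)) < 0.3
    pred$statement[flip] <- sub(" increases ", " decreases ",
                                pred$statement[flip], fixed = TRUE)
  })
  rep <- score_statements(gold, pred)
  tp <- stats::setNames(rep$tp, rep$level)
  expect_lte(tp[["statement"]], tp[["relation"]])
  expect_lte(tp[["relation"]], tp[["relation_secondary"]])
})

test_that("score reports print, tidy and export", {
  gold <- tibble::tibble(sentence_id = "s1",
                         statement = "p(HGNC:A) increases p(HGNC:B)")
  rep <- score_statements(gold, gold)
  expect_output(print(rep), "Statement|statement")
  td <- tidy(rep)
  expect_false(inherits(td, "score_report"))
  expect_equal(glance(rep)$statement_f1, 100)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_score_report(rep, path)
  back <- utils::read.delim(path)
  expect_equal(back$f1, rep$f1)
  p <- ggplot2::autoplot(rep)
  expect_s3_class(p, "ggplot")
})
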