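test_that("parsing puts the relation at the root with arguments in order", {
  t <- parse_statement(
    "cat(p(HGNC:IL2)) increases complex(p(HGNC:LYN), p(HGNC:IL2RB))")
  expect_s3_class(t, "bel_tree")
  expect_equal(t$root$kind, "relation")
  expect_equal(t$root$label, "increases")
  expect_equal(t$root$children[[1]]$label, "cat")
  expect_equal(t$root$children[[1]]$children[[1]]$label, "HGNC:IL2")
  expect_equal(t$root$children[[2]]$label, "complex")
  expect_equal(vapply(t$root$children[[2]]$children, `[[`, "", "label"),
               c("HGNC:LYN", "HGNC:IL2RB"))

  flat <- parse_statement("p(HGNC:A) increases p(HGNC:B)")
  expect_equal(vapply(flat$root$children, `[[`, "", "kind"),
               c("entity", "entity"))
})

test_that("parser errors name the problem", {
  expect_error(parse_statement("p(HGNC:A increases p(HGNC:B)"),
               "unbalanced parentheses at offset")
  expect_error(parse_statement("p(HGNC:A) correlates p(HGNC:B)"),
               class = "belhier_unsupported_relation")
  expect_error(
    parse_statement("p(HGNC:A) increases p(HGNC:B) increases p(HGNC:C)"),
    class = "belhier_unsupported_relation")
})

test_that("quoted multi-word identifiers parse and render", {
  t <- parse_statement('p(HGNC:BMP2) decreases bp(GOBP:"cell cycle")')
  expect_equal(t$root$children[[2]]$label, "GOBP:cell cycle")
  expect_equal(render_statement(t),
               'p(HGNC:BMP2) decreases bp(GOBP:"cell cycle")')
})

test_that("normalization elevates modification functions above entities", {
  t <- parse_statement("p(HGNC:AKT1, pmod(P, S, 21)) increases p(HGNC:GSK3B)")
  n <- normalize_statement(t)
  sub <- n$root$children[[1]]
  expect_equal(sub$kind, "function")
  expect_equal(sub$label, "pmod")
  expect_equal(sub$children[[1]]$label, "HGNC:AKT1")
  expect_equal(vapply(sub$children[-1], `[[`, "", "label"),
               c("P", "S", "21"))
  # rendering reverses the elevation
  expect_equal(render_statement(n),
               "p(HGNC:AKT1,pmod(P,S,21)) increases p(HGNC:GSK3B)")
})

test_that("normalization is idempotent and preserves entity multisets", {
  withr::with_seed(11, {
    for (i in 1:200) {
      t <- random_bel_tree()
      n1 <- normalize_statement(t)
      expect_true(bel_equal(n1, normalize_statement(n1)))
      expect_equal(sort(bel_entity_labels(n1)), sort(bel_entity_labels(t)))
    }
  })
})

test_that("the castanospermine tree serializes to the expected node sequence", {
  expect_equal(as.character(serialize_tree(castano_tree())),
               c("decreases@2", "CHEM_1", "complex@2", "GENE_1", "GENE_2"))
  expect_equal(as.character(serialize_tree(flat_tree())),
               c("increases@2", "GENE_1", "GENE_2"))
})

test_that("deserialization inverts serialization and checks arity", {
  t <- deserialize_sequence(c("decreases@2", "CHEM_1", "complex@2",
                              "GENE_1", "GENE_2"))
  expect_true(bel_equal(t, preincubation_pair()$tree))
  expect_error(deserialize_sequence(c("increases@2", "GENE_1")),
               class = "belhier_malformed_sequence")
  expect_error(deserialize_sequence(c("increases@2", "GENE_1", "GENE_2",
                                      "GENE_3")),
               class = "belhier_malformed_sequence")
})

test_that("serialize/deserialize round-trips on random trees", {
  withr::with_seed(23, {
    for (i in 1:300) {
      t <- random_bel_tree()
      # identity map: entity labels kept verbatim in the sequence
      idmap <- stats::setNames(unique(bel_entity_labels(t)),
                               unique(bel_entity_labels(t)))
      expect_true(bel_equal(deserialize_sequence(serialize_tree(t, idmap)), t))
      # typed placeholder map: compare against the substituted tree
      ph <- bel_placeholders(t)
      expect_true(bel_equal(deserialize_sequence(serialize_tree(t, ph)),
                            substitute_placeholders(t, ph)))
    }
  })
})

test_that("every serialized sequence has exactly one root token", {
  withr::with_seed(31, {
    for (i in 1:100) {
      seq <- serialize_tree(random_bel_tree())
      internal <- grepl("@[0-9]+$", seq)
      total <- sum(as.integer(sub("^.*@", "", seq[internal])))
      expect_equal(total, length(seq) - 1L)
    }
  })
})

test_that("unify/split are mutual inverses and deduplicate", {
  t1 <- flat_tree("decreases", "HGNC:A", "HGNC:B")
  t2 <- flat_tree("decreases", "HGNC:C", "HGNC:D")
  u <- unify_trees(list(t1, t2))
  expect_equal(u$root$kind, "or")
  expect_equal(length(u$root$children), 2L)
  back <- split_unified(u)
  expect_true(bel_equal(back[[1]], t1) && bel_equal(back[[2]], t2))

  expect_true(bel_equal(unify_trees(list(t1)), t1))
  expect_true(bel_equal(unify_trees(list(t1, t1)), t1))  # dedup
  expect_length(split_unified(t1), 1L)
  expect_error(unify_trees(list()), "empty")

  withr::with_seed(47, {
    for (i in 1:100) {
      ts <- list()
      for (k in seq_len(sample(1:4, 1))) {
        repeat {
          cand <- random_bel_tree()
          if (!any(vapply(ts, bel_equal, TRUE, cand))) break
        }
        ts <- c(ts, list(cand))
      }
      back <- split_unified(unify_trees(ts))
      expect_equal(length(back), length(ts))
      for (k in seq_along(ts)) expect_true(bel_equal(back[[k]], ts[[k]]))
    }
  })
})

test_that("parse/render round-trips on random normalized trees", {
  withr::with_seed(59, {
    for (i in 1:300) {
      t <- random_bel_tree()
      s <- render_statement(t)
      expect_true(bel_equal(normalize_statement(parse_statement(s)), t))
    }
  })
})

test_that("placeholder numbering follows first preorder mention per type", {
  t <- parse_statement(
    "complex(p(HGNC:B), a(CHEBI:X), p(HGNC:A)) decreases bp(GOBP:Y)")
  ph <- bel_placeholders(t)
  expect_equal(unname(ph[c("HGNC:B", "HGNC:A", "CHEBI:X", "GOBP:Y")]),
               c("GENE_1", "GENE_2", "CHEM_1", "BP_1"))
})

test_that("serialization demands a complete placeholder map", {
  t <- flat_tree()
  expect_error(serialize_tree(t, c("HGNC:A" = "GENE_1")), "HGNC:B")
  expect_error(render_statement(bel_tree(bel_node("relation", "increases",
    list(bel_node("entity", "GENE_1"), bel_node("entity", "GENE_2")))),
    c(GENE_1 = "HGNC:A")), "GENE_2")
})

test_that("bel pair files round-trip", {
  path <- withr::local_tempfile(fileext = ".tsv")
  pairs <- tibble::tibble(
    sentence_id = c("s1", "s1", "s2"),
    statement = c("p(HGNC:A) increases p(HGNC:B)",
                  "p(HGNC:A) decreases p(HGNC:C)",
                  'a(CHEBI:X) decreases bp(GOBP:"cell cycle")'))
  write_bel_pairs(pairs, path)
  expect_equal(read_bel_pairs(path), pairs)
})
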