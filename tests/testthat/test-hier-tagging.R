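test_that("layer assignment puts parents one above their highest child", {
  la <- assign_layers(flat_tree())
  expect_equal(la$layer, c(2L, 1L, 1L))
  expect_equal(la$L, 2L)
  t <- parse_statement(
    "cat(p(HGNC:IL2)) increases complex(p(HGNC:LYN), p(HGNC:IL2RB))")
  la <- assign_layers(t)
  # preorder: increases, cat, IL2, complex, LYN, IL2RB
  expect_equal(la$layer, c(3L, 2L, 1L, 2L, 1L, 1L))
  expect_equal(la$L, 3L)
  withr::with_seed(149, {
    for (i in 1:100) {
      tree <- random_bel_tree()
      la <- assign_layers(tree)
      nodes <- bel_preorder(tree)
      # walk preorder again: each parent exceeds all children
      sizes <- integer(length(nodes))
      walk <- function(node, pos) {
        n <- 1L
        for (ch in node$children) {
          child_pos <- pos + n
          expect_gt(la$layer[pos], la$layer[child_pos])
          n <- n + walk(ch, child_pos)
        }
        sizes[pos] <<- n
        n
      }
      walk(nodes[[1]], 1L)
      expect_equal(la$L, max(la$layer))
    }
  })
})

test_that("tag generation reproduces the worked-example spans", {
  px <- preincubation_pair()
  tags <- generate_tags(px$source, px$tree, px$links)
  expect_equal(tags$layers[[1]],
               c("O", "O", "S-CHEM", "O", "O", "O", "S-GENE", "O", "S-GENE"))
  expect_equal(tags$layers[[2]],
               c("O", "O", "O", "O", "B-complex", "I-complex", "I-complex",
                 "I-complex", "E-complex"))
  # the relation span covers its trigger and every descendant token
  expect_equal(tags$layers[[3]],
               c("O", "O", "B-decreases", "I-decreases", "I-decreases",
                 "I-decreases", "I-decreases", "I-decreases", "E-decreases"))
})

test_that("adjacent-trigger relations produce S/B-E spans and O elsewhere", {
  tree <- bel_tree(bel_node("relation", "increases",
                            list(bel_node("entity", "GENE_1"),
                                 bel_node("entity", "GENE_2"))))
  toks <- c("maybe", "GENE_1", "elevated", "GENE_2", "somewhat")
  links <- tibble::tibble(source = c(2L, 3L, 4L), target = c(2L, 1L, 3L))
  tags <- generate_tags(toks, tree, links)
  expect_equal(tags$layers[[1]], c("O", "S-GENE", "O", "S-GENE", "O"))
  expect_equal(tags$layers[[2]],
               c("O", "B-increases", "I-increases", "E-increases", "O"))
})

test_that("unalignable instances are rejected with a typed condition", {
  tree <- preincubation_pair()$tree
  toks <- preincubation_pair()$source
  # drop the complex link: the function node has no aligned word
  links <- preincubation_pair()$links
  expect_error(generate_tags(toks, tree, links[links$target != 3L, ]),
               class = "belhier_untaggable")
  # non-strict mode recovers the span from the descendants
  tags <- generate_tags(toks, tree, links[links$target != 3L, ],
                        strict = FALSE)
  expect_equal(tags$layers[[2]][7:9],
               c("B-complex", "I-complex", "E-complex"))
  # a leaf without any link is always fatal
  expect_error(generate_tags(toks, tree, links[links$target != 2L, ],
                             strict = FALSE),
               class = "belhier_untaggable")
})

test_that("BIESO span extraction repairs malformed sequences deterministically", {
  expect_equal(nrow(bieso_spans(rep("O", 4))), 0L)
  sp <- bieso_spans(c("B-x", "I-x", "E-x", "O", "S-y"))
  expect_equal(sp$start, c(1L, 5L))
  expect_equal(sp$end, c(3L, 5L))
  expect_equal(sp$label, c("x", "y"))
  # orphan I opens a block; unterminated B closes at the last contiguous I
  sp <- bieso_spans(c("I-x", "I-x", "O", "B-y", "I-y"))
  expect_equal(sp$start, c(1L, 4L))
  expect_equal(sp$end, c(2L, 5L))
  # label change inside a block splits it
  sp <- bieso_spans(c("B-x", "I-y", "E-y"))
  expect_equal(sp$label, c("x", "y"))
  # stray E without a block becomes a singleton
  sp <- bieso_spans(c("O", "E-x", "O"))
  expect_equal(sp[["start"]], 2L)
})

test_that("tags_to_tree reconstructs the worked example and handles all-O", {
  px <- preincubation_pair()
  tags <- generate_tags(px$source, px$tree, px$links)
  back <- tags_to_tree(tags)
  expect_true(bel_equal(back, px$tree))
  empty <- structure(list(tokens = px$source,
                          layers = replicate(3, rep("O", 9), simplify = FALSE)),
                     class = "layered_tags")
  expect_warning(res <- tags_to_tree(empty), "no")
  expect_null(res)
  expect_null(tags_to_tree(empty, quiet = TRUE))
})

test_that("tag generation and tree reconstruction are mutual inverses", {
  corpus <- generate_corpus(synth_config(400, seed = 151, p_or = 0.2))
  for (i in seq_len(nrow(corpus))) {
    back <- tags_to_tree(corpus$gold_tags[[i]], quiet = TRUE)
    expect_true(bel_equal(back, corpus$unified[[i]]))
  }
})

test_that("spans never partially overlap within or across layers", {
  corpus <- generate_corpus(synth_config(150, seed = 157, p_or = 0.2))
  for (i in seq_len(nrow(corpus))) {
    tags <- corpus$gold_tags[[i]]
    all_spans <- lapply(tags$layers, bieso_spans)
    for (k in seq_along(all_spans)) {
      sp <- all_spans[[k]]
      if (nrow(sp) > 1L) {
        sp <- sp[order(sp$start), ]
        expect_true(all(sp$start[-1] > sp$end[-nrow(sp)]))
      }
      if (k > 1L) {
        lower <- all_spans[[k - 1L]]
        for (r in seq_len(nrow(lower))) {
          # each lower span is nested in at most one upper span
          cover <- sum(sp$start <= lower$start[r] & sp$end >= lower$end[r])
          partial <- sum(sp$start <= lower$end[r] & sp$end >= lower$start[r])
          expect_lte(cover, 1L)
          expect_equal(cover, partial)
        }
      }
    }
  }
})

test_that("parameter leaves are tagged at layer 1 and restored on decode", {
  tree <- normalize_statement(parse_statement(
    "p(HGNC:STAT1, pmod(P, S, 727)) increases p(HGNC:B)"))
  ph <- bel_placeholders(tree)
  tree_ph <- substitute_placeholders(tree, ph)
  toks <- c("GENE_1", "phosphorylation", "at", "Ser", "727",
            "elevated", "GENE_2")
  # preorder: increases, pmod, GENE_1, P, S, 727, GENE_2; the trigger word
  # "phosphorylation" carries both the pmod node and its P-type parameter
  links <- tibble::tibble(source = c(1L, 2L, 2L, 4L, 5L, 6L, 7L),
                          target = c(3L, 2L, 4L, 5L, 6L, 1L, 7L))
  tags <- generate_tags(toks, tree_ph, links)
  expect_equal(tags$layers[[1]][c(2L, 4L, 5L)], c("S-P", "S-AA", "S-NUM"))
  back <- tags_to_tree(tags, quiet = TRUE)
  expect_equal(canonicalize(back, "statement"),
               canonicalize(tree_ph, "statement"))
})

test_that("tag CoNLL files round-trip and padding adds O layers", {
  corpus <- generate_corpus(synth_config(25, seed = 163))
  path <- withr::local_tempfile(fileext = ".conll")
  write_tag_conll(corpus$gold_tags, path)
  back <- read_tag_conll(path)
  expect_length(back, nrow(corpus))
  for (i in seq_along(back)) {
    expect_equal(back[[i]]$tokens, corpus$gold_tags[[i]]$tokens)
    expect_equal(back[[i]]$layers, corpus$gold_tags[[i]]$layers)
  }
  padded <- pad_layers(corpus$gold_tags[[1]], 5L)
  expect_length(padded$layers, 5L)
  expect_true(all(padded$layers[[5]] == "O"))
})
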