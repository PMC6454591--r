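#' @useDynLib belhier, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom generics tidy glance
#' @keywords internal
"_PACKAGE"

#' @export
generics::tidy

#' @export
generics::glance

# Vocabulary tables used across the package ---------------------------------

.bel_relations <- c("increases", "decreases",
                    "directlyIncreases", "directlyDecreases")

# modification functions that are elevated above their entity during
# normalization and pushed back inside the entity term when rendering
.bel_modifications <- c("pmod", "sub", "trunc", "fus")

# activity functions collapsed to act() by the evaluation scheme
.bel_activities <- c("act", "cat", "kin", "tscript", "phos", "gtp",
                     "pep", "ribo", "tport", "chap")

# other BEL term-modifying functions accepted by the parser
.bel_functions <- c("complex", "deg", "tloc", "sec", "surf", .bel_activities)

# entity term functions; the namespace decides which one is rendered
.bel_entity_terms <- c("p", "a", "bp", "path", "g", "r", "m")

# namespace -> placeholder type
.bel_ns_type <- c(HGNC = "GENE", MGI = "GENE", EGID = "GENE",
                  CHEBI = "CHEM", MESHD = "DIS", GOBP = "BP")

# placeholder type -> canonical BEL term function
.bel_type_term <- c(GENE = "p", CHEM = "a", BP = "bp", DIS = "path")

.placeholder_rx <- "^(GENE|CHEM|BP|DIS)_[0-9]+$"

#' Construct a BEL tree node
#'
#' A `bel_node` is the building block of a [bel_tree()]: a relation, function,
#' entity, parameter or `"or"` node with ordered children.  Entity nodes carry
#' a `namespace:identifier` label (or a typed placeholder such as `GENE_1`);
#' parameter nodes carry literals such as `"P"`, `"S"` or `"21"`.
#'
#' @param kind one of `"relation"`, `"function"`, `"entity"`, `"parameter"`,
#'   `"or"`.
#' @param label node label: relation name, function name, entity
#'   `namespace:identifier` or placeholder, or parameter literal.
#' @param children list of `bel_node` children (ordered).
#' @return an object of class `bel_node`.
#' @export
#' @examples
#' bel_node("entity", "HGNC:AKT1")
bel_node <- function(kind = c("relation", "function", "entity", "parameter", "or"),
                     label, children = list()) {
  kind <- match.arg(kind)
  if (!is.character(label) || length(label) != 1L || is.na(label) || !nzchar(label)) {
    abort("`label` must be a single non-empty string")
  }
  if (kind == "parameter" && length(children)) {
    abort("parameter nodes cannot have children")
  }
  structure(list(kind = kind, label = label, children = children),
            class = "bel_node")
}

#' Construct a BEL tree
#'
#' Wraps a root [bel_node()] (a relation, or an `"or"` node unifying several
#' relations) together with the source statement text it was parsed from.
#'
#' @param root a `bel_node` of kind `"relation"` or `"or"`.
#' @param source_statement original text form, if any.
#' @return an object of class `bel_tree`.
#' @export
bel_tree <- function(root, source_statement = NA_character_) {
  stopifnot(inherits(root, "bel_node"))
  if (!root$kind %in% c("relation", "or")) {
    abort("the root of a BEL tree must be a relation or an 'or' node")
  }
  structure(list(root = root, source_statement = source_statement),
            class = "bel_tree")
}

#' Structural equality of BEL nodes and trees
#'
#' Compares kind, label and (recursively, in order) children; for trees the
#' `source_statement` field is ignored so a reparsed tree equals the original.
#'
#' @param a,b `bel_node` or `bel_tree` objects.
#' @return `TRUE` or `FALSE`.
#' @export
bel_equal <- function(a, b) {
  na <- if (inherits(a, "bel_tree")) a$root else a
  nb <- if (inherits(b, "bel_tree")) b$root else b
  if (!inherits(na, "bel_node") || !inherits(nb, "bel_node")) return(FALSE)
  if (na$kind != nb$kind || na$label != nb$label) return(FALSE)
  if (length(na$children) != length(nb$children)) return(FALSE)
  for (i in seq_along(na$children)) {
    if (!bel_equal(na$children[[i]], nb$children[[i]])) return(FALSE)
  }
  TRUE
}

# preorder traversal returning a list of nodes (used by serialization,
# layering and canonicalization)
bel_preorder <- function(node) {
  if (inherits(node, "bel_tree")) node <- node$root
  out <- list(node)
  for (ch in node$children) out <- c(out, bel_preorder(ch))
  out
}

# multiset of entity labels in a tree, preorder
bel_entity_labels <- function(x) {
  nodes <- bel_preorder(x)
  vapply(Filter(function(n) n$kind == "entity", nodes), `[[`, "", "label")
}

# placeholder type of an entity label ("HGNC:AKT1" -> "GENE", "GENE_2" -> "GENE")
entity_type <- function(label) {
  if (grepl(.placeholder_rx, label)) return(sub("_[0-9]+$", "", label))
  ns <- sub(":.*$", "", label)
  ty <- .bel_ns_type[[ns]]
  if (is.null(ty)) abort(sprintf("unknown namespace '%s' in entity '%s'", ns, label))
  ty
}

#' @export
format.bel_node <- function(x, ...) {
  if (!length(x$children)) return(sprintf("%s[%s]", x$kind, x$label))
  kids <- vapply(x$children, format, "")
  sprintf("%s[%s](%s)", x$kind, x$label, paste(kids, collapse = ", "))
}

#' @export
print.bel_node <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
print.bel_tree <- function(x, ...) {
  cat("<bel_tree>", format(x$root), "\n")
  invisible(x)
}

#' Generate a random valid BEL tree
#'
#' Draws a normalized BEL tree from the package grammar (relation root, term
#' children that may be plain entities, functions over entities, or elevated
#' modification functions with parameter leaves).  Used by the round-trip
#' property tests; depth is at most 4 and arity at most 3.  Consumes the
#' session RNG, so wrap in [withr::with_seed()] or `set.seed()` for
#' reproducibility.
#'
#' @param p_function probability that an argument is wrapped in a function.
#' @param p_mod probability that an entity carries an elevated modification.
#' @return a [bel_tree()].
#' @export
random_bel_tree <- function(p_function = 0.5, p_mod = 0.2) {
  ns_pool <- names(.bel_ns_type)
  rand_entity <- function() {
    ns <- sample(ns_pool, 1L)
    bel_node("entity", paste0(ns, ":", paste0("E", sample(1:50, 1L))))
  }
  rand_mod <- function() {
    ent <- rand_entity()
    params <- list(bel_node("parameter", "P"),
                   bel_node("parameter", sample(c("S", "T", "Y"), 1L)),
                   bel_node("parameter", as.character(sample(1:999, 1L))))
    bel_node("function", sample(.bel_modifications[1:3], 1L),
             c(list(ent), params[seq_len(sample(1:3, 1L))]))
  }
  rand_term <- function(depth) {
    if (depth <= 0L || stats::runif(1) >= p_function) {
      if (stats::runif(1) < p_mod) return(rand_mod())
      return(rand_entity())
    }
    fn <- sample(.bel_functions, 1L)
    n_args <- if (fn == "complex") sample(2:3, 1L) else 1L
    bel_node("function", fn, lapply(seq_len(n_args),
                                    function(i) rand_term(depth - 1L)))
  }
  rel <- sample(.bel_relations, 1L)
  bel_tree(bel_node("relation", rel, list(rand_term(2L), rand_term(2L))))
}
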