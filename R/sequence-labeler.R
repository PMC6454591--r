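# Stacked hierarchical sequence labeling.
#
# L per-layer linear-chain CRFs: layer 1 sees word and stem features in a
# window of 5 tokens (offsets -2..+2); layer k additionally sees the layer
# 1..k-1 tags at the same offsets -- gold tags while training (teacher
# forcing), predicted tags at test time.  Label bigram dependencies are the
# CRF transition weights.

.feature_template_version <- "w+s+labels@-2..2/v1"

offset_val <- function(v, i, o) {
  j <- i + o
  if (j < 1L) "_BOS_" else if (j > length(v)) "_EOS_" else v[j]
}

#' Build per-token feature vectors for one layer
#'
#' Layer 1 uses word-identity and stem unigrams at offsets -2..+2; layer
#' `k > 1` adds the lower layers' tags at the same offsets.  Out-of-range
#' offsets yield `_BOS_`/`_EOS_` sentinels.
#'
#' @param tokens character vector of token surfaces.
#' @param lower_labels list of `k - 1` complete tag sequences (layers
#'   1..k-1).
#' @param k layer being featurized.
#' @param stems optional precomputed stems (defaults to [stem_words()]).
#' @return list with one character vector of feature strings per token.
#' @export
featurize <- function(tokens, lower_labels = list(), k = 1L, stems = NULL) {
  if (length(lower_labels) != k - 1L) {
    abort(sprintf("layer %d needs %d lower label sequence(s), got %d",
                  k, k - 1L, length(lower_labels)))
  }
  n <- length(tokens)
  for (ll in lower_labels) {
    if (length(ll) != n) abort("label sequence length does not match tokens")
  }
  if (is.null(stems)) stems <- stem_words(tokens)
  offs <- -2:2
  lapply(seq_len(n), function(i) {
    f <- c("bias",
           vapply(offs, function(o) sprintf("w[%d]=%s", o, offset_val(tokens, i, o)), ""),
           vapply(offs, function(o) sprintf("s[%d]=%s", o, offset_val(stems, i, o)), ""))
    for (j in seq_along(lower_labels)) {
      f <- c(f, vapply(offs, function(o)
        sprintf("L%d[%d]=%s", j, o, offset_val(lower_labels[[j]], i, o)), ""))
    }
    f
  })
}

#' Train the hierarchical sequence labeler
#'
#' Trains `L` stacked CRFs: layer 1 on word/stem features, layer `k` on the
#' same features plus the gold tags of layers `1..k-1`.  Instances shallower
#' than `L` are padded with all-`O` layers.
#'
#' @param instances list of [layered_tags][generate_tags()] objects.
#' @param L layer count; defaults to the deepest instance.
#' @param c2 L2 regularization coefficient passed to [crf_train()].
#' @param maxit maximum optimizer iterations per layer.
#' @param seed integer recorded with the model (training itself draws no
#'   random numbers).
#' @return object of class `hier_model`.
#' @export
train_hier <- function(instances, L = NULL, c2 = 1.0, maxit = 150L, seed = 0L) {
  if (!length(instances)) abort("empty training corpus")
  if (is.null(L)) L <- max(vapply(instances, function(i) length(i$layers), 0L))
  instances <- lapply(instances, pad_layers, L = L)
  stems <- lapply(instances, function(i) stem_words(i$tokens))
  models <- vector("list", L)
  for (k in seq_len(L)) {
    x <- lapply(seq_along(instances), function(i) {
      inst <- instances[[i]]
      featurize(inst$tokens, inst$layers[seq_len(k - 1L)], k, stems = stems[[i]])
    })
    y <- lapply(instances, function(i) i$layers[[k]])
    models[[k]] <- crf_train(x, y, c2 = c2, maxit = maxit)
  }
  structure(list(L = L, models = models,
                 template = .feature_template_version,
                 c2 = c2, maxit = maxit, seed = as.integer(seed)),
            class = "hier_model")
}

#' Predict layered tags for a sentence
#'
#' Layers are decoded in order `1..L`, each consuming the previously
#' predicted layers as features; BIESO repair is applied when spans are
#' extracted by [tags_to_tree()].
#'
#' @param tokens character vector of (simplified) sentence tokens.
#' @param model a [train_hier()] result.
#' @return a [layered_tags][generate_tags()] object.
#' @export
predict_hier <- function(tokens, model) {
  stopifnot(inherits(model, "hier_model"))
  n <- length(tokens)
  layers <- list()
  if (n == 0L) {
    layers <- replicate(model$L, character(0), simplify = FALSE)
    return(structure(list(tokens = tokens, layers = layers),
                     class = "layered_tags"))
  }
  stems <- stem_words(tokens)
  for (k in seq_len(model$L)) {
    x <- list(featurize(tokens, layers, k, stems = stems))
    layers[[k]] <- crf_predict(model$models[[k]], x)[[1]]
  }
  structure(list(tokens = tokens, layers = layers), class = "layered_tags")
}

#' @export
print.hier_model <- function(x, ...) {
  cat(sprintf("<hier_model> %d layer(s), template %s\n", x$L, x$template))
  for (k in seq_len(x$L)) {
    m <- x$models[[k]]
    cat(sprintf("  layer %d: %d labels, %d features\n", k, m$n_lab, m$n_attr))
  }
  invisible(x)
}

#' @export
tidy.hier_model <- function(x, ...) {
  tibble(
    layer = seq_len(x$L),
    n_labels = vapply(x$models, `[[`, 0L, "n_lab"),
    n_features = vapply(x$models, `[[`, 0L, "n_attr"),
    n_parameters = vapply(x$models, function(m) length(m$theta), 0L),
    penalized_nll = vapply(x$models, `[[`, 0, "value"),
    converged = vapply(x$models, function(m) m$convergence == 0L, TRUE)
  )
}

#' @export
glance.hier_model <- function(x, ...) {
  tibble(layers = x$L,
         n_parameters = sum(vapply(x$models, function(m) length(m$theta), 0)),
         template = x$template, c2 = x$c2, seed = x$seed)
}

#' Persist / restore a hierarchical model
#'
#' The model is written as a directory: `metadata.json` (layer count,
#' feature template version, regularization, seed) plus one `layer_k.rds`
#' file per CRF.
#'
#' @param model a [train_hier()] result.
#' @param dir directory path.
#' @return `save_hier_model()` returns `dir` invisibly; `load_hier_model()`
#'   the restored `hier_model`.
#' @export
save_hier_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(L = model$L, template = model$template, c2 = model$c2,
               maxit = model$maxit, seed = model$seed)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                         auto_unbox = TRUE)
  } else {
    dput(meta, file.path(dir, "metadata.R"))
  }
  for (k in seq_len(model$L)) {
    saveRDS(model$models[[k]], file.path(dir, sprintf("layer_%d.rds", k)))
  }
  invisible(dir)
}

#' @rdname save_hier_model
#' @export
load_hier_model <- function(dir) {
  meta_path <- file.path(dir, "metadata.json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::fromJSON(meta_path)
  } else {
    dget(file.path(dir, "metadata.R"))
  }
  models <- lapply(seq_len(meta$L), function(k)
    readRDS(file.path(dir, sprintf("layer_%d.rds", k))))
  structure(list(L = meta$L, models = models, template = meta$template,
                 c2 = meta$c2, maxit = meta$maxit, seed = meta$seed),
            class = "hier_model")
}

#' Per-layer tag accuracy of predictions against gold
#'
#' @param pred,gold lists of `layered_tags` (same length and token counts;
#'   shallower instances are padded).
#' @return tibble with `layer`, `n_tokens`, `accuracy`.
#' @export
tag_accuracy <- function(pred, gold) {
  L <- max(vapply(c(pred, gold), function(i) length(i$layers), 0L))
  pred <- lapply(pred, pad_layers, L = L)
  gold <- lapply(gold, pad_layers, L = L)
  out <- lapply(seq_len(L), function(k) {
    p <- unlist(lapply(pred, function(i) i$layers[[k]]))
    g <- unlist(lapply(gold, function(i) i$layers[[k]]))
    tibble(layer = k, n_tokens = length(g), accuracy = mean(p == g))
  })
  dplyr::bind_rows(out)
}
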