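# Linear-chain conditional random field over string features.
#
# Training maximizes the L2-penalized conditional log-likelihood with
# L-BFGS-B (stats::optim) on the exact gradient computed by the compiled
# forward-backward routine.  Everything is deterministic: weights start at
# zero, the attribute and label dictionaries are sorted, and no random
# numbers are drawn.

#' Train a linear-chain CRF
#'
#' @param x list of sequences; each sequence is a list with one character
#'   vector of feature strings per token.
#' @param y list of character vectors of per-token labels (same shape).
#' @param c2 L2 regularization coefficient (penalty `c2 * sum(theta^2)`).
#' @param maxit maximum L-BFGS-B iterations.
#' @return object of class `crf_model`.
#' @export
crf_train <- function(x, y, c2 = 1.0, maxit = 150L) {
  stopifnot(length(x) == length(y), length(x) >= 1L)
  lens_x <- lengths(x)
  if (any(lens_x != lengths(y))) abort("feature/label length mismatch")
  attrs <- sort(unique(unlist(x, use.names = FALSE)))
  labs <- sort(unique(unlist(y, use.names = FALSE)))
  n_attr <- length(attrs); n_lab <- length(labs)
  seq_lens <- as.integer(lens_x)
  tok_feats <- unlist(x, recursive = FALSE, use.names = FALSE)
  attr_counts <- as.integer(lengths(tok_feats))
  attr_ids <- match(unlist(tok_feats, use.names = FALSE), attrs) - 1L
  labels <- match(unlist(y, use.names = FALSE), labs) - 1L
  np <- n_attr * n_lab + n_lab * n_lab

  cache <- new.env(parent = emptyenv())
  evaluate <- function(theta) {
    key <- theta
    if (!is.null(cache$theta) && identical(cache$theta, key)) return(cache$val)
    r <- crf_nll_grad(theta, n_attr, n_lab, seq_lens, attr_counts,
                      attr_ids, labels)
    r$nll <- r$nll + c2 * sum(theta^2)
    r$grad <- r$grad + 2 * c2 * theta
    cache$theta <- key; cache$val <- r
    r
  }
  fit <- stats::optim(
    par = numeric(np),
    fn = function(th) evaluate(th)$nll,
    gr = function(th) evaluate(th)$grad,
    method = "L-BFGS-B",
    control = list(maxit = as.integer(maxit), factr = 1e7)
  )
  structure(list(theta = fit$par, attrs = attrs, labels = labs,
                 n_attr = n_attr, n_lab = n_lab, c2 = c2, maxit = maxit,
                 value = fit$value, convergence = fit$convergence),
            class = "crf_model")
}

#' Decode label sequences with a trained CRF
#'
#' @param model a [crf_train()] result.
#' @param x list of sequences of per-token feature-string vectors; features
#'   unseen in training are ignored.
#' @return list of character label vectors.
#' @export
crf_predict <- function(model, x) {
  lapply(x, function(seq) {
    if (!length(seq)) return(character(0))
    ids <- lapply(seq, function(f) {
      i <- match(f, model$attrs)
      i[!is.na(i)] - 1L
    })
    out <- crf_viterbi(model$theta, model$n_attr, model$n_lab,
                       as.integer(lengths(ids)),
                       as.integer(unlist(ids, use.names = FALSE)))
    model$labels[out + 1L]
  })
}

#' @export
print.crf_model <- function(x, ...) {
  cat(sprintf("<crf_model> %d labels, %d features, penalized NLL %.3f\n",
              x$n_lab, x$n_attr, x$value))
  invisible(x)
}
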