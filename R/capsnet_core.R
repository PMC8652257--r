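# Forward computation of the capsule classifier: per-source standardization
# encoders (tanh) and the dynamic-routing capsule layer.
#
# Layout conventions (batch size N, l sources, k classes):
#   blocks  list over sources, each N x r_i
#   U       list over sources, each N x n        (primary capsules)
#   uhat    list[l] of list[k], each N x m       (prediction vectors)
#   b, c    list over sources, each N x k        (logits / couplings)
#   s, v    list over classes, each N x m        (weighted sums / type capsules)

#' Squashing nonlinearity
#'
#' Maps each row vector s to a vector parallel to s with norm
#' `||s||^2 / (const + ||s||^2)`: short vectors shrink towards zero, long
#' vectors approach (but never reach) unit length. The zero vector maps to
#' itself.
#'
#' @param s A numeric vector or an N x m matrix of row vectors.
#' @param const Squashing constant in the denominator (default 0.5).
#' @return Same shape as `s`.
#' @export
squash <- function(s, const = 0.5) {
  if (is.null(dim(s))) {
    nrm2 <- sum(s^2)
    if (nrm2 == 0) return(s)
    return(s * sqrt(nrm2) / (const + nrm2))
  }
  nrm2 <- rowSums(s^2)
  scale <- ifelse(nrm2 == 0, 0, sqrt(nrm2) / (const + nrm2))
  s * scale
}

# Row-wise L2 normalization; zero rows stay zero.
l2_normalize_rows <- function(s) {
  nrm <- sqrt(rowSums(s^2))
  s * ifelse(nrm == 0, 0, 1 / nrm)
}

#' Coupling coefficients from routing logits
#'
#' Softmax over the type-capsule axis, per primary capsule, with subtract-max
#' stabilization.
#'
#' @param b An N x k matrix of logits for one primary capsule, or an l x k
#'   matrix (one row per primary capsule for a single sample).
#' @return Matrix of the same shape; every row sums to 1.
#' @export
coupling_from_logits <- function(b) {
  b <- as.matrix(b)
  z <- exp(b - apply(b, 1L, max))
  z / rowSums(z)
}

#' Initialize a capsule model
#'
#' Creates the per-source encoder bank (`W_p[[i]]`, n x r_i, feeding tanh)
#' and the routing weight tensors (`W[[i]][[j]]`, m x n). Weights are drawn
#' Glorot-uniform under the given seed.
#'
#' @param sources List of [source_spec()] objects (one primary capsule each).
#' @param class_names Character vector of class names (one type capsule
#'   each).
#' @param n Primary-capsule length (default 8).
#' @param m Type-capsule length (default 16).
#' @param r Routing iterations (default 3).
#' @param squash_const Squashing-denominator constant (default 0.5).
#' @param normalize_every_iter If `TRUE`, the final weighted sum is also
#'   L2-normalized before squashing (the literal pseudocode reading; default
#'   `FALSE`, see the methods vignette).
#' @param accumulate_logits If `TRUE`, routing logits are accumulated across
#'   iterations (original CapsNet style) instead of overwritten.
#' @param seed Integer seed for weight initialization.
#' @return An object of class `caps_model`.
#' @export
new_caps_model <- function(sources, class_names, n = 8L, m = 16L, r = 3L,
                           squash_const = 0.5, normalize_every_iter = FALSE,
                           accumulate_logits = FALSE, seed = NULL) {
  check_sources(sources)
  stopifnot(n >= 1L, m >= 1L, r >= 1L, length(class_names) >= 1L)
  if (!is.null(seed)) set.seed(seed)
  k <- length(class_names)
  glorot <- function(nr, nc) {
    lim <- sqrt(6 / (nr + nc))
    matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
  }
  W_p <- lapply(sources, function(s) glorot(n, s$length))
  W <- lapply(seq_along(sources), function(i)
    lapply(seq_len(k), function(j) glorot(m, n)))
  structure(
    list(sources = sources, class_names = class_names,
         n = as.integer(n), m = as.integer(m), r = as.integer(r),
         squash_const = squash_const,
         normalize_every_iter = isTRUE(normalize_every_iter),
         accumulate_logits = isTRUE(accumulate_logits),
         W_p = W_p, W = W),
    class = "caps_model"
  )
}

#' @export
print.caps_model <- function(x, ...) {
  cat(sprintf(
    "<caps_model> %d sources -> %d classes | n=%d m=%d r=%d squash=%g\n",
    length(x$sources), length(x$class_names), x$n, x$m, x$r,
    x$squash_const))
  invisible(x)
}

#' Encode modular blocks into primary capsules
#'
#' Applies `u_i = tanh(W_p_i x_i)` per source: each block of r_i raw features
#' becomes an n-vector per sample, standardizing heterogeneous sources to a
#' common length.
#'
#' @param blocks List of N x r_i matrices, one per source.
#' @param model A `caps_model` (its encoder bank is used).
#' @return List of N x n matrices, one per source; all entries in (-1, 1).
#' @export
caps_encode <- function(blocks, model) {
  if (length(blocks) != length(model$W_p))
    stop("got ", length(blocks), " blocks for ", length(model$W_p),
         " encoders")
  lapply(seq_along(blocks), function(i) {
    x <- as.matrix(blocks[[i]])
    if (ncol(x) != ncol(model$W_p[[i]]))
      stop("source '", model$sources[[i]]$name, "': block has ", ncol(x),
           " columns, encoder expects ", ncol(model$W_p[[i]]))
    tanh(x %*% t(model$W_p[[i]]))
  })
}

#' Prediction vectors from primary capsules
#'
#' Computes `u_hat[j|i] = W_ij u_i` for every (source, class) pair.
#'
#' @param U List of N x n primary-capsule matrices.
#' @param W Routing weights: `W[[i]][[j]]` an m x n matrix.
#' @return Nested list `uhat[[i]][[j]]`, each N x m.
#' @export
caps_predict_vectors <- function(U, W) {
  if (length(U) != length(W)) stop("U and W disagree on source count")
  lapply(seq_along(U), function(i) {
    Ui <- as.matrix(U[[i]])
    lapply(W[[i]], function(Wij) {
      if (ncol(Wij) != ncol(Ui))
        stop("routing weight expects length-", ncol(Wij),
             " capsules, got ", ncol(Ui))
      Ui %*% t(Wij)
    })
  })
}

#' Dynamic routing between primary and type capsules
#'
#' The iterative agreement procedure: logits start at zero; each iteration
#' computes couplings by a per-source softmax, forms the coupling-weighted
#' sum `s_j` of prediction vectors, and (on non-final iterations) L2
#' normalizes `s_j` and overwrites the logits with the dot products
#' `u_hat[j|i] . s_j`. After the final iteration the raw weighted sum is
#' squashed into the type capsule `v_j`. Returns the type capsules and the
#' couplings of the final iteration.
#'
#' @param uhat Nested list `uhat[[i]][[j]]` of N x m prediction vectors.
#' @param r Number of routing iterations (>= 1).
#' @param squash_const Squashing constant.
#' @param normalize_every_iter Also normalize the final sum before squash.
#' @param accumulate_logits Accumulate instead of overwrite logits.
#' @return List with `v` (list over classes of N x m type capsules), `c`
#'   (N x l x k coupling array), `s` (list over classes of the final raw
#'   weighted sums), and `scores` (N x k matrix of capsule lengths).
#' @export
caps_routing <- function(uhat, r, squash_const = 0.5,
                         normalize_every_iter = FALSE,
                         accumulate_logits = FALSE) {
  if (r < 1L) stop("routing requires r >= 1 iterations")
  l <- length(uhat)
  k <- length(uhat[[1L]])
  N <- nrow(uhat[[1L]][[1L]])
  b <- replicate(l, matrix(0, N, k), simplify = FALSE)
  cmat <- NULL
  s <- NULL
  for (iter in seq_len(r)) {
    cmat <- lapply(b, coupling_from_logits)
    s <- lapply(seq_len(k), function(j) {
      acc <- matrix(0, N, ncol(uhat[[1L]][[1L]]))
      for (i in seq_len(l)) acc <- acc + cmat[[i]][, j] * uhat[[i]][[j]]
      acc
    })
    if (iter < r) {
      s_use <- lapply(s, l2_normalize_rows)
      for (i in seq_len(l)) {
        bnew <- vapply(seq_len(k), function(j)
          rowSums(uhat[[i]][[j]] * s_use[[j]]), numeric(N))
        bnew <- matrix(bnew, N, k)
        b[[i]] <- if (accumulate_logits) b[[i]] + bnew else bnew
      }
    }
  }
  s_final <- if (normalize_every_iter) lapply(s, l2_normalize_rows) else s
  v <- lapply(s_final, squash, const = squash_const)
  scores <- vapply(v, function(vj) sqrt(rowSums(vj^2)), numeric(N))
  scores <- matrix(scores, N, k)
  c_arr <- array(0, dim = c(N, l, k))
  for (i in seq_len(l)) c_arr[, i, ] <- cmat[[i]]
  list(v = v, c = c_arr, s = s_final, scores = scores)
}

#' Full forward pass
#'
#' Runs encode, prediction vectors and routing; class scores are the type
#' capsule lengths (each in `[0, 1)`), interpreted as class probabilities.
#' The predicted class is the argmax, ties broken by the lowest class index.
#'
#' @param model A `caps_model`.
#' @param data A [modular_dataset()] or a bare list of blocks.
#' @return List with `scores` (N x k, columns named by class), `predicted`
#'   (integer class indices), `couplings` (N x l x k array), and `v`.
#' @export
caps_forward <- function(model, data) {
  blocks <- if (inherits(data, "modular_dataset")) data$blocks else data
  U <- caps_encode(blocks, model)
  uhat <- caps_predict_vectors(U, model$W)
  rt <- caps_routing(uhat, model$r, model$squash_const,
                     model$normalize_every_iter, model$accumulate_logits)
  colnames(rt$scores) <- model$class_names
  dimnames(rt$c) <- list(NULL, source_names(model$sources),
                         model$class_names)
  list(scores = rt$scores,
       predicted = max.col(rt$scores, ties.method = "first"),
       couplings = rt$c, v = rt$v)
}

#' Save / load a capsule model checkpoint
#'
#' Checkpoints are plain JSON: all encoder and routing weights, the source
#' specifications, class names and hyperparameters, plus a format-version
#' field. Loadable for inference and coupling extraction.
#'
#' @param model A `caps_model`.
#' @param path File path (`.json`).
#' @return `save_caps_model` returns `path` invisibly; `load_caps_model`
#'   returns the restored `caps_model`.
#' @export
save_caps_model <- function(model, path) {
  payload <- list(
    format = "modcaps-checkpoint", version = 1L,
    n = model$n, m = model$m, r = model$r,
    squash_const = model$squash_const,
    normalize_every_iter = model$normalize_every_iter,
    accumulate_logits = model$accumulate_logits,
    class_names = model$class_names,
    sources = lapply(model$sources, function(s)
      list(name = s$name, kind = s$kind, features = s$features)),
    W_p = model$W_p,
    W = model$W
  )
  # digits = I(17): 17 *significant* digits round-trip IEEE doubles exactly
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname save_caps_model
#' @export
load_caps_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(p$format) || p$format != "modcaps-checkpoint")
    stop("'", path, "' is not a modcaps checkpoint")
  # rebuild matrices from row-major nested lists; jsonlite's automatic
  # simplification would silently merge equal-shaped sources into 3-D arrays
  as_mat <- function(rows) do.call(rbind, lapply(rows, function(r)
    unlist(r, use.names = FALSE)))
  sources <- lapply(p$sources, function(s)
    source_spec(s$name, s$kind, unlist(s$features, use.names = FALSE)))
  W_p <- lapply(p$W_p, as_mat)
  W <- lapply(p$W, function(wi) lapply(wi, as_mat))
  p$class_names <- unlist(p$class_names, use.names = FALSE)
  structure(
    list(sources = sources, class_names = p$class_names,
         n = as.integer(p$n), m = as.integer(p$m), r = as.integer(p$r),
         squash_const = p$squash_const,
         normalize_every_iter = isTRUE(p$normalize_every_iter),
         accumulate_logits = isTRUE(p$accumulate_logits),
         W_p = W_p, W = W),
    class = "caps_model"
  )
}
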