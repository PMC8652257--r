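# Loss, optimization loop, evaluation metrics and the permutation-importance
# baseline.
#
# There is no automatic differentiation in this stack, so gradients are
# derived analytically. Backpropagation treats the routing coupling
# coefficients as constants of the forward pass (the routing procedure is not
# unrolled into the gradient); see the methods vignette for why this
# approximation is standard and what it changes.

#' Training configuration
#'
#' @param split_ratio Fraction of samples in the training split (stratified
#'   by class; default 0.9 for a 9:1 train/validation division).
#' @param epochs Number of passes over the training split (default 50).
#' @param batch_size Mini-batch size (default 128).
#' @param learning_rate Adam step size (default 1e-3).
#' @param seed Base RNG seed; repeat `t` uses `seed + t - 1`.
#' @param repeats Number of independent training repeats (default 9).
#' @param m_plus,m_minus,lambda_down Margin-loss parameters (defaults 0.9,
#'   0.1, 0.5).
#' @return A list of class `train_config`.
#' @export
train_config <- function(split_ratio = 0.9, epochs = 50L, batch_size = 128L,
                         learning_rate = 1e-3, seed = 1L, repeats = 9L,
                         m_plus = 0.9, m_minus = 0.1, lambda_down = 0.5) {
  stopifnot(split_ratio > 0, split_ratio < 1, epochs >= 1, batch_size >= 1,
            learning_rate > 0, repeats >= 1, m_plus > m_minus)
  structure(list(split_ratio = split_ratio, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 repeats = as.integer(repeats), m_plus = m_plus,
                 m_minus = m_minus, lambda_down = lambda_down),
            class = "train_config")
}

#' Margin loss for capsule lengths
#'
#' `sum_j [ y_j max(0, m_plus - score_j)^2
#'          + lambda (1 - y_j) max(0, score_j - m_minus)^2 ]`
#' with `y` the one-hot label. For a matrix of scores the mean over samples
#' is returned.
#'
#' @param scores Length-k vector, or N x k matrix, of capsule lengths in
#'   `[0, 1)`.
#' @param labels Class index in `1..k` (scalar or length-N vector).
#' @param m_plus,m_minus,lambda_down Loss parameters.
#' @return A scalar loss.
#' @export
margin_loss <- function(scores, labels, m_plus = 0.9, m_minus = 0.1,
                        lambda_down = 0.5) {
  scores <- if (is.null(dim(scores))) matrix(scores, 1L) else
    as.matrix(scores)
  k <- ncol(scores)
  labels <- as.integer(labels)
  if (any(labels < 1L) || any(labels > k) || anyNA(labels))
    stop("labels must be class indices in 1..", k)
  if (length(labels) != nrow(scores))
    stop("length(labels) != nrow(scores)")
  y <- matrix(0, nrow(scores), k)
  y[cbind(seq_len(nrow(scores)), labels)] <- 1
  per <- y * pmax(0, m_plus - scores)^2 +
    lambda_down * (1 - y) * pmax(0, scores - m_minus)^2
  mean(rowSums(per))
}

# dL/dscore for the margin loss, already divided by batch size.
margin_loss_grad <- function(scores, labels, m_plus, m_minus, lambda_down) {
  N <- nrow(scores)
  y <- matrix(0, N, ncol(scores))
  y[cbind(seq_len(N), labels)] <- 1
  (-2 * y * pmax(0, m_plus - scores) +
      2 * lambda_down * (1 - y) * pmax(0, scores - m_minus)) / N
}

# Forward pass that keeps the intermediates needed for gradients, then the
# analytic backward pass. Couplings are treated as constants (see vignette).
caps_grad_step <- function(model, blocks, labels, cfg) {
  l <- length(blocks)
  k <- length(model$class_names)
  h <- model$squash_const
  U <- caps_encode(blocks, model)
  uhat <- caps_predict_vectors(U, model$W)
  rt <- caps_routing(uhat, model$r, h, model$normalize_every_iter,
                     model$accumulate_logits)
  N <- nrow(rt$scores)
  loss <- margin_loss(rt$scores, labels, cfg$m_plus, cfg$m_minus,
                      cfg$lambda_down)
  g_score <- margin_loss_grad(rt$scores, labels, cfg$m_plus, cfg$m_minus,
                              cfg$lambda_down)
  # score_j = a^2/(h+a^2) with a = ||s_j||  =>  dscore/ds = 2h s/(h+a^2)^2
  g_s <- lapply(seq_len(k), function(j) {
    a2 <- rowSums(rt$s[[j]]^2)
    (g_score[, j] * 2 * h / (h + a2)^2) * rt$s[[j]]
  })
  gW <- vector("list", l)
  gWp <- vector("list", l)
  for (i in seq_len(l)) {
    gU_i <- matrix(0, N, model$n)
    gW[[i]] <- vector("list", k)
    for (j in seq_len(k)) {
      g_uhat <- rt$c[, i, j] * g_s[[j]]
      gW[[i]][[j]] <- crossprod(g_uhat, U[[i]])      # m x n
      gU_i <- gU_i + g_uhat %*% model$W[[i]][[j]]
    }
    g_pre <- gU_i * (1 - U[[i]]^2)
    gWp[[i]] <- crossprod(g_pre, as.matrix(blocks[[i]]))  # n x r_i
  }
  list(loss = loss, gW = gW, gWp = gWp)
}

# Minimal Adam over the model's two weight banks.
adam_state <- function(model) {
  zeros <- function(w) lapply(w, function(x)
    if (is.list(x)) lapply(x, function(y) y * 0) else x * 0)
  list(mWp = zeros(model$W_p), vWp = zeros(model$W_p),
       mW = zeros(model$W), vW = zeros(model$W), t = 0L)
}

adam_update <- function(model, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (i in seq_along(model$W_p)) {
    g <- grads$gWp[[i]]
    state$mWp[[i]] <- beta1 * state$mWp[[i]] + (1 - beta1) * g
    state$vWp[[i]] <- beta2 * state$vWp[[i]] + (1 - beta2) * g^2
    model$W_p[[i]] <- model$W_p[[i]] -
      lr * (state$mWp[[i]] / corr1) / (sqrt(state$vWp[[i]] / corr2) + eps)
    for (j in seq_along(model$W[[i]])) {
      g <- grads$gW[[i]][[j]]
      state$mW[[i]][[j]] <- beta1 * state$mW[[i]][[j]] + (1 - beta1) * g
      state$vW[[i]][[j]] <- beta2 * state$vW[[i]][[j]] + (1 - beta2) * g^2
      model$W[[i]][[j]] <- model$W[[i]][[j]] -
        lr * (state$mW[[i]][[j]] / corr1) /
        (sqrt(state$vW[[i]][[j]] / corr2) + eps)
    }
  }
  list(model = model, state = state)
}

#' Stratified train/validation split
#'
#' @param labels Integer class labels in `1..k`.
#' @param split_ratio Training fraction.
#' @param seed RNG seed.
#' @return List with integer index vectors `train` and `val`. Class
#'   proportions are preserved to within one sample per class.
#' @export
stratified_split <- function(labels, split_ratio = 0.9, seed = 1L) {
  set.seed(seed)
  train <- integer(0)
  for (cls in sort(unique(labels))) {
    idx <- which(labels == cls)
    n_tr <- round(length(idx) * split_ratio)
    n_tr <- min(max(n_tr, 1L), length(idx) - 1L)
    train <- c(train, sample(idx, n_tr))
  }
  train <- sort(train)
  list(train = train, val = setdiff(seq_along(labels), train))
}

subset_blocks <- function(blocks, idx)
  lapply(blocks, function(b) b[idx, , drop = FALSE])

#' Train a capsule model
#'
#' Stratified split, then mini-batch Adam on the margin loss through the
#' full forward pass (analytic gradients, couplings detached). No early
#' stopping: the final-epoch model is returned.
#'
#' @param dataset A labeled [modular_dataset()] with at least two classes
#'   and at least two samples per class.
#' @param cfg A [train_config()].
#' @param model Optional pre-initialized `caps_model` (otherwise built from
#'   the dataset's sources under `cfg$seed`).
#' @param n Primary-capsule length used when building the model.
#' @param m Type-capsule length used when building the model.
#' @param r Routing iterations used when building the model.
#' @param verbose Print per-epoch progress.
#' @return An object of class `caps_fit`: `model`, `history` (data frame of
#'   epoch, train_loss, val_accuracy), `split`, `eval` (an [evaluate()]
#'   report on the validation split), and `config`.
#' @export
train_caps <- function(dataset, cfg = train_config(), model = NULL,
                       n = 8L, m = 16L, r = 3L, verbose = FALSE) {
  stopifnot(inherits(dataset, "modular_dataset"))
  if (is.null(dataset$labels)) stop("dataset has no labels")
  labels <- dataset$labels
  k <- length(dataset$class_names)
  if (k < 2L) stop("need at least two classes")
  counts <- tabulate(labels, nbins = k)
  if (any(counts < 2L))
    stop("class '", dataset$class_names[which(counts < 2L)[1L]],
         "' has fewer than 2 samples")
  split <- stratified_split(labels, cfg$split_ratio, cfg$seed)
  if (is.null(model))
    model <- new_caps_model(dataset$sources, dataset$class_names,
                            n = n, m = m, r = r, seed = cfg$seed)
  tr_blocks <- subset_blocks(dataset$blocks, split$train)
  tr_labels <- labels[split$train]
  va_blocks <- subset_blocks(dataset$blocks, split$val)
  va_labels <- labels[split$val]
  state <- adam_state(model)
  n_tr <- length(tr_labels)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_accuracy = numeric(0))
  set.seed(cfg$seed + 10000L)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n_tr)
    ep_loss <- 0
    n_batches <- 0L
    for (start in seq(1L, n_tr, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n_tr)]
      step <- caps_grad_step(model, subset_blocks(tr_blocks, idx),
                             tr_labels[idx], cfg)
      upd <- adam_update(model, step, state, cfg$learning_rate)
      model <- upd$model
      state <- upd$state
      ep_loss <- ep_loss + step$loss
      n_batches <- n_batches + 1L
    }
    va_pred <- caps_forward(model, va_blocks)$predicted
    va_acc <- mean(va_pred == va_labels)
    history <- rbind(history,
                     data.frame(epoch = ep, train_loss = ep_loss / n_batches,
                                val_accuracy = va_acc))
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  val_acc %.3f", ep,
                      ep_loss / n_batches, va_acc))
  }
  val_ds <- modular_dataset(dataset$sources, va_blocks, va_labels,
                            dataset$class_names)
  structure(list(model = model, history = history, split = split,
                 eval = evaluate(model, val_ds), config = cfg),
            class = "caps_fit")
}

#' @export
print.caps_fit <- function(x, ...) {
  cat(sprintf("<caps_fit> %d epochs | final val accuracy %.3f\n",
              nrow(x$history), utils::tail(x$history$val_accuracy, 1L)))
  invisible(x)
}

#' Train several independent repeats
#'
#' Repeat `t` uses seed `cfg$seed + t - 1` for the split, initialization and
#' batching, giving `cfg$repeats` independently trained models on the same
#' dataset.
#'
#' @inheritParams train_caps
#' @return List of `caps_fit` objects, one per repeat.
#' @export
train_repeats <- function(dataset, cfg = train_config(), n = 8L, m = 16L,
                          r = 3L, verbose = FALSE) {
  lapply(seq_len(cfg$repeats), function(t) {
    cfg_t <- cfg
    cfg_t$seed <- cfg$seed + t - 1L
    cfg_t$repeats <- 1L
    train_caps(dataset, cfg_t, n = n, m = m, r = r, verbose = verbose)
  })
}

# Rank-based one-vs-rest AUC with midrank tie handling.
auc_binary <- function(scores, positive) {
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  rk <- rank(scores)
  (sum(rk[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Evaluate a model (or raw scores) on labeled data
#'
#' One-vs-rest AUC per class with the capsule lengths as scores, overall
#' accuracy from the argmax, macro F1, and the confusion matrix. A class
#' absent from the data gets `NA` AUC/F1 and is excluded from the macro
#' averages.
#'
#' @param model A `caps_model`, or an N x k score matrix.
#' @param dataset A labeled [modular_dataset()]; ignored except for labels
#'   when `model` is already a score matrix.
#' @return A list of class `caps_eval`: `auc` (named per class), `accuracy`,
#'   `macro_f1`, `f1` (per class), `confusion` (true x predicted).
#' @export
evaluate <- function(model, dataset) {
  labels <- dataset$labels
  if (is.null(labels)) stop("dataset has no labels")
  k <- length(dataset$class_names)
  scores <- if (is.matrix(model)) model else
    caps_forward(model, dataset)$scores
  pred <- max.col(scores, ties.method = "first")
  auc <- vapply(seq_len(k), function(j)
    auc_binary(scores[, j], labels == j), numeric(1))
  names(auc) <- dataset$class_names
  confusion <- table(factor(labels, levels = seq_len(k)),
                     factor(pred, levels = seq_len(k)),
                     dnn = c("true", "predicted"))
  dimnames(confusion) <- list(true = dataset$class_names,
                              predicted = dataset$class_names)
  f1 <- vapply(seq_len(k), function(j) {
    tp <- confusion[j, j]
    support <- sum(confusion[j, ])
    if (support == 0L) return(NA_real_)
    prec_den <- sum(confusion[, j])
    prec <- if (prec_den == 0L) 0 else tp / prec_den
    rec <- tp / support
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }, numeric(1))
  names(f1) <- dataset$class_names
  structure(list(auc = auc, accuracy = mean(pred == labels),
                 macro_f1 = mean(f1, na.rm = TRUE), f1 = f1,
                 confusion = unclass(confusion)),
            class = "caps_eval")
}

#' @export
print.caps_eval <- function(x, ...) {
  cat(sprintf("<caps_eval> accuracy %.3f | macro F1 %.3f | mean AUC %.3f\n",
              x$accuracy, x$macro_f1, mean(x$auc, na.rm = TRUE)))
  invisible(x)
}

#' Per-feature permutation importance
#'
#' The comparison baseline used against coupling-based importance: for each
#' input feature, shuffle that column across samples (seeded), recompute the
#' mean one-vs-rest AUC, and report baseline minus shuffled, averaged over
#' `n_rep` shuffles. Any scorer can be plugged in through `scorer`, a
#' function mapping a list of blocks to an N x k score matrix.
#'
#' @param scorer A `caps_model` or a `function(blocks) -> N x k matrix`.
#' @param dataset A labeled [modular_dataset()].
#' @param seed RNG seed for the shuffles.
#' @param n_rep Shuffle repetitions per feature (default 5).
#' @return A data frame with columns `source`, `feature`, `importance`
#'   (mean AUC drop).
#' @export
permutation_importance <- function(scorer, dataset, seed = 1L, n_rep = 5L) {
  if (inherits(scorer, "caps_model")) {
    model <- scorer
    scorer <- function(blocks) caps_forward(model, blocks)$scores
  }
  labels <- dataset$labels
  if (is.null(labels)) stop("dataset has no labels")
  k <- length(dataset$class_names)
  mean_auc <- function(scores)
    mean(vapply(seq_len(k), function(j)
      auc_binary(scores[, j], labels == j), numeric(1)), na.rm = TRUE)
  baseline <- mean_auc(scorer(dataset$blocks))
  set.seed(seed)
  N <- n_samples(dataset)
  rows <- list()
  for (i in seq_along(dataset$sources)) {
    src <- dataset$sources[[i]]
    for (f in seq_len(src$length)) {
      drops <- vapply(seq_len(n_rep), function(rep) {
        blocks <- dataset$blocks
        col <- blocks[[i]][, f]
        blocks[[i]][, f] <- col[sample.int(N)]
        baseline - mean_auc(scorer(blocks))
      }, numeric(1))
      rows[[length(rows) + 1L]] <-
        data.frame(source = src$name, feature = src$features[f],
                   importance = mean(drops))
    }
  }
  do.call(rbind, rows)
}

#' Sum per-feature permutation importances within each source
#'
#' @param imp The data frame returned by [permutation_importance()].
#' @param sources Optional list of [source_spec()] fixing the source order.
#' @return A named numeric vector, one summed score per source.
#' @export
group_importance <- function(imp, sources = NULL) {
  agg <- tapply(imp$importance, imp$source, sum)
  ord <- if (is.null(sources)) unique(imp$source) else source_names(sources)
  out <- as.numeric(agg[ord])
  names(out) <- ord
  out
}

#' Pearson correlation between two importance vectors
#'
#' @param a,b Equal-length (>= 3) non-constant numeric vectors of per-source
#'   scores.
#' @return The Pearson correlation coefficient.
#' @export
importance_correlation <- function(a, b) {
  if (length(a) != length(b)) stop("importance vectors differ in length")
  if (length(a) < 3L) stop("need at least 3 sources to correlate")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("undefined correlation: constant importance vector")
  stats::cor(a, b)
}
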