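# Independent oracles: literal scalar-loop implementations kept free of the
# package's vectorized code paths.

# Dynamic routing for ONE sample, transcribed step by step with scalar loops.
# uhat: l x k x m array. Returns list(v = k x m, c = l x k).
oracle_routing <- function(uhat, r, h = 0.5, normalize_every_iter = FALSE,
                           accumulate_logits = FALSE) {
  l <- dim(uhat)[1]; k <- dim(uhat)[2]; m <- dim(uhat)[3]
  b <- matrix(0, l, k)
  cc <- matrix(NA_real_, l, k)
  s <- matrix(0, k, m)
  for (iter in seq_len(r)) {
    for (i in seq_len(l)) {                       # softmax per primary capsule
      mx <- max(b[i, ])
      e <- exp(b[i, ] - mx)
      cc[i, ] <- e / sum(e)
    }
    for (j in seq_len(k)) {                       # weighted sum
      acc <- rep(0, m)
      for (i in seq_len(l))
        for (d in seq_len(m)) acc[d] <- acc[d] + cc[i, j] * uhat[i, j, d]
      s[j, ] <- acc
    }
    if (iter < r) {                               # normalize + logit update
      s_use <- s
      for (j in seq_len(k)) {
        nrm <- sqrt(sum(s[j, ]^2))
        if (nrm > 0) s_use[j, ] <- s[j, ] / nrm
      }
      for (i in seq_len(l)) for (j in seq_len(k)) {
        dot <- 0
        for (d in seq_len(m)) dot <- dot + uhat[i, j, d] * s_use[j, d]
        b[i, j] <- if (accumulate_logits) b[i, j] + dot else dot
      }
    }
  }
  v <- matrix(0, k, m)
  for (j in seq_len(k)) {
    sj <- s[j, ]
    if (normalize_every_iter) {
      nrm <- sqrt(sum(sj^2))
      if (nrm > 0) sj <- sj / nrm
    }
    n2 <- sum(sj^2)
    if (n2 > 0) v[j, ] <- (n2 / (h + n2)) * sj / sqrt(n2)
  }
  list(v = v, c = cc)
}

# Brute-force pairwise concordance AUC; ties count one half.
oracle_auc <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  conc <- 0
  for (p in pos) for (q in neg)
    conc <- conc + (p > q) + 0.5 * (p == q)
  conc / (length(pos) * length(neg))
}

# Pearson correlation from the covariance / sigma definition.
oracle_pearson <- function(a, b) {
  ma <- sum(a) / length(a)
  mb <- sum(b) / length(b)
  cov <- sum((a - ma) * (b - mb)) / (length(a) - 1)
  sa <- sqrt(sum((a - ma)^2) / (length(a) - 1))
  sb <- sqrt(sum((b - mb)^2) / (length(b) - 1))
  cov / (sa * sb)
}

# Double-loop matrix multiply.
oracle_matmul <- function(A, B) {
  out <- matrix(0, nrow(A), ncol(B))
  for (i in seq_len(nrow(A)))
    for (j in seq_len(ncol(B)))
      out[i, j] <- sum(A[i, ] * B[, j])
  out
}

# Batch wrapper: run the scalar routing oracle sample by sample on the
# nested-list uhat layout used by the package.
oracle_routing_batch <- function(uhat_nested, r, h = 0.5, ...) {
  l <- length(uhat_nested); k <- length(uhat_nested[[1]])
  m <- ncol(uhat_nested[[1]][[1]]); N <- nrow(uhat_nested[[1]][[1]])
  v <- array(0, c(N, k, m)); cc <- array(0, c(N, l, k))
  for (smp in seq_len(N)) {
    u1 <- array(0, c(l, k, m))
    for (i in seq_len(l)) for (j in seq_len(k))
      u1[i, j, ] <- uhat_nested[[i]][[j]][smp, ]
    res <- oracle_routing(u1, r, h, ...)
    v[smp, , ] <- res$v
    cc[smp, , ] <- res$c
  }
  list(v = v, c = cc)
}
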