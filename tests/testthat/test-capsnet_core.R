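test_that("squash obeys its norm law, zero case and monotonicity", {
  expect_identical(squash(c(0, 0, 0)), c(0, 0, 0))
  # ||s||^2 = 0.5 maps to norm 0.5 along the same direction
  expect_equal(squash(c(sqrt(0.5), 0)), c(0.5, 0), tolerance = 1e-12)
  norms <- seq(0.01, 100, length.out = 400)
  out <- vapply(norms, function(a) sqrt(sum(squash(c(a, 0, 0))^2)),
                numeric(1))
  expect_equal(out, norms^2 / (0.5 + norms^2), tolerance = 1e-6)
  expect_true(all(diff(out) > 0))
  expect_true(all(out < 1))
  # direction is preserved, matrix rows handled independently
  s <- matrix(c(3, 4, 0, 0), 2, 2, byrow = TRUE)
  sq <- squash(s)
  expect_equal(sq[1, ] / sqrt(sum(sq[1, ]^2)), c(3, 4) / 5, tolerance = 1e-12)
  expect_identical(sq[2, ], c(0, 0))
  # configurable constant
  expect_equal(sqrt(sum(squash(c(2, 0), const = 1)^2)), 4 / 5,
               tolerance = 1e-12)
})

test_that("coupling_from_logits is a stabilized per-row softmax", {
  expect_equal(coupling_from_logits(matrix(0, 2, 3)),
               matrix(1 / 3, 2, 3), tolerance = 1e-12)
  big <- coupling_from_logits(matrix(c(1000, 0), 1))
  expect_false(anyNA(big))
  expect_equal(big[1, ], c(1, 0), tolerance = 1e-12)
  expect_equal(coupling_from_logits(matrix(c(log(2), 0), 1))[1, ],
               c(2 / 3, 1 / 3), tolerance = 1e-9)
  set.seed(3)
  b <- matrix(rnorm(40), 8, 5)
  cc <- coupling_from_logits(b)
  expect_equal(rowSums(cc), rep(1, 8), tolerance = 1e-12)
  expect_true(all(cc > 0))
})

test_that("caps_encode equals tanh of a double-loop matmul and checks shapes", {
  specs <- list(source_spec("a", "numeric", paste0("f", 1:3)),
                source_spec("b", "numeric", paste0("h", 1:2)))
  model <- new_caps_model(specs, c("c1", "c2"), n = 4, m = 3, seed = 9)
  # zero input -> zero capsules; saturation through tanh
  U0 <- caps_encode(list(matrix(0, 5, 3), matrix(0, 5, 2)), model)
  expect_true(all(U0[[1]] == 0) && all(U0[[2]] == 0))
  model_id <- model
  model_id$W_p[[1]] <- diag(3)
  model_id$n <- 3L
  u <- tanh(c(10, -10, 0))
  got <- caps_encode(list(matrix(c(10, -10, 0), 1), matrix(0, 1, 2)),
                     model_id)[[1]]
  expect_equal(got[1, ], c(1, -1, 0), tolerance = 1e-4)
  set.seed(11)
  x <- list(matrix(rnorm(15), 5, 3), matrix(rnorm(10), 5, 2))
  U <- caps_encode(x, model)
  for (i in 1:2)
    expect_equal(U[[i]], tanh(oracle_matmul(x[[i]], t(model$W_p[[i]]))),
                 tolerance = 1e-6)
  expect_error(caps_encode(list(matrix(0, 5, 4), matrix(0, 5, 2)), model),
               "source 'a'")
})

test_that("caps_predict_vectors matches a nested-loop oracle", {
  set.seed(13)
  l <- 2; k <- 3; n <- 4; m <- 2; N <- 6
  U <- lapply(1:l, function(i) matrix(rnorm(N * n), N, n))
  W <- lapply(1:l, function(i) lapply(1:k, function(j)
    matrix(rnorm(m * n), m, n)))
  uhat <- caps_predict_vectors(U, W)
  for (i in 1:l) for (j in 1:k)
    expect_equal(uhat[[i]][[j]], oracle_matmul(U[[i]], t(W[[i]][[j]])),
                 tolerance = 1e-6)
  # zero capsules give zero predictions; identity weights pass through
  U0 <- lapply(U, function(u) u * 0)
  expect_true(all(vapply(caps_predict_vectors(U0, W), function(x)
    all(vapply(x, function(y) all(y == 0), logical(1))), logical(1))))
  Wid <- lapply(1:l, function(i) lapply(1:k, function(j) diag(n)))
  uid <- caps_predict_vectors(U, Wid)
  for (i in 1:l) for (j in 1:k) expect_equal(uid[[i]][[j]], U[[i]])
})

test_that("single-iteration routing keeps couplings uniform", {
  uhat <- random_uhat(N = 4, l = 3, k = 2, m = 5, seed = 21)
  rt <- caps_routing(uhat, r = 1)
  expect_equal(as.vector(rt$c), rep(0.5, 4 * 3 * 2), tolerance = 1e-12)
  sj <- Reduce(`+`, lapply(1:3, function(i) uhat[[i]][[1]])) / 2
  expect_equal(rt$v[[1]], squash(sj), tolerance = 1e-12)
  expect_error(caps_routing(uhat, r = 0), "r >= 1")
})

test_that("routing matches the scalar-loop oracle on random cases", {
  for (cfg in list(c(2, 2, 2, 2), c(3, 2, 4, 3), c(1, 3, 2, 2),
                   c(4, 3, 3, 1))) {
    uhat <- random_uhat(N = 3, l = cfg[1], k = cfg[2], m = cfg[3],
                        seed = sum(cfg))
    rt <- caps_routing(uhat, r = cfg[4])
    orc <- oracle_routing_batch(uhat, r = cfg[4])
    for (j in seq_len(cfg[2]))
      expect_equal(rt$v[[j]], orc$v[, j, , drop = TRUE] |>
                     matrix(nrow = 3), tolerance = 1e-6)
    expect_equal(rt$c, orc$c, tolerance = 1e-6)
  }
})

test_that("routing variants (accumulate, normalize-final) follow the oracle", {
  uhat <- random_uhat(N = 2, l = 3, k = 3, m = 4, seed = 33)
  for (acc in c(FALSE, TRUE)) for (nrm in c(FALSE, TRUE)) {
    rt <- caps_routing(uhat, r = 3, normalize_every_iter = nrm,
                       accumulate_logits = acc)
    orc <- oracle_routing_batch(uhat, r = 3, normalize_every_iter = nrm,
                                accumulate_logits = acc)
    expect_equal(rt$c, orc$c, tolerance = 1e-6)
    for (j in 1:3)
      expect_equal(rt$v[[j]], matrix(orc$v[, j, ], nrow = 2),
                   tolerance = 1e-6)
  }
})

test_that("prediction vectors independent of the source symmetrize couplings", {
  set.seed(17)
  # identical for every (i, j): all agreement dots equal, couplings uniform
  one <- matrix(rnorm(4 * 3), 4, 3)
  uhat_flat <- lapply(1:3, function(i) lapply(1:2, function(j) one))
  rt_flat <- caps_routing(uhat_flat, r = 3)
  expect_equal(as.vector(rt_flat$c), rep(0.5, 4 * 3 * 2), tolerance = 1e-9)
  # identical across sources only: every source gets the same coupling row
  base <- lapply(1:2, function(j) matrix(rnorm(4 * 3), 4, 3))
  uhat <- lapply(1:3, function(i) base)
  rt <- caps_routing(uhat, r = 3)
  for (i in 2:3)
    expect_equal(rt$c[, i, ], rt$c[, 1, ], tolerance = 1e-9)
})

test_that("coupling rows are a probability distribution at any r", {
  for (r in 1:3) {
    uhat <- random_uhat(N = 5, l = 4, k = 3, m = 2, seed = r)
    rt <- caps_routing(uhat, r = r)
    sums <- apply(rt$c, c(1, 2), sum)
    expect_equal(as.vector(sums), rep(1, 20), tolerance = 1e-6)
    expect_true(all(rt$c > 0))
    expect_true(all(rt$scores >= 0 & rt$scores < 1))
  }
})

test_that("permuting primary capsules permutes couplings, leaves v intact", {
  uhat <- random_uhat(N = 3, l = 4, k = 2, m = 3, seed = 55)
  perm <- c(3, 1, 4, 2)
  rt1 <- caps_routing(uhat, r = 3)
  rt2 <- caps_routing(uhat[perm], r = 3)
  expect_equal(rt2$c, rt1$c[, perm, , drop = FALSE], tolerance = 1e-6)
  for (j in 1:2) expect_equal(rt2$v[[j]], rt1$v[[j]], tolerance = 1e-6)
})

test_that("forward pass composes encode, prediction and routing", {
  cfg <- planted_config(30, 2, 3, seed = 77)
  gen <- generate_modular(cfg)
  model <- new_caps_model(gen$dataset$sources, gen$dataset$class_names,
                          n = 4, m = 3, seed = 77)
  fw <- caps_forward(model, gen$dataset)
  expect_true(all(fw$scores >= 0 & fw$scores < 1))
  # independent composition through the oracles
  U <- lapply(seq_along(gen$dataset$blocks), function(i)
    tanh(oracle_matmul(gen$dataset$blocks[[i]], t(model$W_p[[i]]))))
  uhat <- lapply(seq_along(U), function(i) lapply(1:2, function(j)
    oracle_matmul(U[[i]], t(model$W[[i]][[j]]))))
  orc <- oracle_routing_batch(uhat, r = model$r)
  scores <- apply(orc$v, c(1, 2), function(v) sqrt(sum(v^2)))
  expect_equal(unname(fw$scores), scores, tolerance = 1e-5)
  expect_identical(fw$predicted, max.col(scores, ties.method = "first"))
  # degenerate: all-zero input and zero encoders -> equal scores, class 1
  model0 <- model
  model0$W_p <- lapply(model0$W_p, function(w) w * 0)
  fw0 <- caps_forward(model0, gen$dataset)
  expect_equal(fw0$scores[, 1], fw0$scores[, 2], tolerance = 1e-12)
  expect_true(all(fw0$predicted == 1L))
})

test_that("forward is deterministic for fixed input", {
  cfg <- planted_config(10, 2, 2, seed = 5)
  gen <- generate_modular(cfg)
  model <- new_caps_model(gen$dataset$sources, gen$dataset$class_names,
                          seed = 5)
  f1 <- caps_forward(model, gen$dataset)
  f2 <- caps_forward(model, gen$dataset)
  expect_identical(f1$scores, f2$scores)
  expect_identical(f1$couplings, f2$couplings)
})

test_that("checkpoints round-trip through JSON", {
  cfg <- planted_config(8, 2, 2, seed = 31)
  gen <- generate_modular(cfg)
  model <- new_caps_model(gen$dataset$sources, gen$dataset$class_names,
                          n = 3, m = 4, seed = 31)
  f <- withr::local_tempfile(fileext = ".json")
  save_caps_model(model, f)
  back <- load_caps_model(f)
  expect_identical(back$class_names, model$class_names)
  expect_identical(vapply(back$sources, `[[`, character(1), "name"),
                   vapply(model$sources, `[[`, character(1), "name"))
  expect_equal(back$W_p, model$W_p, tolerance = 0, ignore_attr = TRUE)
  expect_equal(back$W, model$W, tolerance = 0, ignore_attr = TRUE)
  fw1 <- caps_forward(model, gen$dataset)
  fw2 <- caps_forward(back, gen$dataset)
  expect_identical(fw1$scores, fw2$scores)
  not_ck <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(format = "other"), not_ck)
  expect_error(load_caps_model(not_ck), "not a modcaps checkpoint")
})
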