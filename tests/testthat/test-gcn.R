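test_that("graph convolution matches dense matrix arithmetic", {
  set.seed(41)
  # isolated node with identity weights: self-loop normalization is 1
  X1 <- matrix(abs(rnorm(4)), 1)
  out1 <- graph_conv(X1, matrix(0, 1, 1), diag(4))
  expect_equal(out1, X1, ignore_attr = TRUE)
  # random small graph vs explicit D^{-1/2}(A+I)D^{-1/2} X W
  A <- random_adjacency(6, 0.5)
  X <- matrix(rnorm(6 * 4), 6)
  W <- matrix(rnorm(4 * 3), 4)
  Ah <- A + diag(6)
  Dm <- diag(1 / sqrt(rowSums(Ah)))
  expect_equal(graph_conv(X, A, W), pmax(Dm %*% Ah %*% Dm %*% X %*% W, 0),
               tolerance = 1e-6)
  # permutation equivariance
  perm <- sample(6)
  expect_equal(graph_conv(X[perm, ], A[perm, perm], W),
               graph_conv(X, A, W)[perm, ], tolerance = 1e-10)
})

test_that("TopK pooling keeps the argsort-selected nodes and gates features", {
  set.seed(42)
  X <- matrix(rnorm(8 * 5), 8)
  A <- random_adjacency(8, 0.4)
  p <- rnorm(5)
  pool <- topk_pool(X, A, 3, p)
  s <- as.numeric(X %*% p) / sqrt(sum(p^2))
  expect_setequal(pool$kept, order(-s)[1:3])
  expect_equal(pool$X, X[pool$kept, ] * tanh(s[pool$kept]),
               ignore_attr = TRUE)
  expect_equal(pool$A, A[pool$kept, pool$kept], ignore_attr = TRUE)
  # k = n keeps everything (gated only); k = 1 keeps the max scorer
  full <- topk_pool(X, A, 8, p)
  expect_equal(sort(full$kept), 1:8)
  one <- topk_pool(X, A, 1, p)
  expect_equal(one$kept, which.max(s))
  expect_error(topk_pool(X, A, 9, p), "exceeds")
})

test_that("forward pass traverses the documented architecture", {
  s <- tiny_dataset()$fused[[1]]
  cfg <- gcn_config("fused", seed = 2)
  fw <- gcn_forward(gcn_init(cfg), s, cfg, trace = TRUE)
  expect_equal(fw$trace$node_counts, c(20, 10, 1))
  expect_equal(fw$trace$widths, c(13, 30, 60, 90, 2))
  expect_length(fw$logits, 2)
  expect_true(all(is.finite(fw$logits)))
  pr <- exp(fw$logits) / sum(exp(fw$logits))
  expect_equal(sum(pr), 1)
})

test_that("graph-level logits are invariant under node permutation", {
  s <- tiny_dataset()$fused[[2]]
  cfg <- gcn_config("fused", seed = 3)
  par <- gcn_init(cfg)
  base <- gcn_forward(par, s, cfg)$logits
  set.seed(43)
  for (rep in 1:3) {
    perm <- sample(20)
    sp <- permute_sample(s, perm)
    expect_equal(gcn_forward(par, sp, cfg)$logits, base, tolerance = 1e-10)
  }
})

test_that("analytic gradients match central finite differences", {
  s <- tiny_dataset()$fused[[1]]
  cfg <- gcn_config("fused", seed = 4)
  par <- gcn_init(cfg)
  lg <- gcn_loss_grad(par, list(s), cfg)
  set.seed(44)
  h <- 1e-5
  for (nm in names(par)) {
    for (i in sample(length(par[[nm]]), min(4, length(par[[nm]])))) {
      pp <- par; pp[[nm]][i] <- pp[[nm]][i] + h
      pm <- par; pm[[nm]][i] <- pm[[nm]][i] - h
      num <- (gcn_loss_grad(pp, list(s), cfg)$loss -
                gcn_loss_grad(pm, list(s), cfg)$loss) / (2 * h)
      an <- lg$grads[[nm]][i]
      expect_lt(abs(num - an) / max(1e-8, abs(num) + abs(an)), 1e-4)
    }
  }
})

test_that("training is deterministic and fits separable data", {
  ds <- small_graph_dataset()$fused
  cfg <- gcn_config("fused", epochs = 120, lr = 5e-3, seed = 7)
  m1 <- gcn_train(ds, cfg)
  m2 <- gcn_train(ds, cfg)
  expect_identical(tail(m1$history, 1), tail(m2$history, 1))
  expect_identical(m1$par$W4, m2$par$W4)
  y <- vapply(ds, `[[`, 0L, "label")
  acc <- mean(gcn_predict(m1, ds)$labels == y)
  expect_gte(acc, 0.95)
  # smoothed loss trend decreases on separable data
  sm <- stats::filter(m1$history, rep(1 / 10, 10), sides = 1)
  sm <- sm[!is.na(sm)]
  expect_lt(tail(sm, 1), sm[1])
  expect_error(gcn_train(ds[y == 1], cfg), "both classes")
})

test_that("unimodal branches accept 14- and 6-node graphs", {
  ds <- small_graph_dataset()
  for (mode in c("eeg", "fnirs")) {
    cfg <- gcn_config(mode, epochs = 60, lr = 5e-3, seed = 8)
    m <- gcn_train(ds[[mode]], cfg)
    pd <- gcn_predict(m, ds[[mode]])
    expect_length(pd$labels, length(ds[[mode]]))
    expect_true(all(pd$prob_ms >= 0 & pd$prob_ms <= 1))
  }
})

test_that("stratified folds keep class proportions within one sample", {
  ds <- small_graph_dataset()$fused
  y <- vapply(ds, `[[`, 0L, "label")
  cfg <- gcn_config("fused", epochs = 30, lr = 5e-3, seed = 9)
  rep_cv <- evaluate_cv(ds, cfg, folds = 4)
  expect_equal(rep_cv$folds, 4)
  expect_equal(nrow(rep_cv$per_fold), 4)
  for (f in seq_len(4)) {
    truth <- rep_cv$predictions[[f]]$truth
    expect_lte(abs(sum(truth == 1) - sum(y == 1) / 4), 1)
    # metrics recomputed from stored predictions match the report
    m <- binary_metrics(truth, rep_cv$predictions[[f]]$pred)
    expect_equal(unname(m), unname(unlist(rep_cv$per_fold[f, ])))
  }
  expect_error(evaluate_cv(ds, cfg, folds = 20), "at least 20")
})

test_that("confusion-matrix metrics follow their closed forms", {
  # all-positive predictor on a 61/75 split
  truth <- c(rep(0, 61), rep(1, 75))
  pred <- rep(1, 136)
  m <- binary_metrics(truth, pred)
  expect_equal(unname(m["recall"]), 1)
  expect_equal(unname(m["precision"]), 75 / 136)
  expect_equal(unname(m["f1"]),
               2 * (75 / 136) / (75 / 136 + 1))
  # no positives predicted
  m0 <- binary_metrics(truth, rep(0, 136))
  expect_equal(unname(m0["f1"]), 0)
  expect_equal(unname(m0["accuracy"]), 61 / 136)
})

test_that("grid search evaluates every combination and picks the dominant one", {
  ds <- small_graph_dataset()$fused
  cfg <- gcn_config("fused", epochs = 40, seed = 10)
  single <- grid_search(ds, list(lr = 5e-3), cfg, folds = 3)
  expect_equal(single$best$lr, 5e-3)
  expect_equal(nrow(single$results), 1)
  gs <- grid_search(ds, list(lr = c(5e-3, 1e3)), cfg, folds = 3)
  expect_equal(nrow(gs$results), 2)
  expect_equal(gs$best$lr, 5e-3)   # the sane configuration dominates
  expect_true(all(c("f1", "accuracy") %in% names(gs$results)))
  expect_error(grid_search(ds, list(), cfg), "non-empty")
})
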