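# Graph convolutional classifier for whole-graph motion-sickness
# recognition. Forward/backward passes are written out explicitly in
# dense matrix algebra; graphs here have at most 20 nodes, so dense
# propagation is both the simplest and the fastest option, and exact
# analytic gradients keep training deterministic and testable against
# finite differences.

#' GCN training configuration
#'
#' Architecture (fused mode): two parallel modality branch convolutions
#' 13 -> 30, a fusion convolution 30 -> 60 on the bimodal adjacency, TopK
#' pooling 20 -> 10, a convolution 60 -> 90, TopK pooling 10 -> 1, and a
#' linear read-out 90 -> 2. Unimodal mode uses a single branch with pool
#' sizes n -> ceil(n/2) -> 1.
#'
#' @param mode `"fused"`, `"eeg"`, or `"fnirs"`.
#' @param d_in Input feature width (13).
#' @param d_branch,d_fuse,d_deep Widths after the branch, fusion, and deep
#'   convolutions (30, 60, 90).
#' @param lr Adam learning rate.
#' @param weight_decay L2 penalty strength.
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param seed RNG seed controlling init and batching.
#' @return A `gcn_config` list.
#' @export
gcn_config <- function(mode = c("fused", "eeg", "fnirs"), d_in = 13,
                       d_branch = 30, d_fuse = 60, d_deep = 90,
                       lr = 1e-3, weight_decay = 5e-4, epochs = 200,
                       batch_size = 16, seed = 1L) {
  mode <- match.arg(mode)
  structure(list(mode = mode, d_in = d_in, d_branch = d_branch,
                 d_fuse = d_fuse, d_deep = d_deep, lr = lr,
                 weight_decay = weight_decay, epochs = epochs,
                 batch_size = batch_size, seed = as.integer(seed)),
            class = "gcn_config")
}

# Symmetric normalization with self-loops: D^{-1/2} (A + I) D^{-1/2}.
norm_adj <- function(A) {
  Ah <- A + diag(nrow(A))
  d <- rowSums(Ah)
  s <- 1 / sqrt(d)
  Ah * outer(s, s)
}

glorot <- function(n_in, n_out) {
  r <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -r, r), n_in, n_out)
}

#' Initialize GCN parameters
#'
#' Glorot-uniform weights, unit-norm random pooling projections, zero
#' read-out bias; deterministic given `cfg$seed`.
#'
#' @param cfg A [gcn_config()].
#' @return Named list of parameter arrays.
#' @export
gcn_init <- function(cfg) {
  with_seed(cfg$seed, {
    p <- list(
      W1 = glorot(cfg$d_in, cfg$d_branch),
      W3 = glorot(cfg$d_branch, cfg$d_fuse),
      p1 = stats::rnorm(cfg$d_fuse),
      W4 = glorot(cfg$d_fuse, cfg$d_deep),
      p2 = stats::rnorm(cfg$d_deep),
      W5 = glorot(cfg$d_deep, 2),
      b5 = numeric(2)
    )
    if (cfg$mode == "fused") p$W2 <- glorot(cfg$d_in, cfg$d_branch)
    p
  })
}

#' One graph-convolution layer
#'
#' X' = ReLU(D^{-1/2} (A + I) D^{-1/2} X W).
#'
#' @param X n x d_in feature matrix.
#' @param A n x n symmetric adjacency with zero diagonal.
#' @param W d_in x d_out weight matrix.
#' @return n x d_out matrix.
#' @export
graph_conv <- function(X, A, W) {
  pmax(norm_adj(A) %*% X %*% W, 0)
}

#' TopK pooling
#'
#' Scores nodes by the normalized projection s = X p / ||p||, keeps the
#' `k` highest-scoring nodes (ties broken toward the lower node index),
#' gates their features by tanh(s), and restricts the adjacency to the
#' kept nodes.
#'
#' @param X n x d feature matrix.
#' @param A n x n adjacency.
#' @param k Number of nodes to keep (k <= n).
#' @param p Projection vector of length d.
#' @return List with `X` (k x d), `A` (k x k), and `kept` (indices).
#' @export
topk_pool <- function(X, A, k, p) {
  if (k > nrow(X)) stop("k exceeds node count")
  s <- as.numeric(X %*% p) / sqrt(sum(p^2))
  kept <- order(-s, seq_along(s))[seq_len(k)]
  kept <- sort(kept)
  list(X = X[kept, , drop = FALSE] * tanh(s[kept]),
       A = A[kept, kept, drop = FALSE], kept = kept, scores = s)
}

# Per-sample precomputation: normalized adjacencies and block indices.
# Called once per dataset, not per epoch.
gcn_prepare <- function(samples, cfg) {
  lapply(samples, function(s) {
    if (cfg$mode == "fused") {
      if (!any(s$modality_mask == 2))
        stop("fused mode needs a fused sample with both modality blocks")
      i1 <- which(s$modality_mask == 1)
      i2 <- which(s$modality_mask == 2)
      list(X = s$node_feats, A = s$adjacency, y = s$label,
           i1 = i1, i2 = i2,
           N1 = norm_adj(s$adjacency[i1, i1, drop = FALSE]),
           N2 = norm_adj(s$adjacency[i2, i2, drop = FALSE]),
           Nf = norm_adj(s$adjacency))
    } else {
      list(X = s$node_feats, A = s$adjacency, y = s$label,
           Nf = norm_adj(s$adjacency))
    }
  })
}

# Forward pass on a prepared sample. Returns logits and, if wanted, the
# cache needed for backprop or the architecture trace.
gcn_forward_prep <- function(par, pr, cfg, keep_cache = FALSE) {
  n <- nrow(pr$X)
  if (cfg$mode == "fused") {
    Z1 <- pr$N1 %*% pr$X[pr$i1, , drop = FALSE] %*% par$W1
    Z2 <- pr$N2 %*% pr$X[pr$i2, , drop = FALSE] %*% par$W2
    H1 <- matrix(0, n, cfg$d_branch)
    H1[pr$i1, ] <- pmax(Z1, 0)
    H1[pr$i2, ] <- pmax(Z2, 0)
  } else {
    Z1 <- pr$Nf %*% pr$X %*% par$W1
    H1 <- pmax(Z1, 0)
  }
  Z3 <- pr$Nf %*% H1 %*% par$W3
  H3 <- pmax(Z3, 0)
  k1 <- ceiling(n / 2)
  pool1 <- topk_pool(H3, pr$A, k1, par$p1)
  N4 <- norm_adj(pool1$A)
  Z4 <- N4 %*% pool1$X %*% par$W4
  H4 <- pmax(Z4, 0)
  pool2 <- topk_pool(H4, pool1$A, 1, par$p2)
  logits <- as.numeric(pool2$X %*% par$W5 + par$b5)
  if (!keep_cache) return(list(logits = logits))
  list(logits = logits, Z1 = Z1, Z2 = if (cfg$mode == "fused") Z2,
       H1 = H1, Z3 = Z3, H3 = H3, pool1 = pool1, N4 = N4, Z4 = Z4,
       H4 = H4, pool2 = pool2, n = n, k1 = k1)
}

#' Forward pass of the classifier
#'
#' @param par Parameter list from [gcn_init()] or a trained model.
#' @param sample A `graph_sample` (fused for `mode = "fused"`).
#' @param cfg The [gcn_config()].
#' @param trace If `TRUE`, also return the node counts and feature widths
#'   traversed by the pass.
#' @return List with `logits` (length-2) and optionally `trace`.
#' @export
gcn_forward <- function(par, sample, cfg, trace = FALSE) {
  pr <- gcn_prepare(list(sample), cfg)[[1]]
  out <- gcn_forward_prep(par, pr, cfg, keep_cache = trace)
  if (trace) {
    out$trace <- list(
      node_counts = c(out$n, out$k1, 1),
      widths = c(ncol(sample$node_feats), ncol(out$H1), ncol(out$H3),
                 ncol(out$H4), length(out$logits)))
    out <- out[c("logits", "trace")]
  }
  out
}

# Backward pass for the TopK pooling operator. s = X p / ||p||;
# X'[j, ] = X[kept_j, ] * tanh(s[kept_j]).
topk_backward <- function(X, p, pool, dXk) {
  th <- tanh(pool$scores[pool$kept])
  dX <- matrix(0, nrow(X), ncol(X))
  dX[pool$kept, ] <- dXk * th
  ds <- numeric(nrow(X))
  ds[pool$kept] <- rowSums(dXk * X[pool$kept, , drop = FALSE]) * (1 - th^2)
  pn <- sqrt(sum(p^2))
  dX <- dX + outer(ds, p / pn)
  dp <- as.numeric(crossprod(X, ds)) / pn -
    p * sum(pool$scores * ds) / pn^2
  list(dX = dX, dp = dp)
}

# Loss and analytic gradients for one prepared sample. Cross-entropy on
# softmax(logits); gradients for every parameter array.
gcn_sample_grad <- function(par, pr, cfg) {
  cache <- gcn_forward_prep(par, pr, cfg, keep_cache = TRUE)
  logits <- cache$logits
  m <- max(logits)
  lse <- m + log(sum(exp(logits - m)))
  prob <- exp(logits - lse)
  y1 <- pr$y + 1L
  loss <- -(logits[y1] - lse)
  dlog <- prob
  dlog[y1] <- dlog[y1] - 1
  g <- list()
  G2 <- cache$pool2$X
  g$W5 <- crossprod(G2, matrix(dlog, 1))
  g$b5 <- dlog
  dG2 <- matrix(dlog, 1) %*% t(par$W5)
  bk2 <- topk_backward(cache$H4, par$p2, cache$pool2, dG2)
  g$p2 <- bk2$dp
  dZ4 <- bk2$dX * (cache$Z4 > 0)
  M4 <- cache$N4 %*% cache$pool1$X
  g$W4 <- crossprod(M4, dZ4)
  dG1 <- cache$N4 %*% dZ4 %*% t(par$W4)
  bk1 <- topk_backward(cache$H3, par$p1, cache$pool1, dG1)
  g$p1 <- bk1$dp
  dZ3 <- bk1$dX * (cache$Z3 > 0)
  g$W3 <- crossprod(pr$Nf %*% cache$H1, dZ3)
  dH1 <- pr$Nf %*% dZ3 %*% t(par$W3)
  if (cfg$mode == "fused") {
    dZ1 <- dH1[pr$i1, , drop = FALSE] * (cache$Z1 > 0)
    dZ2 <- dH1[pr$i2, , drop = FALSE] * (cache$Z2 > 0)
    g$W1 <- crossprod(pr$N1 %*% pr$X[pr$i1, , drop = FALSE], dZ1)
    g$W2 <- crossprod(pr$N2 %*% pr$X[pr$i2, , drop = FALSE], dZ2)
  } else {
    dZ1 <- dH1 * (cache$Z1 > 0)
    g$W1 <- crossprod(pr$Nf %*% pr$X, dZ1)
  }
  list(loss = loss, grads = g, prob = prob)
}

#' Mean loss and gradients over a set of samples
#'
#' Exposed mainly for the finite-difference gradient check; training uses
#' it internally per minibatch. The L2 penalty is not included here (it
#' is applied as weight decay inside the Adam step).
#'
#' @param par Parameter list.
#' @param prepared Prepared samples from the internal representation; a
#'   plain list of `graph_sample`s is also accepted.
#' @param cfg The [gcn_config()].
#' @return List with `loss` and `grads`.
#' @export
gcn_loss_grad <- function(par, prepared, cfg) {
  if (length(prepared) && inherits(prepared[[1]], "graph_sample"))
    prepared <- gcn_prepare(prepared, cfg)
  acc <- NULL
  loss <- 0
  for (pr in prepared) {
    sg <- gcn_sample_grad(par, pr, cfg)
    loss <- loss + sg$loss
    if (is.null(acc)) acc <- sg$grads
    else for (nm in names(acc)) acc[[nm]] <- acc[[nm]] + sg$grads[[nm]]
  }
  nb <- length(prepared)
  for (nm in names(acc)) acc[[nm]] <- acc[[nm]] / nb
  list(loss = loss / nb, grads = acc)
}

#' Train the GCN classifier
#'
#' Minibatch Adam on the softmax cross-entropy, with L2 regularization
#' applied as decoupled weight decay (AdamW-style) on all weights and
#' projections (not the bias). Fully deterministic given `cfg$seed`.
#' Feature scaling is fitted on the supplied samples and stored in the
#' model.
#'
#' @param samples List of `graph_sample`s (both classes present).
#' @param cfg A [gcn_config()].
#' @param scale If `TRUE` (default), z-score features before training and
#'   store the scaler.
#' @return A `gcn_model`: parameters, config, scaler, loss history.
#' @export
gcn_train <- function(samples, cfg = gcn_config(), scale = TRUE) {
  ys <- vapply(samples, `[[`, 0L, "label")
  if (length(unique(ys)) < 2)
    stop("training set must contain both classes")
  scaler <- NULL
  if (scale) {
    sc <- scale_features(samples)
    samples <- sc$samples
    scaler <- sc$scaler
  }
  prepared <- gcn_prepare(samples, cfg)
  par <- gcn_init(cfg)
  mstate <- lapply(par, function(x) x * 0)
  vstate <- mstate
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  t_step <- 0
  history <- numeric(cfg$epochs)
  nb <- length(prepared)
  with_seed(derive_seed(cfg$seed, "batches"), {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(nb)
      ep_loss <- 0
      for (start in seq(1, nb, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1, nb)]
        lg <- gcn_loss_grad(par, prepared[idx], cfg)
        ep_loss <- ep_loss + lg$loss * length(idx)
        t_step <- t_step + 1
        for (nm in names(par)) {
          gr <- lg$grads[[nm]]
          mstate[[nm]] <- b1 * mstate[[nm]] + (1 - b1) * gr
          vstate[[nm]] <- b2 * vstate[[nm]] + (1 - b2) * gr^2
          mh <- mstate[[nm]] / (1 - b1^t_step)
          vh <- vstate[[nm]] / (1 - b2^t_step)
          # decoupled L2 weight decay (AdamW); bias not decayed
          decay <- if (nm == "b5") 0 else cfg$lr * cfg$weight_decay * par[[nm]]
          par[[nm]] <- par[[nm]] - cfg$lr * mh / (sqrt(vh) + eps) - decay
        }
      }
      history[ep] <- ep_loss / nb
    }
  })
  structure(list(par = par, cfg = cfg, scaler = scaler, history = history),
            class = "gcn_model")
}

#' @export
print.gcn_model <- function(x, ...) {
  cat(sprintf("<gcn_model> mode %s, %d epochs, final loss %.4f\n",
              x$cfg$mode, x$cfg$epochs, utils::tail(x$history, 1)))
  invisible(x)
}

#' Predict labels (and class probabilities) for graph samples
#'
#' @param model A `gcn_model`.
#' @param samples List of `graph_sample`s.
#' @return List with `labels` (0/1 vector) and `prob_ms` (probability of
#'   the motion-sickness class).
#' @export
gcn_predict <- function(model, samples) {
  if (!is.null(model$scaler))
    samples <- scale_features(samples, model$scaler)$samples
  prepared <- gcn_prepare(samples, model$cfg)
  probs <- vapply(prepared, function(pr) {
    lg <- gcn_forward_prep(model$par, pr, model$cfg)$logits
    1 / (1 + exp(lg[1] - lg[2]))
  }, 0)
  list(labels = as.integer(probs > 0.5), prob_ms = probs)
}

#' Confusion-matrix metrics for binary classification
#'
#' Accuracy, and precision/recall/F1 of the positive (motion-sickness)
#' class; precision and F1 are 0 when no positives are predicted.
#'
#' @param truth,pred 0/1 vectors.
#' @return Named numeric vector.
#' @export
binary_metrics <- function(truth, pred) {
  tp <- sum(truth == 1 & pred == 1)
  fp <- sum(truth == 0 & pred == 1)
  fn <- sum(truth == 1 & pred == 0)
  acc <- mean(truth == pred)
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  c(accuracy = acc, f1 = f1, recall = rec, precision = prec)
}

# Stratified fold assignment: classes are shuffled separately (seeded)
# and dealt round-robin, keeping fold class proportions within one sample
# of the global proportions.
stratified_folds <- function(labels, folds, seed) {
  assign <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign
}

#' Stratified k-fold cross-validation of the classifier
#'
#' For each fold: z-scoring fitted on the training split only, model
#' trained on the training split, metrics computed on the held-out fold
#' (accuracy, binary F1 on the motion-sickness class, recall, precision).
#'
#' @param samples List of `graph_sample`s.
#' @param cfg A [gcn_config()].
#' @param folds Number of folds (default 10); each class must have at
#'   least `folds` members.
#' @return A `model_report`: per-fold metrics, their mean and sd, the
#'   config, and per-fold predictions.
#' @export
evaluate_cv <- function(samples, cfg = gcn_config(), folds = 10) {
  labels <- vapply(samples, `[[`, 0L, "label")
  if (any(table(labels) < folds))
    stop("each class needs at least ", folds, " samples for ", folds,
         "-fold CV")
  assign <- stratified_folds(labels, folds, derive_seed(cfg$seed, "folds"))
  per_fold <- matrix(NA_real_, folds, 4,
                     dimnames = list(NULL, c("accuracy", "f1", "recall",
                                             "precision")))
  preds <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- samples[assign != f]
    te <- samples[assign == f]
    model <- gcn_train(tr, cfg)
    pd <- gcn_predict(model, te)
    truth <- vapply(te, `[[`, 0L, "label")
    per_fold[f, ] <- binary_metrics(truth, pd$labels)
    preds[[f]] <- list(truth = truth, pred = pd$labels,
                       prob_ms = pd$prob_ms)
  }
  structure(list(per_fold = as.data.frame(per_fold),
                 mean = colMeans(per_fold),
                 sd = apply(per_fold, 2, stats::sd),
                 folds = folds, cfg = cfg, predictions = preds),
            class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("<model_report> %d-fold CV (%s mode)\n", x$folds, x$cfg$mode))
  m <- rbind(mean = x$mean, sd = x$sd)
  print(round(m, 3))
  invisible(x)
}

#' Grid search over GCN hyperparameters
#'
#' Exhaustive evaluation of every grid combination via [evaluate_cv()];
#' the configuration with the highest mean F1 wins, ties broken by higher
#' accuracy and then smaller weight decay.
#'
#' @param samples List of `graph_sample`s.
#' @param grid Named list of parameter vectors to cross (e.g.
#'   `list(lr = c(1e-3, 1e-2), weight_decay = c(5e-4, 5e-3))`).
#' @param cfg Base [gcn_config()]; grid values override its fields.
#' @param folds CV folds per combination.
#' @return List with `best` (the winning config), `best_report`, and
#'   `results` (a data frame of every combination and its mean metrics).
#' @export
grid_search <- function(samples, grid, cfg = gcn_config(), folds = 10) {
  if (!length(grid)) stop("grid must be non-empty")
  combos <- expand.grid(grid, stringsAsFactors = FALSE)
  results <- combos
  results$f1 <- NA_real_
  results$accuracy <- NA_real_
  reports <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    ci <- cfg
    for (nm in names(combos)) ci[[nm]] <- combos[[nm]][i]
    class(ci) <- "gcn_config"
    rep_i <- evaluate_cv(samples, ci, folds = folds)
    reports[[i]] <- rep_i
    results$f1[i] <- rep_i$mean["f1"]
    results$accuracy[i] <- rep_i$mean["accuracy"]
  }
  wd <- if ("weight_decay" %in% names(results)) results$weight_decay
        else rep(cfg$weight_decay, nrow(results))
  best_i <- order(-results$f1, -results$accuracy, wd)[1]
  best <- cfg
  for (nm in names(combos)) best[[nm]] <- combos[[nm]][best_i]
  class(best) <- "gcn_config"
  list(best = best, best_report = reports[[best_i]], results = results)
}
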