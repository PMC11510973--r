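# Small named graphs with known metric values.
graph_complete <- function(N) {
  A <- matrix(1, N, N); diag(A) <- 0
  brain_network(A, paste0("n", seq_len(N)))
}
graph_star <- function(N) {
  A <- matrix(0, N, N); A[1, 2:N] <- 1; A[2:N, 1] <- 1
  brain_network(A, paste0("n", seq_len(N)))
}
graph_path <- function(N) {
  A <- matrix(0, N, N)
  for (i in 1:(N - 1)) A[i, i + 1] <- A[i + 1, i] <- 1
  brain_network(A, paste0("n", seq_len(N)))
}
graph_cycle <- function(N) {
  net <- graph_path(N)
  A <- net$adjacency; A[1, N] <- A[N, 1] <- 1
  brain_network(A, paste0("n", seq_len(N)))
}
# Ring lattice (k neighbors each side) with a few shortcuts: the
# canonical small-world construction.
graph_smallworld <- function(N = 14, k = 2, shortcuts = 2) {
  A <- matrix(0, N, N)
  for (i in seq_len(N)) for (d in seq_len(k)) {
    j <- ((i + d - 1) %% N) + 1
    A[i, j] <- A[j, i] <- 1
  }
  A[1, N %/% 2] <- A[N %/% 2, 1] <- 1
  A[3, N %/% 2 + 3] <- A[N %/% 2 + 3, 3] <- 1
  brain_network(A, paste0("n", seq_len(N)))
}

test_that("binarization uses a strict threshold and keeps provenance", {
  vals <- matrix(c(0, .26, .5, .26, 0, .1, .5, .1, 0), 3)
  cm <- connectivity_matrix(vals, c("a", "b", "c"), band = "beta")
  net <- binarize(cm, 0.26)
  expect_equal(sum(net$adjacency), 2)        # only the .5 edge survives
  expect_equal(net$adjacency["a", "c"], 1)
  expect_equal(net$adjacency["a", "b"], 0)   # equality does not exceed
  expect_equal(net$threshold, 0.26)
  expect_equal(sum(binarize(cm, 1)$adjacency), 0)
  allpos <- matrix(0.4, 3, 3); diag(allpos) <- 0
  cm2 <- connectivity_matrix(allpos, c("a", "b", "c"))
  expect_equal(sum(binarize(cm2, 0)$adjacency), 6)  # complete
  expect_error(binarize(cm, 1.2), "\\[0, 1\\]")
})

test_that("closed-form graphs give exact metric values", {
  k5 <- graph_complete(5)
  expect_equal(unname(node_degree(k5)), rep(4L, 5))
  expect_equal(clustering_coef(k5)$mean, 1)
  expect_equal(global_efficiency(k5)$value, 1)
  expect_equal(local_efficiency(k5)$value, 1)

  star <- graph_star(6)
  expect_equal(unname(node_degree(star)), c(5L, rep(1L, 5)))
  expect_equal(unname(clustering_coef(star)$per_node), rep(0, 6))
  expect_equal(local_efficiency(star)$value, 0)
  expect_identical(key_nodes(star), "n1")   # center is the only hub

  path <- graph_path(5)
  expect_equal(unname(clustering_coef(path)$per_node), rep(0, 5))

  cyc <- graph_cycle(8)
  expect_identical(key_nodes(cyc), character(0))  # perfect symmetry

  iso <- brain_network(matrix(0, 2, 2), c("a", "b"))
  expect_equal(global_efficiency(iso)$value, 0)
})

test_that("metrics match brute-force oracles on random graphs", {
  set.seed(21)
  for (rep in 1:50) {
    N <- sample(4:14, 1)
    A <- random_adjacency(N, p = runif(1, 0.15, 0.6))
    net <- brain_network(A, paste0("n", seq_len(N)))
    expect_equal(unname(node_degree(net)), as.integer(rowSums(A)))
    expect_equal(unname(clustering_coef(net)$per_node),
                 oracle_clustering(A)$per_node, tolerance = 1e-12)
    expect_equal(unname(global_efficiency(net)$per_node),
                 oracle_global_eff(A)$per_node, tolerance = 1e-12)
    expect_equal(unname(local_efficiency(net)$per_node),
                 oracle_local_eff(A)$per_node, tolerance = 1e-12)
    expect_equal(unname(betweenness_norm(net)),
                 oracle_betweenness(A), tolerance = 1e-10)
  }
})

test_that("metrics are equivariant under node relabeling", {
  set.seed(22)
  A <- random_adjacency(10, 0.4)
  net <- brain_network(A, paste0("n", 1:10))
  perm <- sample(10)
  netp <- brain_network(A[perm, perm], paste0("n", 1:10)[perm])
  expect_equal(unname(node_degree(netp)), unname(node_degree(net))[perm])
  expect_equal(unname(betweenness_norm(netp)),
               unname(betweenness_norm(net))[perm], tolerance = 1e-12)
  expect_equal(unname(local_efficiency(netp)$per_node),
               unname(local_efficiency(net)$per_node)[perm],
               tolerance = 1e-12)
})

test_that("edge count is non-increasing in the threshold", {
  set.seed(23)
  vals <- matrix(runif(14 * 14), 14)
  vals <- (vals + t(vals)) / 2
  diag(vals) <- 0
  cm <- connectivity_matrix(vals, paste0("n", 1:14))
  counts <- sapply(seq(0, 1, 0.05), function(t) sum(binarize(cm, t)$adjacency))
  expect_true(all(diff(counts) <= 0))
})

test_that("small-world sigma separates lattice-like from degenerate graphs", {
  sw <- graph_smallworld()
  expect_gt(small_world_sigma(sw, n_rand = 50, seed = 3), 1)
  # complete graph: rewiring is the identity, sigma exactly 1
  expect_equal(small_world_sigma(graph_complete(8), n_rand = 5, seed = 1), 1)
  # Erdos-Renyi graphs are their own surrogate family: sigma near 1 on
  # average (individual realizations scatter around it)
  set.seed(24)
  sigs <- replicate(5, {
    repeat {
      A <- random_adjacency(14, 0.35)
      g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
      if (max(igraph::components(g)$csize) >= 13) break
    }
    small_world_sigma(brain_network(A, paste0("n", 1:14)),
                      n_rand = 50, seed = 4)
  })
  expect_gt(mean(sigs), 0.7)
  expect_lt(mean(sigs), 1.4)
  # too fragmented to assess
  frag <- brain_network(diag(0, 6), paste0("n", 1:6))
  expect_error(small_world_sigma(frag, seed = 1), "giant component")
})

test_that("threshold selection honors both constraints or fails loudly", {
  # feasible: strong small-world backbone at 0.8, background at 0.1
  sw <- graph_smallworld()
  vals <- ifelse(sw$adjacency == 1, 0.8, 0.1)
  diag(vals) <- 0
  set.seed(25)
  noise <- matrix(runif(196, -0.03, 0.03), 14)
  noise <- (noise + t(noise)) / 2; diag(noise) <- 0
  cm <- connectivity_matrix(pmin(pmax(vals + noise, 0), 1),
                            paste0("n", 1:14))
  sel <- select_threshold(list(cm, cm), grid_step = 0.05, n_rand = 20,
                          seed = 5)
  expect_gte(sel$mean_degree, log(14))
  expect_gt(sel$sigma, 1)
  # independently recount the mean degree at the selected threshold
  expect_equal(sel$mean_degree,
               mean(rowSums(binarize(cm, sel$threshold)$adjacency)))
  # infeasible: no structure anywhere
  flat <- connectivity_matrix(matrix(0.01, 14, 14) - diag(0.01, 14),
                              paste0("n", 1:14))
  expect_error(select_threshold(list(flat), grid_step = 0.1),
               "no feasible threshold")
  expect_error(select_threshold(list()), "at least one")
})

test_that("group comparison matches the exact rank-permutation oracle", {
  same <- c(1, 2, 3, 4, 5)
  res <- compare_groups(same, same)
  expect_gt(res$p, 0.9)
  expect_identical(res$stars, "")
  sep <- compare_groups(c(1, 2, 3), c(10, 11, 12))
  expect_true(sep$U %in% c(0, 9))
  expect_lte(sep$p, 0.1)   # exact two-sided p = 2/20 at full separation
  set.seed(26)
  for (rep in 1:5) {
    x <- rnorm(4); y <- rnorm(4) + rep / 2
    expect_equal(compare_groups(x, y)$p, oracle_mw_exact(x, y),
                 tolerance = 1e-12)
  }
  strong <- compare_groups(rnorm(20), rnorm(20) + 10)
  expect_identical(strong$stars, "***")
  expect_error(compare_groups(1:2, 1:5), "at least 3")
})
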