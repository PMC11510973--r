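#' Binary functional brain network
#'
#' Undirected binary graph over channels with the threshold that produced
#' it. Adjacency is symmetric 0/1 with zero diagonal.
#'
#' @param adjacency Binary symmetric matrix, zero diagonal.
#' @param channel_names Node names.
#' @param threshold Threshold used to binarize (provenance).
#' @param band Band label.
#' @return A `brain_network`.
#' @export
brain_network <- function(adjacency, channel_names = rownames(adjacency),
                          threshold = NA_real_, band = NA_character_) {
  adjacency <- as.matrix(adjacency)
  if (nrow(adjacency) != ncol(adjacency)) stop("adjacency must be square")
  if (!all(adjacency %in% c(0, 1))) stop("adjacency must be binary")
  if (!identical(adjacency, t(adjacency))) stop("adjacency must be symmetric")
  if (any(diag(adjacency) != 0)) stop("diagonal must be 0")
  if (is.null(channel_names)) channel_names <- as.character(seq_len(nrow(adjacency)))
  dimnames(adjacency) <- list(channel_names, channel_names)
  structure(list(adjacency = adjacency, channel_names = channel_names,
                 threshold = threshold, band = band),
            class = "brain_network")
}

#' @export
print.brain_network <- function(x, ...) {
  cat(sprintf("<brain_network> %d nodes, %d edges, threshold %s, band %s\n",
              nrow(x$adjacency), sum(x$adjacency) / 2,
              format(x$threshold), x$band))
  invisible(x)
}

as_igraph <- function(net) {
  igraph::graph_from_adjacency_matrix(net$adjacency, mode = "undirected")
}

#' Threshold a connectivity matrix into a binary network
#'
#' An edge is kept iff its connectivity strictly exceeds the threshold
#' ("exceeds", so equality drops the edge); the diagonal stays 0.
#'
#' @param conn A `connectivity_matrix`.
#' @param threshold Scalar in `[0, 1]`.
#' @return A `brain_network`.
#' @export
binarize <- function(conn, threshold) {
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  adj <- (conn$values > threshold) * 1
  diag(adj) <- 0
  brain_network(adj, conn$channel_names, threshold = threshold,
                band = conn$band)
}

#' Node degree
#'
#' Number of nodes directly connected to each node.
#'
#' @param net A `brain_network`.
#' @return Named integer vector.
#' @export
node_degree <- function(net) {
  d <- rowSums(net$adjacency)
  stats::setNames(as.integer(d), net$channel_names)
}

#' Clustering coefficient
#'
#' Per-node C_i = 2 E_i / (k_i (k_i - 1)), the fraction of realized edges
#' among each node's neighbors, with C_i = 0 for nodes of degree < 2, and
#' the network mean over all nodes.
#'
#' @param net A `brain_network`.
#' @return List with `per_node` (named vector) and `mean`.
#' @export
clustering_coef <- function(net) {
  g <- as_igraph(net)
  ci <- igraph::transitivity(g, type = "local", isolates = "zero")
  ci <- stats::setNames(ci, net$channel_names)
  list(per_node = ci, mean = mean(ci))
}

# Nodal efficiency from a distance matrix: mean of 1/d to all other
# nodes, with 1/Inf = 0 for disconnected pairs.
nodal_eff_from_dist <- function(D) {
  N <- nrow(D)
  if (N < 2) return(stats::setNames(numeric(N), rownames(D)))
  inv <- 1 / D
  diag(inv) <- 0
  inv[is.infinite(D)] <- 0
  rowSums(inv) / (N - 1)
}

#' Global efficiency
#'
#' Nodal global efficiency E_glob(i) is the mean inverse shortest-path
#' length from node i to every other node (0 for unreachable pairs); the
#' network value is the mean over nodes. Shortest paths are unweighted.
#'
#' @param net A `brain_network`.
#' @return List with `per_node` and `value`.
#' @export
global_efficiency <- function(net) {
  D <- igraph::distances(as_igraph(net))
  e <- stats::setNames(nodal_eff_from_dist(D), net$channel_names)
  list(per_node = e, value = mean(e))
}

#' Local efficiency
#'
#' Nodal local efficiency E_loc(i) is the global efficiency of the
#' subgraph induced by node i's neighbors (0 when the node has fewer than
#' 2 neighbors); the network value is the mean over nodes.
#'
#' @param net A `brain_network`.
#' @return List with `per_node` and `value`.
#' @export
local_efficiency <- function(net) {
  g <- as_igraph(net)
  e <- vapply(seq_len(nrow(net$adjacency)), function(i) {
    nb <- which(net$adjacency[i, ] == 1)
    if (length(nb) < 2) return(0)
    D <- igraph::distances(igraph::induced_subgraph(g, nb))
    mean(nodal_eff_from_dist(D))
  }, 0)
  e <- stats::setNames(e, net$channel_names)
  list(per_node = e, value = mean(e))
}

#' Normalized betweenness centrality
#'
#' Fraction of shortest paths passing through each node, normalized by
#' (N-1)(N-2)/2 so values lie in `[0, 1]`.
#'
#' @param net A `brain_network`.
#' @return Named numeric vector.
#' @export
betweenness_norm <- function(net) {
  b <- igraph::betweenness(as_igraph(net), normalized = TRUE)
  stats::setNames(as.numeric(b), net$channel_names)
}

#' Key nodes by betweenness centrality
#'
#' Flags hub nodes of the network. The default rule keeps nodes whose
#' normalized betweenness exceeds the mean plus one standard deviation
#' across nodes; `rule = "topk"` keeps the `k` highest-ranked nodes (ties
#' included).
#'
#' @param net A `brain_network`.
#' @param rule `"mean_sd"` or `"topk"`.
#' @param k Number of nodes for `rule = "topk"`.
#' @return Character vector of channel names (possibly empty).
#' @export
key_nodes <- function(net, rule = c("mean_sd", "topk"), k = 3) {
  rule <- match.arg(rule)
  b <- betweenness_norm(net)
  if (rule == "mean_sd") {
    cut <- mean(b) + stats::sd(b)
    names(b)[b > cut]
  } else {
    thr <- sort(b, decreasing = TRUE)[min(k, length(b))]
    names(b)[b >= thr]
  }
}

# Characteristic path length over connected pairs.
char_path_length <- function(g) {
  igraph::mean_distance(g, unconnected = TRUE)
}

#' Small-world index
#'
#' sigma = (C / C_rand) / (L / L_rand), where C is the mean clustering
#' coefficient, L the characteristic path length, and the rand values are
#' averages over degree-preserving rewired surrogates. sigma > 1
#' indicates small-world organization (clustered yet short paths).
#'
#' @param net A `brain_network` whose giant component spans at least
#'   N - 2 nodes.
#' @param n_rand Number of rewired surrogates (default 100).
#' @param seed Seed for the rewiring.
#' @return Scalar sigma (may be `Inf` if surrogates have no triangles).
#' @export
small_world_sigma <- function(net, n_rand = 100, seed = 1) {
  g <- as_igraph(net)
  N <- nrow(net$adjacency)
  comp <- igraph::components(g)
  if (max(comp$csize) < N - 2)
    stop("giant component spans ", max(comp$csize), " of ", N,
         " nodes; need at least N - 2 for a meaningful sigma")
  m <- igraph::ecount(g)
  if (m < 2) stop("graph too sparse to rewire (fewer than 2 edges)")
  C <- clustering_coef(net)$mean
  L <- char_path_length(g)
  stats_r <- with_seed(seed, {
    vapply(seq_len(n_rand), function(i) {
      gr <- igraph::rewire(g, igraph::keeping_degseq(niter = 20 * m))
      cr <- igraph::transitivity(gr, type = "local", isolates = "zero")
      c(mean(cr), char_path_length(gr))
    }, c(0, 0))
  })
  C_rand <- mean(stats_r[1, ])
  L_rand <- mean(stats_r[2, ])
  if (C_rand == 0 || L == 0) return(Inf)
  (C / C_rand) / (L / L_rand)
}

#' Select a binarization threshold for a group of connectivity matrices
#'
#' Scans a threshold grid on the group-average connectivity matrix and
#' returns the largest threshold satisfying both constraints: (1) mean
#' node degree of the binarized network at least ln(N) and (2) a
#' small-world index above 1. Picking the largest feasible threshold
#' maximizes sparsity under the constraints.
#'
#' @param conns Non-empty list of `connectivity_matrix` objects (same
#'   channels).
#' @param grid_step Grid spacing in `(0, 1)` (default 0.02).
#' @param n_rand Surrogates per sigma evaluation.
#' @param seed Seed for the sigma surrogates.
#' @return List with `threshold`, `mean_degree`, `sigma`, and the scanned
#'   `grid` report (data frame).
#' @export
select_threshold <- function(conns, grid_step = 0.02, n_rand = 50, seed = 1) {
  if (!length(conns)) stop("need at least one connectivity matrix")
  avg <- Reduce(`+`, lapply(conns, `[[`, "values")) / length(conns)
  cm <- connectivity_matrix(avg, conns[[1]]$channel_names,
                            band = conns[[1]]$band)
  N <- nrow(avg)
  grid <- seq(grid_step, 1 - grid_step, by = grid_step)
  report <- data.frame(threshold = grid, mean_degree = NA_real_,
                       sigma = NA_real_, feasible = FALSE)
  for (i in rev(seq_along(grid))) {
    t <- grid[i]
    net <- binarize(cm, t)
    md <- mean(node_degree(net))
    report$mean_degree[i] <- md
    if (md < log(N)) next
    sig <- tryCatch(small_world_sigma(net, n_rand = n_rand, seed = seed),
                    error = function(e) NA_real_)
    report$sigma[i] <- sig
    if (!is.na(sig) && sig > 1) {
      report$feasible[i] <- TRUE
      return(list(threshold = t, mean_degree = md, sigma = sig,
                  grid = report))
    }
  }
  stop("no feasible threshold: no grid point gives mean degree >= ln(N) = ",
       round(log(N), 3), " together with small-world sigma > 1; ",
       "max mean degree on grid = ",
       round(max(report$mean_degree, na.rm = TRUE), 3),
       ", max sigma = ",
       ifelse(all(is.na(report$sigma)), "none evaluated",
              round(max(report$sigma, na.rm = TRUE), 3)))
}

#' Mann-Whitney comparison of a network metric between groups
#'
#' Two-sided rank-sum test (exact for small tie-free samples, normal
#' approximation with tie correction otherwise), annotated with the usual
#' significance stars: `***` p < 0.001, `**` p < 0.01, `*` p < 0.05.
#'
#' @param values_nm,values_ms Numeric vectors (length >= 3 each).
#' @return List with `U`, `p`, and `stars`.
#' @export
compare_groups <- function(values_nm, values_ms) {
  if (length(values_nm) < 3 || length(values_ms) < 3)
    stop("each group needs at least 3 values")
  wt <- suppressWarnings(stats::wilcox.test(values_nm, values_ms,
                                            alternative = "two.sided"))
  stars <- if (wt$p.value < 0.001) "***"
           else if (wt$p.value < 0.01) "**"
           else if (wt$p.value < 0.05) "*"
           else ""
  list(U = unname(wt$statistic), p = wt$p.value, stars = stars)
}

#' All graph metrics of a network
#'
#' Convenience wrapper returning degree, clustering, global/local
#' efficiency, and normalized betweenness in one list.
#'
#' @param net A `brain_network`.
#' @return List of metric results.
#' @export
network_metrics <- function(net) {
  list(degree = node_degree(net),
       clustering = clustering_coef(net),
       global_efficiency = global_efficiency(net),
       local_efficiency = local_efficiency(net),
       betweenness = betweenness_norm(net))
}
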