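#' Names of the 13 node features
#'
#' Nine signal features computed on the node's band-limited series (MAV,
#' variance, max, min, RMS, excess kurtosis, skewness, total spectral
#' power, relative band power) followed by four graph features (degree,
#' clustering coefficient, nodal global efficiency, nodal local
#' efficiency).
#'
#' @return Character vector of length 13.
#' @export
feature_names <- function() {
  c("mav", "var", "max", "min", "rms", "kurtosis", "skewness",
    "psd_total", "psd_rel_band", "degree", "clustering",
    "global_eff", "local_eff")
}

#' 13-dimensional feature vector of one network node
#'
#' @param band_x Band-limited (or dCOE) series of the node's channel.
#' @param broad_x Broadband series of the same channel, used for the two
#'   spectral-power features (total power over `total_range`, relative
#'   power within `band_range`).
#' @param fs Sampling rate in Hz.
#' @param band_range `c(low, high)` of the node's band.
#' @param total_range `c(low, high)` of the broadband reference.
#' @param net A `brain_network` containing the node.
#' @param node Node index or channel name in `net`.
#' @param metrics Optional precomputed [network_metrics()] of `net`.
#' @return Named numeric vector of length 13.
#' @export
node_features <- function(band_x, broad_x, fs, band_range, total_range,
                          net, node, metrics = network_metrics(net)) {
  if (is.character(node)) node <- match(node, net$channel_names)
  if (is.na(node)) stop("node not found in network")
  sig <- c(
    mean(abs(band_x)),
    stats::var(band_x),
    max(band_x),
    min(band_x),
    sqrt(mean(band_x^2)),
    safe_kurtosis(band_x),
    safe_skewness(band_x),
    band_power(broad_x, fs, total_range[1], total_range[2]),
    band_power_fraction(broad_x, fs, band_range[1], band_range[2])
  )
  graph_f <- c(metrics$degree[node],
               metrics$clustering$per_node[node],
               metrics$global_efficiency$per_node[node],
               metrics$local_efficiency$per_node[node])
  stats::setNames(c(sig, graph_f), feature_names())
}

#' Classifier-ready graph sample
#'
#' @param node_feats n x 13 feature matrix (rows ordered like
#'   `node_names`).
#' @param adjacency n x n binary adjacency.
#' @param node_names Node (channel) names.
#' @param label 0 (NM) or 1 (MS).
#' @param modality `"eeg"`, `"fnirs"`, or `"fused"`.
#' @param modality_mask Integer vector: 1 for EEG nodes, 2 for fNIRS
#'   nodes (used by the branch convolutions of fused samples).
#' @param segment_id Segment identifier.
#' @return A `graph_sample`.
#' @export
graph_sample <- function(node_feats, adjacency, node_names, label,
                         modality, modality_mask = NULL,
                         segment_id = NA_character_) {
  node_feats <- as.matrix(node_feats)
  if (nrow(node_feats) != nrow(adjacency))
    stop("feature rows must match adjacency size")
  if (is.null(modality_mask))
    modality_mask <- rep(if (modality == "fnirs") 2L else 1L, nrow(node_feats))
  rownames(node_feats) <- node_names
  structure(list(node_feats = node_feats, adjacency = adjacency,
                 node_names = node_names, label = as.integer(label),
                 modality = modality,
                 modality_mask = as.integer(modality_mask),
                 segment_id = segment_id),
            class = "graph_sample")
}

#' @export
print.graph_sample <- function(x, ...) {
  cat(sprintf("<graph_sample> %s, %d nodes x %d features, label %d (%s)\n",
              x$segment_id, nrow(x$node_feats), ncol(x$node_feats),
              x$label, x$modality))
  invisible(x)
}

# Build a unimodal graph sample from a band-limited recording and its
# thresholded network.
build_modal_sample <- function(band_rec, broad_rec, net, band_range,
                               total_range, label, modality, segment_id) {
  metrics <- network_metrics(net)
  feats <- t(vapply(seq_along(net$channel_names), function(i) {
    node_features(band_rec$samples[i, ], broad_rec$samples[i, ],
                  band_rec$fs, band_range, total_range, net, i, metrics)
  }, numeric(13)))
  graph_sample(feats, net$adjacency, net$channel_names, label, modality,
               segment_id = segment_id)
}

#' Fuse an EEG and an fNIRS graph sample into one bimodal graph
#'
#' The fused adjacency is block-diagonal in the two unaltered unimodal
#' networks, plus bridge edges of weight one connecting overlapping
#' channels across modalities; feature matrices are stacked row-wise.
#' With the default montages the fused graph has 20 nodes (14 EEG + 6
#' fNIRS).
#'
#' @param eeg_sample,fnirs_sample `graph_sample`s from the same segment
#'   (labels must agree).
#' @param bridge_map Named list mapping fNIRS channels to EEG channel
#'   vectors; default [default_bridge_map()].
#' @return A fused `graph_sample`.
#' @export
build_bimodal_graph <- function(eeg_sample, fnirs_sample,
                                bridge_map = default_bridge_map()) {
  if (eeg_sample$label != fnirs_sample$label)
    stop("label mismatch between modalities: ", eeg_sample$label,
         " vs ", fnirs_sample$label)
  n1 <- nrow(eeg_sample$adjacency)
  n2 <- nrow(fnirs_sample$adjacency)
  A <- matrix(0, n1 + n2, n1 + n2)
  A[1:n1, 1:n1] <- eeg_sample$adjacency
  A[(n1 + 1):(n1 + n2), (n1 + 1):(n1 + n2)] <- fnirs_sample$adjacency
  names_all <- c(eeg_sample$node_names, fnirs_sample$node_names)
  for (fch in names(bridge_map)) {
    j <- match(fch, names_all)
    if (is.na(j)) next
    for (ech in bridge_map[[fch]]) {
      i <- match(ech, names_all)
      if (is.na(i)) stop("bridge map references unknown EEG channel ", ech)
      A[i, j] <- A[j, i] <- 1
    }
  }
  dimnames(A) <- list(names_all, names_all)
  graph_sample(rbind(eeg_sample$node_feats, fnirs_sample$node_feats),
               A, names_all, eeg_sample$label, "fused",
               modality_mask = c(rep(1L, n1), rep(2L, n2)),
               segment_id = eeg_sample$segment_id)
}

#' Build classifier-ready graph samples from segment pairs
#'
#' Runs preprocessing, WPLI connectivity, and thresholding per segment,
#' then assembles one `graph_sample` per requested modality. The default
#' thresholds are the band-specific values used throughout the package
#' (delta 0.36, theta 0.42, alpha 0.40, beta 0.26, fNIRS 0.35).
#'
#' @param pairs List of `segment_pair`s.
#' @param band EEG band used for the `eeg` and `fused` modalities.
#' @param modalities Subset of `c("eeg", "fnirs", "fused")`.
#' @param thresholds Named list of binarization thresholds (per band and
#'   `fnirs`).
#' @param bridge_map Bridge map for fused samples.
#' @param n_epochs WPLI epoch setting (see [wpli()]).
#' @return Named list of lists of `graph_sample`s, one entry per
#'   modality, each in segment order.
#' @export
build_dataset <- function(pairs, band = "beta",
                          modalities = c("eeg", "fnirs", "fused"),
                          thresholds = default_thresholds(),
                          bridge_map = default_bridge_map(),
                          n_epochs = 1) {
  stopifnot(band %in% names(eeg_bands()))
  modalities <- match.arg(modalities, several.ok = TRUE)
  need_eeg <- any(c("eeg", "fused") %in% modalities)
  need_fn <- any(c("fnirs", "fused") %in% modalities)
  out <- stats::setNames(vector("list", length(modalities)), modalities)
  for (m in modalities) out[[m]] <- vector("list", length(pairs))
  for (k in seq_along(pairs)) {
    pp <- preprocess_pair(pairs[[k]], bands = if (need_eeg) band else character())
    if (need_eeg) {
      brec <- pp$eeg_bands[[band]]
      conn <- wpli_matrix(brec, band = band, segment_id = pp$segment_id,
                          n_epochs = n_epochs)
      net <- binarize(conn, thresholds[[band]])
      es <- build_modal_sample(brec, pp$eeg_broad, net, eeg_bands()[[band]],
                               c(0.5, 45), pp$label, "eeg", pp$segment_id)
    }
    if (need_fn) {
      conn <- wpli_matrix(pp$coe, band = "coe", segment_id = pp$segment_id,
                          n_epochs = n_epochs)
      net <- binarize(conn, thresholds$fnirs)
      fsamp <- build_modal_sample(pp$coe, pp$coe, net, fnirs_osc_band(),
                                  fnirs_band(), pp$label, "fnirs",
                                  pp$segment_id)
    }
    if ("eeg" %in% modalities) out$eeg[[k]] <- es
    if ("fnirs" %in% modalities) out$fnirs[[k]] <- fsamp
    if ("fused" %in% modalities)
      out$fused[[k]] <- build_bimodal_graph(es, fsamp, bridge_map)
  }
  out
}

#' Band-specific binarization thresholds
#'
#' Default thresholds applied to WPLI matrices before graph analysis:
#' 0.36 (delta), 0.42 (theta), 0.40 (alpha), 0.26 (beta), 0.35 (fNIRS).
#'
#' @return Named list.
#' @export
default_thresholds <- function() {
  list(delta = 0.36, theta = 0.42, alpha = 0.40, beta = 0.26, fnirs = 0.35)
}

#' Z-score graph-sample features
#'
#' Standardizes each of the 13 features over all nodes of all samples.
#' When `scaler` is supplied (e.g. fitted on a training split) it is
#' applied unchanged, so no information leaks from validation folds.
#' Zero-variance features are left unscaled.
#'
#' @param samples List of `graph_sample`s.
#' @param scaler Optional list with `mean` and `sd` per feature.
#' @return List with `samples` (scaled) and `scaler`.
#' @export
scale_features <- function(samples, scaler = NULL) {
  if (is.null(scaler)) {
    all_f <- do.call(rbind, lapply(samples, `[[`, "node_feats"))
    mu <- colMeans(all_f)
    sdv <- apply(all_f, 2, stats::sd)
    sdv[sdv < .Machine$double.eps] <- 1
    scaler <- list(mean = mu, sd = sdv)
  }
  samples <- lapply(samples, function(s) {
    s$node_feats <- sweep(sweep(s$node_feats, 2, scaler$mean), 2,
                          scaler$sd, `/`)
    s
  })
  list(samples = samples, scaler = scaler)
}

#' Serialize graph samples to JSON + TSV
#'
#' Writes one JSON per sample (nodes, features, edges, label) plus an
#' adjacency TSV, and a dataset manifest CSV (segment_id, label,
#' modality).
#'
#' @param samples List of `graph_sample`s.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_graph_samples <- function(samples, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- data.frame(segment_id = character(), label = integer(),
                         modality = character())
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    stem <- sprintf("%s_%s", s$segment_id, s$modality)
    edges <- which(upper.tri(s$adjacency) & s$adjacency == 1, arr.ind = TRUE)
    jsonlite::write_json(
      list(nodes = s$node_names,
           features = apply(s$node_feats, 1, as.numeric, simplify = FALSE),
           edges = apply(edges, 1, function(r) s$node_names[r],
                         simplify = FALSE),
           label = s$label, modality = s$modality,
           segment_id = s$segment_id),
      file.path(dir, paste0(stem, ".json")), auto_unbox = TRUE, digits = NA)
    utils::write.table(s$adjacency, file.path(dir, paste0(stem, ".tsv")),
                       sep = "\t", quote = FALSE)
    manifest <- rbind(manifest,
                      data.frame(segment_id = s$segment_id, label = s$label,
                                 modality = s$modality))
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}
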