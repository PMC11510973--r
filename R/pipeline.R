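# End-to-end orchestration: simulate -> preprocess -> connectivity ->
# network -> stats -> dataset -> train/evaluate -> report, with one
# config, per-stage manifests (config + input hashes) and idempotent
# re-runs. All artifacts are plain text (CSV/TSV/JSON).

#' Pipeline configuration
#'
#' Assembles the full pipeline configuration with the package defaults:
#' band definitions, 0.5-45 Hz EEG broadband filter, 0.01-0.2 Hz fNIRS
#' band, the band-specific binarization thresholds (or `"auto"` to search
#' them with [select_threshold()]), the default bridge map, and the GCN
#' settings.
#'
#' @param out_dir Artifact directory.
#' @param seed Global seed; per-stage seeds are derived from it.
#' @param n_segments_nm,n_segments_ms,segment_len,noise_sd,signal_split
#'   Passed to [synth_config()].
#' @param band EEG band used for classification.
#' @param thresholds Named list of thresholds, or `"auto"`.
#' @param modalities Modalities to evaluate.
#' @param folds CV folds.
#' @param gcn Named list overriding [gcn_config()] fields.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = "wplinet_out", seed = 1L,
                            n_segments_nm = 61, n_segments_ms = 75,
                            segment_len = 300, noise_sd = 0.3,
                            signal_split = "both", band = "beta",
                            thresholds = default_thresholds(),
                            modalities = c("eeg", "fnirs", "fused"),
                            folds = 10, gcn = list()) {
  if (!identical(thresholds, "auto")) {
    bad <- unlist(thresholds) < 0 | unlist(thresholds) > 1
    if (any(bad)) stop("explicit thresholds must lie in [0, 1]")
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 n_segments_nm = n_segments_nm,
                 n_segments_ms = n_segments_ms,
                 segment_len = segment_len, noise_sd = noise_sd,
                 signal_split = signal_split, band = band,
                 eeg_broadband = c(0.5, 45), fnirs_range = fnirs_band(),
                 thresholds = thresholds, bridge_map = default_bridge_map(),
                 modalities = modalities, folds = folds, gcn = gcn),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys absent from the file keep the [pipeline_config()] defaults.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  for (nm in names(user)) cfg[[nm]] <- user[[nm]]
  class(cfg) <- "pipeline_config"
  cfg
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(as.character(jsonlite::toJSON(unclass(config),
                                           auto_unbox = TRUE, digits = NA,
                                           force = TRUE)), f)
  unname(tools::md5sum(f))
}

stage_prereqs <- function(stage) {
  switch(stage,
         simulate = character(),
         preprocess = "simulate",
         connectivity = "preprocess",
         network = "connectivity",
         stats = "network",
         dataset = "network",
         train = "dataset",
         evaluate = "dataset",
         report = c("stats", "evaluate"),
         stop("unknown stage: ", stage))
}

stage_dir <- function(config, stage) file.path(config$out_dir, stage)

read_manifest <- function(config, stage) {
  f <- file.path(stage_dir(config, stage), "manifest.json")
  if (!file.exists(f)) return(NULL)
  jsonlite::read_json(f)
}

#' Run one pipeline stage
#'
#' Checks that prerequisite stages have completed (an informative error
#' names the stage to run first), skips work when the stage already ran
#' with identical config and inputs, and otherwise writes the stage's
#' artifacts plus a manifest recording the config hash, input hashes, and
#' the seed used.
#'
#' @param stage One of `"simulate"`, `"preprocess"`, `"connectivity"`,
#'   `"network"`, `"stats"`, `"dataset"`, `"train"`, `"evaluate"`,
#'   `"report"`.
#' @param config A `pipeline_config`.
#' @param quiet Suppress progress messages.
#' @return The stage directory, invisibly.
#' @export
run_stage <- function(stage, config, quiet = FALSE) {
  prereqs <- stage_prereqs(stage)
  input_hashes <- list()
  for (p in prereqs) {
    mf <- file.path(stage_dir(config, p), "manifest.json")
    if (!file.exists(mf))
      stop("stage '", stage, "' needs the output of stage '", p,
           "'; run run_stage(\"", p, "\", config) first")
    input_hashes[[p]] <- unname(tools::md5sum(mf))
  }
  ch <- config_hash(config)
  old <- read_manifest(config, stage)
  if (!is.null(old) && identical(old$config_hash, ch) &&
      identical(lapply(old$input_hashes, identity),
                lapply(input_hashes, identity))) {
    if (!quiet) message("stage '", stage, "' up to date; skipping")
    return(invisible(stage_dir(config, stage)))
  }
  d <- stage_dir(config, stage)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  seed <- derive_seed(config$seed, stage)
  if (!quiet) message("running stage '", stage, "'")
  switch(stage,
         simulate = stage_simulate(config, d),
         preprocess = stage_preprocess(config, d),
         connectivity = stage_connectivity(config, d),
         network = stage_network(config, d, seed),
         stats = stage_stats(config, d),
         dataset = stage_dataset(config, d),
         train = stage_train(config, d, seed),
         evaluate = stage_evaluate(config, d, seed),
         report = stage_report(config, d))
  jsonlite::write_json(list(stage = stage, config_hash = ch,
                            input_hashes = input_hashes, seed = seed),
                       file.path(d, "manifest.json"), auto_unbox = TRUE)
  invisible(d)
}

#' Run the full pipeline
#'
#' Executes every stage in order.
#'
#' @param config A `pipeline_config`.
#' @param quiet Suppress progress messages.
#' @return The report directory, invisibly.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  for (s in c("simulate", "preprocess", "connectivity", "network", "stats",
              "dataset", "train", "evaluate", "report"))
    run_stage(s, config, quiet = quiet)
  invisible(stage_dir(config, "report"))
}

pipeline_synth_config <- function(config) {
  synth_config(n_segments_nm = config$n_segments_nm,
               n_segments_ms = config$n_segments_ms,
               segment_len = config$segment_len,
               noise_sd = config$noise_sd,
               signal_split = config$signal_split,
               seed = derive_seed(config$seed, "simulate"))
}

stage_simulate <- function(config, d) {
  pairs <- gen_dataset(pipeline_synth_config(config))
  write_dataset(pairs, file.path(d, "segments"))
}

stage_preprocess <- function(config, d) {
  pairs <- read_dataset(file.path(stage_dir(config, "simulate"), "segments"))
  for (p in pairs) {
    pd <- file.path(d, p$segment_id)
    dir.create(pd, showWarnings = FALSE, recursive = TRUE)
    pp <- preprocess_pair(p, bands = config$band,
                          eeg_broadband = config$eeg_broadband,
                          fnirs_range = config$fnirs_range)
    write_recording_csv(pp$eeg_broad, file.path(pd, "eeg_broad.csv"))
    write_recording_csv(pp$eeg_bands[[config$band]],
                        file.path(pd, paste0("eeg_", config$band, ".csv")))
    write_recording_csv(pp$coe, file.path(pd, "coe.csv"))
    jsonlite::write_json(list(subject_id = p$subject_id,
                              segment_id = p$segment_id,
                              fms_score = p$fms_score, label = p$label),
                         file.path(pd, "labels.json"), auto_unbox = TRUE)
  }
}

pipeline_segments <- function(config, stage) {
  sort(list.dirs(stage_dir(config, stage), recursive = FALSE))
}

write_matrix_tsv <- function(m, path) {
  utils::write.table(m, path, sep = "\t", quote = FALSE)
}

read_matrix_tsv <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", check.names = FALSE))
}

stage_connectivity <- function(config, d) {
  for (pd in pipeline_segments(config, "preprocess")) {
    seg <- basename(pd)
    od <- file.path(d, seg)
    dir.create(od, showWarnings = FALSE, recursive = TRUE)
    brec <- read_recording(file.path(pd, paste0("eeg_", config$band, ".csv")),
                           "EEG")
    conn <- wpli_matrix(brec, band = config$band, segment_id = seg)
    write_matrix_tsv(conn$values,
                     file.path(od, paste0("eeg_", config$band, ".tsv")))
    coe <- read_recording(file.path(pd, "coe.csv"), "COE")
    connf <- wpli_matrix(coe, band = "coe", segment_id = seg)
    write_matrix_tsv(connf$values, file.path(od, "coe.tsv"))
    file.copy(file.path(pd, "labels.json"), file.path(od, "labels.json"),
              overwrite = TRUE)
  }
}

stage_network <- function(config, d, seed) {
  segs <- pipeline_segments(config, "connectivity")
  conns_eeg <- list(); conns_coe <- list(); labels <- integer()
  for (i in seq_along(segs)) {
    pd <- segs[i]
    ve <- read_matrix_tsv(file.path(pd, paste0("eeg_", config$band, ".tsv")))
    vc <- read_matrix_tsv(file.path(pd, "coe.tsv"))
    conns_eeg[[i]] <- connectivity_matrix(ve, rownames(ve),
                                          band = config$band,
                                          segment_id = basename(pd))
    conns_coe[[i]] <- connectivity_matrix(vc, rownames(vc), band = "coe",
                                          segment_id = basename(pd))
    labels[i] <- jsonlite::read_json(file.path(pd, "labels.json"))$label
  }
  thr <- config$thresholds
  if (identical(thr, "auto")) {
    te <- select_threshold(conns_eeg, seed = seed)
    tc <- select_threshold(conns_coe, seed = seed)
    thr <- stats::setNames(list(te$threshold, tc$threshold),
                           c(config$band, "fnirs"))
  }
  jsonlite::write_json(thr[c(config$band, "fnirs")],
                       file.path(d, "thresholds.json"), auto_unbox = TRUE)
  rows <- list()
  for (i in seq_along(segs)) {
    seg <- basename(segs[i])
    od <- file.path(d, seg)
    dir.create(od, showWarnings = FALSE, recursive = TRUE)
    for (mod in c("eeg", "fnirs")) {
      conn <- if (mod == "eeg") conns_eeg[[i]] else conns_coe[[i]]
      t_i <- if (mod == "eeg") thr[[config$band]] else thr$fnirs
      net <- binarize(conn, t_i)
      write_matrix_tsv(net$adjacency,
                       file.path(od, paste0(mod, ".tsv")))
      rows[[length(rows) + 1]] <- data.frame(
        segment_id = seg, label = labels[i], modality = mod,
        band = if (mod == "eeg") config$band else "coe",
        clustering = clustering_coef(net)$mean,
        global_eff = global_efficiency(net)$value,
        local_eff = local_efficiency(net)$value,
        mean_degree = mean(node_degree(net)))
    }
  }
  utils::write.csv(do.call(rbind, rows), file.path(d, "metrics.csv"),
                   row.names = FALSE)
}

#' Group-comparison table of network metrics
#'
#' Produces the standard summary: one row per band/modality and metric
#' (clustering coefficient, global efficiency, local efficiency) with NM
#' and MS group mean +- sd and the Mann-Whitney significance stars.
#'
#' @param metrics Data frame with columns `label`, `band`, and the metric
#'   columns `clustering`, `global_eff`, `local_eff` (one row per
#'   segment/band as written by the network stage).
#' @return Data frame with columns band, metric, nm, ms, p, stars.
#' @export
report_networks <- function(metrics) {
  out <- list()
  fmt <- function(v) sprintf("%.3f ± %.3f", mean(v), stats::sd(v))
  for (b in unique(metrics$band)) {
    sub <- metrics[metrics$band == b, ]
    for (met in c("clustering", "global_eff", "local_eff")) {
      nm <- sub[[met]][sub$label == 0]
      ms <- sub[[met]][sub$label == 1]
      cmp <- compare_groups(nm, ms)
      out[[length(out) + 1]] <- data.frame(
        band = b, metric = met, nm = fmt(nm), ms = fmt(ms),
        p = cmp$p, stars = cmp$stars)
    }
  }
  do.call(rbind, out)
}

stage_stats <- function(config, d) {
  metrics <- utils::read.csv(file.path(stage_dir(config, "network"),
                                       "metrics.csv"))
  tab <- report_networks(metrics)
  utils::write.csv(tab, file.path(d, "network_stats.csv"), row.names = FALSE)
}

# Rebuild graph samples from the stage artifacts (preprocessed series +
# binarized networks), without re-running filters or WPLI.
pipeline_samples <- function(config) {
  nd <- stage_dir(config, "network")
  thr <- jsonlite::read_json(file.path(nd, "thresholds.json"))
  segs <- pipeline_segments(config, "preprocess")
  out <- list(eeg = list(), fnirs = list(), fused = list())
  for (pd in segs) {
    seg <- basename(pd)
    label <- jsonlite::read_json(file.path(pd, "labels.json"))$label
    brec <- read_recording(file.path(pd, paste0("eeg_", config$band, ".csv")),
                           "EEG")
    broad <- read_recording(file.path(pd, "eeg_broad.csv"), "EEG")
    coe <- read_recording(file.path(pd, "coe.csv"), "COE")
    ae <- read_matrix_tsv(file.path(nd, seg, "eeg.tsv"))
    af <- read_matrix_tsv(file.path(nd, seg, "fnirs.tsv"))
    net_e <- brain_network(ae, rownames(ae),
                           threshold = thr[[config$band]],
                           band = config$band)
    net_f <- brain_network(af, rownames(af), threshold = thr$fnirs,
                           band = "coe")
    es <- build_modal_sample(brec, broad, net_e, eeg_bands()[[config$band]],
                             config$eeg_broadband, label, "eeg", seg)
    fsamp <- build_modal_sample(coe, coe, net_f, fnirs_osc_band(),
                                config$fnirs_range, label, "fnirs", seg)
    out$eeg[[seg]] <- es
    out$fnirs[[seg]] <- fsamp
    out$fused[[seg]] <- build_bimodal_graph(es, fsamp, config$bridge_map)
  }
  out
}

stage_dataset <- function(config, d) {
  samples <- pipeline_samples(config)
  for (mod in config$modalities)
    write_graph_samples(unname(samples[[mod]]), file.path(d, mod))
}

pipeline_gcn_config <- function(config, mode, seed) {
  cfg <- gcn_config(mode = mode, seed = seed)
  for (nm in names(config$gcn)) cfg[[nm]] <- config$gcn[[nm]]
  class(cfg) <- "gcn_config"
  cfg
}

stage_train <- function(config, d, seed) {
  samples <- pipeline_samples(config)
  mode <- if ("fused" %in% config$modalities) "fused"
          else config$modalities[1]
  cfg <- pipeline_gcn_config(config, mode, seed)
  model <- gcn_train(unname(samples[[mode]]), cfg)
  jsonlite::write_json(
    list(cfg = unclass(cfg), seed = seed,
         scaler = model$scaler,
         par = lapply(model$par, function(m) unclass(as.matrix(m))),
         final_loss = utils::tail(model$history, 1)),
    file.path(d, "model.json"), digits = NA, auto_unbox = TRUE)
}

stage_evaluate <- function(config, d, seed) {
  samples <- pipeline_samples(config)
  out <- list()
  for (mod in config$modalities) {
    cfg <- pipeline_gcn_config(config, mod, seed)
    rep_m <- evaluate_cv(unname(samples[[mod]]), cfg, folds = config$folds)
    out[[mod]] <- list(mean = as.list(rep_m$mean), sd = as.list(rep_m$sd),
                       per_fold = rep_m$per_fold)
  }
  jsonlite::write_json(out, file.path(d, "report.json"), auto_unbox = TRUE,
                       digits = NA)
}

stage_report <- function(config, d) {
  stats_tab <- utils::read.csv(file.path(stage_dir(config, "stats"),
                                         "network_stats.csv"))
  eval_rep <- jsonlite::read_json(file.path(stage_dir(config, "evaluate"),
                                            "report.json"))
  jsonlite::write_json(list(network_stats = stats_tab,
                            classification = eval_rep),
                       file.path(d, "report.json"), auto_unbox = TRUE,
                       digits = NA)
}
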