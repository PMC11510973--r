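# Shared fixtures, built once per test run and cached in this
# environment. Sizes are kept small: short segments are enough for the
# structural checks, while the acceptance suite builds its own
# full-size datasets.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env))
    assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

tiny_synth_cfg <- function(...) {
  synth_config(n_segments_nm = 2, n_segments_ms = 2, segment_len = 30,
               seed = 101, ...)
}

tiny_pairs <- function() {
  fixture("tiny_pairs", function() gen_dataset(tiny_synth_cfg()))
}

tiny_dataset <- function() {
  fixture("tiny_dataset", function() build_dataset(tiny_pairs(), band = "beta"))
}

# A moderately sized labeled graph dataset for classifier unit tests:
# 12 + 12 short segments, strongly separable by construction.
small_graph_dataset <- function() {
  fixture("small_graph_dataset", function() {
    cfg <- synth_config(n_segments_nm = 12, n_segments_ms = 12,
                        segment_len = 30, seed = 202)
    build_dataset(gen_dataset(cfg), band = "beta")
  })
}

# Acceptance-scale datasets (built lazily so only the acceptance file
# pays for them): 61 NM / 75 MS segments of 60 s.
acceptance_dataset_both <- function() {
  fixture("acc_both", function() {
    cfg <- synth_config(segment_len = 60, seed = 42)
    build_dataset(gen_dataset(cfg), band = "beta")
  })
}

acceptance_dataset_split <- function() {
  fixture("acc_split", function() {
    cfg <- synth_config(segment_len = 60, seed = 99,
                        signal_split = "alternate")
    build_dataset(gen_dataset(cfg), band = "beta")
  })
}
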