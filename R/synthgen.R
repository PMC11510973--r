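#' Declare a planted coupling between two channels
#'
#' A coupling entry makes the second (follower) channel's band component a
#' phase-lagged copy of the first (leader) channel's component, mixed in
#' proportion to `strength`. A constant phase lag away from 0 and pi
#' yields an imaginary cross-spectrum of constant sign, hence a WPLI near
#' `strength`-dependent saturation.
#'
#' @param pair Character vector `c(leader, follower)`.
#' @param band `"delta"`, `"theta"`, `"alpha"`, `"beta"` (EEG) or `"coe"`
#'   (fNIRS hemodynamic oscillation).
#' @param phase_lag Phase lag in radians, in `(-pi, pi]`.
#' @param strength Mixing proportion in `[0, 1]`.
#' @return A `coupling` list.
#' @export
coupling <- function(pair, band, phase_lag = pi / 2, strength = 0.85) {
  stopifnot(length(pair) == 2, is.character(pair))
  if (!band %in% c(names(eeg_bands()), "coe"))
    stop("unknown band: ", band)
  if (!(phase_lag > -pi && phase_lag <= pi))
    stop("phase_lag must lie in (-pi, pi]")
  if (strength < 0 || strength > 1)
    stop("coupling strength must lie in [0, 1]")
  structure(list(pair = pair, band = band, phase_lag = phase_lag,
                 strength = strength), class = "coupling")
}

#' Default state-dependent coupling topologies
#'
#' Qualitative defaults for the two states: in motion sickness (MS) the
#' prefrontal fNIRS coupling is denser than in the non-sickness state
#' (NM), while beta-band EEG coupling is sparser. Delta, theta and alpha
#' couplings are identical across states (null bands). Fully overridable
#' via [synth_config()].
#'
#' @param state `"NM"` or `"MS"`.
#' @return List of [coupling()] entries.
#' @export
default_coupling <- function(state = c("NM", "MS")) {
  state <- match.arg(state)
  shared <- list(
    coupling(c("AF3", "F3"), "delta", pi / 2, 0.8),
    coupling(c("AF4", "F4"), "delta", pi / 2, 0.8),
    coupling(c("F7", "T7"), "theta", pi / 2, 0.8),
    coupling(c("F8", "T8"), "theta", pi / 2, 0.8),
    coupling(c("O1", "O2"), "alpha", pi / 2, 0.8),
    coupling(c("P7", "P8"), "alpha", pi / 2, 0.8)
  )
  if (state == "NM") {
    c(shared, list(
      coupling(c("Ch1", "Ch5"), "coe", pi / 2, 0.85),
      coupling(c("Ch2", "Ch3"), "coe", pi / 3, 0.7),
      coupling(c("AF3", "AF4"), "beta", pi / 2, 0.85),
      coupling(c("F3", "F4"), "beta", pi / 2, 0.85),
      coupling(c("FC5", "FC6"), "beta", pi / 2, 0.85),
      coupling(c("T7", "T8"), "beta", pi / 2, 0.85),
      coupling(c("P7", "P8"), "beta", pi / 2, 0.85),
      coupling(c("O1", "O2"), "beta", pi / 2, 0.85),
      coupling(c("F7", "F8"), "beta", pi / 2, 0.85),
      coupling(c("AF3", "F3"), "beta", pi / 3, 0.8),
      coupling(c("AF4", "F4"), "beta", pi / 3, 0.8)
    ))
  } else {
    c(shared, list(
      coupling(c("Ch1", "Ch5"), "coe", pi / 2, 0.85),
      coupling(c("Ch1", "Ch2"), "coe", pi / 2, 0.85),
      coupling(c("Ch2", "Ch5"), "coe", pi / 3, 0.85),
      coupling(c("Ch2", "Ch3"), "coe", pi / 2, 0.85),
      coupling(c("Ch2", "Ch4"), "coe", pi / 2, 0.85),
      coupling(c("Ch4", "Ch6"), "coe", pi / 2, 0.85),
      coupling(c("Ch3", "Ch4"), "coe", pi / 3, 0.85),
      coupling(c("F4", "F8"), "beta", pi / 2, 0.85),
      coupling(c("FC6", "T8"), "beta", pi / 2, 0.85),
      coupling(c("F4", "FC6"), "beta", pi / 3, 0.85)
    ))
  }
}

#' Synthetic dataset configuration
#'
#' Configures the generator that emulates the study conditions: 5-minute
#' segments of 14-channel EEG at 128 Hz and 6-channel prefrontal fNIRS at
#' 10 Hz, with a 61/75 split of non-motion-sickness (NM) vs motion
#' sickness (MS) segments and state-dependent coupling topologies.
#'
#' @param n_segments_nm,n_segments_ms Segment counts per state.
#' @param segment_len Segment length in seconds.
#' @param fs_eeg,fs_fnirs Sampling rates in Hz.
#' @param coupling_nm,coupling_ms Lists of [coupling()] entries per state.
#' @param noise_sd Additive noise sd relative to the unit-RMS band
#'   oscillators (pink noise for EEG, white for fNIRS).
#' @param band_amplitudes Named amplitudes of the four EEG band
#'   components, shaping the broadband spectrum.
#' @param signal_split `"both"` plants the MS signature in both
#'   modalities of every MS segment; `"alternate"` plants it in EEG only /
#'   fNIRS only for alternating MS segments, so that neither modality
#'   alone separates the classes fully.
#' @param seed Integer master seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_segments_nm = 61, n_segments_ms = 75,
                         segment_len = 300, fs_eeg = 128, fs_fnirs = 10,
                         coupling_nm = default_coupling("NM"),
                         coupling_ms = default_coupling("MS"),
                         noise_sd = 0.3,
                         band_amplitudes = c(delta = 1, theta = 0.8,
                                             alpha = 0.7, beta = 0.6),
                         signal_split = c("both", "alternate"),
                         seed = 1L) {
  signal_split <- match.arg(signal_split)
  stopifnot(segment_len > 0, fs_eeg > 0, fs_fnirs > 0, noise_sd >= 0)
  if (n_segments_nm < 0 || n_segments_ms < 0)
    stop("segment counts must be non-negative")
  cfg <- structure(
    list(n_segments_nm = as.integer(n_segments_nm),
         n_segments_ms = as.integer(n_segments_ms),
         segment_len = segment_len, fs_eeg = fs_eeg, fs_fnirs = fs_fnirs,
         coupling_nm = coupling_nm, coupling_ms = coupling_ms,
         noise_sd = noise_sd,
         band_amplitudes = band_amplitudes[names(eeg_bands())],
         signal_split = signal_split, seed = as.integer(seed)),
    class = "synth_config"
  )
  validate_couplings(cfg)
  cfg
}

validate_couplings <- function(cfg) {
  for (map in list(cfg$coupling_nm, cfg$coupling_ms)) {
    for (cp in map) {
      declared <- if (cp$band == "coe") fnirs_channels() else eeg_montage()
      unknown <- setdiff(cp$pair, declared)
      if (length(unknown))
        stop("coupling references undeclared channel(s): ",
             paste(unknown, collapse = ", "), " (band ", cp$band, ")")
    }
  }
  invisible(cfg)
}

# Center frequencies used to convert a phase lag into a time delay.
band_center <- function(band) {
  if (band == "coe") return(0.06)
  r <- eeg_bands()[[band]]
  mean(r)
}

# Unit-RMS band-limited Gaussian process (order-4 zero-phase Butterworth
# bandpass of white noise).
band_oscillator <- function(n, fs, low, high) {
  b <- signal::butter(4, c(low, high) * 2 / fs, type = "pass")
  x <- signal::filtfilt(b, stats::rnorm(n))
  x / stats::sd(x)
}

apply_couplings <- function(comps, couplings, band, fs) {
  for (cp in couplings) {
    if (cp$band != band) next
    leader <- cp$pair[1]; follower <- cp$pair[2]
    tau <- cp$phase_lag / (2 * pi * band_center(band))
    lagged <- frac_delay(comps[[leader]], tau, fs)
    comps[[follower]] <- cp$strength * lagged +
      (1 - cp$strength) * comps[[follower]]
  }
  comps
}

#' Generate one synthetic EEG segment
#'
#' Each channel is a sum over the four bands of unit-RMS narrow-band
#' oscillators (amplitude-weighted per band) plus pink noise. Couplings of
#' the selected state make follower components phase-lagged copies of
#' leader components. Deterministic given `seed`.
#'
#' @param state `"NM"` or `"MS"`.
#' @param cfg A [synth_config()].
#' @param seed Integer seed for this segment.
#' @return A `recording` with modality `"EEG"`.
#' @export
gen_eeg_segment <- function(state = c("NM", "MS"), cfg = synth_config(),
                            seed = cfg$seed) {
  state <- match.arg(state)
  couplings <- if (state == "NM") cfg$coupling_nm else cfg$coupling_ms
  n <- round(cfg$segment_len * cfg$fs_eeg)
  chans <- eeg_montage()
  with_seed(seed, {
    comps <- lapply(names(eeg_bands()), function(b) {
      r <- eeg_bands()[[b]]
      cl <- lapply(chans, function(ch) band_oscillator(n, cfg$fs_eeg, r[1], r[2]))
      names(cl) <- chans
      cl
    })
    names(comps) <- names(eeg_bands())
    for (b in names(comps))
      comps[[b]] <- apply_couplings(comps[[b]], couplings, b, cfg$fs_eeg)
    noise <- lapply(chans, function(ch) pink_noise(n))
    out <- matrix(0, length(chans), n)
    for (i in seq_along(chans)) {
      acc <- cfg$noise_sd * noise[[i]]
      for (b in names(comps))
        acc <- acc + cfg$band_amplitudes[[b]] * comps[[b]][[chans[i]]]
      out[i, ] <- acc
    }
    recording(out, fs = cfg$fs_eeg, channel_names = chans, modality = "EEG")
  })
}

#' Generate one synthetic fNIRS segment (HbO and HbR)
#'
#' Each channel's HbO series is a unit-RMS slow hemodynamic oscillator
#' (0.02-0.1 Hz band) plus a sub-0.01 Hz drift and white noise; HbR is
#' anti-correlated with HbO (factor -0.5) plus independent noise, so the
#' cerebral-oxygen-exchange series dCOE = HbR - HbO carries the planted
#' coupling with amplitude 1.5.
#'
#' @inheritParams gen_eeg_segment
#' @return List with elements `hbo` and `hbr`, both `recording`s.
#' @export
gen_fnirs_segment <- function(state = c("NM", "MS"), cfg = synth_config(),
                              seed = cfg$seed) {
  state <- match.arg(state)
  couplings <- if (state == "NM") cfg$coupling_nm else cfg$coupling_ms
  n <- round(cfg$segment_len * cfg$fs_fnirs)
  chans <- fnirs_channels()
  with_seed(seed, {
    comps <- lapply(chans, function(ch)
      band_oscillator(n, cfg$fs_fnirs, 0.02, 0.1))
    names(comps) <- chans
    comps <- apply_couplings(comps, couplings, "coe", cfg$fs_fnirs)
    tt <- (seq_len(n) - 1) / cfg$fs_fnirs
    hbo <- matrix(0, length(chans), n)
    hbr <- matrix(0, length(chans), n)
    for (i in seq_along(chans)) {
      drift <- 0.3 * sin(2 * pi * tt / cfg$segment_len + stats::runif(1, 0, 2 * pi))
      hbo[i, ] <- comps[[chans[i]]] + drift +
        0.6 * cfg$noise_sd * stats::rnorm(n)
      hbr[i, ] <- -0.5 * comps[[chans[i]]] +
        0.3 * cfg$noise_sd * stats::rnorm(n)
    }
    list(hbo = recording(hbo, cfg$fs_fnirs, chans, modality = "HBO"),
         hbr = recording(hbr, cfg$fs_fnirs, chans, modality = "HBR"))
  })
}

#' Generate a labeled synthetic dataset of EEG+fNIRS segment pairs
#'
#' Produces `n_segments_nm + n_segments_ms` labeled pairs. FMS self-report
#' scores are 1 for NM segments and uniform on 2..6 for MS segments; the
#' label is 0 iff the score is 1. Reproducible from `cfg$seed`.
#'
#' @param cfg A [synth_config()].
#' @return List of `segment_pair` objects with fields `eeg`, `fnirs_hbo`,
#'   `fnirs_hbr`, `fms_score`, `label`, `subject_id`, `segment_id`.
#' @export
gen_dataset <- function(cfg = synth_config()) {
  n_tot <- cfg$n_segments_nm + cfg$n_segments_ms
  if (n_tot < 1) stop("dataset must contain at least one segment")
  states <- c(rep("NM", cfg$n_segments_nm), rep("MS", cfg$n_segments_ms))
  ms_idx <- which(states == "MS")
  split <- rep("both", n_tot)
  if (cfg$signal_split == "alternate" && length(ms_idx))
    split[ms_idx] <- rep(c("eeg", "fnirs"), length.out = length(ms_idx))
  fms <- with_seed(derive_seed(cfg$seed, "fms"), {
    ifelse(states == "NM", 1L, sample(2:6, n_tot, replace = TRUE))
  })
  lapply(seq_len(n_tot), function(i) {
    st <- states[i]
    eeg_state <- if (st == "MS" && split[i] %in% c("both", "eeg")) "MS" else "NM"
    fn_state <- if (st == "MS" && split[i] %in% c("both", "fnirs")) "MS" else "NM"
    eeg <- gen_eeg_segment(eeg_state, cfg, derive_seed(cfg$seed, paste0("eeg", i)))
    fn <- gen_fnirs_segment(fn_state, cfg, derive_seed(cfg$seed, paste0("fnirs", i)))
    structure(
      list(eeg = eeg, fnirs_hbo = fn$hbo, fnirs_hbr = fn$hbr,
           fms_score = fms[i], label = label_segment(fms[i]),
           subject_id = sprintf("S%02d", (i - 1) %/% 6 + 1),
           segment_id = sprintf("seg%03d", i)),
      class = "segment_pair"
    )
  })
}

#' @export
print.segment_pair <- function(x, ...) {
  cat(sprintf("<segment_pair> %s (subject %s): FMS %d, label %d\n",
              x$segment_id, x$subject_id, x$fms_score, x$label))
  invisible(x)
}

#' Write a dataset to disk, one directory per segment
#'
#' Each segment directory holds `eeg.csv`, `fnirs_hbo.csv`,
#' `fnirs_hbr.csv` (time column plus one column per channel) and a
#' `labels.json` sidecar.
#'
#' @param pairs List of `segment_pair`s from [gen_dataset()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(pairs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in pairs) {
    d <- file.path(dir, p$segment_id)
    dir.create(d, showWarnings = FALSE)
    write_recording_csv(p$eeg, file.path(d, "eeg.csv"))
    write_recording_csv(p$fnirs_hbo, file.path(d, "fnirs_hbo.csv"))
    write_recording_csv(p$fnirs_hbr, file.path(d, "fnirs_hbr.csv"))
    jsonlite::write_json(
      list(subject_id = p$subject_id, segment_id = p$segment_id,
           fms_score = p$fms_score, label = p$label),
      file.path(d, "labels.json"), auto_unbox = TRUE)
  }
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Dataset directory.
#' @return List of `segment_pair`s.
#' @export
read_dataset <- function(dir) {
  segs <- sort(list.dirs(dir, recursive = FALSE))
  if (!length(segs)) stop("no segment directories under ", dir)
  lapply(segs, function(d) {
    meta <- jsonlite::read_json(file.path(d, "labels.json"))
    structure(
      list(eeg = read_recording(file.path(d, "eeg.csv"), "EEG"),
           fnirs_hbo = read_recording(file.path(d, "fnirs_hbo.csv"), "HBO"),
           fnirs_hbr = read_recording(file.path(d, "fnirs_hbr.csv"), "HBR"),
           fms_score = as.integer(meta$fms_score),
           label = as.integer(meta$label),
           subject_id = meta$subject_id, segment_id = meta$segment_id),
      class = "segment_pair"
    )
  })
}
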