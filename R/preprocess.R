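#' Zero-phase Butterworth band-pass filter
#'
#' Order-`order` Butterworth filter applied forward and backward
#' (zero-phase, doubling the effective magnitude roll-off). With `low = 0`
#' a pure low-pass is designed; otherwise DC is removed by the high-pass
#' edge.
#'
#' @param rec A `recording`.
#' @param low,high Band edges in Hz; require `0 <= low < high < fs/2`.
#' @param order Filter order (default 4).
#' @return Filtered `recording`, same shape and metadata.
#' @export
bandpass <- function(rec, low, high, order = 4) {
  nyq <- rec$fs / 2
  if (!(low >= 0 && low < high && high < nyq))
    stop("band [", low, ", ", high, "] must satisfy 0 <= low < high < fs/2 = ", nyq)
  b <- if (low == 0) {
    signal::butter(order, high / nyq, type = "low")
  } else {
    signal::butter(order, c(low, high) / nyq, type = "pass")
  }
  out <- rec
  out$samples <- t(apply(rec$samples, 1, function(x) signal::filtfilt(b, x)))
  rownames(out$samples) <- rec$channel_names
  out
}

#' Decompose a broadband EEG recording into the four sub-bands
#'
#' Applies the band-pass of [eeg_bands()] to each channel, returning one
#' recording per band (delta 0.5-4, theta 4-8, alpha 8-12, beta 12-32 Hz).
#' The input is expected to be broadband-filtered EEG (0.5-45 Hz).
#'
#' @param eeg A `recording` with modality `"EEG"`.
#' @param order Filter order per band.
#' @return Named list of `recording`s, one per band.
#' @export
decompose_bands <- function(eeg, order = 4) {
  if (eeg$modality != "EEG") stop("decompose_bands expects an EEG recording")
  lapply(eeg_bands(), function(r) bandpass(eeg, r[1], r[2], order = order))
}

#' Cerebral oxygen exchange from HbO and HbR recordings
#'
#' Samplewise dCOE = dC_HbR - dC_HbO: the difference between the
#' deoxygenated and oxygenated hemoglobin concentration changes,
#' summarizing oxygenation status per fNIRS channel.
#'
#' @param hbo,hbr `recording`s with identical fs, channels, and length.
#' @return A `recording` with modality `"COE"`.
#' @export
compute_coe <- function(hbo, hbr) {
  if (hbo$fs != hbr$fs ||
      !identical(dim(hbo$samples), dim(hbr$samples)) ||
      !identical(hbo$channel_names, hbr$channel_names))
    stop("HbO and HbR recordings must share fs, channels, and length")
  recording(hbr$samples - hbo$samples, hbo$fs, hbo$channel_names,
            modality = "COE", t0 = hbo$t0)
}

#' Motion-sickness label from an FMS score
#'
#' The 6-point Fast Motion Sickness scale is dichotomized: a score of 1
#' (no sensation at all) labels the segment non-motion-sickness (0), any
#' score above 1 labels it motion sickness (1).
#'
#' @param fms_score Integer in 1..6.
#' @return 0 or 1.
#' @export
label_segment <- function(fms_score) {
  if (length(fms_score) != 1 || is.na(fms_score) ||
      fms_score != round(fms_score) || fms_score < 1 || fms_score > 6)
    stop("FMS score must be an integer in 1..6, got ", fms_score)
  if (fms_score == 1) 0L else 1L
}

#' Artifact-removal hook
#'
#' Placeholder for artifact-removal procedures (e.g. ICA for EEG motion
#' artifacts) that operate on real recordings; the default is the
#' identity, appropriate for synthetic data. A user-supplied function must
#' preserve the recording's shape and sampling rate.
#'
#' @param rec A `recording`.
#' @param method `"none"` or a function `recording -> recording`.
#' @return A `recording`.
#' @export
artifact_hook <- function(rec, method = "none") {
  if (identical(method, "none")) return(rec)
  if (!is.function(method)) stop("method must be \"none\" or a function")
  out <- method(rec)
  if (!inherits(out, "recording") ||
      !identical(dim(out$samples), dim(rec$samples)) || out$fs != rec$fs)
    stop("artifact hook must preserve recording shape and fs")
  out
}

#' Preprocess a segment pair for network construction
#'
#' EEG: 0.5-45 Hz broadband filter, optional artifact hook, then sub-band
#' decomposition. fNIRS: dCOE from HbO/HbR, then the fNIRS band-pass.
#'
#' @param pair A `segment_pair`.
#' @param bands Character vector of EEG band names to decompose
#'   (default all four).
#' @param eeg_broadband `c(low, high)` of the broadband EEG filter.
#' @param fnirs_range `c(low, high)` of the fNIRS band-pass.
#' @param artifact EEG artifact hook passed to [artifact_hook()].
#' @return List with `eeg_broad` (recording), `eeg_bands` (named list of
#'   recordings), `coe` (recording), and the pair's label metadata.
#' @export
preprocess_pair <- function(pair, bands = names(eeg_bands()),
                            eeg_broadband = c(0.5, 45),
                            fnirs_range = fnirs_band(),
                            artifact = "none") {
  eeg <- bandpass(pair$eeg, eeg_broadband[1], eeg_broadband[2])
  eeg <- artifact_hook(eeg, artifact)
  sub <- lapply(eeg_bands()[bands], function(r) bandpass(eeg, r[1], r[2]))
  coe <- compute_coe(pair$fnirs_hbo, pair$fnirs_hbr)
  coe <- bandpass(coe, fnirs_range[1], fnirs_range[2])
  list(eeg_broad = eeg, eeg_bands = sub, coe = coe,
       label = pair$label, fms_score = pair$fms_score,
       subject_id = pair$subject_id, segment_id = pair$segment_id)
}
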