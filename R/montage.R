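#' Canonical 14-channel EEG montage
#'
#' Channel names of the 14-electrode frontal/temporal/parietal/occipital
#' montage (international 10-20 placement) expected for full-montage EEG
#' recordings, in canonical order.
#'
#' @return Character vector of 14 channel names.
#' @export
eeg_montage <- function() {
  c("AF3", "F7", "F3", "FC5", "T7", "P7", "O1",
    "O2", "P8", "T8", "FC6", "F4", "F8", "AF4")
}

#' Prefrontal fNIRS channel names
#'
#' Six optode-pair channels covering the prefrontal cortex: Ch1/Ch5 left,
#' Ch2/Ch3 midline, Ch4/Ch6 right.
#'
#' @return Character vector of 6 channel names.
#' @export
fnirs_channels <- function() {
  paste0("Ch", 1:6)
}

#' EEG frequency band definitions
#'
#' The four classic sub-bands used throughout the pipeline. The delta band
#' is bounded below at 0.5 Hz because the broadband filter high-passes at
#' 0.5 Hz, so content below that is unattainable.
#'
#' @return Named list of `c(low, high)` ranges in Hz.
#' @export
eeg_bands <- function() {
  list(
    delta = c(0.5, 4),
    theta = c(4, 8),
    alpha = c(8, 12),
    beta  = c(12, 32)
  )
}

#' fNIRS analysis band
#'
#' Pass band applied to cerebral-oxygen-exchange series before
#' connectivity estimation. Hemodynamic oscillations of interest sit below
#' 0.1 Hz; the 0.2 Hz upper edge removes cardiac/respiratory residue.
#'
#' @return `c(low, high)` in Hz.
#' @export
fnirs_band <- function() {
  c(0.01, 0.2)
}

# Sub-band used for the "relative band power" node feature of COE series.
fnirs_osc_band <- function() {
  c(0.01, 0.1)
}

#' Default bimodal bridge map
#'
#' Channel pairing used to bridge the fNIRS prefrontal channels to the
#' spatially nearest frontal EEG electrodes when fusing the two networks:
#' left channels to AF3/F7, midline channels to both AF3 and AF4, right
#' channels to AF4/F8.
#'
#' @return Named list mapping each fNIRS channel to EEG channel names.
#' @export
default_bridge_map <- function() {
  list(
    Ch1 = "AF3",
    Ch5 = "F7",
    Ch3 = c("AF3", "AF4"),
    Ch2 = c("AF3", "AF4"),
    Ch4 = "AF4",
    Ch6 = "F8"
  )
}
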