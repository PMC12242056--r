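#' Posterior (visual-cortex) channel names
#'
#' The six occipital / parieto-occipital electrodes over visual cortex that
#' the channel-perturbation experiment targets.
#'
#' @return Character vector of six channel names.
#' @export
posterior_channels <- function() {
  c("O1", "O2", "Oz", "PO3", "PO4", "POz")
}

# full 64-name 10-10 montage (Easycap-style layout); posterior six included
.montage64 <- c(
  "Fp1", "Fpz", "Fp2", "AF7", "AF3", "AFz", "AF4", "AF8",
  "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
  "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
  "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
  "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
  "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
  "PO7", "PO3", "POz", "PO4", "PO8", "O1", "Oz", "O2", "Iz",
  "P9", "P10"
)

#' EEG montage channel names
#'
#' Returns `n_channels` names from a 64-channel 10-10 montage. When a subset
#' is requested the six posterior channels (`O1, O2, Oz, PO3, PO4, POz`) are
#' always retained, so scaled-down configurations remain usable for the
#' visual-cortex perturbation experiment.
#'
#' @param n_channels Number of channels, between 7 and 64.
#' @return Character vector of channel names.
#' @examples
#' montage_1010(17)
#' @export
montage_1010 <- function(n_channels = 64) {
  if (n_channels < 7 || n_channels > 64) {
    stop_arg("n_channels must be between 7 and 64")
  }
  if (n_channels == 64) {
    return(.montage64)
  }
  post <- posterior_channels()
  rest <- setdiff(.montage64, post)
  # spread the remaining picks across the scalp
  pick <- rest[round(seq(1, length(rest), length.out = n_channels - 6L))]
  out <- c(pick, post)
  out[order(match(out, .montage64))]
}
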