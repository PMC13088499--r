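#' Default 24-channel 10-20 montage
#'
#' Fixed table of 24 electrode positions from the international 10-20 system,
#' covering the motor strip (C3, Cz, C4), its surround, frontal and occipital
#' sites, with approximate 2-D head-circle coordinates (unit head radius,
#' nose up).  The coordinates are used to spread spatially localized events
#' (eye blinks, muscle bursts) across neighbouring channels with a
#' distance-based decay.
#'
#' @return A data.frame with columns `name`, `x`, `y`.
#' @export
#' @examples
#' head(default_montage())
default_montage <- function() {
  tab <- rbind(
    c("Fp1", -0.31, 0.95), c("Fp2", 0.31, 0.95),
    c("F7",  -0.81, 0.59), c("F3", -0.55, 0.68), c("Fz", 0.00, 0.72),
    c("F4",   0.55, 0.68), c("F8",  0.81, 0.59),
    c("FC5", -0.59, 0.35), c("FC1", -0.28, 0.38),
    c("FC2",  0.28, 0.38), c("FC6", 0.59, 0.35),
    c("T7",  -1.00, 0.00), c("C3", -0.50, 0.00), c("Cz", 0.00, 0.00),
    c("C4",   0.50, 0.00), c("T8",  1.00, 0.00),
    c("CP5", -0.59, -0.35), c("CP1", -0.28, -0.38),
    c("CP2",  0.28, -0.38), c("CP6", 0.59, -0.35),
    c("P3",  -0.55, -0.68), c("Pz", 0.00, -0.72), c("P4", 0.55, -0.68),
    c("Oz",   0.00, -1.00)
  )
  data.frame(
    name = tab[, 1],
    x = as.numeric(tab[, 2]),
    y = as.numeric(tab[, 3]),
    stringsAsFactors = FALSE
  )
}

montage_distance <- function(montage, from_channel) {
  i <- match(from_channel, montage$name)
  if (is.na(i)) stop_mibci("channel '%s' not in montage", from_channel)
  sqrt((montage$x - montage$x[i])^2 + (montage$y - montage$y[i])^2)
}
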