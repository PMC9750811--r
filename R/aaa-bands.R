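#' Band names of the five-band multispectral sensor
#'
#' Band centers 450 (blue), 560 (green), 650 (red), 730 (red edge) and
#' 840 nm (near infrared), in sensor order.
#' @export
SPECTRAL_BANDS <- c("B450", "G560", "R650", "RE730", "NIR840")
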