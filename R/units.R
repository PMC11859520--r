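#' Convert an attenuation coefficient to m^-1
#'
#' Internal unit convention is SI (m^-1, m). Tables and user input may carry
#' coefficients in cm^-1, which is the common unit in the biophotonics
#' literature; conversion is an exact factor of 100 so a cm^-1 -> m^-1 ->
#' cm^-1 round trip is lossless.
#'
#' @param x numeric vector of coefficients.
#' @param units one of `"m^-1"` or `"cm^-1"`.
#' @return coefficients in m^-1.
#' @examples
#' coef_to_per_m(0.028, "cm^-1")  # 2.8 m^-1
#' @export
coef_to_per_m <- function(x, units = c("m^-1", "cm^-1")) {
  units <- match.arg(units)
  if (units == "cm^-1") x * 100 else x
}

#' Convert an attenuation coefficient from m^-1 to cm^-1
#' @param x numeric vector in m^-1.
#' @return coefficients in cm^-1.
#' @export
coef_to_per_cm <- function(x) x / 100
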