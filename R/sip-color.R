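# CIELab / HSV color statistics.

# 256-bin histogram entropy (bits) of values in [0, 1]. Hue uses the same
# partition; since the bins tile the full circle the binning wraps
# naturally.
channel_entropy_bits <- function(v, bins = 256) {
  b <- pmin(floor(v * bins) + 1L, bins)
  counts <- tabulate(b, nbins = bins)
  p <- counts / sum(counts)
  shannon_entropy(p) / log(2)
}

#' Color statistics in CIELab and HSV
#'
#' Converts sRGB (D65) to CIELab and HSV and summarizes each channel.
#' Means are arithmetic except the hue mean, which is circular and reported
#' as an angle in degrees `[0, 360)`. Channel entropies use 256-bin
#' histograms and are reported in bits; the hue histogram partition tiles
#' the full color circle. The Lab b mean captures the yellow-blue balance,
#' HSV S the mean saturation, and the hue entropy is a colorfulness
#' measure: 0 for a single hue, up to 8 bits for a flat hue distribution.
#'
#' @param img RGB array in `[0, 1]`.
#' @return A named list: `lab_L_mean`, `lab_a_mean`, `lab_b_mean`,
#'   `hsv_H_mean` (degrees), `hsv_S_mean`, `hsv_V_mean`, `entropy_hsv_H`,
#'   `entropy_hsv_S`, `entropy_hsv_V` (bits).
#' @export
color_statistics <- function(img) {
  img <- as_rgb_image(img)
  lab <- rgb_to_lab(img)
  hsv <- rgb_to_hsv_mat(img)
  ang <- hsv[, 1] * 2 * pi
  hue_mean <- (atan2(mean(sin(ang)), mean(cos(ang))) * 180 / pi) %% 360
  list(
    lab_L_mean = mean(lab[, 1]),
    lab_a_mean = mean(lab[, 2]),
    lab_b_mean = mean(lab[, 3]),
    hsv_H_mean = hue_mean,
    hsv_S_mean = mean(hsv[, 2]),
    hsv_V_mean = mean(hsv[, 3]),
    entropy_hsv_H = channel_entropy_bits(hsv[, 1]),
    entropy_hsv_S = channel_entropy_bits(hsv[, 2]),
    entropy_hsv_V = channel_entropy_bits(hsv[, 3])
  )
}
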