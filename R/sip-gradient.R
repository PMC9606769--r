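# Gradient machinery shared by the HOG-style SIPs (complexity, PHOG
# self-similarity/anisotropy, mirror symmetry).

# Central differences with replicate boundary (one-sided at the edges).
grad_x <- function(m) {
  w <- ncol(m)
  m[, c(2:w, w), drop = FALSE] - m[, c(1, 1:(w - 1)), drop = FALSE]
}
grad_y <- function(m) {
  h <- nrow(m)
  m[c(2:h, h), , drop = FALSE] - m[c(1, 1:(h - 1)), , drop = FALSE]
}

# Lab channels on a 0-255 convention so gradient magnitudes follow the
# classical 8-bit HOG scale: L in [0,100] -> x2.55, a/b shifted by +128.
lab_channels_255 <- function(img) {
  lab <- rgb_to_lab(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  list(
    matrix(lab[, 1] * 2.55, h, w),
    matrix(lab[, 2] + 128, h, w),
    matrix(lab[, 3] + 128, h, w)
  )
}

# Color gradient field: per Lab channel central-difference gradients; at each
# pixel the channel with the largest magnitude wins and contributes both the
# magnitude and the (unsigned, mod 180 degrees) orientation.
gradient_field <- function(img) {
  chans <- lab_channels_255(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  best_mag <- matrix(0, h, w)
  best_ori <- matrix(0, h, w)
  for (ch in chans) {
    gx <- grad_x(ch); gy <- grad_y(ch)
    mag <- sqrt(gx^2 + gy^2)
    upd <- mag > best_mag
    if (any(upd)) {
      ori <- (atan2(gy, gx) * 180 / pi) %% 180
      best_ori[upd] <- ori[upd]
      best_mag[upd] <- mag[upd]
    }
  }
  list(magnitude = best_mag, orientation = best_ori)
}

#' Gradient-based image complexity
#'
#' Mean gradient strength of the image (HOG approach): per-channel first
#' derivative magnitudes in CIELab space (channels on a 0-255 convention),
#' the pixelwise maximum over channels, averaged over all pixels. Zero for a
#' constant image; dense fine texture scores higher than coarse structure of
#' the same contrast.
#'
#' @param img An RGB array (H x W x 3, values in `[0, 1]`).
#' @return A single non-negative number.
#' @export
gradient_complexity <- function(img) {
  img <- as_rgb_image(img)
  mean(gradient_field(img)$magnitude)
}
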