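#' Specify a random-phase stimulus
#'
#' Bundles the parameters of a random-phase image: the square side length in
#' pixels, the target slope of log Fourier power versus log spatial frequency,
#' and the RNG seed. Random-phase patterns with slopes near -2 resemble the
#' second-order statistics of natural scenes; steeper (more negative) slopes
#' look cloud-like, a slope of 0 is white noise.
#'
#' @param size_px Square side in pixels; must be even and at least 16.
#'   Default 1024, the resolution at which study stimuli are rendered.
#' @param set_slope Target spectral slope alpha (log power vs log frequency).
#'   Study conditions use -5, -4, -3, -2, -1, 0; any non-positive value is
#'   typical, positive values are allowed but unusual.
#' @param seed Integer seed; the whole synthesis is deterministic given it.
#' @return An object of class `random_phase_spec`.
#' @seealso [synthesize_gray_random_phase()], [synthesize_colored_random_phase()]
#' @export
random_phase_spec <- function(size_px = 1024, set_slope = -2, seed = 1L) {
  if (!is.numeric(size_px) || length(size_px) != 1L || is.na(size_px) ||
      size_px < 16 || size_px %% 2 != 0) {
    abort("`size_px` must be a single even integer >= 16.",
          class = "sipstats_invalid_spec")
  }
  if (!is.numeric(set_slope) || length(set_slope) != 1L || !is.finite(set_slope)) {
    abort("`set_slope` must be a single finite number.",
          class = "sipstats_invalid_spec")
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer.", class = "sipstats_invalid_spec")
  }
  structure(
    list(size_px = as.integer(size_px), set_slope = set_slope,
         seed = as.integer(seed)),
    class = "random_phase_spec"
  )
}

#' @export
print.random_phase_spec <- function(x, ...) {
  cat(sprintf("<random_phase_spec> %dx%d px, set slope %.2f, seed %d\n",
              x$size_px, x$size_px, x$set_slope, x$seed))
  invisible(x)
}

# Signed frequency (cycles/image) for 0-based DFT index along one axis.
dft_freq <- function(n) {
  idx <- 0:(n - 1)
  ifelse(idx > n / 2, idx - n, idx)
}

# Hermitian-symmetrized phase field. Phases are drawn uniform on [0, 2pi)
# column-major; each cell's conjugate partner gets the negated phase and
# self-conjugate cells (DC and Nyquist combinations) are forced real.
hermitian_phases <- function(n, phi) {
  idx0 <- 0:(n - 1)
  p0 <- (n - idx0) %% n            # 0-based partner index per axis
  lin <- outer(idx0, idx0 * n, "+")        # 0-based col-major linear index
  lin_partner <- outer(p0, p0 * n, "+")
  partner_phi <- phi[p0 + 1, p0 + 1]
  out <- ifelse(lin < lin_partner, phi, -partner_phi)
  out[lin == lin_partner] <- 0
  out
}

# Radial amplitude grid |A(f)| = f^(alpha/2), DC forced to zero.
radial_amplitude <- function(n, alpha) {
  f1 <- dft_freq(n)
  f <- sqrt(outer(f1^2, f1^2, "+"))
  amp <- matrix(0, n, n)
  nz <- f > 0
  amp[nz] <- f[nz]^(alpha / 2)
  amp
}

#' Synthesize a grayscale random-phase image
#'
#' Builds a deterministic amplitude spectrum `|A(f)| = f^(alpha/2)` over
#' radial spatial frequency `f` (cycles/image), so that Fourier power falls as
#' `f^alpha`, pairs it with uniformly random phases under Hermitian symmetry,
#' and inverse-transforms. The DC component is zeroed and the result is
#' linearly rescaled to `[0, 1]`, which leaves the measured log-log slope
#' unchanged (spectra are scale invariant away from DC).
#'
#' @param spec A [random_phase_spec()].
#' @return A `size_px` x `size_px` numeric matrix with values in `[0, 1]`.
#' @examples
#' img <- synthesize_gray_random_phase(random_phase_spec(128, -2, seed = 7))
#' range(img)
#' @export
synthesize_gray_random_phase <- function(spec) {
  stopifnot(inherits(spec, "random_phase_spec"))
  n <- spec$size_px
  phi <- withr::with_seed(spec$seed,
                          matrix(runif(n * n, 0, 2 * pi), n, n))
  phi <- hermitian_phases(n, phi)
  amp <- radial_amplitude(n, spec$set_slope)
  spec_grid <- amp * exp(1i * phi)
  img <- Re(fft(spec_grid, inverse = TRUE)) / n^2
  rescale01(img)
}

#' Synthesize a colored random-phase image
#'
#' Merges three independent grayscale random-phase syntheses of the same
#' slope into the R, G and B channels. Channel sub-seeds are derived from the
#' master seed by fixed offsets (`seed + (channel - 1) * 1000003`), so output
#' is reproducible and channels are pairwise uncorrelated in expectation.
#'
#' @inheritParams synthesize_gray_random_phase
#' @return A `size_px` x `size_px` x 3 numeric array with values in `[0, 1]`.
#' @export
synthesize_colored_random_phase <- function(spec) {
  stopifnot(inherits(spec, "random_phase_spec"))
  chans <- lapply(0:2, function(k) {
    sub <- random_phase_spec(spec$size_px, spec$set_slope,
                             spec$seed + k * 1000003L)
    synthesize_gray_random_phase(sub)
  })
  array(c(chans[[1]], chans[[2]], chans[[3]]),
        dim = c(spec$size_px, spec$size_px, 3L))
}

#' Measure the Fourier spectral slope of an image
#'
#' Converts RGB input to Rec. 709 luminance, computes the 2-D power spectrum,
#' averages power in log-spaced radial frequency bins, and fits a least
#' squares line of log power against log frequency over `fit_range`.
#' Natural scenes and most paintings sit near a slope of -2.
#'
#' @param img A grayscale matrix or H x W x 3 array.
#' @param fit_range Numeric `(f_min, f_max)` in cycles/image. Default
#'   `c(10, N/4)` avoids DC leakage at low frequencies and corner anisotropy
#'   near Nyquist.
#' @param n_bins Number of log-spaced radial bins (default 30).
#' @return A one-row tibble: `slope`, `intercept`, `r_squared`, `f_min`,
#'   `f_max`, `n_bins_used`.
#' @export
measure_fourier_slope <- function(img, fit_range = NULL, n_bins = 30) {
  x <- if (length(dim(img)) == 3L) luminance(img) else img
  stopifnot(is.matrix(x))
  n <- nrow(x)
  if (ncol(x) != n) {
    # pad-free handling: crop to the central square so the radial grid is
    # isotropic in cycles/image
    m <- min(dim(x))
    x <- x[seq_len(m) + (nrow(x) - m) %/% 2, seq_len(m) + (ncol(x) - m) %/% 2]
    n <- m
  }
  if (is.null(fit_range)) fit_range <- c(10, n / 4)
  f_min <- fit_range[1]; f_max <- fit_range[2]
  if (f_min < 1 || f_max > n / 2 || f_min >= f_max) {
    abort("`fit_range` must satisfy 1 <= f_min < f_max <= Nyquist (size/2).",
          class = "sipstats_range_error")
  }
  if (n < 2 * f_min) {
    abort("image side must be at least 2 * f_min.",
          class = "sipstats_range_error")
  }
  pw <- Mod(fft(x))^2
  f1 <- dft_freq(n)
  f <- sqrt(outer(f1^2, f1^2, "+"))
  keep <- f >= f_min & f <= f_max
  pvals <- pw[keep]
  fvals <- f[keep]
  if (all(pvals < .Machine$double.eps * n^2)) {
    abort("degenerate spectrum: image is (near) constant.",
          class = "sipstats_degenerate_spectrum")
  }
  edges <- exp(seq(log(f_min), log(f_max), length.out = n_bins + 1))
  bin <- findInterval(fvals, edges, rightmost.closed = TRUE)
  bin[bin < 1] <- 1; bin[bin > n_bins] <- n_bins
  lf <- tapply(log(fvals), bin, mean)
  lp <- log(tapply(pvals, bin, mean))
  ok <- is.finite(lf) & is.finite(lp)
  fit <- lm(lp[ok] ~ lf[ok])
  r2 <- suppressWarnings(summary(fit)$r.squared)
  tibble(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = r2,
    f_min = f_min, f_max = f_max,
    n_bins_used = sum(ok)
  )
}

#' Visual angle subtended by a stimulus
#'
#' `2 * atan(width / (2 * distance))`, in degrees. The study geometry
#' (28.22 cm wide at 80 cm) gives 20 degrees.
#'
#' @param stimulus_width_cm Physical stimulus width (> 0).
#' @param viewing_distance_cm Viewing distance (> 0), same units.
#' @return Visual angle in degrees.
#' @examples
#' compute_visual_angle(28.22, 80)
#' @export
compute_visual_angle <- function(stimulus_width_cm, viewing_distance_cm) {
  if (!is.numeric(stimulus_width_cm) || !is.numeric(viewing_distance_cm) ||
      any(stimulus_width_cm <= 0) || any(viewing_distance_cm <= 0)) {
    abort("width and distance must be positive.",
          class = "sipstats_domain_error")
  }
  2 * atan(stimulus_width_cm / (2 * viewing_distance_cm)) * 180 / pi
}
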