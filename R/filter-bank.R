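# Deterministic built-in filter bank standing behind the P_a / P_f variance
# measures. The measures only require a fixed bank of zero-mean, unit-norm
# linear filters whose responses span orientation, scale and color
# opponency; the bank is pluggable (see import_filter_bank) so externally
# trained first-layer weights can be dropped in.

gabor_kernel <- function(theta_deg, sigma, phase = c("even", "odd"),
                         gamma = 0.5, lambda = 3 * sigma) {
  phase <- match.arg(phase)
  r <- ceiling(3 * sigma)
  off <- -r:r
  x <- matrix(rep(off, each = 2 * r + 1), 2 * r + 1)
  y <- matrix(rep(off, times = 2 * r + 1), 2 * r + 1)
  th <- theta_deg * pi / 180
  xp <- x * cos(th) + y * sin(th)
  yp <- -x * sin(th) + y * cos(th)
  env <- exp(-(xp^2 + gamma^2 * yp^2) / (2 * sigma^2))
  carrier <- if (phase == "even") cos(2 * pi * xp / lambda)
             else sin(2 * pi * xp / lambda)
  normalize_kernel(env * carrier)
}

dog_spatial_kernel <- function(sigma_center, sigma_surround) {
  r <- ceiling(3 * sigma_surround)
  off <- -r:r
  x <- matrix(rep(off, each = 2 * r + 1), 2 * r + 1)
  y <- matrix(rep(off, times = 2 * r + 1), 2 * r + 1)
  g <- function(s) exp(-(x^2 + y^2) / (2 * s^2)) / (2 * pi * s^2)
  normalize_kernel(g(sigma_center) - g(sigma_surround))
}

normalize_kernel <- function(k) {
  k <- k - mean(k)
  n <- sqrt(sum(k^2))
  if (n < .Machine$double.eps) {
    abort("kernel is numerically zero after zero-mean correction.",
          class = "sipstats_filter_bank_error")
  }
  k / n
}

new_filter <- function(kernel, weights, orientation = NA_real_,
                       scale = NA_real_, tag = "luminance") {
  list(kernel = kernel, weights = weights / sqrt(sum(weights^2)),
       orientation = orientation, scale = scale, tag = tag)
}

#' Default filter bank for the variance SIPs
#'
#' A deterministic bank of 50 zero-mean, L2-normalized linear filters:
#' Gabor pairs (even and odd phase) at 8 orientations and 3 scales applied
#' to luminance, plus two center-surround color-opponent filters
#' (red-green and yellow-blue channel weights on a difference-of-Gaussians
#' spatial profile). Every filter responds 0 to any constant image: the
#' luminance kernels are zero-mean spatially and the opponent filters have
#' zero-sum channel weights combined with a zero-mean spatial kernel.
#'
#' @param orientations Number of Gabor orientations (default 8).
#' @param scales Gabor envelope scales in pixels (default `c(1.5, 3, 6)`).
#' @return An object of class `filter_bank` (a list of filters).
#' @export
default_filter_bank <- function(orientations = 8, scales = c(1.5, 3, 6)) {
  filters <- list()
  for (s in scales) {
    for (k in seq_len(orientations)) {
      theta <- (k - 1) * 180 / orientations
      filters <- c(filters, list(
        new_filter(gabor_kernel(theta, s, "even"), LUMA_709, theta, s),
        new_filter(gabor_kernel(theta, s, "odd"), LUMA_709, theta, s)
      ))
    }
  }
  dog <- dog_spatial_kernel(2, 4)
  filters <- c(filters, list(
    new_filter(dog, c(1, -1, 0) / sqrt(2), tag = "opponent_rg"),
    new_filter(dog, c(0.5, 0.5, -1) / sqrt(1.5), tag = "opponent_by")
  ))
  structure(filters, class = "filter_bank")
}

#' @export
print.filter_bank <- function(x, ...) {
  sizes <- vapply(x, function(f) nrow(f$kernel), integer(1))
  cat(sprintf("<filter_bank> %d filters, kernel sides %s\n",
              length(x), paste(sort(unique(sizes)), collapse = "/")))
  invisible(x)
}

validate_filter_bank <- function(bank) {
  if (!inherits(bank, "filter_bank") || length(bank) == 0L) {
    abort("`bank` must be a non-empty filter_bank.",
          class = "sipstats_filter_bank_error")
  }
  for (f in bank) {
    k <- f$kernel
    if (!is.matrix(k) || nrow(k) != ncol(k) || nrow(k) %% 2 == 0) {
      abort("kernels must be square with odd side.",
            class = "sipstats_filter_bank_error")
    }
    combined_mean <- mean(k) * sum(f$weights)
    if (abs(combined_mean) > 1e-10) {
      abort("kernel not zero-mean: constant images would respond.",
            class = "sipstats_filter_bank_error")
    }
    if (abs(sum(k^2) - 1) > 1e-8) {
      abort("kernel not L2-normalized.", class = "sipstats_filter_bank_error")
    }
  }
  invisible(bank)
}

#' Import a filter bank from a plain-text kernel dump
#'
#' Reads a CSV with columns `filter`, `row`, `col`, `value`, `w_r`, `w_g`,
#' `w_b` (one row per kernel entry; channel weights repeated per filter).
#' Kernels are zero-meaned and L2-normalized on load.
#'
#' @param path CSV file path.
#' @return A `filter_bank`.
#' @export
import_filter_bank <- function(path) {
  d <- utils::read.csv(path)
  need <- c("filter", "row", "col", "value", "w_r", "w_g", "w_b")
  if (!all(need %in% names(d))) {
    abort(paste0("filter bank CSV needs columns: ",
                 paste(need, collapse = ", ")),
          class = "sipstats_filter_bank_error")
  }
  filters <- lapply(split(d, d$filter), function(g) {
    side <- max(g$row)
    k <- matrix(0, side, side)
    k[cbind(g$row, g$col)] <- g$value
    new_filter(normalize_kernel(k), c(g$w_r[1], g$w_g[1], g$w_b[1]),
               tag = "imported")
  })
  validate_filter_bank(structure(unname(filters), class = "filter_bank"))
}
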