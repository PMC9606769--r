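# The P_a(k) / P_f(k) variance measures over filter-bank responses.

# Rectified-magnitude response maps of the whole bank (circular-padded FFT
# convolution). Each filter sees the channel combination given by its
# weights.
filter_responses <- function(img, bank) {
  validate_filter_bank(bank)
  lapply(bank, function(f) {
    combined <- f$weights[1] * img[, , 1] + f$weights[2] * img[, , 2] +
      f$weights[3] * img[, , 3]
    abs(EBImage::filter2(combined, f$kernel))
  })
}

# Max-pool a response map onto a k x k grid.
max_pool_grid <- function(resp, k) {
  h <- nrow(resp); w <- ncol(resp)
  rb <- tile_breaks(h, k); cb <- tile_breaks(w, k)
  out <- matrix(0, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      out[i, j] <- max(resp[(rb[i] + 1):rb[i + 1], (cb[j] + 1):cb[j + 1]])
    }
  }
  out
}

#' Filter-bank variance features P_a(k) and P_f(k)
#'
#' Convolves the image with every filter in the bank, rectifies the
#' responses, and max-pools each response map onto a `k x k` grid, giving
#' `k^2 * F` pooled entries. `variance_Pa` is the variance over the whole
#' pooled set (an inverse measure of richness: images dominated by a few
#' response patterns have high pooled variance). `variance_Pf` is the
#' median over filters of the variance of that filter's `k^2` entries
#' (a measure of spatial variability of individual feature channels).
#'
#' @param img RGB array in `[0, 1]`.
#' @param bank A `filter_bank` (default [default_filter_bank()]).
#' @param k Pooling grid side; one of the study's 2, 4, 8, 16, 30 or any
#'   positive integer not exceeding the image side.
#' @param responses Optional precomputed [filter] response list (internal
#'   reuse across multiple `k`).
#' @return A list with `variance_Pa` and `variance_Pf`.
#' @export
filter_variance_features <- function(img, bank = default_filter_bank(), k,
                                     responses = NULL) {
  img <- as_rgb_image(img)
  if (k < 1 || k > min(dim(img)[1:2])) {
    abort("`k` must be between 1 and the image side.",
          class = "sipstats_grid_error")
  }
  if (is.null(responses)) responses <- filter_responses(img, bank)
  pooled <- lapply(responses, max_pool_grid, k = k)
  all_entries <- unlist(pooled)
  per_filter_var <- vapply(pooled, function(p) var(as.numeric(p)),
                           numeric(1))
  list(
    variance_Pa = var(all_entries),
    variance_Pf = median(per_filter_var)
  )
}
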