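# PHOG-style self-similarity, anisotropy and mirror symmetry. Orientation
# histograms are magnitude-weighted, unsigned (mod 180 degrees), with
# `bins` equal-width bins; cell grids follow the spatial-pyramid convention
# (level L has 2^L x 2^L cells).

# Magnitude-weighted orientation histogram (unnormalized).
orientation_histogram <- function(ori, mag, bins) {
  b <- pmin(floor(ori / (180 / bins)) + 1L, bins)
  as.numeric(tapply(mag, factor(b, levels = seq_len(bins)), sum, default = 0))
}

l1_normalize <- function(h) {
  s <- sum(h)
  if (s <= 0) h else h / s
}

# Histogram intersection kernel of two L1-normalized histograms.
hik <- function(a, b) sum(pmin(a, b))

# Tile bounds splitting n pixels into k near-equal runs.
tile_breaks <- function(n, k) floor((0:k) * n / k)

# Per-cell unnormalized histograms on a g x g grid.
cell_histograms <- function(field, g, bins) {
  h <- nrow(field$magnitude); w <- ncol(field$magnitude)
  rb <- tile_breaks(h, g); cb <- tile_breaks(w, g)
  out <- vector("list", g * g)
  idx <- 1L
  for (i in seq_len(g)) {
    for (j in seq_len(g)) {
      rows <- (rb[i] + 1):rb[i + 1]
      cols <- (cb[j] + 1):cb[j + 1]
      out[[idx]] <- orientation_histogram(
        field$orientation[rows, cols], field$magnitude[rows, cols], bins)
      idx <- idx + 1L
    }
  }
  out
}

#' PHOG self-similarity, anisotropy and complexity
#'
#' Computes magnitude-weighted histograms of gradient orientations over a
#' spatial pyramid. Self-similarity is the median, over the finest-level
#' cells, of the histogram-intersection similarity between the (normalized)
#' cell histogram and the (normalized) whole-image histogram: 1 means every
#' subregion repeats the global orientation structure. Anisotropy is the
#' standard deviation of the mean finest-level histogram, scaled so a single
#' dominant orientation gives 1 and a flat orientation profile gives 0.
#' PHOG complexity is the mean gradient magnitude rescaled by its
#' central-difference bound to `[0, 1]`.
#'
#' Cells with no gradient energy contribute similarity 0 (their orientation
#' structure is undefined) and are excluded from the anisotropy average.
#'
#' @param img RGB array in `[0, 1]`.
#' @param levels Finest pyramid level (default 3, i.e. an 8 x 8 cell grid).
#' @param bins Orientation bins over `[0, 180)` degrees (default 16).
#' @return A list with `self_similarity`, `anisotropy`, `phog_complexity`,
#'   all in `[0, 1]`.
#' @export
phog_features <- function(img, levels = 3, bins = 16) {
  img <- as_rgb_image(img)
  field <- gradient_field(img)
  if (sum(field$magnitude) <= 0) {
    abort("zero-gradient image: orientation histograms undefined.",
          class = "sipstats_degenerate_input")
  }
  global <- l1_normalize(orientation_histogram(field$orientation,
                                               field$magnitude, bins))
  g <- 2L^levels
  cells <- cell_histograms(field, g, bins)
  sims <- vapply(cells, function(h) {
    if (sum(h) <= 0) 0 else hik(l1_normalize(h), global)
  }, numeric(1))
  nonzero <- Filter(function(h) sum(h) > 0, cells)
  mean_hist <- Reduce(`+`, lapply(nonzero, l1_normalize)) / length(nonzero)
  list(
    self_similarity = median(sims),
    anisotropy = min(1, sd(mean_hist) * sqrt(bins)),
    phog_complexity = min(1, mean(field$magnitude) / (2 * 255 * sqrt(2)))
  )
}

# Mean per-cell HIK between two half-image gradient fields on a g x g grid.
# Cells empty on both sides count as perfectly similar, one-sided emptiness
# as fully dissimilar.
half_similarity <- function(field_a, field_b, g, bins) {
  ca <- cell_histograms(field_a, g, bins)
  cb <- cell_histograms(field_b, g, bins)
  sims <- mapply(function(a, b) {
    sa <- sum(a); sb <- sum(b)
    if (sa <= 0 && sb <= 0) return(1)
    if (sa <= 0 || sb <= 0) return(0)
    hik(l1_normalize(a), l1_normalize(b))
  }, ca, cb)
  mean(sims)
}

#' Combined left/right and up/down mirror symmetry
#'
#' Left/right symmetry compares PHOG level-2 (4 x 4 grid) orientation
#' histograms of the left half against those of the mirror-reflected right
#' half; reflecting the half flips the horizontal gradient component, so
#' orientations are reflected automatically when the field is recomputed on
#' the flipped half. Up/down symmetry is defined analogously on row-flipped
#' halves. The combined value is the mean of the two components; 1 means
#' perfect mirror symmetry of the oriented gradient structure.
#'
#' @param img RGB array in `[0, 1]`.
#' @param bins Orientation bins (default 16).
#' @return A value in `[0, 1]`.
#' @export
mirror_symmetry_lrud <- function(img, bins = 16) {
  img <- as_rgb_image(img)
  if (sum(gradient_field(img)$magnitude) <= 0) {
    abort("zero-gradient image: symmetry undefined.",
          class = "sipstats_degenerate_input")
  }
  h <- dim(img)[1]; w <- dim(img)[2]
  half_w <- w %/% 2; half_h <- h %/% 2
  left  <- img[, 1:half_w, , drop = FALSE]
  right <- img[, w:(w - half_w + 1), , drop = FALSE]   # column-flipped
  top    <- img[1:half_h, , , drop = FALSE]
  bottom <- img[h:(h - half_h + 1), , , drop = FALSE]  # row-flipped
  lr <- half_similarity(gradient_field(left), gradient_field(right), 4L, bins)
  ud <- half_similarity(gradient_field(top), gradient_field(bottom), 4L, bins)
  structure(mean(c(lr, ud)), components = c(lr = lr, ud = ud))
}
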