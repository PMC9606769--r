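#' Configuration for SIP computation
#'
#' All statistical image properties are computed at a fixed internal
#' resolution (default 800 x 800, the study convention), so prior resizing
#' or lossless re-encoding of an input image cannot change its SIPs.
#'
#' @param resolution Internal square resolution in pixels (default 800).
#'   Desk-scale analyses and tests typically use 64-256.
#' @param phog_levels,phog_bins PHOG pyramid depth and orientation bins.
#' @param n_orientations,n_edges,n_dist_bins,max_pairs,pair_seed,edge_sigma
#'   Edge-orientation entropy parameters, see
#'   [edge_orientation_entropies()].
#' @param bank Filter bank for the variance SIPs.
#' @param pool_sizes Pooling grids `k` for `P_a(k)` / `P_f(k)` (study set
#'   2, 4, 8, 16, 30).
#' @param slope_fit_range Frequency range for [measure_fourier_slope()];
#'   `NULL` uses the default `c(10, resolution/4)`.
#' @param promote_gray Promote grayscale inputs to RGB instead of erroring.
#' @return A list of class `sip_config`.
#' @export
sip_config <- function(resolution = 800, phog_levels = 3, phog_bins = 16,
                       n_orientations = 24, n_edges = 10000,
                       n_dist_bins = 20, max_pairs = 1e6, pair_seed = 1,
                       edge_sigma = 1.5, bank = default_filter_bank(),
                       pool_sizes = c(2, 4, 8, 16, 30),
                       slope_fit_range = NULL, promote_gray = TRUE) {
  stopifnot(resolution >= 64, all(pool_sizes >= 1),
            all(pool_sizes <= resolution))
  structure(
    list(resolution = as.integer(resolution), phog_levels = phog_levels,
         phog_bins = phog_bins, n_orientations = n_orientations,
         n_edges = n_edges, n_dist_bins = n_dist_bins,
         max_pairs = max_pairs, pair_seed = pair_seed,
         edge_sigma = edge_sigma, bank = bank,
         pool_sizes = as.integer(pool_sizes),
         slope_fit_range = slope_fit_range, promote_gray = promote_gray),
    class = "sip_config"
  )
}

#' The eight model SIPs
#'
#' Names of the reduced, low-collinearity SIP set used in the rating
#' models: gradient complexity, PHOG self-similarity, second-order edge
#' entropy, the pooled filter variances `P_a(2)` and `P_f(30)`, the Lab
#' yellow-blue mean, mean saturation, and hue entropy.
#'
#' @return A character vector of column names.
#' @export
eight_model_sips <- function() {
  c("complexity", "self_similarity", "entropy_second_order",
    "variance_Pa_2", "variance_Pf_30", "lab_b_mean", "hsv_S_mean",
    "entropy_hsv_H")
}

sip_column_names <- function(config = sip_config()) {
  c("complexity", "self_similarity", "phog_anisotropy",
    "entropy_first_order", "entropy_second_order",
    paste0("variance_Pa_", config$pool_sizes),
    paste0("variance_Pf_", config$pool_sizes),
    "lab_L_mean", "lab_a_mean", "lab_b_mean",
    "hsv_H_mean", "hsv_S_mean", "hsv_V_mean",
    "entropy_hsv_H", "entropy_hsv_S", "entropy_hsv_V",
    "symmetry_lrud", "fourier_slope")
}

#' Compute the full SIP vector of one image
#'
#' Resamples the image to the configured internal resolution (bilinear)
#' and computes all statistical image properties: gradient complexity,
#' PHOG self-similarity/anisotropy, first- and second-order
#' edge-orientation entropies, filter-bank variances `P_a(k)`/`P_f(k)` for
#' every configured pooling grid, CIELab/HSV color statistics, combined
#' mirror symmetry, and the Fourier spectral slope. Deterministic given the
#' configuration.
#'
#' For degenerate (constant) images the gradient- and spectrum-based SIPs
#' are undefined and returned as `NA`; the zero-valued SIPs (complexity,
#' pooled variances, saturation entropy, ...) are reported as computed.
#'
#' @param img RGB array in `[0, 1]` (grayscale promoted when
#'   `config$promote_gray`).
#' @param config A [sip_config()].
#' @return A one-row tibble with one column per SIP.
#' @export
compute_sip_vector <- function(img, config = sip_config()) {
  stopifnot(inherits(config, "sip_config"))
  img <- as_rgb_image(img, promote_gray = config$promote_gray)
  if (min(dim(img)[1:2]) < 64) {
    abort("image side must be at least 64 px.",
          class = "sipstats_format_error")
  }
  img <- resize_rgb(img, config$resolution)

  na_if_degenerate <- function(expr) {
    tryCatch(expr, sipstats_degenerate_input = function(e) NULL,
             sipstats_degenerate_spectrum = function(e) NULL,
             sipstats_insufficient_edges = function(e) NULL)
  }

  phog <- na_if_degenerate(
    phog_features(img, config$phog_levels, config$phog_bins))
  ent <- na_if_degenerate(
    edge_orientation_entropies(img, config$n_orientations, config$n_edges,
                               config$n_dist_bins, config$max_pairs,
                               config$pair_seed, config$edge_sigma))
  symm <- na_if_degenerate(mirror_symmetry_lrud(img, config$phog_bins))
  slope <- na_if_degenerate(
    measure_fourier_slope(img, config$slope_fit_range))

  responses <- filter_responses(img, config$bank)
  fv <- lapply(config$pool_sizes, function(k) {
    filter_variance_features(img, config$bank, k, responses = responses)
  })
  col <- color_statistics(img)

  out <- c(
    list(complexity = gradient_complexity(img),
         self_similarity = phog$self_similarity %||% NA_real_,
         phog_anisotropy = phog$anisotropy %||% NA_real_,
         entropy_first_order = ent$entropy_first_order %||% NA_real_,
         entropy_second_order = ent$entropy_second_order %||% NA_real_),
    setNames(lapply(fv, `[[`, "variance_Pa"),
             paste0("variance_Pa_", config$pool_sizes)),
    setNames(lapply(fv, `[[`, "variance_Pf"),
             paste0("variance_Pf_", config$pool_sizes)),
    col,
    list(symmetry_lrud = if (is.null(symm)) NA_real_ else as.numeric(symm),
         fourier_slope = slope$slope %||% NA_real_)
  )
  as_tibble(out)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Compute a SIP table for a set of images
#'
#' @param images A named list of RGB arrays, or a directory path readable
#'   by [read_images()].
#' @param config A [sip_config()].
#' @param category Optional category label(s) for the rows (recycled):
#'   one of `"original"`, `"random_phase"`, `"style_transferred"`,
#'   `"reference"`.
#' @param subset `"all"` or `"eight"` to restrict columns to the eight
#'   model SIPs.
#' @return A tibble with `image_id`, `category` and one column per SIP.
#' @export
compute_sips <- function(images, config = sip_config(), category = NULL,
                         subset = c("all", "eight")) {
  subset <- match.arg(subset)
  if (is.character(images)) images <- read_images(images)
  if (is.null(names(images)) || anyDuplicated(names(images))) {
    abort("`images` must be a uniquely named list.",
          class = "sipstats_format_error")
  }
  if (!is.null(category)) {
    category <- rep_len(category, length(images))
    bad <- setdiff(unique(category),
                   c("original", "random_phase", "style_transferred",
                     "reference"))
    if (length(bad)) {
      abort(paste0("unknown category: ", paste(bad, collapse = ", ")),
            class = "sipstats_format_error")
    }
  }
  rows <- purrr::imap(images, function(img, id) {
    dplyr::bind_cols(tibble(image_id = id), compute_sip_vector(img, config))
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::mutate(out,
                       category = if (is.null(category)) NA_character_
                                  else category,
                       .after = "image_id")
  if (subset == "eight") {
    out <- dplyr::select(out, "image_id", "category",
                         dplyr::all_of(eight_model_sips()))
  }
  out
}
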