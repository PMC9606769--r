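# Synthetic study generator: image sets, balanced design assignment, and
# ratings with recorded ground truth, so the whole pipeline can be
# validated at desk scale without any external data.

#' Configuration of a synthetic rating study
#'
#' Defaults mirror the study design being emulated: 40 raters, six
#' spectral-slope conditions (-5..0) with 25 random-phase images each, a
#' 150-image textured "pseudo-painting" set standing in for
#' style-transferred artworks, three rating dimensions, and a balanced
#' 30-of-150 random-phase assignment giving 8 ratings per image. Rater
#' heterogeneity is planted as archetype clusters: `u_shaped` raters peak
#' at intermediate slopes, `increasing`/`decreasing` raters have monotone
#' slope preferences, and `anticorrelated_HI` raters load Interesting
#' opposite to Harmonious.
#'
#' Ratings follow a linear model on z-scored SIPs plus an archetype
#' slope-preference term, a participant offset, and Gaussian noise, and
#' are clipped to `[0, 1]`.
#'
#' @param n_participants Number of raters (default 40).
#' @param slopes Set-slope conditions (default -5:0).
#' @param images_per_slope Random-phase images per slope (default 25).
#' @param rated_per_slope Random-phase images each rater sees per slope
#'   (default 5, i.e. 30 of 150 overall).
#' @param n_pseudo_paintings Textured images rated by everyone
#'   (default 150).
#' @param image_size Synthesis resolution in pixels (default 256; the
#'   full-scale stimuli use 1024).
#' @param cluster_proportions Named archetype proportions, summing to 1.
#' @param beta_star 3 x 8 matrix of planted SIP loadings (rows Pleasing,
#'   Harmonious, Interesting; columns [eight_model_sips()]).
#' @param rating_scale Multiplier from the z-scored linear predictor to
#'   the `[0, 1]` rating scale (default 0.12).
#' @param noise_sd Trial-level rating noise (default 0.08).
#' @param participant_offset_sd Between-rater offset sd (default 0.05).
#' @param slope_pref_amplitude Amplitude of the archetype slope term
#'   (default 0.15).
#' @param u_peak,u_width Peak location and half-width of the u-shaped
#'   preference curve (defaults -2.5 and 2.5).
#' @param base_rating Grand mean rating (default 0.5).
#' @param seed Master study seed.
#' @return A list of class `synthetic_study_config`.
#' @export
synthetic_study_config <- function(n_participants = 40,
                                   slopes = -5:0,
                                   images_per_slope = 25,
                                   rated_per_slope = 5,
                                   n_pseudo_paintings = 150,
                                   image_size = 256,
                                   cluster_proportions = c(
                                     u_shaped = 0.5, increasing = 0.2,
                                     decreasing = 0.2,
                                     anticorrelated_HI = 0.1),
                                   beta_star = default_beta_star(),
                                   rating_scale = 0.12,
                                   noise_sd = 0.08,
                                   participant_offset_sd = 0.05,
                                   slope_pref_amplitude = 0.15,
                                   u_peak = -2.5, u_width = 2.5,
                                   base_rating = 0.5,
                                   seed = 1L) {
  if (abs(sum(cluster_proportions) - 1) > 1e-8) {
    abort("cluster proportions must sum to 1.",
          class = "sipstats_config_error")
  }
  known <- c("u_shaped", "increasing", "decreasing", "anticorrelated_HI")
  if (!all(names(cluster_proportions) %in% known)) {
    abort(paste0("archetypes must be among: ",
                 paste(known, collapse = ", ")),
          class = "sipstats_config_error")
  }
  if (noise_sd <= 0) {
    abort("noise_sd must be > 0.", class = "sipstats_config_error")
  }
  if (!is.matrix(beta_star) || nrow(beta_star) != 3 ||
      !all(is.finite(beta_star))) {
    abort("beta_star must be a finite 3 x p matrix.",
          class = "sipstats_config_error")
  }
  rownames(beta_star) <- RATING_DIMENSIONS
  structure(
    list(n_participants = as.integer(n_participants), slopes = slopes,
         images_per_slope = as.integer(images_per_slope),
         rated_per_slope = as.integer(rated_per_slope),
         n_pseudo_paintings = as.integer(n_pseudo_paintings),
         image_size = as.integer(image_size),
         cluster_proportions = cluster_proportions,
         beta_star = beta_star, rating_scale = rating_scale,
         noise_sd = noise_sd,
         participant_offset_sd = participant_offset_sd,
         slope_pref_amplitude = slope_pref_amplitude,
         u_peak = u_peak, u_width = u_width,
         base_rating = base_rating, seed = as.integer(seed)),
    class = "synthetic_study_config"
  )
}

#' Default planted SIP loadings
#'
#' Planted standardized loadings of the three rating dimensions on the
#' eight model SIPs. Signs follow the qualitative pattern the analysis is
#' meant to detect: complexity and pooled variance P_a(2) load negatively
#' on Pleasing/Harmonious, P_f(30) positively on Pleasing/Interesting,
#' self-similarity positively on Harmonious but negatively on
#' Interesting, hue entropy the other way around. Magnitudes sit in the
#' weak-to-moderate effect band.
#'
#' @return A 3 x 8 numeric matrix (rows Pleasing, Harmonious,
#'   Interesting).
#' @export
default_beta_star <- function() {
  m <- rbind(
    Pleasing    = c(-0.30,  0.00, 0.00, -0.20,  0.30, -0.20, -0.30,  0.20),
    Harmonious  = c(-0.30,  0.30, 0.00, -0.20,  0.00,  0.00, -0.20, -0.20),
    Interesting = c(-0.20, -0.30, 0.00,  0.00,  0.30, -0.20, -0.20,  0.30)
  )
  colnames(m) <- eight_model_sips()
  m
}

#' Generate the synthetic image sets
#'
#' Random-phase images come from the spectral-slope synthesizer (25 per
#' slope by default). Pseudo-paintings are parametric texture collages of
#' overlapping colored soft-edged elongated patches; their generator
#' parameters (patch scale, hue spread, saturation, orientation
#' concentration) sweep the eight model SIPs over a wide range: larger
#' patches shift spectral energy to low frequencies (more negative
#' Fourier slope), wider hue spread raises hue entropy, and so on.
#'
#' @param config A [synthetic_study_config()].
#' @return A list with `random_phase` (named image list), `manifest`
#'   (tibble `image_id`, `set_slope`, `seed`), `pseudo_paintings` (named
#'   image list) and `pseudo_params` (tibble of generator parameters).
#' @export
generate_image_sets <- function(config = synthetic_study_config()) {
  stopifnot(inherits(config, "synthetic_study_config"))
  manifest <- tidyr::expand_grid(set_slope = config$slopes,
                                 rep = seq_len(config$images_per_slope))
  manifest$image_id <- sprintf("rp_s%+d_%02d", manifest$set_slope,
                               manifest$rep)
  manifest$seed <- config$seed + 7919L * seq_len(nrow(manifest))
  random_phase <- purrr::pmap(manifest, function(set_slope, rep,
                                                 image_id, seed) {
    synthesize_colored_random_phase(
      random_phase_spec(config$image_size, set_slope, seed))
  })
  names(random_phase) <- manifest$image_id

  n_pp <- config$n_pseudo_paintings
  pseudo_params <- withr::with_seed(config$seed + 104729L, tibble(
    image_id = sprintf("pp_%03d", seq_len(n_pp)),
    patch_scale = runif(n_pp, 0.03, 0.30),
    hue_center = runif(n_pp),
    hue_spread = runif(n_pp, 0.01, 0.35),
    saturation = runif(n_pp, 0.15, 0.95),
    n_patches = sample(25:70, n_pp, replace = TRUE),
    orientation = runif(n_pp, 0, 180),
    orientation_kappa = runif(n_pp, 0, 8),
    seed = config$seed + 15485863L + seq_len(n_pp)
  ))
  pseudo_paintings <- purrr::pmap(
    dplyr::select(pseudo_params, -"image_id"),
    function(patch_scale, hue_center, hue_spread, saturation, n_patches,
             orientation, orientation_kappa, seed) {
      generate_pseudo_painting(config$image_size, patch_scale, hue_center,
                               hue_spread, saturation, n_patches,
                               orientation, orientation_kappa, seed)
    })
  names(pseudo_paintings) <- pseudo_params$image_id
  list(random_phase = random_phase,
       manifest = manifest[c("image_id", "set_slope", "seed")],
       pseudo_paintings = pseudo_paintings,
       pseudo_params = pseudo_params)
}

#' Render one pseudo-painting texture collage
#'
#' Overlapping soft-edged (Gaussian-alpha) elongated color patches on a
#' tinted canvas. Patch hue is drawn around `hue_center` with circular sd
#' `hue_spread`; patch orientation concentrates around `orientation`
#' (higher `orientation_kappa` = stronger bias); `patch_scale` is the
#' characteristic patch size as a fraction of the image side.
#'
#' @param size Image side in pixels.
#' @param patch_scale Patch size fraction (e.g. 0.03-0.3).
#' @param hue_center Base hue in `[0, 1)`.
#' @param hue_spread Circular sd of patch hues.
#' @param saturation Mean patch saturation in `[0, 1]`.
#' @param n_patches Number of patches.
#' @param orientation Preferred patch orientation in degrees.
#' @param orientation_kappa Orientation concentration (0 = isotropic).
#' @param seed RNG seed.
#' @return An RGB array in `[0, 1]`.
#' @export
generate_pseudo_painting <- function(size, patch_scale, hue_center,
                                     hue_spread, saturation,
                                     n_patches = 40, orientation = 0,
                                     orientation_kappa = 0, seed = 1) {
  withr::with_seed(seed, {
    base_col <- grDevices::hsv(hue_center, saturation * 0.4, 0.45)
    base_rgb <- grDevices::col2rgb(base_col) / 255
    img <- array(rep(base_rgb, each = size * size),
                 dim = c(size, size, 3))
    xs <- seq_len(size)
    # hold canvas coverage roughly constant: smaller patches come in
    # larger numbers, so patch_scale controls the spectral content
    # (fine texture vs coarse structure) rather than the fill fraction
    n_eff <- max(8L, min(500L,
                         round(n_patches * (0.12 / patch_scale)^2)))
    for (p in seq_len(n_eff)) {
      cx <- runif(1, 1, size); cy <- runif(1, 1, size)
      s_major <- patch_scale * size * runif(1, 0.6, 1.4)
      s_minor <- s_major * runif(1, 0.25, 1)
      theta <- if (orientation_kappa > 0) {
        (orientation + rnorm(1, 0, 45 / (1 + orientation_kappa))) * pi / 180
      } else {
        runif(1, 0, pi)
      }
      hue <- (hue_center + rnorm(1, 0, hue_spread)) %% 1
      sat <- min(1, max(0, saturation + rnorm(1, 0, 0.15)))
      val <- runif(1, 0.25, 1)
      col <- grDevices::col2rgb(grDevices::hsv(hue, sat, val)) / 255
      amp <- runif(1, 0.55, 0.95)
      r <- ceiling(3 * s_major)
      rows <- max(1, floor(cy - r)):min(size, ceiling(cy + r))
      cols <- max(1, floor(cx - r)):min(size, ceiling(cx + r))
      dx <- outer(rep(1, length(rows)), xs[cols] - cx)
      dy <- outer(rows - cy, rep(1, length(cols)))
      u <- dx * cos(theta) + dy * sin(theta)
      v <- -dx * sin(theta) + dy * cos(theta)
      # elliptical patch with a soft edge of fixed width in pixels, so
      # patch size sets the spectral knee rather than the edge softness
      q <- sqrt((u / s_major)^2 + (v / s_minor)^2)
      alpha <- amp / (1 + exp((q - 1) * s_minor / 1.2))
      for (ch in 1:3) {
        img[rows, cols, ch] <- img[rows, cols, ch] * (1 - alpha) +
          col[ch] * alpha
      }
    }
    # fine painterly grain, then a smoothing pass whose width scales with
    # the patch size: patch_scale thereby sets the fine-detail cutoff and
    # drives the measured spectral slope monotonically
    img <- img + array(rnorm(length(img), 0, 0.02), dim = dim(img))
    sigma_blur <- patch_scale * size * 0.12
    if (sigma_blur > 0.3) {
      r <- ceiling(3 * sigma_blur)
      off <- -r:r
      g1 <- exp(-off^2 / (2 * sigma_blur^2))
      kern <- outer(g1, g1); kern <- kern / sum(kern)
      for (ch in 1:3) {
        img[, , ch] <- EBImage::filter2(img[, , ch], kern)
      }
    }
    pmin(pmax(img, 0), 1)
  })
}

#' Generate the balanced rating design
#'
#' Every participant rates all pseudo-paintings, but only
#' `rated_per_slope` random-phase images per slope (5 of 25 under the
#' defaults, i.e. 30 of 150), assigned cyclically so that every
#' random-phase image is rated by exactly
#' `n_participants * rated_per_slope / images_per_slope` raters (8 under
#' the defaults). Random-phase and pseudo-painting blocks come in
#' randomized order per participant.
#'
#' @param config A [synthetic_study_config()].
#' @return A tibble: `participant_id`, `image_id`, `category`,
#'   `set_slope` (`NA` for pseudo-paintings), `block`.
#' @export
generate_design <- function(config = synthetic_study_config()) {
  stopifnot(inherits(config, "synthetic_study_config"))
  n <- config$n_participants
  m <- config$images_per_slope
  r <- config$rated_per_slope
  if ((n * r) %% m != 0) {
    abort(sprintf(
      "infeasible balance: n_participants * rated_per_slope = %d * %d = %d is not a multiple of images_per_slope = %d.",
      n, r, n * r, m), class = "sipstats_config_error")
  }
  participants <- sprintf("P%02d", seq_len(n))
  withr::with_seed(config$seed + 31L, {
    rp_rows <- purrr::map_dfr(config$slopes, function(s) {
      ids <- sprintf("rp_s%+d_%02d", s, sample(m))   # shuffled image labels
      porder <- sample(n)                            # shuffled participants
      purrr::map_dfr(seq_len(n), function(jj) {
        j <- porder[jj]
        sel <- ((jj - 1L) * r + 0:(r - 1L)) %% m + 1L
        tibble(participant_id = participants[j], image_id = ids[sel],
               category = "random_phase", set_slope = s)
      })
    })
    pp_rows <- tidyr::expand_grid(
      participant_id = participants,
      image_id = sprintf("pp_%03d", seq_len(config$n_pseudo_paintings)))
    pp_rows$category <- "style_transferred"
    pp_rows$set_slope <- NA_real_
    block_first <- sample(c("random_phase", "style_transferred"), n,
                          replace = TRUE)
  })
  design <- dplyr::bind_rows(rp_rows, pp_rows)
  design$block <- ifelse(
    design$category == block_first[match(design$participant_id,
                                         participants)], 1L, 2L)
  dplyr::arrange(design, .data$participant_id, .data$block,
                 .data$image_id)
}

# Archetype slope-preference term on the rating scale.
slope_pref_term <- function(archetype, set_slope, config) {
  s <- set_slope
  span <- diff(range(config$slopes))
  amp <- config$slope_pref_amplitude
  out <- numeric(length(s))
  u <- archetype %in% c("u_shaped", "anticorrelated_HI")
  out[u] <- amp * (1 - ((s[u] - config$u_peak) / config$u_width)^2)
  inc <- archetype == "increasing"
  out[inc] <- amp * (2 * (s[inc] - mean(range(config$slopes))) / span)
  dec <- archetype == "decreasing"
  out[dec] <- -amp * (2 * (s[dec] - mean(range(config$slopes))) / span)
  out[is.na(s)] <- 0
  out
}

#' Generate synthetic ratings with ground truth
#'
#' Builds the planted rating model on top of a SIP table and a design:
#' `rating = base + scale * sum_j beta[d, j] z(SIP_j) + slope-preference
#' term + participant offset + noise`, clipped to `[0, 1]`.
#' `anticorrelated_HI` raters use the negated Harmonious loadings for
#' Interesting. SIP columns are z-scored across all images in `sips`.
#'
#' The returned ground truth records the archetype labels, the planted
#' loading matrix, and — per category and dimension — the target
#' standardized coefficients (the projection of the noiseless expected
#' per-image means onto the within-category z-scored SIPs) and the
#' implied adjusted R^2 once averaging noise is added back.
#'
#' @param sips SIP table covering every designed image (columns
#'   [eight_model_sips()]).
#' @param design A [generate_design()] table.
#' @param config A [synthetic_study_config()].
#' @param seed Seed for archetype assignment, offsets and noise
#'   (defaults to the study seed).
#' @return A list: `ratings` (long tibble), `ground_truth`.
#' @export
generate_ratings <- function(sips, design, config, seed = config$seed) {
  stopifnot(inherits(config, "synthetic_study_config"))
  sip_cols <- colnames(config$beta_star)
  missing <- setdiff(sip_cols, names(sips))
  if (length(missing)) {
    abort(paste0("SIP table lacks planted predictors: ",
                 paste(missing, collapse = ", ")),
          class = "sipstats_config_error")
  }
  if (!all(design$image_id %in% sips$image_id)) {
    abort("design references images missing from the SIP table.",
          class = "sipstats_config_error")
  }
  Z <- scale(as.matrix(sips[sip_cols]))
  Z[!is.finite(Z)] <- 0
  rownames(Z) <- sips$image_id
  B <- config$beta_star
  participants <- sort(unique(design$participant_id))
  n <- length(participants)

  counts <- floor(config$cluster_proportions * n)
  rest <- n - sum(counts)
  if (rest > 0) {
    o <- order(config$cluster_proportions * n - counts, decreasing = TRUE)
    counts[o[seq_len(rest)]] <- counts[o[seq_len(rest)]] + 1L
  }
  draws <- withr::with_seed(seed, list(
    archetype = sample(rep(names(counts), counts)),
    offsets = rnorm(n, 0, config$participant_offset_sd)
  ))
  archetype <- setNames(draws$archetype, participants)
  offsets <- setNames(draws$offsets, participants)

  long <- tidyr::expand_grid(design, dimension = RATING_DIMENSIONS)
  eta_all <- Z %*% t(B)                       # images x 3
  eta_anti_I <- as.numeric(Z %*% -B["Harmonious", ])
  img_idx <- match(long$image_id, rownames(Z))
  dim_idx <- match(long$dimension, RATING_DIMENSIONS)
  eta <- eta_all[cbind(img_idx, dim_idx)]
  anti <- archetype[long$participant_id] == "anticorrelated_HI" &
    long$dimension == "Interesting"
  eta[anti] <- eta_anti_I[img_idx[anti]]
  pref <- slope_pref_term(archetype[long$participant_id],
                          long$set_slope, config)
  signal <- config$base_rating + config$rating_scale * eta + pref
  noise <- withr::with_seed(seed + 977L,
                            rnorm(nrow(long), 0, config$noise_sd))
  long$rating <- pmin(pmax(
    signal + offsets[long$participant_id] + noise, 0), 1)
  ratings <- as_tibble(long[c("participant_id", "image_id", "category",
                              "dimension", "set_slope", "rating")])

  # ground truth: noiseless expected means projected on z-scored SIPs
  noiseless <- long
  noiseless$rating <- pmin(pmax(signal, 0), 1)
  nl_means <- aggregate_ratings(noiseless, "image")
  raters_per_image <- dplyr::count(design, .data$category,
                                   .data$image_id)
  truth_rows <- list()
  for (cat in unique(design$category)) {
    ids <- unique(design$image_id[design$category == cat])
    if (length(ids) <= length(sip_cols) + 2) next
    n_raters <- min(raters_per_image$n[raters_per_image$category == cat])
    d_cat <- dplyr::inner_join(
      nl_means[nl_means$category == cat, ],
      sips[sips$image_id %in% ids, c("image_id", sip_cols)],
      by = "image_id")
    for (dim in RATING_DIMENSIONS) {
      dd <- d_cat[d_cat$dimension == dim, ]
      if (sd(dd$mean_rating) == 0) next
      fit <- standardized_regression(dd, "mean_rating", sip_cols)
      var_sig <- var(dd$mean_rating)
      var_resid <- (config$participant_offset_sd^2 +
                      config$noise_sd^2) / n_raters
      r2 <- var_sig / (var_sig + var_resid)
      truth_rows[[length(truth_rows) + 1L]] <- dplyr::mutate(
        tidy(fit)[c("term", "beta_star")],
        category = cat, dimension = dim,
        r_squared_target = r2,
        r_squared_adj_target = adj_r2(r2, nrow(dd), length(sip_cols)))
    }
  }
  ground_truth <- list(
    archetype = archetype,
    offsets = offsets,
    beta_star_planted = B,
    slope_pref = list(amplitude = config$slope_pref_amplitude,
                      u_peak = config$u_peak, u_width = config$u_width),
    targets = dplyr::bind_rows(truth_rows)
  )
  list(ratings = ratings, ground_truth = ground_truth)
}

#' Planted inter-rating correlation archetypes
#'
#' Draws participant correlation vectors (rho_PH, rho_PI, rho_HI) around
#' five archetype centers, one of which has a negative
#' Harmonious-Interesting correlation — the structure the rater
#' clustering is meant to recover.
#'
#' @param n_per Cluster sizes (default `c(14, 13, 4, 5, 4)`).
#' @param centers 5 x 3 matrix of archetype centers.
#' @param sd Within-cluster spread (default 0.04).
#' @param seed RNG seed.
#' @return A list: `x` (matrix of vectors), `labels` (planted cluster).
#' @export
plant_correlation_archetypes <- function(n_per = c(14, 13, 4, 5, 4),
                                         centers = rbind(
                                           c(0.55, 0.64, 0.47),
                                           c(0.44, 0.39, 0.31),
                                           c(0.64, 0.29, 0.01),
                                           c(0.21, 0.56, 0.04),
                                           c(0.04, 0.32, -0.34)),
                                         sd = 0.04, seed = 1) {
  stopifnot(length(n_per) == nrow(centers))
  withr::with_seed(seed, {
    labels <- rep(seq_along(n_per), n_per)
    x <- centers[labels, ] +
      matrix(rnorm(length(labels) * 3, 0, sd), ncol = 3)
    colnames(x) <- c("rho_PH", "rho_PI", "rho_HI")
    rownames(x) <- sprintf("P%02d", seq_along(labels))
    list(x = x, labels = labels)
  })
}

#' Planted sweet-spot data for distance validation
#'
#' Generates a Gaussian reference cloud and test points whose ratings
#' decay with squared Mahalanobis distance from the reference center —
#' the "images near the sweet spot are rated higher" structure.
#'
#' @param n_reference,n_test Row counts.
#' @param p Number of SIP-like variables.
#' @param decay Rating decay per unit squared distance (default 0.02).
#' @param noise_sd Rating noise (default 0.02).
#' @param seed RNG seed.
#' @return List: `reference` (tibble), `test` (tibble with `image_id`),
#'   `ratings` (per-image mean ratings, all three dimensions).
#' @export
plant_sweet_spot <- function(n_reference = 200, n_test = 100, p = 5,
                             decay = 0.02, noise_sd = 0.02, seed = 1) {
  withr::with_seed(seed, {
    vars <- paste0("sip", seq_len(p))
    A <- matrix(rnorm(p * p, 0, 0.3), p) + diag(p)
    ref <- matrix(rnorm(n_reference * p), ncol = p) %*% A
    tst <- matrix(rnorm(n_test * p, sd = 1.5), ncol = p) %*% A
    colnames(ref) <- colnames(tst) <- vars
    reference <- as_tibble(ref)
    test <- dplyr::bind_cols(
      tibble(image_id = sprintf("t%03d", seq_len(n_test))),
      as_tibble(tst))
    refd <- build_reference(reference, vars)
    d2 <- mahalanobis_sq(as.matrix(tst), refd)
    ratings <- tidyr::expand_grid(image_id = test$image_id,
                                  dimension = RATING_DIMENSIONS)
    ratings$category <- "style_transferred"
    ratings$mean_rating <- pmin(pmax(
      0.9 - decay * rep(d2, each = 3) +
        rnorm(nrow(ratings), 0, noise_sd), 0), 1)
    ratings$n_ratings <- 40L
    list(reference = reference, test = test, ratings = ratings,
         d_squared = d2)
  })
}
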