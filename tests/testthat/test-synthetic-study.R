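# A small synthetic SIP table standing in for computed image SIPs; the
# rating generator only consumes the eight model SIP columns.
fake_sip_table <- function(design, seed = 99) {
  ids <- unique(design$image_id)
  withr::with_seed(seed, {
    m <- matrix(rnorm(length(ids) * 8), ncol = 8,
                dimnames = list(NULL, eight_model_sips()))
    dplyr::bind_cols(tibble::tibble(image_id = ids), tibble::as_tibble(m))
  })
}

small_config <- function(...) {
  synthetic_study_config(n_participants = 20, images_per_slope = 5,
                         rated_per_slope = 1, n_pseudo_paintings = 30,
                         image_size = 64, ...)
}

test_that("the default configuration matches the study design arithmetic", {
  cfg <- synthetic_study_config()
  expect_equal(cfg$n_participants, 40L)
  expect_equal(length(cfg$slopes) * cfg$images_per_slope, 150L)
  expect_equal(length(cfg$slopes) * cfg$rated_per_slope, 30L)
  # 40 raters x 30 rated / 150 images = 8 ratings per image
  expect_equal(cfg$n_participants * cfg$rated_per_slope /
                 cfg$images_per_slope, 8)
})

test_that("the balanced design yields the exact rater counts", {
  design <- generate_design(small_config())
  rp <- design[design$category == "random_phase", ]
  per_image <- table(rp$image_id)
  expect_true(all(per_image == 20 * 1 / 5))   # n * rated / images = 4
  per_part <- table(rp$participant_id, rp$set_slope)
  expect_true(all(per_part == 1))   # rated_per_slope per slope each
  expect_error(generate_design(synthetic_study_config(n_participants = 7,
                                                      images_per_slope = 25,
                                                      rated_per_slope = 5)),
               class = "sipstats_config_error")
})

test_that("30 participants on the full design give 6 raters per image", {
  cfg <- synthetic_study_config(n_participants = 30,
                                n_pseudo_paintings = 1)
  design <- generate_design(cfg)
  rp <- design[design$category == "random_phase", ]
  expect_true(all(table(rp$image_id) == 6))
  expect_true(all(table(rp$participant_id, rp$set_slope) == 5))
})

test_that("rating generation is deterministic and respects the seed", {
  cfg <- small_config()
  design <- generate_design(cfg)
  sips <- fake_sip_table(design)
  g1 <- generate_ratings(sips, design, cfg)
  g2 <- generate_ratings(sips, design, cfg)
  expect_identical(g1$ratings, g2$ratings)
  g3 <- generate_ratings(sips, design, cfg, seed = cfg$seed + 1)
  expect_false(identical(g1$ratings, g3$ratings))
  expect_true(all(g1$ratings$rating >= 0 & g1$ratings$rating <= 1))
})

test_that("near-noiseless ratings identify the planted loadings", {
  cfg <- small_config(noise_sd = 1e-6, participant_offset_sd = 1e-9,
                      cluster_proportions = c(u_shaped = 1))
  design <- generate_design(cfg)
  sips <- fake_sip_table(design)
  gen <- generate_ratings(sips, design, cfg)
  means <- aggregate_ratings(
    gen$ratings[gen$ratings$category == "style_transferred", ], "image")
  d <- dplyr::inner_join(
    means[means$dimension == "Pleasing", ], sips, by = "image_id")
  fit <- standardized_regression(d, "mean_rating", eight_model_sips())
  target <- gen$ground_truth$targets
  tt <- target[target$category == "style_transferred" &
                 target$dimension == "Pleasing", ]
  got <- tidy(fit)
  expect_equal(got$beta_star[match(tt$term, got$term)], tt$beta_star,
               tolerance = 0.01)
  expect_gt(glance(fit)$r_squared_adj, 0.999)
})

test_that("anticorrelated raters flip the Interesting loadings", {
  cfg <- small_config(noise_sd = 1e-6, participant_offset_sd = 1e-9,
                      cluster_proportions = c(anticorrelated_HI = 1))
  design <- generate_design(cfg)
  sips <- fake_sip_table(design)
  gen <- generate_ratings(sips, design, cfg)
  t_i <- gen$ground_truth$targets
  t_i <- t_i[t_i$category == "style_transferred", ]
  beta_h <- t_i$beta_star[t_i$dimension == "Harmonious"]
  beta_i <- t_i$beta_star[t_i$dimension == "Interesting"]
  expect_equal(beta_i, -beta_h, tolerance = 1e-6)
})

test_that("u-shaped raters produce an inverted-U slope preference", {
  cfg <- small_config(noise_sd = 0.02,
                      cluster_proportions = c(u_shaped = 1))
  design <- generate_design(cfg)
  sips <- fake_sip_table(design)
  gen <- generate_ratings(sips, design, cfg)
  rp <- gen$ratings[gen$ratings$category == "random_phase", ]
  sp <- tidy(slope_preference_curves(rp))
  expect_true(all(sp$curvature < 0))
  expect_true(all(sp$vertex > -3 & sp$vertex < -2))
})

test_that("monotone raters produce the planted linear trend", {
  zero_beta <- matrix(0, 3, 8,
                      dimnames = list(NULL, eight_model_sips()))
  cfg <- small_config(noise_sd = 0.02, beta_star = zero_beta,
                      cluster_proportions = c(increasing = 1))
  design <- generate_design(cfg)
  sips <- fake_sip_table(design)
  gen <- generate_ratings(sips, design, cfg)
  rp <- gen$ratings[gen$ratings$category == "random_phase", ]
  # SIP-driven variation is slope-independent; the slope term is linear
  sp <- tidy(slope_preference_curves(rp))
  expect_true(all(abs(sp$c) < 0.02))     # no planted curvature
  expect_true(all(sp$b > 0))             # increasing trend
})

test_that("pseudo-painting parameters steer the SIPs as designed", {
  spreads <- seq(0.02, 0.4, length.out = 5)
  ents <- sapply(spreads, function(hs) {
    img <- generate_pseudo_painting(64, patch_scale = 0.12,
                                    hue_center = 0.6, hue_spread = hs,
                                    saturation = 0.7, n_patches = 40,
                                    seed = 7)
    color_statistics(img)$entropy_hsv_H
  })
  expect_true(all(diff(ents) > 0))

  scales <- seq(0.04, 0.3, length.out = 8)
  slopes <- sapply(scales, function(ps) {
    img <- generate_pseudo_painting(64, patch_scale = ps,
                                    hue_center = 0.2, hue_spread = 0.1,
                                    saturation = 0.7, n_patches = 40,
                                    seed = 11)
    measure_fourier_slope(img, fit_range = c(4, 16))$slope
  })
  expect_lt(cor(scales, slopes, method = "spearman"), -0.8)
})

test_that("generated image sets carry a consistent manifest", {
  cfg <- synthetic_study_config(images_per_slope = 2, image_size = 64,
                                n_pseudo_paintings = 4,
                                n_participants = 4, rated_per_slope = 1)
  sets <- generate_image_sets(cfg)
  expect_length(sets$random_phase, 12)       # 6 slopes x 2
  expect_equal(nrow(sets$manifest), 12)
  expect_setequal(sets$manifest$image_id, names(sets$random_phase))
  expect_length(sets$pseudo_paintings, 4)
  expect_true(all(table(sets$manifest$set_slope) == 2))
  # SIP spread: the pseudo set is heterogeneous
  expect_gt(sd(sapply(sets$pseudo_paintings,
                      function(i) color_statistics(i)$hsv_S_mean)), 0.02)
})

test_that("synthetic categories separate on the SIPs the generator varies", {
  cfg <- synthetic_study_config(images_per_slope = 2, image_size = 64,
                                n_pseudo_paintings = 12,
                                n_participants = 4, rated_per_slope = 1)
  sets <- generate_image_sets(cfg)
  sc <- sip_config(resolution = 64, n_edges = 300)
  sips <- dplyr::bind_rows(
    compute_sips(sets$random_phase, sc, category = "random_phase"),
    compute_sips(sets$pseudo_paintings, sc,
                 category = "style_transferred"))
  for (v in c("complexity", "entropy_hsv_H", "entropy_second_order")) {
    gt <- kruskal_dunn(sips[[v]], sips$category)
    expect_lt(gt$p_value, 0.01)
  }
})
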