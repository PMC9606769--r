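make_toy_ratings <- function() {
  tibble::tibble(
    participant_id = c("P1", "P1", "P2"),
    image_id = c("a", "b", "a"),
    category = "style_transferred",
    dimension = "Pleasing",
    rating = c(0.2, 0.4, 0.6)
  )
}

test_that("aggregation means and counts match hand arithmetic", {
  agg <- aggregate_ratings(make_toy_ratings(), "image")
  expect_equal(agg$mean_rating[agg$image_id == "a"], (0.2 + 0.6) / 2)
  expect_equal(agg$n_ratings[agg$image_id == "a"], 2L)
  expect_equal(agg$mean_rating[agg$image_id == "b"], 0.4)
  expect_error(aggregate_ratings(make_toy_ratings(), "artist"),
               class = "sipstats_argument_error")
  expect_error(aggregate_ratings(make_toy_ratings(), "slope"))
})

test_that("full-factorial designs report full per-image counts", {
  full <- tidyr::expand_grid(participant_id = sprintf("P%02d", 1:40),
                             image_id = sprintf("i%03d", 1:20),
                             dimension = "Pleasing")
  full$category <- "style_transferred"
  full$rating <- 0.5
  agg <- aggregate_ratings(full, "image")
  expect_true(all(agg$n_ratings == 40L))
})

test_that("a response equal to one predictor gets beta* 1, strong band", {
  set.seed(5)
  d <- tibble::as_tibble(matrix(rnorm(300), 100,
                                dimnames = list(NULL, c("a", "b", "c"))))
  d$y <- 3 * d$a + 2                       # affine in a alone
  fit <- standardized_regression(d, "y", c("a", "b", "c"))
  co <- tidy(fit)
  expect_equal(co$beta_star[co$term == "a"], 1, tolerance = 1e-10)
  expect_equal(co$beta_star[co$term == "b"], 0, tolerance = 1e-10)
  expect_equal(co$effect_band[co$term == "a"], "strong")
  expect_equal(glance(fit)$r_squared_adj, 1, tolerance = 1e-12)
})

test_that("effect bands follow the 0.2 / 0.5 thresholds inclusively", {
  bands <- sipstats:::effect_band(c(0.19, 0.2, -0.2, 0.49, 0.5, -0.7))
  expect_equal(as.character(bands),
               c("weak", "moderate", "moderate", "moderate", "strong",
                 "strong"))
})

test_that("beta* is invariant to affine rescaling of data", {
  set.seed(8)
  d <- tibble::as_tibble(matrix(rnorm(240), 80,
                                dimnames = list(NULL, c("a", "b", "c"))))
  d$y <- 0.5 * d$a - 0.3 * d$b + rnorm(80, sd = 0.4)
  f1 <- standardized_regression(d, "y", c("a", "b", "c"))
  d2 <- dplyr::mutate(d, a = 100 * a - 3, y = 0.01 * y + 5)
  f2 <- standardized_regression(d2, "y", c("a", "b", "c"))
  expect_equal(tidy(f1)$beta_star, tidy(f2)$beta_star, tolerance = 1e-10)
  expect_equal(glance(f1)$r_squared, glance(f2)$r_squared,
               tolerance = 1e-10)
})

test_that("constant predictors and collinearity are caught", {
  d <- tibble::tibble(a = rnorm(30), k = 1, y = rnorm(30))
  expect_error(standardized_regression(d, "y", c("a", "k")),
               class = "sipstats_argument_error")
  set.seed(2)
  d2 <- tibble::tibble(a = rnorm(50))
  d2$b <- d2$a + rnorm(50, sd = 1e-6)
  d2$y <- d2$a + rnorm(50)
  expect_warning(standardized_regression(d2, "y", c("a", "b")),
                 "collinear")
})

test_that("Kruskal-Wallis H matches hand rank-sum arithmetic", {
  vals <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12)
  grp <- rep(c("g1", "g2", "g3"), each = 4)
  gt <- kruskal_dunn(vals, grp)
  expect_equal(gt$h, 128 / 13, tolerance = 1e-12)  # 12/(N(N+1)) * sum - 3(N+1)
  p13 <- gt$pairwise[gt$pairwise$group1 == "g1" &
                       gt$pairwise$group2 == "g3", ]
  expect_equal(abs(p13$z), 8 / sqrt(13 * 0.5), tolerance = 1e-12)
  expect_true(all(gt$pairwise$p_adj >= gt$pairwise$p_raw))
})

test_that("identical groups yield a null result and invariance to monotone maps", {
  set.seed(4)
  vals <- rnorm(60)
  grp <- rep(letters[1:3], 20)
  gt <- kruskal_dunn(vals, grp)
  expect_gt(gt$p_value, 0.05)
  gt2 <- kruskal_dunn(exp(vals), grp)
  expect_equal(gt$h, gt2$h, tolerance = 1e-12)
  expect_warning(kruskal_dunn(c(vals, 1), c(grp, "lonely")), "dropping")
})

test_that("quadratic fits interpolate and recover the planted parabola", {
  slopes <- -5:0
  ratings <- tidyr::expand_grid(participant_id = "P1",
                                image_id = paste0("rp", 1:6),
                                dimension = c("Pleasing", "Harmonious",
                                              "Interesting"))
  ratings$category <- "random_phase"
  ratings$set_slope <- slopes[match(ratings$image_id, paste0("rp", 1:6))]
  ratings$rating <- 0.8 - 0.1 * (ratings$set_slope + 2.5)^2
  sp <- slope_preference_curves(ratings)
  quad <- tidy(sp)
  expect_equal(quad$vertex, rep(-2.5, 3), tolerance = 1e-8)
  expect_true(all(quad$curvature < 0))
  expect_equal(quad$r_squared, rep(1, 3), tolerance = 1e-10)
  # exact interpolation through any 3 distinct points
  three <- ratings[ratings$set_slope %in% c(-4, -2, 0), ]
  three$rating <- c(0.1, 0.9, 0.3)[match(three$set_slope, c(-4, -2, 0))]
  q3 <- tidy(slope_preference_curves(three))
  expect_equal(q3$r_squared, rep(1, 3), tolerance = 1e-10)
})

test_that("inter-rating correlations detect identical and anticorrelated raters", {
  set.seed(6)
  imgs <- paste0("i", 1:20)
  base <- runif(20)
  long <- tidyr::expand_grid(participant_id = c("same", "anti"),
                             image_id = imgs,
                             dimension = c("Pleasing", "Harmonious",
                                           "Interesting"))
  long$category <- "style_transferred"
  long$rating <- base[match(long$image_id, imgs)]
  flip <- long$participant_id == "anti" & long$dimension == "Interesting"
  long$rating[flip] <- 1 - long$rating[flip]
  per <- inter_rating_correlations(long, "per_participant")
  expect_equal(per$rho_PH[per$participant_id == "same"], 1)
  expect_equal(per$rho_HI[per$participant_id == "same"], 1)
  expect_equal(per$rho_HI[per$participant_id == "anti"], -1)
  pooled <- inter_rating_correlations(long, "pooled")
  expect_equal(nrow(pooled), 3)
})

test_that("pooled correlations equal a brute-force rank correlation", {
  set.seed(10)
  imgs <- paste0("i", 1:10)
  long <- tidyr::expand_grid(participant_id = c("P1", "P2"),
                             image_id = imgs,
                             dimension = c("Pleasing", "Harmonious",
                                           "Interesting"))
  long$category <- "style_transferred"
  long$rating <- runif(nrow(long))
  pooled <- inter_rating_correlations(long, "pooled")
  means <- aggregate_ratings(long, "image")
  wide <- tidyr::pivot_wider(means[c("image_id", "dimension",
                                     "mean_rating")],
                             names_from = "dimension",
                             values_from = "mean_rating")
  hand <- cor(rank(wide$Pleasing), rank(wide$Harmonious))
  expect_equal(pooled$rho[pooled$pair == "Pleasing-Harmonious"], hand,
               tolerance = 1e-12)
})
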