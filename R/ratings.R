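# Rating-table analyses: aggregation, standardized-coefficient regression,
# Kruskal-Wallis + Dunn group tests, quadratic slope-preference curves,
# and inter-rating correlations.

RATING_DIMENSIONS <- c("Pleasing", "Harmonious", "Interesting")

check_rating_table <- function(ratings) {
  need <- c("participant_id", "image_id", "category", "dimension", "rating")
  missing <- setdiff(need, names(ratings))
  if (length(missing)) {
    abort(paste0("rating table lacks column(s): ",
                 paste(missing, collapse = ", ")),
          class = "sipstats_argument_error")
  }
  if (any(ratings$rating < 0 | ratings$rating > 1, na.rm = TRUE)) {
    abort("ratings must lie in [0, 1].", class = "sipstats_argument_error")
  }
  invisible(ratings)
}

significance_stars <- function(p) {
  dplyr::case_when(
    p < 1e-4 ~ "****", p < 1e-3 ~ "***", p < 1e-2 ~ "**",
    p < 0.05 ~ "*", TRUE ~ ""
  )
}

effect_band <- function(beta) {
  cut(abs(beta), breaks = c(0, 0.2, 0.5, Inf),
      labels = c("weak", "moderate", "strong"),
      right = FALSE, include.lowest = TRUE)
}

#' Aggregate a long rating table
#'
#' Arithmetic mean ratings with counts, grouped per image, per artist
#' (requires an `artist` column), or per participant-by-slope cell
#' (requires a `set_slope` column). The reported counts support coverage
#' audits, e.g. a balanced 30-of-150 design with 40 raters yields exactly
#' 8 ratings per image.
#'
#' @param ratings Long rating table with columns `participant_id`,
#'   `image_id`, `category`, `dimension`, `rating`.
#' @param by One of `"image"`, `"artist"`, `"participant_slope"`.
#' @return A tibble of group keys, `mean_rating` and `n_ratings`.
#' @export
aggregate_ratings <- function(ratings,
                              by = c("image", "artist",
                                     "participant_slope")) {
  by <- match.arg(by)
  check_rating_table(ratings)
  if (nrow(ratings) == 0L) {
    abort("empty rating table.", class = "sipstats_argument_error")
  }
  keys <- switch(by,
    image = c("image_id", "category", "dimension"),
    artist = c("artist", "category", "dimension"),
    participant_slope = c("participant_id", "set_slope", "dimension"))
  missing <- setdiff(keys, names(ratings))
  if (length(missing)) {
    abort(paste0("grouping `", by, "` needs column(s): ",
                 paste(missing, collapse = ", ")),
          class = "sipstats_argument_error")
  }
  dplyr::summarise(
    dplyr::group_by(ratings, dplyr::across(dplyr::all_of(keys))),
    mean_rating = mean(.data$rating),
    n_ratings = dplyr::n(),
    .groups = "drop")
}

#' Standardized-coefficient multiple regression
#'
#' Z-scores the response and every predictor, fits ordinary least squares,
#' and reports standardized coefficients (beta*) with partial two-sided
#' t-tests ("controlled for" the other predictors in the full model).
#' Coefficients are banded by the conventional effect sizes: |beta*| < 0.2
#' weak, 0.2 <= |beta*| < 0.5 moderate, >= 0.5 strong.
#'
#' @param data Data frame holding response and predictors (typically
#'   per-image mean ratings joined to a SIP table).
#' @param response Response column name.
#' @param predictors Character vector of predictor column names.
#' @param condition_warn Condition-number bound above which a collinearity
#'   warning with variance-inflation factors is emitted (default 1e4).
#' @return Object of class `std_regression`; see [tidy.std_regression()]
#'   and [glance.std_regression()].
#' @export
standardized_regression <- function(data, response, predictors,
                                    condition_warn = 1e4) {
  data <- as_tibble(data)
  stopifnot(response %in% names(data), all(predictors %in% names(data)))
  d <- data[complete.cases(data[c(response, predictors)]),
            c(response, predictors)]
  n <- nrow(d); p <- length(predictors)
  if (n <= p + 2) {
    abort("need n > p + 2 complete rows.",
          class = "sipstats_argument_error")
  }
  sds <- vapply(d, sd, numeric(1))
  if (any(sds[predictors] == 0)) {
    abort(paste0("constant predictor(s): ",
                 paste(predictors[sds[predictors] == 0], collapse = ", ")),
          class = "sipstats_argument_error")
  }
  z <- as_tibble(lapply(d, function(v) as.numeric(scale(v))))
  X <- as.matrix(z[predictors])
  kappa_x <- kappa(crossprod(X), exact = TRUE)
  vifs <- NULL
  if (is.finite(kappa_x) && kappa_x > condition_warn) {
    r2j <- vapply(seq_len(p), function(j) {
      summary(lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared
    }, numeric(1))
    vifs <- setNames(1 / (1 - r2j), predictors)
    warn(paste0("predictors are nearly collinear (condition number ",
                format(kappa_x, digits = 3), "); VIF: ",
                paste(sprintf("%s=%.1f", predictors, vifs),
                      collapse = ", ")))
  }
  fml <- stats::reformulate(predictors, response = response)
  fit <- lm(fml, data = z)
  sm <- suppressWarnings(summary(fit))   # perfect fits are legitimate here
  ct <- sm$coefficients[predictors, , drop = FALSE]
  coefs <- tibble(
    term = predictors,
    beta_star = unname(ct[, 1]),
    std_error = unname(ct[, 2]),
    statistic = unname(ct[, 3]),
    p_value = unname(ct[, 4]),
    significant = unname(ct[, 4] < 0.05),
    stars = significance_stars(unname(ct[, 4])),
    effect_band = as.character(effect_band(unname(ct[, 1])))
  )
  fstat <- sm$fstatistic
  structure(
    list(coefficients = coefs,
         r_squared = sm$r.squared,
         r_squared_adj = sm$adj.r.squared,
         n = n, p = p,
         f_p_value = unname(pf(fstat[1], fstat[2], fstat[3],
                               lower.tail = FALSE)),
         response = response, vif = vifs, fit = fit),
    class = "std_regression"
  )
}

#' @export
print.std_regression <- function(x, ...) {
  cat(sprintf("<std_regression> %s ~ %d SIPs, n = %d, adj R^2 = %.3f\n",
              x$response, x$p, x$n, x$r_squared_adj))
  print(as.data.frame(x$coefficients[c("term", "beta_star", "p_value",
                                       "stars", "effect_band")]),
        digits = 3, row.names = FALSE)
  invisible(x)
}

#' Tidy a standardized regression
#'
#' @param x A `std_regression` object.
#' @param ... Unused.
#' @return Tibble with `term`, `beta_star`, `std_error`, `statistic`,
#'   `p_value`, `significant`, `stars`, `effect_band`.
#' @exportS3Method generics::tidy
tidy.std_regression <- function(x, ...) x$coefficients

#' Model-level summary of a standardized regression
#'
#' @param x A `std_regression` object.
#' @param ... Unused.
#' @return One-row tibble with `r_squared`, `r_squared_adj`, `n`, `p`,
#'   `f_p_value`.
#' @exportS3Method generics::glance
glance.std_regression <- function(x, ...) {
  tibble(r_squared = x$r_squared, r_squared_adj = x$r_squared_adj,
         n = x$n, p = x$p, f_p_value = x$f_p_value)
}

#' Kruskal-Wallis test with Dunn's post-test
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square p-value
#' (via [stats::kruskal.test()]), followed by Dunn's z for every group
#' pair with multiplicity-adjusted p-values (Holm by default, Bonferroni
#' available) and the conventional significance stars
#' (0.05 / 0.01 / 0.001 / 0.0001).
#'
#' @param values Numeric vector.
#' @param groups Group labels, same length.
#' @param p_adjust `"holm"` (default) or `"bonferroni"`.
#' @return Object of class `group_test`: `h`, `df`, `p_value`, and a
#'   `pairwise` tibble (`group1`, `group2`, `z`, `p_raw`, `p_adj`,
#'   `stars`).
#' @export
kruskal_dunn <- function(values, groups, p_adjust = c("holm",
                                                      "bonferroni")) {
  p_adjust <- match.arg(p_adjust)
  stopifnot(length(values) == length(groups))
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- as.character(groups[ok])
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warn(paste0("dropping group(s) with < 2 values: ",
                paste(small, collapse = ", ")))
    keep <- !(groups %in% small)
    values <- values[keep]; groups <- groups[keep]
    sizes <- table(groups)
  }
  if (length(sizes) < 2) {
    abort("need at least 2 groups with >= 2 values.",
          class = "sipstats_argument_error")
  }
  kw <- kruskal.test(values, factor(groups))
  # Dunn's z with tie correction
  n_tot <- length(values)
  rk <- rank(values)
  mean_rank <- tapply(rk, groups, mean)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n_tot - 1))
  base_var <- n_tot * (n_tot + 1) / 12 - tie_term
  gnames <- names(sizes)
  combs <- combn(gnames, 2L)
  zvals <- apply(combs, 2, function(gp) {
    se <- sqrt(base_var * (1 / sizes[gp[1]] + 1 / sizes[gp[2]]))
    (mean_rank[gp[1]] - mean_rank[gp[2]]) / se
  })
  p_raw <- 2 * pnorm(abs(zvals), lower.tail = FALSE)
  p_adj <- pmin(p.adjust(p_raw, method = p_adjust), 1)
  pairwise <- tibble(
    group1 = combs[1, ], group2 = combs[2, ],
    z = unname(zvals), p_raw = unname(p_raw), p_adj = unname(p_adj),
    stars = significance_stars(p_adj)
  )
  structure(
    list(h = unname(kw$statistic), df = unname(kw$parameter),
         p_value = kw$p.value, pairwise = pairwise,
         adjust_method = p_adjust, group_sizes = sizes),
    class = "group_test"
  )
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("<group_test> Kruskal-Wallis H = %.3f (df = %d), p = %.3g; Dunn/%s pairs:\n",
              x$h, x$df, x$p_value, x$adjust_method))
  print(as.data.frame(x$pairwise), digits = 3, row.names = FALSE)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.group_test <- function(x, ...) x$pairwise

#' @exportS3Method generics::glance
glance.group_test <- function(x, ...) {
  tibble(h = x$h, df = x$df, p_value = x$p_value,
         n_groups = length(x$group_sizes))
}

#' Quadratic preference curves over set spectral slopes
#'
#' For each rating dimension: a Kruskal-Wallis test (with Dunn pairs)
#' comparing per-image mean ratings across the set-slope levels, and a
#' least-squares quadratic fit of mean rating versus set slope. An
#' inverted-U preference (peak at intermediate slopes, typically between
#' -3 and -2) shows up as a negative quadratic coefficient with a vertex
#' in that range.
#'
#' @param ratings Long rating table restricted to one category; must
#'   carry a `set_slope` column, or supply `set_slopes`.
#' @param set_slopes Optional lookup tibble (`image_id`, `set_slope`).
#' @return Object of class `slope_preference`: per dimension a
#'   `quadratic` tibble row (`a`, `b`, `c`, `vertex`, `curvature`,
#'   `r_squared`) and a `group_test`.
#' @export
slope_preference_curves <- function(ratings, set_slopes = NULL) {
  check_rating_table(ratings)
  if (!is.null(set_slopes)) {
    ratings <- dplyr::inner_join(
      dplyr::select(ratings, -dplyr::any_of("set_slope")),
      set_slopes, by = "image_id")
  }
  if (!"set_slope" %in% names(ratings)) {
    abort("no `set_slope` available for the rated images.",
          class = "sipstats_argument_error")
  }
  if (dplyr::n_distinct(ratings$set_slope) < 3) {
    abort("need at least 3 distinct slope levels.",
          class = "sipstats_argument_error")
  }
  per_image <- dplyr::summarise(
    dplyr::group_by(ratings, .data$image_id, .data$set_slope,
                    .data$dimension),
    mean_rating = mean(.data$rating), .groups = "drop")
  dims <- intersect(RATING_DIMENSIONS, unique(per_image$dimension))
  fits <- lapply(dims, function(dim) {
    d <- per_image[per_image$dimension == dim, ]
    qf <- lm(mean_rating ~ set_slope + I(set_slope^2), data = d)
    cf <- coef(qf)
    quad <- tibble(
      dimension = dim, a = unname(cf[1]), b = unname(cf[2]),
      c = unname(cf[3]),
      vertex = if (abs(cf[3]) > 1e-12) unname(-cf[2] / (2 * cf[3]))
               else NA_real_,
      curvature = sign(unname(cf[3])),
      r_squared = suppressWarnings(summary(qf)$r.squared)
    )
    gt <- tryCatch(
      suppressWarnings(kruskal_dunn(d$mean_rating, d$set_slope)),
      sipstats_argument_error = function(e) NULL)  # < 2 images per level
    list(quadratic = quad, group_test = gt)
  })
  names(fits) <- dims
  structure(list(dimensions = fits), class = "slope_preference")
}

#' @export
print.slope_preference <- function(x, ...) {
  print(tidy(x))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.slope_preference <- function(x, ...) {
  dplyr::bind_rows(lapply(x$dimensions, `[[`, "quadratic"))
}

#' Correlations between rating dimensions
#'
#' Spearman correlations between the three rating dimension pairs
#' (Pleasing-Harmonious, Pleasing-Interesting, Harmonious-Interesting),
#' either pooled on per-image mean ratings or within each participant's
#' own ratings. The per-participant vectors feed the rater clustering.
#'
#' @param ratings Long rating table.
#' @param scope `"pooled"` (per-image means) or `"per_participant"`.
#' @param min_images Minimum common images per participant (default 5);
#'   participants below it are excluded with a warning.
#' @return Pooled: tibble (`pair`, `rho`, `p_value`). Per participant:
#'   tibble (`participant_id`, `rho_PH`, `rho_PI`, `rho_HI`, `n_images`).
#' @export
inter_rating_correlations <- function(ratings,
                                      scope = c("pooled",
                                                "per_participant"),
                                      min_images = 5) {
  scope <- match.arg(scope)
  check_rating_table(ratings)
  spear <- function(x, y) {
    ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                    exact = FALSE))
    c(unname(ct$estimate), ct$p.value)
  }
  pair_frame <- function(wide) {
    ph <- spear(wide$Pleasing, wide$Harmonious)
    pi_ <- spear(wide$Pleasing, wide$Interesting)
    hi <- spear(wide$Harmonious, wide$Interesting)
    tibble(pair = c("Pleasing-Harmonious", "Pleasing-Interesting",
                    "Harmonious-Interesting"),
           rho = c(ph[1], pi_[1], hi[1]),
           p_value = c(ph[2], pi_[2], hi[2]))
  }
  if (scope == "pooled") {
    wide <- tidyr::pivot_wider(
      aggregate_ratings(ratings, "image")[c("image_id", "dimension",
                                            "mean_rating")],
      names_from = "dimension", values_from = "mean_rating")
    wide <- wide[complete.cases(wide), ]
    return(pair_frame(wide))
  }
  per <- lapply(split(ratings, ratings$participant_id), function(d) {
    wide <- tidyr::pivot_wider(d[c("image_id", "dimension", "rating")],
                               names_from = "dimension",
                               values_from = "rating")
    wide <- wide[complete.cases(wide), ]
    if (nrow(wide) < min_images) return(NULL)
    pf <- pair_frame(wide)
    tibble(participant_id = d$participant_id[1],
           rho_PH = pf$rho[1], rho_PI = pf$rho[2], rho_HI = pf$rho[3],
           n_images = nrow(wide))
  })
  excluded <- names(per)[vapply(per, is.null, logical(1))]
  if (length(excluded)) {
    warn(paste0("participant(s) with < ", min_images,
                " common images excluded: ",
                paste(excluded, collapse = ", ")))
  }
  dplyr::bind_rows(per)
}
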