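# Distance of images to a reference corpus ("sweet spot") in SIP space.

#' Build a reference distribution in SIP space
#'
#' Summarizes a reference SIP table (e.g. a corpus of traditional
#' paintings) by the per-variable median center and the full sample
#' covariance of the reference rows. The covariance is ridge-regularized
#' by `ridge * mean(diag)` when near-singular. Variables can be supplied
#' explicitly or selected automatically as those whose Kruskal-Wallis
#' comparison between the test and reference categories is significant.
#'
#' @param reference_sips SIP table (tibble) of the reference corpus.
#' @param variables Character vector of SIP columns, or `"auto"` together
#'   with `test_sips`.
#' @param test_sips Optional test-set SIP table for automatic variable
#'   selection.
#' @param alpha Significance level for automatic selection (default 0.05).
#' @param ridge Ridge fraction of the mean diagonal (default 1e-8).
#' @return Object of class `reference_distribution`: `variables`,
#'   `center`, `covariance`, `n_reference`.
#' @export
build_reference <- function(reference_sips, variables, test_sips = NULL,
                            alpha = 0.05, ridge = 1e-8) {
  reference_sips <- as_tibble(reference_sips)
  if (identical(variables, "auto")) {
    if (is.null(test_sips)) {
      abort("automatic variable selection needs `test_sips`.",
            class = "sipstats_argument_error")
    }
    candidates <- intersect(names(reference_sips), names(test_sips))
    candidates <- candidates[vapply(reference_sips[candidates], is.numeric,
                                    logical(1))]
    pvals <- vapply(candidates, function(v) {
      vals <- c(reference_sips[[v]], test_sips[[v]])
      grp <- rep(c("reference", "test"),
                 c(nrow(reference_sips), nrow(test_sips)))
      ok <- is.finite(vals)
      if (diff(range(vals[ok])) == 0) return(1)
      kruskal.test(vals[ok], factor(grp[ok]))$p.value
    }, numeric(1))
    variables <- candidates[pvals < alpha]
    if (length(variables) == 0L) {
      abort("no SIP differs significantly; supply `variables` explicitly.",
            class = "sipstats_argument_error")
    }
    # the covariance needs more reference rows than variables; keep the
    # most clearly separated ones if the subspace would be too large
    max_vars <- sum(complete.cases(reference_sips[variables])) - 3L
    if (length(variables) > max_vars) {
      variables <- variables[order(pvals[variables])][seq_len(max_vars)]
    }
  }
  stopifnot(all(variables %in% names(reference_sips)))
  m <- as.matrix(reference_sips[variables])
  m <- m[complete.cases(m), , drop = FALSE]
  if (nrow(m) <= length(variables) + 2) {
    abort("need more reference rows than variables + 2.",
          class = "sipstats_argument_error")
  }
  center <- apply(m, 2, median)
  covariance <- cov(m)
  # genuinely redundant variables cannot be rescued by a tiny ridge
  cors <- abs(suppressWarnings(stats::cov2cor(covariance)))
  diag(cors) <- 0
  if (any(!is.finite(cors)) || max(cors) > 1 - 1e-10) {
    worst <- which(cors == max(cors), arr.ind = TRUE)[1, ]
    abort(paste0("singular reference covariance; offending variables: ",
                 paste(variables[worst], collapse = ", ")),
          class = "sipstats_singular_covariance")
  }
  if (rcond(covariance) < 1e-12) {
    covariance <- covariance +
      diag(ridge * mean(diag(covariance)), length(variables))
  }
  structure(
    list(variables = variables, center = center, covariance = covariance,
         n_reference = nrow(m)),
    class = "reference_distribution"
  )
}

#' @export
print.reference_distribution <- function(x, ...) {
  cat(sprintf("<reference_distribution> %d variables, n = %d\n",
              length(x$variables), x$n_reference))
  print(round(x$center, 3))
  invisible(x)
}

#' Squared Mahalanobis distance to a reference
#'
#' `(x - center)' Sigma^-1 (x - center)` with the reference covariance
#' Sigma: a multivariate analogue of squared Euclidean distance that
#' whitens correlated SIPs. With an identity covariance it reduces to the
#' squared Euclidean distance; it is invariant under joint invertible
#' affine transforms of query and reference.
#'
#' @param x A numeric vector (one image), or a matrix / data frame with
#'   one row per image; columns must cover `ref$variables`.
#' @param ref A [build_reference()] result.
#' @return Numeric vector of squared distances.
#' @export
mahalanobis_sq <- function(x, ref) {
  stopifnot(inherits(ref, "reference_distribution"))
  if (is.data.frame(x)) x <- as.matrix(x[ref$variables])
  if (is.null(dim(x))) {
    if (!is.null(names(x))) {
      if (!all(ref$variables %in% names(x))) {
        abort("`x` lacks reference variables.",
              class = "sipstats_argument_error")
      }
      x <- x[ref$variables]
    }
    x <- matrix(x, nrow = 1)
  }
  if (ncol(x) != length(ref$variables)) {
    abort("dimension mismatch with reference variables.",
          class = "sipstats_argument_error")
  }
  unname(mahalanobis(x, center = ref$center, cov = ref$covariance))
}

#' Distance table of a SIP set against a reference
#'
#' Per image: squared Mahalanobis distance in the reference subspace and,
#' per SIP, the absolute (1-D Euclidean) distance to the reference median.
#'
#' @param sips SIP table with `image_id`.
#' @param ref A [build_reference()] result.
#' @return Tibble with `image_id`, `mahalanobis_sq`, and one
#'   `dist_<variable>` column per reference SIP.
#' @export
distance_table <- function(sips, ref) {
  stopifnot("image_id" %in% names(sips))
  m <- as.matrix(sips[ref$variables])
  out <- tibble(image_id = sips$image_id,
                mahalanobis_sq = mahalanobis_sq(m, ref))
  for (v in ref$variables) {
    out[[paste0("dist_", v)]] <- abs(sips[[v]] - ref$center[[v]])
  }
  out
}

#' Correlate distances to the reference with ratings
#'
#' Spearman correlations between each rating dimension and (a) each
#' per-SIP absolute distance to the reference median, (b) the squared
#' Mahalanobis distance. Negative correlations mean images closer to the
#' reference corpus are rated higher.
#'
#' @param distances A [distance_table()] result.
#' @param ratings Aggregated per-image ratings
#'   ([aggregate_ratings()] output) or a long rating table.
#' @param min_shared Minimum number of shared images (default 10).
#' @return Tibble with `dimension`, `distance` (SIP name or
#'   `"mahalanobis_sq"`), `rho`, `p_value`, `n`.
#' @export
distance_rating_correlation <- function(distances, ratings,
                                        min_shared = 10) {
  if (!"mean_rating" %in% names(ratings)) {
    ratings <- aggregate_ratings(ratings, "image")
  }
  joined <- dplyr::inner_join(distances, ratings, by = "image_id")
  dist_cols <- c(grep("^dist_", names(distances), value = TRUE),
                 "mahalanobis_sq")
  rows <- list()
  for (dim in unique(joined$dimension)) {
    d <- joined[joined$dimension == dim, ]
    if (nrow(d) < min_shared) {
      abort(sprintf("only %d shared images for %s (need >= %d).",
                    nrow(d), dim, min_shared),
            class = "sipstats_insufficient_data")
    }
    for (dc in dist_cols) {
      ct <- suppressWarnings(cor.test(d[[dc]], d$mean_rating,
                                      method = "spearman", exact = FALSE))
      rows[[length(rows) + 1L]] <- tibble(
        dimension = dim,
        distance = sub("^dist_", "", dc),
        rho = unname(ct$estimate), p_value = ct$p.value, n = nrow(d))
    }
  }
  dplyr::bind_rows(rows)
}
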