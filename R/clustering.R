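# Participant clustering: feature construction, k-means with k-means++
# restarts, and cluster-count diagnostics (elbow, silhouette, gap) under a
# minimum-cluster-size constraint.

#' Participant feature vectors for clustering
#'
#' Mode `"inter_rating"` builds the 3-vector of within-participant
#' Spearman correlations between rating dimensions (rho_PH, rho_PI,
#' rho_HI). Mode `"slope_profile"` builds the 18-vector of mean ratings
#' per set-slope level and dimension (6 slopes x 3 dimensions with the
#' study's conditions), z-scored per feature. Participants with
#' insufficient data are excluded with a warning.
#'
#' @param ratings Long rating table; slope mode needs a `set_slope`
#'   column (restrict to the random-phase category first).
#' @param mode `"inter_rating"` or `"slope_profile"`.
#' @param min_images Minimum common images for inter-rating correlations.
#' @return A numeric matrix with participants as (named) rows.
#' @export
participant_feature_vectors <- function(ratings,
                                        mode = c("inter_rating",
                                                 "slope_profile"),
                                        min_images = 5) {
  mode <- match.arg(mode)
  check_rating_table(ratings)
  if (mode == "inter_rating") {
    tab <- inter_rating_correlations(ratings, "per_participant",
                                     min_images = min_images)
    m <- as.matrix(tab[c("rho_PH", "rho_PI", "rho_HI")])
    rownames(m) <- tab$participant_id
    return(m)
  }
  agg <- aggregate_ratings(ratings, "participant_slope")
  wide <- tidyr::pivot_wider(
    agg[c("participant_id", "set_slope", "dimension", "mean_rating")],
    names_from = c("dimension", "set_slope"),
    values_from = "mean_rating", names_sep = "_at_")
  complete <- complete.cases(wide)
  if (any(!complete)) {
    warn(paste0("participant(s) without full slope coverage excluded: ",
                paste(wide$participant_id[!complete], collapse = ", ")))
    wide <- wide[complete, ]
  }
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$participant_id
  scale(m)
}

# k-means++ initial centers (deterministic given the RNG state).
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- numeric(k)
  centers[1] <- sample.int(n, 1L)
  d2 <- rowSums((X - X[rep(centers[1], n), , drop = FALSE])^2)
  for (j in seq_len(k - 1L) + 1L) {
    probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j] <- sample.int(n, 1L, prob = probs)
    nd <- rowSums((X - X[rep(centers[j], n), , drop = FALSE])^2)
    d2 <- pmin(d2, nd)
  }
  X[centers, , drop = FALSE]
}

run_kmeans <- function(X, k, n_init) {
  best <- NULL
  for (r in seq_len(n_init)) {
    init <- kmeanspp_centers(X, k)
    fit <- suppressWarnings(
      kmeans(X, centers = init, iter.max = 100, algorithm = "Lloyd"))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  best
}

mean_silhouette <- function(X, assignment) {
  if (length(unique(assignment)) < 2L) return(NA_real_)
  mean(cluster::silhouette(assignment, dist(X))[, "sil_width"])
}

#' K-means clustering with count diagnostics
#'
#' Lloyd's algorithm with `n_init` k-means++ restarts per `k` (best
#' within-cluster sum of squares kept), reporting three cluster-count
#' diagnostics over `k_range`: the elbow criterion (largest second
#' difference of the WSS curve), mean silhouette width, and the gap
#' statistic against a uniform bounding-box reference. The chosen k
#' follows the elbow suggestion, demoted to the largest k whose best
#' solution has every cluster larger than `min_cluster_size - 1`
#' members (so no cluster of three or fewer raters is reported under the
#' default).
#'
#' @param X Numeric matrix, observations in rows (e.g.
#'   [participant_feature_vectors()]).
#' @param k_range Candidate cluster counts (default 1:8).
#' @param n_init Restarts per k (default 25).
#' @param seed RNG seed for restarts and the gap reference.
#' @param min_cluster_size Smallest admissible cluster (default 4).
#' @param gap_b Gap-statistic reference draws (default 50).
#' @return Object of class `cluster_result`: `assignments`, `centers`,
#'   `chosen_k`, `elbow_k`, `diagnostics` (tibble per k),
#'   `constraint_violations`, `fits`.
#' @export
kmeans_with_diagnostics <- function(X, k_range = 1:8, n_init = 25,
                                    seed = 1, min_cluster_size = 4,
                                    gap_b = 50) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (max(k_range) > n) {
    abort("k cannot exceed the number of observations.",
          class = "sipstats_argument_error")
  }
  k_range <- sort(unique(as.integer(k_range)))
  withr::local_seed(seed)
  fits <- lapply(k_range, function(k) {
    if (k == 1L) {
      ctr <- matrix(colMeans(X), 1)
      wss <- sum(scale(X, scale = FALSE)^2)
      list(cluster = rep(1L, n), centers = ctr, tot.withinss = wss,
           size = n)
    } else {
      run_kmeans(X, k, n_init)
    }
  })
  names(fits) <- as.character(k_range)
  wss <- vapply(fits, `[[`, numeric(1), "tot.withinss")
  sil <- vapply(seq_along(k_range), function(i) {
    mean_silhouette(X, fits[[i]]$cluster)
  }, numeric(1))
  # gap statistic: uniform draws over the data's bounding box
  lo <- apply(X, 2, min); hi <- apply(X, 2, max)
  ref_wss <- matrix(NA_real_, gap_b, length(k_range))
  for (b in seq_len(gap_b)) {
    Xi <- sapply(seq_along(lo), function(j) runif(n, lo[j], hi[j]))
    Xi <- matrix(Xi, n)
    for (i in seq_along(k_range)) {
      k <- k_range[i]
      ref_wss[b, i] <- if (k == 1L) sum(scale(Xi, scale = FALSE)^2)
                       else run_kmeans(Xi, k, 3L)$tot.withinss
    }
  }
  gap <- colMeans(log(ref_wss)) - log(wss)
  # elbow: largest second difference of the WSS curve (interior k only)
  elbow_k <- if (length(k_range) >= 3L) {
    second_diff <- diff(wss, differences = 2)
    k_range[which.max(second_diff) + 1L]
  } else {
    k_range[which.max(-wss)]
  }
  min_size <- vapply(fits, function(f) min(f$size), numeric(1))
  admissible <- k_range[min_size >= min_cluster_size | k_range == 1L]
  chosen_k <- max(admissible[admissible <= elbow_k], 1L)
  violations <- k_range[min_size < min_cluster_size & k_range > 1L]
  chosen <- fits[[as.character(chosen_k)]]
  assignments <- setNames(chosen$cluster, rownames(X))
  structure(
    list(assignments = assignments, centers = chosen$centers,
         chosen_k = chosen_k, elbow_k = elbow_k,
         diagnostics = tibble(k = k_range, wss = unname(wss),
                              silhouette = sil, gap = unname(gap),
                              min_cluster_size = unname(min_size)),
         constraint_violations = violations,
         min_cluster_size_required = min_cluster_size,
         fits = fits),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> chosen k = %d (elbow %d), sizes: %s\n",
              x$chosen_k, x$elbow_k,
              paste(sort(table(x$assignments), decreasing = TRUE),
                    collapse = ", ")))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cluster_result <- function(x, ...) {
  tibble(participant_id = names(x$assignments) %||%
           as.character(seq_along(x$assignments)),
         cluster = unname(x$assignments))
}

#' @exportS3Method generics::glance
glance.cluster_result <- function(x, ...) {
  tibble(chosen_k = x$chosen_k, elbow_k = x$elbow_k,
         wss = x$diagnostics$wss[x$diagnostics$k == x$chosen_k],
         silhouette = x$diagnostics$silhouette[
           x$diagnostics$k == x$chosen_k])
}
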