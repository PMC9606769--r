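# First- and second-order edge-orientation entropy. Oriented edge strength
# comes from a bank of first-derivative-of-Gaussian filters applied to
# luminance; the strongest non-overlapping edge pixels are kept and their
# orientation statistics summarized as Shannon entropies.

# Derivative-of-Gaussian kernel for a directional derivative along
# (cos theta, sin theta); theta in degrees. x = column offset, y = row
# offset (downward). Kernel is zero-mean by construction and L2-normalized.
dog_kernel <- function(theta_deg, sigma = 1.5) {
  r <- ceiling(3 * sigma)
  off <- -r:r
  x <- matrix(rep(off, each = 2 * r + 1), 2 * r + 1)   # column offset
  y <- matrix(rep(off, times = 2 * r + 1), 2 * r + 1)  # row offset
  th <- theta_deg * pi / 180
  g <- exp(-(x^2 + y^2) / (2 * sigma^2))
  k <- -(x * cos(th) + y * sin(th)) / sigma^2 * g
  k <- k - mean(k)
  k / sqrt(sum(k^2))
}

# Oriented edge map: per-pixel max |response| over orientations and the
# argmax orientation index.
oriented_edge_map <- function(lum, n_orientations, sigma = 1.5) {
  best_strength <- matrix(-Inf, nrow(lum), ncol(lum))
  best_ori <- matrix(1L, nrow(lum), ncol(lum))
  for (k in seq_len(n_orientations)) {
    theta <- (k - 1) * 180 / n_orientations
    resp <- abs(EBImage::filter2(lum, dog_kernel(theta, sigma)))
    upd <- resp > best_strength
    best_ori[upd] <- k
    best_strength[upd] <- resp[upd]
  }
  list(strength = best_strength, orientation = best_ori,
       margin = ceiling(3 * sigma))
}

# Greedy non-maximum suppression: accept pixels in decreasing strength
# order, blocking a Chebyshev radius around each accepted pixel. A margin
# equal to the filter radius is excluded (circular padding wraps there).
# Candidates are capped for speed; the cap never binds on test-size images.
select_edges <- function(edge_map, n_edges, radius = 3,
                         candidate_cap = 50L * n_edges) {
  h <- nrow(edge_map$strength); w <- ncol(edge_map$strength)
  m <- edge_map$margin
  valid <- matrix(FALSE, h, w)
  valid[(m + 1):(h - m), (m + 1):(w - m)] <- TRUE
  cand <- which(valid & edge_map$strength > 0)
  ord <- order(edge_map$strength[cand], -cand, decreasing = TRUE)
  cand <- cand[ord]
  if (length(cand) > candidate_cap) cand <- cand[seq_len(candidate_cap)]
  blocked <- matrix(FALSE, h, w)
  keep <- integer(0)
  for (p in cand) {
    i <- (p - 1L) %% h + 1L
    j <- (p - 1L) %/% h + 1L
    if (blocked[i, j]) next
    keep <- c(keep, p)
    if (length(keep) >= n_edges) break
    blocked[max(1L, i - radius):min(h, i + radius),
            max(1L, j - radius):min(w, j + radius)] <- TRUE
  }
  list(
    row = (keep - 1L) %% h + 1L,
    col = (keep - 1L) %/% h + 1L,
    strength = edge_map$strength[keep],
    orientation = edge_map$orientation[keep]
  )
}

shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' First- and second-order edge-orientation entropy
#'
#' Edges are detected with first-derivative-of-Gaussian filters at
#' `n_orientations` orientations on luminance; the `n_edges` strongest
#' non-overlapping edge pixels (greedy non-maximum suppression, 3-pixel
#' radius) are retained. The first-order entropy is the Shannon entropy of
#' the strength-weighted orientation histogram, normalized by
#' `log(n_orientations)`: 0 for a single dominant orientation, 1 when all
#' orientations carry equal edge energy. The second-order entropy looks at
#' pairwise statistics: edge pairs are grouped into log-spaced distance
#' bins and, within each bin, the entropy of the (strength-product-weighted)
#' histogram of absolute circular orientation differences is computed and
#' normalized; the result averages over non-empty distance bins. High values
#' mean edge orientations are unpredictable from one another across the
#' image, as in isotropic noise; low values indicate long-range orientation
#' order.
#'
#' When the number of pairs exceeds `max_pairs` a seeded uniform subsample
#' of pairs is used.
#'
#' @param img RGB array in `[0, 1]` (or grayscale matrix).
#' @param n_orientations Number of filter orientations (default 24).
#' @param n_edges Maximum edge pixels kept (default 10000).
#' @param n_dist_bins Log-spaced pair-distance bins (default 20).
#' @param max_pairs Cap on edge pairs evaluated (default 1e6).
#' @param pair_seed Seed for the pair subsample (default 1).
#' @param sigma Gaussian derivative scale in pixels (default 1.5).
#' @return A list with `entropy_first_order` and `entropy_second_order`,
#'   both in `[0, 1]`, plus `n_edges_used`.
#' @export
edge_orientation_entropies <- function(img, n_orientations = 24,
                                       n_edges = 10000, n_dist_bins = 20,
                                       max_pairs = 1e6, pair_seed = 1,
                                       sigma = 1.5) {
  lum <- if (length(dim(img)) == 3L) luminance(as_rgb_image(img)) else img
  if (diff(range(lum)) < .Machine$double.eps) {
    abort("constant image: no edges.", class = "sipstats_degenerate_input")
  }
  em <- oriented_edge_map(lum, n_orientations, sigma)
  edges <- select_edges(em, n_edges)
  m <- length(edges$row)
  if (m < n_orientations) {
    abort(sprintf("only %d edge pixels found (need >= %d).",
                  m, n_orientations),
          class = "sipstats_insufficient_edges")
  }
  # first order: strength-weighted orientation distribution
  w1 <- tapply(edges$strength,
               factor(edges$orientation, levels = seq_len(n_orientations)),
               sum, default = 0)
  e1 <- shannon_entropy(w1 / sum(w1)) / log(n_orientations)

  # second order: pairwise orientation differences by distance
  n_pairs_total <- m * (m - 1) / 2
  if (n_pairs_total <= max_pairs) {
    pr <- utils::combn(m, 2L)
    ii <- pr[1, ]; jj <- pr[2, ]
  } else {
    pick <- withr::with_seed(pair_seed, {
      a <- sample.int(m, max_pairs, replace = TRUE)
      b <- sample.int(m - 1L, max_pairs, replace = TRUE)
      b <- b + (b >= a)
      cbind(a, b)
    })
    ii <- pick[, 1]; jj <- pick[, 2]
  }
  d <- sqrt((edges$row[ii] - edges$row[jj])^2 +
            (edges$col[ii] - edges$col[jj])^2)
  diff_raw <- (edges$orientation[ii] - edges$orientation[jj]) %% n_orientations
  odiff <- pmin(diff_raw, n_orientations - diff_raw)   # 0 .. n/2
  wts <- edges$strength[ii] * edges$strength[jj]
  d_max <- sqrt((nrow(lum) - 1)^2 + (ncol(lum) - 1)^2)
  dedges <- exp(seq(log(1), log(d_max), length.out = n_dist_bins + 1))
  dbin <- findInterval(d, dedges, rightmost.closed = TRUE)
  dbin[dbin < 1] <- 1; dbin[dbin > n_dist_bins] <- n_dist_bins
  n_diff_bins <- floor(n_orientations / 2) + 1L
  ents <- vapply(seq_len(n_dist_bins), function(b) {
    sel <- dbin == b
    if (!any(sel)) return(NA_real_)
    hw <- tapply(wts[sel], factor(odiff[sel], levels = 0:(n_diff_bins - 1L)),
                 sum, default = 0)
    shannon_entropy(hw / sum(hw)) / log(n_diff_bins)
  }, numeric(1))
  list(
    entropy_first_order = unname(e1),
    entropy_second_order = mean(ents, na.rm = TRUE),
    n_edges_used = m
  )
}
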