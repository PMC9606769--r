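# Independent brute-force oracles: straightforward loop implementations,
# kept deliberately naive and separate from the package's vectorized /
# FFT-based code paths.

# --- random-phase construction: explicit loops over the frequency grid ---
oracle_gray_random_phase <- function(n, alpha, seed) {
  phi <- withr::with_seed(seed, matrix(runif(n * n, 0, 2 * pi), n, n))
  spec <- matrix(0+0i, n, n)
  for (j in seq_len(n)) {
    for (i in seq_len(n)) {
      i0 <- i - 1L; j0 <- j - 1L
      fx <- if (i0 > n / 2) i0 - n else i0
      fy <- if (j0 > n / 2) j0 - n else j0
      f <- sqrt(fx^2 + fy^2)
      amp <- if (f > 0) f^(alpha / 2) else 0
      pi0 <- (n - i0) %% n; pj0 <- (n - j0) %% n
      lin <- i0 + n * j0; lin_p <- pi0 + n * pj0
      ph <- if (lin == lin_p) 0
            else if (lin < lin_p) phi[i, j]
            else -phi[pi0 + 1, pj0 + 1]
      spec[i, j] <- amp * exp(1i * ph)
    }
  }
  img <- Re(fft(spec, inverse = TRUE)) / n^2
  r <- range(img)
  (img - r[1]) / (r[2] - r[1])
}

# --- direct circular convolution (flipped kernel, centered) -------------
oracle_conv_circular <- function(x, k) {
  h <- nrow(x); w <- ncol(x)
  kc <- (nrow(k) + 1) %/% 2
  out <- matrix(0, h, w)
  for (u in seq_len(nrow(k))) {
    for (v in seq_len(ncol(k))) {
      if (k[u, v] == 0) next
      ri <- ((seq_len(h) + kc - u - 1) %% h) + 1
      ci <- ((seq_len(w) + kc - v - 1) %% w) + 1
      out <- out + k[u, v] * x[ri, ci]
    }
  }
  out
}

# --- Lab gradient field by explicit per-pixel loops ---------------------
oracle_lab_255 <- function(img) {
  px <- cbind(as.numeric(img[, , 1]), as.numeric(img[, , 2]),
              as.numeric(img[, , 3]))
  lab <- grDevices::convertColor(px, from = "sRGB", to = "Lab")
  h <- dim(img)[1]; w <- dim(img)[2]
  list(matrix(lab[, 1] * 2.55, h, w), matrix(lab[, 2] + 128, h, w),
       matrix(lab[, 3] + 128, h, w))
}

oracle_gradient_field <- function(img) {
  chans <- oracle_lab_255(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  mag <- matrix(0, h, w); ori <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      best <- -1; best_o <- 0
      for (ch in chans) {
        jl <- max(1, j - 1); jr <- min(w, j + 1)
        iu <- max(1, i - 1); id <- min(h, i + 1)
        gx <- ch[i, jr] - ch[i, jl]
        gy <- ch[id, j] - ch[iu, j]
        m <- sqrt(gx^2 + gy^2)
        if (m > best) {
          best <- m
          best_o <- (atan2(gy, gx) * 180 / pi) %% 180
        }
      }
      mag[i, j] <- best; ori[i, j] <- best_o
    }
  }
  list(magnitude = mag, orientation = ori)
}

oracle_complexity <- function(img) mean(oracle_gradient_field(img)$magnitude)

# --- PHOG by loops ------------------------------------------------------
oracle_orientation_hist <- function(ori, mag, bins) {
  h <- rep(0, bins)
  for (t in seq_along(ori)) {
    b <- min(floor(ori[t] / (180 / bins)) + 1, bins)
    h[b] <- h[b] + mag[t]
  }
  h
}

oracle_phog <- function(img, levels = 3, bins = 16) {
  field <- oracle_gradient_field(img)
  g <- 2^levels
  h <- nrow(field$magnitude); w <- ncol(field$magnitude)
  norm1 <- function(x) if (sum(x) > 0) x / sum(x) else x
  global <- norm1(oracle_orientation_hist(field$orientation,
                                          field$magnitude, bins))
  rb <- floor((0:g) * h / g); cb <- floor((0:g) * w / g)
  sims <- c(); hists <- list()
  for (i in seq_len(g)) {
    for (j in seq_len(g)) {
      rows <- (rb[i] + 1):rb[i + 1]; cols <- (cb[j] + 1):cb[j + 1]
      hh <- oracle_orientation_hist(field$orientation[rows, cols],
                                    field$magnitude[rows, cols], bins)
      sims <- c(sims, if (sum(hh) > 0) sum(pmin(norm1(hh), global)) else 0)
      if (sum(hh) > 0) hists[[length(hists) + 1]] <- norm1(hh)
    }
  }
  mh <- Reduce(`+`, hists) / length(hists)
  list(self_similarity = median(sims),
       anisotropy = min(1, sd(mh) * sqrt(bins)),
       phog_complexity = min(1, mean(field$magnitude) / (2 * 255 * sqrt(2))))
}

oracle_half_similarity <- function(fa, fb, g, bins) {
  h <- nrow(fa$magnitude); w <- ncol(fa$magnitude)
  rb <- floor((0:g) * h / g); cb <- floor((0:g) * w / g)
  norm1 <- function(x) if (sum(x) > 0) x / sum(x) else x
  sims <- c()
  for (i in seq_len(g)) {
    for (j in seq_len(g)) {
      rows <- (rb[i] + 1):rb[i + 1]; cols <- (cb[j] + 1):cb[j + 1]
      ha <- oracle_orientation_hist(fa$orientation[rows, cols],
                                    fa$magnitude[rows, cols], bins)
      hb <- oracle_orientation_hist(fb$orientation[rows, cols],
                                    fb$magnitude[rows, cols], bins)
      sims <- c(sims,
                if (sum(ha) <= 0 && sum(hb) <= 0) 1
                else if (sum(ha) <= 0 || sum(hb) <= 0) 0
                else sum(pmin(norm1(ha), norm1(hb))))
    }
  }
  mean(sims)
}

oracle_symmetry <- function(img, bins = 16) {
  h <- dim(img)[1]; w <- dim(img)[2]
  hw <- w %/% 2; hh <- h %/% 2
  left <- img[, 1:hw, , drop = FALSE]
  right <- img[, w:(w - hw + 1), , drop = FALSE]
  top <- img[1:hh, , , drop = FALSE]
  bottom <- img[h:(h - hh + 1), , , drop = FALSE]
  lr <- oracle_half_similarity(oracle_gradient_field(left),
                               oracle_gradient_field(right), 4, bins)
  ud <- oracle_half_similarity(oracle_gradient_field(top),
                               oracle_gradient_field(bottom), 4, bins)
  mean(c(lr, ud))
}

# --- edge-orientation entropies by loops, full pair enumeration ---------
oracle_dog_kernel <- function(theta_deg, sigma) {
  r <- ceiling(3 * sigma)
  side <- 2 * r + 1
  k <- matrix(0, side, side)
  th <- theta_deg * pi / 180
  for (u in seq_len(side)) {
    for (v in seq_len(side)) {
      y <- u - r - 1; x <- v - r - 1
      k[u, v] <- -(x * cos(th) + y * sin(th)) / sigma^2 *
        exp(-(x^2 + y^2) / (2 * sigma^2))
    }
  }
  k <- k - mean(k)
  k / sqrt(sum(k^2))
}

oracle_edge_entropies <- function(img, n_orientations = 8, n_edges = 150,
                                  n_dist_bins = 20, sigma = 1.5) {
  lum <- 0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3]
  h <- nrow(lum); w <- ncol(lum)
  strength <- matrix(-Inf, h, w); orient <- matrix(1L, h, w)
  for (k in seq_len(n_orientations)) {
    resp <- abs(oracle_conv_circular(lum,
                                     oracle_dog_kernel((k - 1) * 180 /
                                                         n_orientations,
                                                       sigma)))
    upd <- resp > strength
    orient[upd] <- k; strength[upd] <- resp[upd]
  }
  m <- ceiling(3 * sigma)
  cand <- c()
  for (j in (m + 1):(w - m)) {
    for (i in (m + 1):(h - m)) {
      if (strength[i, j] > 0) cand <- c(cand, (j - 1) * h + i)
    }
  }
  ord <- order(strength[cand], -cand, decreasing = TRUE)
  cand <- cand[ord]
  keep <- integer(0)
  for (p in cand) {
    i <- (p - 1) %% h + 1; j <- (p - 1) %/% h + 1
    clash <- FALSE
    for (q in keep) {
      qi <- (q - 1) %% h + 1; qj <- (q - 1) %/% h + 1
      if (max(abs(qi - i), abs(qj - j)) <= 3) { clash <- TRUE; break }
    }
    if (!clash) keep <- c(keep, p)
    if (length(keep) >= n_edges) break
  }
  rows <- (keep - 1) %% h + 1; cols <- (keep - 1) %/% h + 1
  str <- strength[keep]; ori <- orient[keep]
  hist1 <- rep(0, n_orientations)
  for (t in seq_along(keep)) hist1[ori[t]] <- hist1[ori[t]] + str[t]
  p1 <- hist1 / sum(hist1)
  e1 <- -sum(p1[p1 > 0] * log(p1[p1 > 0])) / log(n_orientations)
  d_max <- sqrt((h - 1)^2 + (w - 1)^2)
  edges <- exp(seq(log(1), log(d_max), length.out = n_dist_bins + 1))
  n_diff <- floor(n_orientations / 2) + 1
  acc <- matrix(0, n_dist_bins, n_diff)
  mm <- length(keep)
  for (a in 1:(mm - 1)) {
    for (b in (a + 1):mm) {
      d <- sqrt((rows[a] - rows[b])^2 + (cols[a] - cols[b])^2)
      bin <- findInterval(d, edges, rightmost.closed = TRUE)
      bin <- min(max(bin, 1), n_dist_bins)
      dr <- (ori[a] - ori[b]) %% n_orientations
      dd <- min(dr, n_orientations - dr)
      acc[bin, dd + 1] <- acc[bin, dd + 1] + str[a] * str[b]
    }
  }
  ents <- c()
  for (bin in seq_len(n_dist_bins)) {
    tot <- sum(acc[bin, ])
    if (tot == 0) next
    p <- acc[bin, ] / tot
    ents <- c(ents, -sum(p[p > 0] * log(p[p > 0])) / log(n_diff))
  }
  list(entropy_first_order = e1, entropy_second_order = mean(ents),
       n_edges_used = mm)
}

# --- filter variances by direct convolution and loop pooling ------------
oracle_filter_variance <- function(img, bank, k) {
  pooled <- list()
  for (f in bank) {
    combined <- f$weights[1] * img[, , 1] + f$weights[2] * img[, , 2] +
      f$weights[3] * img[, , 3]
    resp <- abs(oracle_conv_circular(combined, f$kernel))
    h <- nrow(resp); w <- ncol(resp)
    rb <- floor((0:k) * h / k); cb <- floor((0:k) * w / k)
    pm <- matrix(0, k, k)
    for (i in seq_len(k)) {
      for (j in seq_len(k)) {
        pm[i, j] <- max(resp[(rb[i] + 1):rb[i + 1], (cb[j] + 1):cb[j + 1]])
      }
    }
    pooled[[length(pooled) + 1]] <- pm
  }
  pf <- sapply(pooled, function(p) var(as.numeric(p)))
  list(variance_Pa = var(unlist(pooled)), variance_Pf = median(pf))
}

# --- color statistics by explicit histogram loops -----------------------
oracle_color_statistics <- function(img) {
  px <- cbind(as.numeric(img[, , 1]), as.numeric(img[, , 2]),
              as.numeric(img[, , 3]))
  lab <- grDevices::convertColor(px, from = "sRGB", to = "Lab")
  hsv <- t(grDevices::rgb2hsv(t(px), maxColorValue = 1))
  ent <- function(v) {
    counts <- rep(0, 256)
    for (t in seq_along(v)) {
      b <- min(floor(v[t] * 256) + 1, 256)
      counts[b] <- counts[b] + 1
    }
    p <- counts / sum(counts)
    -sum(p[p > 0] * log2(p[p > 0]))
  }
  ang <- hsv[, 1] * 2 * pi
  list(
    lab_L_mean = mean(lab[, 1]), lab_a_mean = mean(lab[, 2]),
    lab_b_mean = mean(lab[, 3]),
    hsv_H_mean = (atan2(mean(sin(ang)), mean(cos(ang))) * 180 / pi) %% 360,
    hsv_S_mean = mean(hsv[, 2]), hsv_V_mean = mean(hsv[, 3]),
    entropy_hsv_H = ent(hsv[, 1]), entropy_hsv_S = ent(hsv[, 2]),
    entropy_hsv_V = ent(hsv[, 3])
  )
}

# --- spectral slope fit from a hand-binned power table ------------------
oracle_slope_fit <- function(img, f_min, f_max, n_bins = 30) {
  lum <- if (length(dim(img)) == 3)
    0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3]
  else img
  n <- nrow(lum)
  pw <- Mod(fft(lum))^2
  edges <- exp(seq(log(f_min), log(f_max), length.out = n_bins + 1))
  sum_lf <- rep(0, n_bins); sum_p <- rep(0, n_bins); cnt <- rep(0, n_bins)
  for (j in seq_len(n)) {
    for (i in seq_len(n)) {
      fx <- if ((i - 1) > n / 2) (i - 1) - n else (i - 1)
      fy <- if ((j - 1) > n / 2) (j - 1) - n else (j - 1)
      f <- sqrt(fx^2 + fy^2)
      if (f < f_min || f > f_max) next
      b <- findInterval(f, edges, rightmost.closed = TRUE)
      b <- min(max(b, 1), n_bins)
      sum_lf[b] <- sum_lf[b] + log(f)
      sum_p[b] <- sum_p[b] + pw[i, j]
      cnt[b] <- cnt[b] + 1
    }
  }
  use <- cnt > 0 & sum_p > 0
  x <- sum_lf[use] / cnt[use]
  y <- log(sum_p[use] / cnt[use])
  # closed-form least squares
  mx <- mean(x); my <- mean(y)
  slope <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  list(slope = slope, intercept = my - slope * mx)
}

# --- best-subset oracle: lm() on every subset ---------------------------
oracle_best_subsets <- function(X, y, n_best, size_cap) {
  X <- as.matrix(X)
  p <- ncol(X); n <- nrow(X)
  vn <- colnames(X)
  out <- list()
  for (s in seq_len(size_cap)) {
    subs <- utils::combn(p, s, simplify = FALSE)
    r2a <- sapply(subs, function(idx) {
      fit <- lm(y ~ X[, idx, drop = FALSE])
      sm <- suppressWarnings(summary(fit))
      1 - (1 - sm$r.squared) * (n - 1) / (n - s - 1)
    })
    ord <- order(r2a, decreasing = TRUE)[seq_len(min(n_best, length(subs)))]
    out[[s]] <- lapply(ord, function(i) sort(vn[subs[[i]]]))
  }
  out
}
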