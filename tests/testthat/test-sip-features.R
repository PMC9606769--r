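cfg64 <- sip_config(resolution = 64, n_edges = 500, max_pairs = 2e5)

test_that("constant images give the degenerate SIP pattern", {
  flat <- array(0.5, dim = c(64, 64, 3))
  v <- compute_sip_vector(flat, cfg64)
  expect_equal(v$complexity, 0)
  expect_equal(v$hsv_S_mean, 0)
  expect_equal(v$entropy_hsv_S, 0)
  expect_equal(v$lab_b_mean, 0, tolerance = 1e-8)
  expect_lt(abs(v$variance_Pa_2), 1e-20)
  expect_lt(abs(v$variance_Pf_30), 1e-20)
  expect_true(is.na(v$self_similarity))
  expect_true(is.na(v$fourier_slope))
  expect_error(phog_features(flat), class = "sipstats_degenerate_input")
  expect_error(edge_orientation_entropies(flat),
               class = "sipstats_degenerate_input")
})

test_that("a seamless tiling has self-similarity 1", {
  img <- make_tiled_texture(128, cell_side = 16)
  ph <- phog_features(img, levels = 3, bins = 16)
  expect_equal(ph$self_similarity, 1, tolerance = 1e-9)
})

test_that("a single-orientation grating maximizes anisotropy and kills first-order entropy", {
  img <- make_grating(128, period = 16)
  ph <- phog_features(img)
  expect_equal(ph$anisotropy, 1, tolerance = 1e-9)
  ent <- edge_orientation_entropies(img, n_orientations = 24,
                                    n_edges = 300)
  expect_lt(ent$entropy_first_order, 0.05)
  iso <- random_colored_image(128, -2, seed = 3)
  expect_gt(edge_orientation_entropies(iso, n_edges = 300)$entropy_first_order,
            0.95)
})

test_that("finer texture at the same contrast is more complex", {
  fine <- make_checkerboard(64, period = 2)
  coarse <- make_checkerboard(64, period = 16)
  expect_gt(gradient_complexity(fine), gradient_complexity(coarse))
})

test_that("step-edge complexity matches the explicit-loop oracle", {
  img <- make_step_image(64)
  expect_equal(gradient_complexity(img), oracle_complexity(img),
               tolerance = 1e-10)
})

test_that("mirror symmetry components behave under mirroring and rotation", {
  base <- random_colored_image(64, -2, seed = 13)
  sym <- base
  sym[, 33:64, ] <- mirror_lr(base)[, 33:64, ]   # force exact lr symmetry
  s <- mirror_symmetry_lrud(sym)
  expect_equal(unname(attr(s, "components")["lr"]), 1, tolerance = 1e-12)
  rot <- rotate90(sym)
  s_rot <- mirror_symmetry_lrud(rot)
  expect_equal(unname(attr(s_rot, "components")["ud"]),
               unname(attr(s, "components")["lr"]), tolerance = 1e-9)
})

test_that("color statistics hit the closed-form cases", {
  red <- array(0, dim = c(64, 64, 3)); red[, , 1] <- 1
  cs <- color_statistics(red)
  expect_equal(cs$hsv_S_mean, 1)
  expect_equal(cs$entropy_hsv_H, 0)
  expect_equal(cs$hsv_H_mean, 0)

  two <- array(0, dim = c(64, 64, 3))
  two[, 1:32, 3] <- 1                       # blue half
  two[, 33:64, 1] <- 1; two[, 33:64, 2] <- 1  # yellow half
  expect_equal(color_statistics(two)$entropy_hsv_H, 1)

  gray <- array(0.7, dim = c(64, 64, 3))
  cg <- color_statistics(gray)
  expect_equal(cg$lab_a_mean, 0, tolerance = 1e-8)
  expect_equal(cg$lab_b_mean, 0, tolerance = 1e-8)
  expect_equal(cg$hsv_S_mean, 0)
  expect_equal(cg$entropy_hsv_S, 0)
})

test_that("hue mean is circular", {
  # hues at 350 and 10 degrees average to 0, not 180
  img <- array(0, dim = c(64, 64, 3))
  left <- grDevices::col2rgb(grDevices::hsv(350 / 360, 1, 1)) / 255
  right <- grDevices::col2rgb(grDevices::hsv(10 / 360, 1, 1)) / 255
  for (ch in 1:3) {
    img[, 1:32, ch] <- left[ch]
    img[, 33:64, ch] <- right[ch]
  }
  hm <- color_statistics(img)$hsv_H_mean
  expect_true(hm < 1 || hm > 359)
})

test_that("the default filter bank is zero-mean, unit-norm, and pluggable", {
  bank <- default_filter_bank()
  expect_length(bank, 50)
  expect_silent(validate_filter_bank(bank))
  flat_red <- array(0, dim = c(64, 64, 3)); flat_red[, , 1] <- 0.8
  fv <- filter_variance_features(flat_red, bank, k = 2)
  expect_lt(abs(fv$variance_Pa), 1e-20)
  expect_lt(abs(fv$variance_Pf), 1e-20)
  expect_error(filter_variance_features(random_colored_image(64), bank,
                                        k = 100),
               class = "sipstats_grid_error")
})

test_that("filter bank round-trips through the CSV dump format", {
  bank <- default_filter_bank(orientations = 2, scales = 1.5)
  rows <- do.call(rbind, lapply(seq_along(bank), function(i) {
    k <- bank[[i]]$kernel
    data.frame(filter = i, row = as.vector(row(k)),
               col = as.vector(col(k)), value = as.vector(k),
               w_r = bank[[i]]$weights[1], w_g = bank[[i]]$weights[2],
               w_b = bank[[i]]$weights[3])
  }))
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(rows, f, row.names = FALSE)
  bank2 <- import_filter_bank(f)
  expect_length(bank2, length(bank))
  expect_equal(bank2[[1]]$kernel, bank[[1]]$kernel, tolerance = 1e-12)
})

test_that("toy filter variance equals a hand-unrolled computation", {
  img <- random_colored_image(64, -2, seed = 31)[1:16, 1:16, , drop = FALSE]
  k1 <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  k2 <- matrix(c(-1, 0, 1, -1, 0, 1, -1, 0, 1), 3, 3)
  bank <- structure(list(
    list(kernel = k1 / sqrt(sum(k1^2)), weights = c(1, 0, 0)),
    list(kernel = (k2 - mean(k2)) / sqrt(sum((k2 - mean(k2))^2)),
         weights = c(0, 1, 0))
  ), class = "filter_bank")
  impl <- filter_variance_features(img, bank, k = 2)
  orc <- oracle_filter_variance(img, bank, k = 2)
  expect_equal(impl$variance_Pa, orc$variance_Pa, tolerance = 1e-10)
  expect_equal(impl$variance_Pf, orc$variance_Pf, tolerance = 1e-10)
})

test_that("pooled variances at neighboring grids are rank-consistent", {
  sips <- purrr::map_dfr(1:40, function(i) {
    img <- random_colored_image(64, sample(seq(-5, 0, 0.5), 1),
                                seed = 400 + i)
    fv2 <- filter_variance_features(img, k = 2)
    fv4 <- filter_variance_features(img, k = 4)
    tibble::tibble(pa2 = fv2$variance_Pa, pa4 = fv4$variance_Pa)
  })
  expect_gt(cor(sips$pa2, sips$pa4, method = "spearman"), 0.7)
})

test_that("SIPs are invariant to pre-resizing and lossless re-encoding", {
  img <- quantize8(random_colored_image(128, -2, seed = 17))
  pre <- sipstats:::resize_rgb(img, 64)
  v1 <- compute_sip_vector(img, cfg64)
  v2 <- compute_sip_vector(pre, cfg64)
  expect_equal(v1, v2, tolerance = 1e-12)

  f <- withr::local_tempfile(fileext = ".png")
  write_image(img, f)
  v3 <- compute_sip_vector(png::readPNG(f), cfg64)
  expect_equal(v1, v3, tolerance = 1e-12)
})

test_that("second-order entropy pair subsampling agrees with full enumeration", {
  img <- random_colored_image(128, -2, seed = 23)
  full <- edge_orientation_entropies(img, n_orientations = 8,
                                     n_edges = 2000, max_pairs = 1e7)
  sub <- edge_orientation_entropies(img, n_orientations = 8,
                                    n_edges = 2000, max_pairs = 5e4,
                                    pair_seed = 5)
  expect_lt(abs(full$entropy_second_order - sub$entropy_second_order),
            0.02)
})
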