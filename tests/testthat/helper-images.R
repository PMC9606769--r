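# Deterministic test images, built in code.

make_checkerboard <- function(n, period) {
  idx <- 0:(n - 1)
  m <- outer(idx %/% period, idx %/% period, function(a, b) (a + b) %% 2)
  array(rep(m, 3), dim = c(n, n, 3))
}

make_grating <- function(n, period, vertical = TRUE) {
  v <- 0.5 + 0.5 * sin(2 * pi * (0:(n - 1)) / period)
  m <- if (vertical) matrix(v, n, n, byrow = TRUE) else matrix(v, n, n)
  array(rep(m, 3), dim = c(n, n, 3))
}

# Texture cell with a constant border so tiling is seamless under
# replicate-padded gradients; tiled to fill an n x n image.
make_tiled_texture <- function(n, cell_side = 16, seed = 42) {
  cell <- withr::with_seed(seed, {
    m <- matrix(0.5, cell_side, cell_side)
    interior <- 2:(cell_side - 1)
    m[interior, interior] <- runif(length(interior)^2)
    m
  })
  reps <- n / cell_side
  m <- cell[rep(seq_len(cell_side), reps), rep(seq_len(cell_side), reps)]
  array(rep(m, 3), dim = c(n, n, 3))
}

make_step_image <- function(n, level_left = 0.2, level_right = 0.8) {
  m <- matrix(level_left, n, n)
  m[, (n %/% 2 + 1):n] <- level_right
  img <- array(0.5, dim = c(n, n, 3))
  img[, , 1] <- m
  img
}

mirror_lr <- function(img) img[, dim(img)[2]:1, , drop = FALSE]

# rotate each channel 90 degrees clockwise
rotate90 <- function(img) {
  out <- array(0, dim = c(dim(img)[2], dim(img)[1], 3))
  for (ch in 1:3) out[, , ch] <- t(img[dim(img)[1]:1, , ch])
  out
}

quantize8 <- function(img) round(img * 255) / 255

random_colored_image <- function(n = 64, slope = -2, seed = 7) {
  synthesize_colored_random_phase(random_phase_spec(n, slope, seed))
}
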