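test_that("spearman matrix hits the rank-correlation identities", {
  d <- tibble::tibble(x = 1:5, y = 5:1, z = exp(1:5))
  sm <- spearman_matrix(d)
  expect_equal(sm$rho["x", "y"], -1)
  expect_equal(sm$rho["x", "z"], 1)      # monotone transform
  expect_equal(sm$rho, t(sm$rho))
  expect_equal(unname(diag(sm$rho)), rep(1, 3))
})

test_that("spearman with ties matches hand-computed average ranks", {
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(2, 2, 3, 5, 4, 6)
  sm <- spearman_matrix(tibble::tibble(x = x, y = y))
  rx <- rank(x); ry <- c(1.5, 1.5, 3, 5, 4, 6)  # hand ranks
  hand <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(sm$rho["x", "y"], hand, tolerance = 1e-12)
})

test_that("constant columns are flagged NA, not zero", {
  d <- tibble::tibble(x = 1:6, k = rep(2, 6))
  expect_warning(sm <- spearman_matrix(d), "constant")
  expect_true(is.na(sm$rho["x", "k"]))
})

test_that("an exact predictor wins the size-1 search with adjusted R2 of 1", {
  set.seed(1)
  X <- matrix(rnorm(60 * 5), 60, dimnames = list(NULL, paste0("x", 1:5)))
  res <- best_subset_search(X, X[, 3])
  top1 <- res$by_size[res$by_size$size == 1 & res$by_size$rank == 1, ]
  expect_equal(top1$members[[1]], "x3")
  expect_equal(top1$r_squared_adj, 1)
})

test_that("retained lists match the lm-oracle enumeration (p = 8)", {
  set.seed(42)
  p <- 8; n <- 60
  X <- matrix(rnorm(n * p), n, dimnames = list(NULL, paste0("x", 1:p)))
  y <- X %*% rnorm(p) + rnorm(n)
  res <- best_subset_search(X, y, n_best = 10)
  orc <- oracle_best_subsets(X, y, n_best = 10, size_cap = p)
  for (s in 1:p) {
    got <- lapply(res$by_size$members[res$by_size$size == s], sort)
    expect_equal(got, orc[[s]], info = paste("size", s))
    expect_equal(length(got), min(10, choose(p, s)))
  }
})

test_that("branch-and-bound returns the exhaustive lists", {
  set.seed(7)
  p <- 9; n <- 50
  X <- matrix(rnorm(n * p), n, dimnames = list(NULL, paste0("x", 1:p)))
  y <- X %*% c(2, -1, rep(0, p - 2)) + rnorm(n)
  exh <- best_subset_search(X, y, n_best = 5)
  bb <- best_subset_search(X, y, n_best = 5, enumeration_cap = 1)
  expect_equal(lapply(bb$by_size$members, sort),
               lapply(exh$by_size$members, sort))
  expect_equal(bb$by_size$r_squared_adj, exh$by_size$r_squared_adj,
               tolerance = 1e-12)
})

test_that("search is invariant to column order and affine predictor scaling", {
  set.seed(3)
  X <- matrix(rnorm(50 * 6), 50, dimnames = list(NULL, paste0("x", 1:6)))
  y <- X %*% c(1, 0, -1, 0, 0.5, 0) + rnorm(50, sd = 0.5)
  base <- best_subset_search(X, y, n_best = 3)
  Xs <- sweep(sweep(X, 2, c(2, 0.1, 5, 1, 3, 0.5), "*"), 2,
              c(-1, 4, 0, 2, 2, 7), "+")
  scaled <- best_subset_search(Xs, y, n_best = 3)
  perm <- sample(6)
  reordered <- best_subset_search(X[, perm], y, n_best = 3)
  canon <- function(r) lapply(r$by_size$members, sort)
  expect_equal(canon(scaled), canon(base))
  expect_equal(canon(reordered), canon(base))
})

test_that("robustness counting and the 12-variable cut are reproducible", {
  set.seed(9)
  X <- matrix(rnorm(80 * 6), 80, dimnames = list(NULL, paste0("x", 1:6)))
  y1 <- X[, 1] + rnorm(80, sd = 0.1)
  y2 <- X[, 2] + rnorm(80, sd = 0.1)
  r1 <- best_subset_search(X, y1, n_best = 3, size_cap = 3)
  r2 <- best_subset_search(X, y2, n_best = 3, size_cap = 3)
  rc <- robustness_counts(r1, r2)
  expect_setequal(rc$variable, colnames(X))
  expect_equal(sum(rc$count), 2 * sum(3 * (1:3)))  # 3 models per size 1..3
  expect_true(all(c("x1", "x2") %in% head(rc$variable, 2)))
  expect_equal(select_robust_variables(r1, r2, n_keep = 2),
               head(rc$variable, 2))
})

test_that("pruning removes duplicates and planted near-duplicates", {
  set.seed(11)
  n <- 100
  base <- matrix(rnorm(n * 8), n, dimnames = list(NULL, paste0("v", 1:8)))
  d <- tibble::as_tibble(base)
  for (j in 1:4) {
    d[[paste0("dup", j)]] <- base[, j] + rnorm(n, sd = 0.05)
  }
  robust <- setNames(c(rep(10, 8), rep(1, 4)), names(d))
  pr <- prune_collinear(d, names(d), threshold = 0.6, robustness = robust)
  expect_setequal(pr$keep, paste0("v", 1:8))
  expect_equal(nrow(pr$dropped), 4)
  rho <- suppressWarnings(spearman_matrix(d, vars = pr$keep)$rho)
  diag(rho) <- 0
  expect_true(max(abs(rho)) <= 0.6)
})

test_that("pruning is the identity below threshold and rejects empty input", {
  set.seed(13)
  d <- tibble::as_tibble(matrix(rnorm(300), 100,
                                dimnames = list(NULL, c("a", "b", "c"))))
  pr <- prune_collinear(d, c("a", "b", "c"))
  expect_equal(pr$keep, c("a", "b", "c"))
  expect_equal(nrow(pr$dropped), 0)
  expect_error(prune_collinear(d, character(0)),
               class = "sipstats_argument_error")
  d2 <- d; d2$a2 <- d$a
  pr2 <- prune_collinear(d2, c("a", "a2"))
  expect_length(pr2$keep, 1)
})

test_that("the PCA reference model recovers a first-component response", {
  set.seed(17)
  n <- 120
  scores <- rnorm(n, sd = 4)
  load <- runif(10, -1, 1)
  X <- outer(scores, load) + matrix(rnorm(n * 10, sd = 0.05), n)
  colnames(X) <- paste0("s", 1:10)
  y <- 2 * scores + rnorm(n, sd = 0.01)
  pm <- pca_reference_model(tibble::as_tibble(X), y, n_components = 3)
  expect_gt(pm$r_squared_adj, 0.99)
  off_diag <- pm$component_r[upper.tri(pm$component_r)]
  expect_true(all(abs(off_diag) < 1e-10))
  expect_warning(pca_reference_model(tibble::as_tibble(X[, 1:3]), y,
                                     n_components = 5),
                 "reduced")
})
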