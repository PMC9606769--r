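# Variable-reduction machinery: Spearman correlation matrices, exhaustive /
# branch-and-bound best-subset regression ranked by adjusted R^2, robustness
# counting, and collinearity pruning.

#' Spearman correlation matrix with p-values
#'
#' Rank-based correlations (average ranks on ties) between all numeric
#' columns, with two-sided p-values. Rank correlation is preferred here
#' because many SIPs are far from normally distributed. Constant columns
#' have undefined correlations and are reported as `NA` with a warning,
#' never as 0.
#'
#' @param data A data frame; non-numeric columns are dropped.
#' @param vars Optional character vector restricting the columns.
#' @return An object of class `sip_correlation`: list with `rho` and
#'   `p_value` matrices.
#' @export
spearman_matrix <- function(data, vars = NULL) {
  num <- dplyr::select(as_tibble(data), dplyr::where(is.numeric))
  if (!is.null(vars)) num <- dplyr::select(num, dplyr::all_of(vars))
  num <- num[complete.cases(num), , drop = FALSE]
  if (nrow(num) < 3) {
    abort("need at least 3 complete rows.", class = "sipstats_argument_error")
  }
  p <- ncol(num)
  constant <- vapply(num, function(v) diff(range(v)) == 0, logical(1))
  if (any(constant)) {
    warn(paste0("constant column(s), correlation undefined: ",
                paste(names(num)[constant], collapse = ", ")))
  }
  rho <- matrix(NA_real_, p, p, dimnames = list(names(num), names(num)))
  pval <- rho
  diag(rho) <- 1
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (j <= i || constant[i] || constant[j]) next
      ct <- suppressWarnings(
        cor.test(num[[i]], num[[j]], method = "spearman", exact = FALSE))
      rho[i, j] <- rho[j, i] <- unname(ct$estimate)
      pval[i, j] <- pval[j, i] <- ct$p.value
    }
  }
  structure(list(rho = rho, p_value = pval, n = nrow(num)),
            class = "sip_correlation")
}

#' @export
print.sip_correlation <- function(x, ...) {
  cat(sprintf("<sip_correlation> %d variables, n = %d\n",
              ncol(x$rho), x$n))
  print(round(x$rho, 2))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.sip_correlation <- function(x, ...) {
  nm <- colnames(x$rho)
  pairs <- which(upper.tri(x$rho), arr.ind = TRUE)
  tibble(
    var1 = nm[pairs[, 1]], var2 = nm[pairs[, 2]],
    rho = x$rho[pairs], p_value = x$p_value[pairs]
  )
}

# Residual sum of squares of y on the centered predictor subset, from the
# joint cross-product matrix (predictors 1..p, response p+1).
subset_rss <- function(S, idx) {
  p1 <- ncol(S)
  if (length(idx) == 0L) return(S[p1, p1])
  ch <- tryCatch(chol(S[idx, idx, drop = FALSE]), error = function(e) NULL)
  if (is.null(ch)) return(NA_real_)
  z <- backsolve(ch, forwardsolve(t(ch), S[idx, p1]))
  max(S[p1, p1] - sum(S[idx, p1] * z), 0)
}

adj_r2 <- function(r2, n, s) 1 - (1 - r2) * (n - 1) / (n - s - 1)

# Depth-first branch and bound for the n_best lowest-RSS subsets of size s.
# Bound: RSS never increases when variables are added, so a partial subset
# whose full completion already exceeds the current n_best-th RSS cannot
# lead to a retained model.
bb_search_size <- function(S, p, s, n_best) {
  best <- list()          # list of list(idx, rss), kept sorted by rss
  worst <- Inf
  push <- function(idx, rss) {
    best[[length(best) + 1L]] <<- list(idx = idx, rss = rss)
    o <- order(vapply(best, `[[`, numeric(1), "rss"))
    best <<- best[o][seq_len(min(n_best, length(best)))]
    worst <<- if (length(best) < n_best) Inf
              else best[[length(best)]]$rss
  }
  recurse <- function(chosen, next_var) {
    remaining <- p - next_var + 1L
    need <- s - length(chosen)
    if (need == 0L) {
      rss <- subset_rss(S, chosen)
      if (!is.na(rss) && rss < worst) push(chosen, rss)
      return(invisible())
    }
    if (remaining < need) return(invisible())
    full_rss <- subset_rss(S, c(chosen, next_var:p))
    if (!is.na(full_rss) && full_rss >= worst) return(invisible())
    recurse(c(chosen, next_var), next_var + 1L)
    recurse(chosen, next_var + 1L)
  }
  recurse(integer(0), 1L)
  best
}

#' Exhaustive best-subset regression search
#'
#' For every model size `s` up to `size_cap`, finds the `n_best` predictor
#' subsets with the highest adjusted R^2 (equivalently, lowest residual sum
#' of squares within a size). Subsets are enumerated exhaustively while the
#' number of candidate models is below `enumeration_cap`; larger problems
#' use a branch-and-bound on RSS that returns the identical retained lists.
#' Per-variable robustness counts (number of appearances across all
#' retained models) summarize which predictors survive across model sizes.
#'
#' Rank-deficient candidate subsets are skipped with a warning.
#'
#' @param X Data frame or matrix of predictors.
#' @param y Numeric response.
#' @param n_best Models retained per size (default 10).
#' @param size_cap Largest model size searched (default all predictors).
#' @param enumeration_cap Exhaustive-enumeration limit per size
#'   (default 2e6).
#' @return An object of class `subset_search`; see [tidy.subset_search()].
#' @export
best_subset_search <- function(X, y, n_best = 10, size_cap = ncol(X),
                               enumeration_cap = 2e6) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  stopifnot(is.numeric(y), nrow(X) == length(y))
  p <- ncol(X); n <- nrow(X)
  size_cap <- min(size_cap, p)
  if (n <= size_cap + 2) {
    abort("need n > size_cap + 2 rows.", class = "sipstats_argument_error")
  }
  var_names <- colnames(X) %||% paste0("x", seq_len(p))
  Z <- cbind(scale(X, scale = FALSE), y - mean(y))
  S <- crossprod(Z)
  tss <- S[p + 1, p + 1]
  skipped <- 0L

  rows <- list()
  for (s in seq_len(size_cap)) {
    n_models <- choose(p, s)
    if (n_models <= enumeration_cap) {
      subs <- combn(p, s, simplify = FALSE)
      rss <- vapply(subs, function(idx) subset_rss(S, idx), numeric(1))
      skipped <- skipped + sum(is.na(rss))
      ok <- which(!is.na(rss))
      ord <- ok[order(rss[ok])][seq_len(min(n_best, length(ok)))]
      kept <- lapply(ord, function(i) list(idx = subs[[i]], rss = rss[i]))
    } else {
      kept <- bb_search_size(S, p, s, n_best)
    }
    for (r in seq_along(kept)) {
      r2 <- 1 - kept[[r]]$rss / tss
      rows[[length(rows) + 1L]] <- tibble(
        size = s, rank = r,
        members = list(var_names[kept[[r]]$idx]),
        r_squared = r2,
        r_squared_adj = adj_r2(r2, n, s)
      )
    }
  }
  if (skipped > 0L) {
    warn(sprintf("%d rank-deficient candidate subset(s) skipped.", skipped))
  }
  by_size <- dplyr::bind_rows(rows)
  counts <- table(factor(unlist(by_size$members), levels = var_names))
  structure(
    list(by_size = by_size,
         robustness = setNames(as.integer(counts), var_names),
         n = n, p = p, var_names = var_names),
    class = "subset_search"
  )
}

#' @export
print.subset_search <- function(x, ...) {
  cat(sprintf("<subset_search> p = %d predictors, n = %d rows, %d retained models\n",
              x$p, x$n, nrow(x$by_size)))
  top <- dplyr::slice_max(x$by_size, .data$r_squared_adj, n = 1,
                          with_ties = FALSE)
  cat(sprintf("best model (size %d): {%s}, adj R^2 = %.3f\n", top$size,
              paste(top$members[[1]], collapse = ", "), top$r_squared_adj))
  invisible(x)
}

#' Tidy a subset-search result
#'
#' @param x A `subset_search` object.
#' @param ... Unused.
#' @return A tibble with one row per retained model: `size`, `rank`,
#'   `members` (list column), `r_squared`, `r_squared_adj`.
#' @exportS3Method generics::tidy
tidy.subset_search <- function(x, ...) x$by_size

#' Robustness counts across one or several subset searches
#'
#' Appearance counts of each variable over all retained models, summed
#' across searches (e.g. one search per rating dimension).
#'
#' @param ... `subset_search` objects.
#' @return A tibble `variable`, `count`, `best_adj_r2` sorted by count.
#' @export
robustness_counts <- function(...) {
  results <- list(...)
  stopifnot(all(vapply(results, inherits, logical(1), "subset_search")))
  all_models <- dplyr::bind_rows(lapply(results, `[[`, "by_size"))
  vars <- unique(unlist(lapply(results, `[[`, "var_names")))
  long <- tidyr::unnest(all_models, "members")
  agg <- dplyr::summarise(
    dplyr::group_by(long, variable = .data$members),
    count = dplyr::n(), best_adj_r2 = max(.data$r_squared_adj),
    .groups = "drop")
  missing <- setdiff(vars, agg$variable)
  if (length(missing)) {
    agg <- dplyr::bind_rows(agg, tibble(variable = missing, count = 0L,
                                        best_adj_r2 = NA_real_))
  }
  dplyr::arrange(agg, dplyr::desc(.data$count),
                 dplyr::desc(.data$best_adj_r2), .data$variable)
}

#' Select the most robust predictors
#'
#' Operationalizes "predicts the ratings most robustly across models" as
#' the total appearance count over all retained models of all searches,
#' with ties broken by the best single-model adjusted R^2, then
#' alphabetically.
#'
#' @param ... `subset_search` objects (typically one per rating dimension).
#' @param n_keep Number of variables to keep (default 12).
#' @return Character vector of variable names.
#' @export
select_robust_variables <- function(..., n_keep = 12) {
  rc <- robustness_counts(...)
  head(rc$variable, n_keep)
}

#' Prune collinear variables
#'
#' Repeatedly inspects the candidate pair with the largest absolute
#' Spearman correlation above `threshold` and drops the member with the
#' lower robustness count; ties are broken by the weaker maximum
#' correlation with the response, then alphabetically (the later name is
#' dropped). Stops when no pair exceeds the threshold, so the survivors
#' are guaranteed mutually below it.
#'
#' @param data Data frame containing the candidate columns (and the
#'   response if used for tie-breaks).
#' @param candidates Character vector of candidate variable names.
#' @param threshold Absolute Spearman correlation above which a pair is
#'   considered collinear (default 0.6).
#' @param robustness Optional named counts from [robustness_counts()].
#' @param response Optional response column name for tie-breaking.
#' @return A list: `keep` (surviving names) and `dropped` (audit tibble
#'   with the offending pair, its correlation, and the drop reason).
#' @export
prune_collinear <- function(data, candidates, threshold = 0.6,
                            robustness = NULL, response = NULL) {
  if (length(candidates) == 0L) {
    abort("empty candidate list.", class = "sipstats_argument_error")
  }
  stopifnot(all(candidates %in% names(data)))
  get_count <- function(v) {
    if (is.null(robustness)) return(0)
    cnt <- unname(robustness[v])
    if (length(cnt) != 1L || is.na(cnt)) 0 else cnt
  }
  resp_cor <- function(v) {
    if (is.null(response)) return(0)
    abs(suppressWarnings(cor(rank(data[[v]]), rank(data[[response]]))))
  }
  keep <- candidates
  dropped <- list()
  repeat {
    if (length(keep) < 2L) break
    rho <- suppressWarnings(spearman_matrix(data, vars = keep)$rho)
    arho <- abs(rho); diag(arho) <- 0
    if (all(is.na(arho)) || max(arho, na.rm = TRUE) <= threshold) break
    worst <- which(arho == max(arho, na.rm = TRUE), arr.ind = TRUE)[1, ]
    a <- keep[worst[1]]; b <- keep[worst[2]]
    ca <- get_count(a); cb <- get_count(b)
    if (ca != cb) {
      drop <- if (ca < cb) a else b
      reason <- "lower robustness count"
    } else if (resp_cor(a) != resp_cor(b)) {
      drop <- if (resp_cor(a) < resp_cor(b)) a else b
      reason <- "weaker response correlation"
    } else {
      drop <- max(a, b)
      reason <- "alphabetical tie-break"
    }
    dropped[[length(dropped) + 1L]] <- tibble(
      dropped = drop, partner = setdiff(c(a, b), drop),
      rho = rho[worst[1], worst[2]], reason = reason)
    keep <- setdiff(keep, drop)
  }
  list(keep = keep, dropped = dplyr::bind_rows(dropped))
}

#' Principal-component reference model
#'
#' Benchmarks a reduced-variable model against the information ceiling of
#' the full SIP set: columns are standardized, projected onto the leading
#' principal components, and the response is regressed on the component
#' scores. Comparable adjusted R^2 between this model and a small SIP
#' subset indicates little predictive power was lost in the reduction.
#'
#' @param data Data frame of predictor columns (e.g. the full SIP set).
#' @param y Numeric response.
#' @param n_components Number of leading components (default 8); reduced
#'   automatically (with a warning) if it exceeds the rank.
#' @return A list of class `pca_model`: `n_components`, `r_squared`,
#'   `r_squared_adj`, `component_r` (score cross-correlations), `fit`.
#' @export
pca_reference_model <- function(data, y, n_components = 8) {
  num <- dplyr::select(as_tibble(data), dplyr::where(is.numeric))
  keep <- vapply(num, function(v) diff(range(v)) > 0, logical(1))
  num <- num[, keep, drop = FALSE]
  if (ncol(num) < 1) {
    abort("no non-constant predictor columns.",
          class = "sipstats_argument_error")
  }
  pc <- prcomp(as.matrix(num), center = TRUE, scale. = TRUE)
  rank_x <- sum(pc$sdev > 1e-10)
  if (n_components > rank_x) {
    warn(sprintf("n_components reduced from %d to rank %d.",
                 n_components, rank_x))
    n_components <- rank_x
  }
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  fit <- lm(y ~ scores)
  sm <- summary(fit)
  structure(
    list(n_components = n_components,
         r_squared = sm$r.squared,
         r_squared_adj = sm$adj.r.squared,
         component_r = suppressWarnings(cor(scores)),
         fit = fit),
    class = "pca_model"
  )
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d components, adj R^2 = %.3f\n",
              x$n_components, x$r_squared_adj))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.pca_model <- function(x, ...) {
  tibble(n_components = x$n_components, r_squared = x$r_squared,
         r_squared_adj = x$r_squared_adj)
}
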