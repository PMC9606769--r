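# End-to-end orchestration of the synthetic study pipeline.

#' Simulate a complete synthetic rating study
#'
#' Runs the generator chain: image sets, SIP tables, balanced design, and
#' ratings with ground truth. All randomness flows from the study seed.
#'
#' @param config A [synthetic_study_config()].
#' @param sip_resolution Internal SIP resolution (default 128 for desk
#'   scale; the study convention is 800).
#' @param out_dir Optional directory to write `ratings.csv`,
#'   `sips.csv`, `manifest.csv` and `truth.json` (images as PNG under
#'   `images/`).
#' @return A list: `images`, `manifest`, `sips`, `design`, `ratings`,
#'   `ground_truth`, `config`.
#' @export
simulate_study <- function(config = synthetic_study_config(),
                           sip_resolution = 128, out_dir = NULL) {
  sets <- generate_image_sets(config)
  sc <- sip_config(resolution = sip_resolution)
  sips <- dplyr::bind_rows(
    compute_sips(sets$random_phase, sc, category = "random_phase"),
    compute_sips(sets$pseudo_paintings, sc,
                 category = "style_transferred"))
  design <- generate_design(config)
  gen <- generate_ratings(sips, design, config)
  out <- list(images = c(sets$random_phase, sets$pseudo_paintings),
              manifest = sets$manifest, sips = sips, design = design,
              ratings = gen$ratings, ground_truth = gen$ground_truth,
              config = config)
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "images"), recursive = TRUE,
               showWarnings = FALSE)
    for (id in names(out$images)) {
      write_image(out$images[[id]],
                  file.path(out_dir, "images", paste0(id, ".png")))
    }
    utils::write.csv(out$manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
    utils::write.csv(out$sips, file.path(out_dir, "sips.csv"),
                     row.names = FALSE)
    utils::write.csv(out$ratings, file.path(out_dir, "ratings.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(archetype = as.list(out$ground_truth$archetype),
           beta_star_planted = out$ground_truth$beta_star_planted,
           targets = out$ground_truth$targets),
      file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Run the full analysis pipeline on a synthetic study
#'
#' Orchestrates every stage on one seeded synthetic study: SIP tables,
#' best-subset selection with robustness counting and collinearity
#' pruning, standardized-coefficient rating models per dimension,
#' distances to the random-phase reference cloud, and participant
#' clustering (both modes). Writes the five stage artifacts plus a
#' provenance record carrying the configuration hash; artifacts from
#' different configurations therefore cannot be mixed silently.
#'
#' @param config A [synthetic_study_config()].
#' @param out_dir Output directory for the artifact bundle
#'   (`sips.csv`, `selection.json`, `results.json`, `dist.json`,
#'   `clusters.json`, `provenance.json`).
#' @param sip_resolution Internal SIP resolution (default 128).
#' @param size_cap Largest model size in the subset search (default 5).
#' @param n_keep Robust variables kept before pruning (default 12).
#' @param rho_threshold Collinearity pruning threshold (default 0.6).
#' @param n_best Models retained per size (default 10).
#' @return A list with every stage result (invisibly if `out_dir` is
#'   given).
#' @export
run_pipeline <- function(config = synthetic_study_config(),
                         out_dir = NULL, sip_resolution = 128,
                         size_cap = 5, n_keep = 12, rho_threshold = 0.6,
                         n_best = 10) {
  study <- simulate_study(config, sip_resolution = sip_resolution)
  sips <- study$sips
  sip_cols <- setdiff(names(sips)[vapply(sips, is.numeric, logical(1))],
                      "set_slope")
  pp_sips <- sips[sips$category == "style_transferred", ]
  usable <- sip_cols[vapply(pp_sips[sip_cols], function(v) {
    all(is.finite(v)) && sd(v) > 0
  }, logical(1))]

  means <- aggregate_ratings(
    study$ratings[study$ratings$category == "style_transferred", ],
    "image")
  wide <- tidyr::pivot_wider(means[c("image_id", "dimension",
                                     "mean_rating")],
                             names_from = "dimension",
                             values_from = "mean_rating")
  model_data <- dplyr::inner_join(wide, pp_sips, by = "image_id")

  searches <- lapply(RATING_DIMENSIONS, function(dim) {
    best_subset_search(model_data[usable], model_data[[dim]],
                       n_best = n_best, size_cap = size_cap)
  })
  names(searches) <- RATING_DIMENSIONS
  rc <- do.call(robustness_counts, unname(searches))
  robust12 <- head(rc$variable, n_keep)
  pruned <- prune_collinear(model_data, robust12,
                            threshold = rho_threshold,
                            robustness = setNames(rc$count, rc$variable),
                            response = "Pleasing")

  models <- lapply(RATING_DIMENSIONS, function(dim) {
    standardized_regression(model_data, dim, pruned$keep)
  })
  names(models) <- RATING_DIMENSIONS

  ref <- build_reference(sips[sips$category == "random_phase", ],
                         variables = "auto", test_sips = pp_sips)
  dists <- distance_table(pp_sips, ref)
  dist_cor <- distance_rating_correlation(dists, means)

  clusters_ir <- kmeans_with_diagnostics(
    participant_feature_vectors(study$ratings, "inter_rating"),
    seed = config$seed)
  rp_ratings <- study$ratings[study$ratings$category == "random_phase", ]
  clusters_sp <- kmeans_with_diagnostics(
    participant_feature_vectors(rp_ratings, "slope_profile"),
    seed = config$seed)

  result <- list(
    study = study, searches = searches, robustness = rc,
    selected = pruned, models = models, reference = ref,
    distances = dists, distance_correlations = dist_cor,
    clusters_inter_rating = clusters_ir,
    clusters_slope_profile = clusters_sp)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    config_hash <- rlang::hash(config)
    write_stage <- function(obj, file) {
      jsonlite::write_json(c(list(config_hash = config_hash), obj),
                           file.path(out_dir, file), auto_unbox = TRUE,
                           digits = NA, force = TRUE)
    }
    utils::write.csv(cbind(config_hash = config_hash, sips),
                     file.path(out_dir, "sips.csv"), row.names = FALSE)
    write_stage(list(
      robustness = rc, kept = pruned$keep, dropped = pruned$dropped,
      by_size = lapply(searches, function(s) {
        d <- tidy(s)
        d$members <- vapply(d$members, paste, character(1),
                            collapse = ",")
        d
      })), "selection.json")
    write_stage(list(models = lapply(models, function(m) {
      list(coefficients = tidy(m), fit = glance(m))
    })), "results.json")
    write_stage(list(variables = ref$variables,
                     distances = dists,
                     correlations = dist_cor), "dist.json")
    write_stage(list(
      inter_rating = list(chosen_k = clusters_ir$chosen_k,
                          assignments = as.list(clusters_ir$assignments),
                          diagnostics = clusters_ir$diagnostics),
      slope_profile = list(chosen_k = clusters_sp$chosen_k,
                           assignments = as.list(clusters_sp$assignments),
                           diagnostics = clusters_sp$diagnostics)),
      "clusters.json")
    write_stage(list(
      package_version = as.character(utils::packageVersion("sipstats")),
      r_version = R.version.string,
      seed = config$seed,
      timestamp = format(Sys.time(), tz = "UTC")), "provenance.json")
    return(invisible(result))
  }
  result
}
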