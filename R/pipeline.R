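#' Pipeline configuration
#'
#' Collects every threshold, analysis switch and seed of the end-to-end
#' pipeline in one object that round-trips through YAML, so a run is fully
#' reproducible from its echoed configuration.
#'
#' @param seed master seed for all randomness.
#' @param stay_d,stay_t stay-point thresholds (m, s).
#' @param poi_radius POI trim radius (m).
#' @param max_speed,max_gap trajectory cleaning thresholds (m/s, s).
#' @param k_range k-medoids cluster counts to evaluate.
#' @param profile_range latent-profile counts to evaluate.
#' @param blrt_b bootstrap replicates of the BLRT.
#' @param lpa_starts EM starts for full-data mixture fits.
#' @param cohort a [cohort_config()] used when no logs are supplied;
#'   defaults to the study design with the study exclusion pattern.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            stay_d = 1.0, stay_t = 5.0,
                            poi_radius = 15, max_speed = 10, max_gap = 30,
                            k_range = 3:7, profile_range = 3:7,
                            blrt_b = 100, lpa_starts = 50,
                            cohort = cohort_config(exclusions = "study")) {
  thresholds <- c(stay_d = stay_d, stay_t = stay_t, poi_radius = poi_radius,
                  max_speed = max_speed, max_gap = max_gap)
  if (any(thresholds <= 0)) stop("all thresholds must be positive")
  stopifnot(is.numeric(seed), length(seed) == 1, seed == round(seed))
  structure(list(seed = as.integer(seed), stay_d = stay_d, stay_t = stay_t,
                 poi_radius = poi_radius, max_speed = max_speed,
                 max_gap = max_gap, k_range = k_range,
                 profile_range = profile_range, blrt_b = blrt_b,
                 lpa_starts = lpa_starts, cohort = cohort),
            class = "pipeline_config")
}

#' Write or read a pipeline configuration as YAML
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `write_pipeline_config()`: `path` invisibly;
#'   `read_pipeline_config()`: a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  lst <- unclass(config)
  lst$cohort <- list(n = as.list(lst$cohort$n),
                     exclusions = if (identical(lst$cohort$exclusions, "study"))
                       "study" else NULL,
                     behaviors = lapply(lst$cohort$behaviors, unclass))
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  lst <- yaml::read_yaml(path)
  beh <- lapply(lst$cohort$behaviors, function(b) do.call(group_behavior, b))
  coh <- cohort_config(n = unlist(lst$cohort$n), behaviors = beh,
                       exclusions = lst$cohort$exclusions)
  pipeline_config(seed = lst$seed, stay_d = lst$stay_d, stay_t = lst$stay_t,
                  poi_radius = lst$poi_radius, max_speed = lst$max_speed,
                  max_gap = lst$max_gap, k_range = lst$k_range,
                  profile_range = lst$profile_range, blrt_b = lst$blrt_b,
                  lpa_starts = lst$lpa_starts, cohort = coh)
}

#' Run the full wayfinding analysis pipeline
#'
#' simulate (when no logs are given) -> ingest -> features -> trajectory
#' clustering -> latent profiles -> mixed models -> SCD classification,
#' with row counts recorded at every filter stage.
#'
#' @param config a [pipeline_config()].
#' @param logs optional list of `track_log`s or a `wayfinding_cohort`; when
#'   NULL a cohort is simulated from `config$cohort` under `config$seed`.
#' @param route_map optional route map (defaults to the cohort's).
#' @param participants participant covariate data frame (id, group, sex,
#'   familiarity); taken from the cohort when available.
#' @param exclusion_list flagged (participant, track) pairs; taken from the
#'   cohort when available.
#' @return a `pipeline_result` list: `config`, `counts`, `features`,
#'   `cluster`, `lpa`, `models`, `classify`, `cohort` (when simulated).
#' @export
run_pipeline <- function(config = pipeline_config(), logs = NULL,
                         route_map = NULL, participants = NULL,
                         exclusion_list = NULL) {
  cohort <- NULL
  if (is.null(logs)) {
    cohort <- simulate_cohort(config$cohort, seed = config$seed)
    logs <- cohort
  }
  if (inherits(logs, "wayfinding_cohort")) {
    cohort <- logs
    if (is.null(route_map)) route_map <- cohort$route_map
    if (is.null(participants)) participants <- cohort$participants
    if (is.null(exclusion_list)) exclusion_list <- cohort$exclusions
  }
  if (is.null(route_map)) stop("route_map required")

  ing <- ingest_pipeline(logs, route_map, exclusion_list,
                         poi_radius_m = config$poi_radius,
                         max_speed_mps = config$max_speed,
                         max_gap_s = config$max_gap)

  features <- build_feature_table(
    ing$analysis_tracks, route_map,
    reference_ids = unique(vapply(ing$complete_tracks, `[[`, character(1),
                                  "participant_id")),
    d_thresh_m = config$stay_d, t_thresh_s = config$stay_t)

  complete_ids <- unique(vapply(ing$complete_tracks, `[[`, character(1),
                                "participant_id"))
  labels <- features$participants$group[
    match(complete_ids, features$participants$participant_id)]

  D <- pairwise_dissimilarity(ing$complete_tracks)
  clus <- select_k(D, config$k_range, labels = labels)

  Z <- feature_zscores(features, ids = complete_ids)
  lpa <- sweep_profiles(Z, K_range = config$profile_range, labels = labels,
                        B = config$blrt_b, seed = config$seed,
                        n_starts = config$lpa_starts)

  models <- fit_performance_models(features$tracks, participants)
  dp_model <- decision_point_model(models$data)

  cls <- classify_scd(features$participants)

  structure(list(
    config = config,
    counts = ing$counts,
    participants_complete = ing$participants_complete,
    features = features,
    dissimilarity = D,
    cluster = clus,
    lpa = lpa,
    models = models,
    decision_point_model = dp_model,
    classify = cls,
    cohort = cohort
  ), class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("wayfinding pipeline result\n")
  cat("  counts:", paste(names(x$counts), x$counts, sep = "=",
                         collapse = ", "), "\n")
  cat(sprintf("  clustering: best k=%d (silhouette %.2f), purity %.3f\n",
              x$cluster$best_k, max(x$cluster$silhouettes$silhouette),
              x$cluster$best$purity))
  cat(sprintf("  profiles: chosen K=%d, purity %.3f\n",
              x$lpa$chosen_K, x$lpa$purity))
  cat(sprintf("  classifier: AUC=%.3f, LOO accuracy=%.2f\n",
              x$classify$roc$auc, x$classify$loo$accuracy))
  invisible(x)
}

#' Write the pipeline report bundle
#'
#' Emits the analysis outputs as plain files: the per-track and
#' per-participant feature tables and the dissimilarity matrix as CSV, a
#' model-summary CSV shaped like the group-difference coefficient table
#' (one column block per performance measure), the profile-selection table,
#' Sankey-ready class x cluster / class x profile count tables, ROC points,
#' and a top-level JSON report echoing configuration, seed, package
#' version, and filter-stage counts.
#'
#' @param result a `pipeline_result`.
#' @param dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
write_report <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  wr <- function(obj, name) {
    p <- file.path(dir, name)
    write.csv(obj, p, row.names = FALSE)
    paths <<- c(paths, p)
    p
  }
  wr(result$features$tracks, "feature_tracks.csv")
  wr(result$features$participants, "feature_participants.csv")

  D <- as.data.frame(unclass(result$dissimilarity))
  D <- cbind(participant_id = rownames(D), D)
  wr(D, "dissimilarity.csv")

  wr(result$cluster$silhouettes, "cluster_silhouettes.csv")
  wr(result$lpa$table, "profile_selection.csv")

  # coefficient table across the five models
  coef_rows <- do.call(rbind, lapply(
    c("distance", "duration", "speed", "map_views", "stops"),
    function(m) {
      fit <- result$models[[m]]$full
      co <- fit$coefficients
      data.frame(measure = m, term = co$term, estimate = co$estimate,
                 ci_lo = co$ci_lo, ci_hi = co$ci_hi, p = co$p,
                 delta_AIC = result$models[[m]]$comparison$delta_AIC,
                 R2 = result$models[[m]]$comparison$R2,
                 R2_method = result$models[[m]]$comparison$R2_method)
    }))
  wr(coef_rows, "model_coefficients.csv")
  wr(result$decision_point_model$coefficients, "decision_point_model.csv")

  # Sankey-ready class x cluster / class x profile counts
  complete_ids <- rownames(unclass(result$dissimilarity))
  labels <- result$features$participants$group[
    match(complete_ids, result$features$participants$participant_id)]
  sankey <- list(
    cluster = as.data.frame(table(class = labels,
                                  cluster = result$cluster$best$assignment)),
    profile = as.data.frame(table(class = labels,
                                  profile = result$lpa$chosen_fit$assignment))
  )
  p <- file.path(dir, "sankey_counts.json")
  jsonlite::write_json(sankey, p, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, p)

  wr(result$classify$roc$points, "roc_points.csv")

  report <- list(
    package_version = as.character(utils::packageVersion("wayfindr")),
    seed = result$config$seed,
    config = list(stay_d = result$config$stay_d, stay_t = result$config$stay_t,
                  poi_radius = result$config$poi_radius,
                  max_speed = result$config$max_speed,
                  max_gap = result$config$max_gap,
                  k_range = result$config$k_range,
                  profile_range = result$config$profile_range,
                  blrt_b = result$config$blrt_b),
    counts = as.list(result$counts),
    cluster = list(best_k = result$cluster$best_k,
                   purity = result$cluster$best$purity),
    profiles = list(chosen_K = result$lpa$chosen_K, purity = result$lpa$purity),
    classifier = list(auc = result$classify$roc$auc,
                      odds_ratio = result$classify$fit$odds_ratio,
                      loo_accuracy = result$classify$loo$accuracy)
  )
  p <- file.path(dir, "report.json")
  jsonlite::write_json(report, p, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, p)
  invisible(paths)
}
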