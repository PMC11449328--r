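#' Per-track wayfinding metrics
#'
#' Wayfinding distance (sum of haversine distances of adjacent fixes),
#' wayfinding duration (sum of time differences of adjacent fixes, i.e. the
#' time span), and movement speed (distance / duration). Computed on the
#' full walking-phase fixes, so time spent in map views counts towards the
#' duration while the map-view and orientation-stop counts remain separate
#' measures.
#'
#' @param track a `clean_track` (or anything with `$full_fixes`).
#' @return named numeric vector `c(distance_m, duration_s, speed_mps)`.
#' @export
track_metrics <- function(track) {
  fx <- if (inherits(track, "clean_track")) track$full_fixes else track
  if (nrow(fx) < 2) stop("need at least 2 fixes")
  distance <- path_length_m(fx)
  duration <- fx$t[nrow(fx)] - fx$t[1]
  if (duration <= 0) stop("zero duration")
  c(distance_m = distance, duration_s = duration,
    speed_mps = distance / duration)
}

#' Stay-point (orientation stop) detection
#'
#' Detects intervals during which the participant moved less than
#' `d_thresh_m` for at least `t_thresh_s` (default: less than one meter in
#' five seconds), the operational definition of an orientation stop. The
#' scan anchors at fix i, finds the smallest j > i whose distance from the
#' anchor exceeds `d_thresh_m`, and emits a stay event spanning fixes
#' `[i, j-1]` if their time span reaches `t_thresh_s`, moving the anchor to
#' j; otherwise the anchor advances by one. A trailing cluster at the end
#' of the track that satisfies the time criterion is also emitted.
#'
#' @param track a `clean_track` (detection runs on `walking_fixes`) or a
#'   data frame of fixes with `t`, `lat`, `lon`.
#' @param d_thresh_m displacement threshold in meters, default 1.
#' @param t_thresh_s minimum dwell time in seconds, default 5.
#' @return data frame with one row per stay event: `start_t`, `end_t`,
#'   `duration_s`, `centroid_lat`, `centroid_lon`, `i_start`, `i_end`.
#' @export
detect_stay_points <- function(track, d_thresh_m = 1.0, t_thresh_s = 5.0) {
  fx <- if (inherits(track, "clean_track")) track$walking_fixes else track
  empty <- data.frame(start_t = numeric(0), end_t = numeric(0),
                      duration_s = numeric(0), centroid_lat = numeric(0),
                      centroid_lon = numeric(0), i_start = integer(0),
                      i_end = integer(0))
  n <- nrow(fx)
  if (is.null(n) || n < 2) return(empty)
  events <- list()
  i <- 1
  while (i < n) {
    d <- haversine_m(fx$lat[i], fx$lon[i],
                     fx$lat[(i + 1):n], fx$lon[(i + 1):n])
    j_rel <- which(d > d_thresh_m)[1]
    if (is.na(j_rel)) {
      # trailing cluster: everything to the end stays within the radius
      if (fx$t[n] - fx$t[i] >= t_thresh_s) {
        events[[length(events) + 1]] <- c(i, n)
      }
      break
    }
    j <- i + j_rel
    if (fx$t[j - 1] - fx$t[i] >= t_thresh_s) {
      events[[length(events) + 1]] <- c(i, j - 1)
      i <- j
    } else {
      i <- i + 1
    }
  }
  if (!length(events)) return(empty)
  do.call(rbind, lapply(events, function(e) {
    idx <- e[1]:e[2]
    data.frame(start_t = fx$t[e[1]], end_t = fx$t[e[2]],
               duration_s = fx$t[e[2]] - fx$t[e[1]],
               centroid_lat = mean(fx$lat[idx]),
               centroid_lon = mean(fx$lon[idx]),
               i_start = e[1], i_end = e[2])
  }))
}

#' Count orientation stops on a track
#'
#' @param track a `clean_track`.
#' @inheritParams detect_stay_points
#' @return non-negative integer: number of stay events during walking.
#' @export
count_orientation_stops <- function(track, d_thresh_m = 1.0, t_thresh_s = 5.0) {
  nrow(detect_stay_points(track, d_thresh_m, t_thresh_s))
}

#' Build the per-track and per-participant feature tables
#'
#' Computes the five performance measures for every clean track (wayfinding
#' distance, duration, movement speed, map views, orientation stops), joins
#' the track's decision-point count, and aggregates to participant level:
#' the mean of each measure over the participant's completed analyzed
#' tracks (for stops this equals total stops divided by the number of
#' completed tracks) plus z-scores of the five means standardized against a
#' reference sample.
#'
#' @param clean_tracks list of `clean_track`s (ingest pipeline output).
#' @param route_map route map providing decision-point counts.
#' @param reference_ids participant ids defining the z-score reference
#'   sample (mean 0, sd 1 within this set); defaults to all participants in
#'   `clean_tracks`.
#' @param d_thresh_m,t_thresh_s stay-point thresholds.
#' @return list with `tracks` (one row per participant x track:
#'   `participant_id`, `group`, `track_id`, `distance_m`, `duration_s`,
#'   `speed_mps`, `map_views`, `stops`, `decision_points`) and
#'   `participants` (means, `stops_per_track`, `n_tracks`, and `z_*`
#'   columns).
#' @export
build_feature_table <- function(clean_tracks, route_map,
                                reference_ids = NULL,
                                d_thresh_m = 1.0, t_thresh_s = 5.0) {
  rows <- lapply(clean_tracks, function(ct) {
    m <- track_metrics(ct)
    tr <- .get_track(route_map, ct$track_id)
    data.frame(participant_id = ct$participant_id, group = ct$group,
               track_id = ct$track_id,
               distance_m = unname(m["distance_m"]),
               duration_s = unname(m["duration_s"]),
               speed_mps = unname(m["speed_mps"]),
               map_views = ct$n_map_views,
               stops = count_orientation_stops(ct, d_thresh_m, t_thresh_s),
               decision_points = tr$decision_points,
               stringsAsFactors = FALSE)
  })
  tracks <- do.call(rbind, rows)
  tracks <- tracks[order(tracks$participant_id, tracks$track_id), ]
  rownames(tracks) <- NULL

  measures <- c("distance_m", "duration_s", "speed_mps", "map_views", "stops")
  sp <- split(tracks, tracks$participant_id)
  parts <- do.call(rbind, lapply(sp, function(d) {
    out <- data.frame(participant_id = d$participant_id[1],
                      group = d$group[1], n_tracks = nrow(d))
    for (m in measures) out[[m]] <- mean(d[[m]])
    out$stops_per_track <- sum(d$stops) / nrow(d)
    out
  }))
  rownames(parts) <- NULL
  if (any(parts$n_tracks == 0)) {
    warning("participants with zero tracks excluded")
    parts <- parts[parts$n_tracks > 0, , drop = FALSE]
  }
  if (is.null(reference_ids)) reference_ids <- parts$participant_id
  ref <- parts[parts$participant_id %in% reference_ids, , drop = FALSE]
  if (nrow(ref) < 2) stop("reference sample needs at least 2 participants")
  for (m in measures) {
    mu <- mean(ref[[m]]); s <- sd(ref[[m]])
    parts[[paste0("z_", m)]] <- if (s > 0) (parts[[m]] - mu) / s else 0
  }
  list(tracks = tracks, participants = parts)
}

#' Z-score matrix of the five performance measures
#'
#' Convenience accessor: the n x 5 matrix of z-scored mean performance
#' measures used as latent-profile-analysis input.
#'
#' @param features output of [build_feature_table()].
#' @param ids optional subset of participant ids (rows), in order.
#' @return numeric matrix with rownames = participant ids.
#' @export
feature_zscores <- function(features, ids = NULL) {
  parts <- features$participants
  if (!is.null(ids)) parts <- parts[match(ids, parts$participant_id), ]
  z <- as.matrix(parts[, c("z_distance_m", "z_duration_s", "z_speed_mps",
                           "z_map_views", "z_stops")])
  rownames(z) <- parts$participant_id
  colnames(z) <- c("distance", "duration", "speed", "map_views", "stops")
  z
}
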