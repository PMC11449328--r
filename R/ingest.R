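#' Parse raw wayfinding logs
#'
#' Reads a CSV in the log schema written by [write_track_logs()]
#' (`participant_id`, `group`, `track_id`, `t_epoch_s`, `lat`, `lon`,
#' `phase`, `event`; unknown extra columns are tolerated, a `flag` column is
#' picked up as a track quality flag) and splits it into one `track_log` per
#' participant x track, with fixes sorted by timestamp.
#'
#' @param path CSV file path, or a data frame already in the schema.
#' @return list of `track_log` objects.
#' @export
parse_logs <- function(path) {
  df <- if (is.data.frame(path)) path else read.csv(path, stringsAsFactors = FALSE)
  mandatory <- c("participant_id", "group", "track_id", "t_epoch_s", "lat", "lon")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols)) {
    stop("missing mandatory columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!"phase" %in% names(df)) df$phase <- "walking"
  if (!"event" %in% names(df)) df$event <- ""
  df$event[is.na(df$event)] <- ""
  bad <- which(!is.finite(df$t_epoch_s) | !is.finite(df$lat) | !is.finite(df$lon))
  if (length(bad)) stop("malformed row(s) at line(s): ",
                        paste(head(bad, 5) + 1, collapse = ", "))
  oor <- which(abs(df$lat) > 90 | abs(df$lon) > 180)
  if (length(oor)) stop("coordinate out of range at line(s): ",
                        paste(head(oor, 5) + 1, collapse = ", "))

  key <- paste(df$participant_id, df$track_id, sep = "\r")
  lapply(split(seq_len(nrow(df)), key)[unique(key)], function(idx) {
    sub <- df[idx, , drop = FALSE]
    sub <- sub[order(sub$t_epoch_s), , drop = FALSE]
    flags <- character(0)
    if ("flag" %in% names(sub)) {
      fl <- unique(sub$flag[!is.na(sub$flag) & sub$flag != ""])
      flags <- as.character(fl)
    }
    structure(list(
      participant_id = sub$participant_id[1],
      group = sub$group[1],
      track_id = sub$track_id[1],
      fixes = data.frame(t = sub$t_epoch_s, lat = sub$lat, lon = sub$lon,
                         phase = sub$phase, event = sub$event,
                         stringsAsFactors = FALSE),
      flags = flags
    ), class = "track_log")
  })
}

#' Clean a GPS trajectory
#'
#' Removes duplicated timestamps (first fix kept), drops fixes implying an
#' instantaneous speed above `max_speed_mps` (GPS artifacts), and flags
#' tracks containing a temporal gap above `max_gap_s` as `signal_loss`.
#' The thresholds are generous for pedestrians and configurable; removals
#' are recorded in the returned log's `cleaning` element.
#'
#' @param track a `track_log`.
#' @param max_speed_mps artifact speed threshold, default 10 m/s.
#' @param max_gap_s signal-loss gap threshold, default 30 s.
#' @return the cleaned `track_log` (idempotent on clean input).
#' @export
clean_trajectory <- function(track, max_speed_mps = 10, max_gap_s = 30) {
  stopifnot(inherits(track, "track_log"))
  fx <- track$fixes
  if (nrow(fx) == 0) stop("track has no fixes")
  n_dup <- sum(duplicated(fx$t))
  fx <- fx[!duplicated(fx$t), , drop = FALSE]

  # forward scan against the last retained fix
  keep <- rep(TRUE, nrow(fx))
  last <- 1
  for (i in seq_len(nrow(fx))[-1]) {
    dt <- fx$t[i] - fx$t[last]
    sp <- haversine_m(fx$lat[last], fx$lon[last], fx$lat[i], fx$lon[i]) / dt
    if (is.finite(sp) && sp > max_speed_mps) keep[i] <- FALSE else last <- i
  }
  n_speed <- sum(!keep)
  fx <- fx[keep, , drop = FALSE]
  if (nrow(fx) == 0) stop("all fixes removed during cleaning")

  flags <- track$flags
  if (nrow(fx) > 1 && any(diff(fx$t) > max_gap_s)) {
    flags <- union(flags, "signal_loss")
  }
  track$fixes <- fx
  track$flags <- flags
  track$cleaning <- list(n_duplicates = n_dup, n_speed_artifacts = n_speed)
  track
}

#' Trim the POI approach zone
#'
#' Removes fixes recorded within `radius_m` of the track's own target POI on
#' the end-of-track approach (where the QR sign is already visible). Only
#' the trailing contiguous run of fixes inside the radius is removed;
#' earlier pass-bys of other POIs are untouched.
#'
#' @param track a `track_log`.
#' @param route_map route map holding the POI locations.
#' @param radius_m trim radius, default 15 m; 0 is the identity.
#' @return the trimmed `track_log`.
#' @export
trim_poi_zone <- function(track, route_map, radius_m = 15) {
  stopifnot(inherits(track, "track_log"))
  if (radius_m <= 0) return(track)
  poi <- .get_target_poi(route_map, track$track_id)
  fx <- track$fixes
  d <- haversine_m(fx$lat, fx$lon, poi["lat"], poi["lon"])
  inside <- d < radius_m
  # trailing contiguous inside-run
  n <- nrow(fx)
  i <- n
  while (i >= 1 && inside[i]) i <- i - 1
  if (i < n && i >= 1) {
    # the arrival happened; keep the event on the last retained fix, and
    # close any help interval truncated by the trim at the boundary
    arrived <- any(fx$event[(i + 1):n] == "arrive")
    fx <- fx[seq_len(i), , drop = FALSE]
    if (arrived) {
      # don't clobber a help_close sitting on the boundary fix
      if (fx$event[i] == "help_close" && i > 1 && fx$event[i - 1] == "") {
        fx$event[i - 1] <- "help_close"
      }
      fx$event[i] <- "arrive"
    }
    n_open <- sum(fx$event == "help_open") - sum(fx$event == "help_close")
    if (n_open > 0) {
      io_last <- rev(which(fx$event == "help_open"))[1]
      slot <- which(fx$event == "" & seq_len(i) > io_last)[1]
      if (!is.na(slot)) {
        fx$event[slot] <- "help_close"
      } else {
        # the whole view fell inside the trimmed zone; discard its open
        fx$event[io_last] <- ""
      }
    }
    track$fixes <- fx
  }
  track
}

#' Select analyzed tracks
#'
#' Drops the return track (the highest track id, where participants walk
#' back to the start) for every participant, then drops tracks listed in
#' the exclusion list (technical problems or protocol violations). Tracks
#' missing because of dropouts are simply absent from the input.
#'
#' @param logs list of `track_log` objects.
#' @param exclusion_list data frame with `participant_id`, `track_id` (and
#'   optionally `reason`), or `NULL`. Tracks whose own `flags` are non-empty
#'   are excluded as well.
#' @param return_track id of the return track, default 6.
#' @return list of retained `track_log`s with attribute `"retained"` (count)
#'   and `"n_excluded"`.
#' @export
select_analysis_tracks <- function(logs, exclusion_list = NULL,
                                   return_track = 6) {
  ids <- vapply(logs, `[[`, character(1), "participant_id")
  if (!is.null(exclusion_list) && nrow(exclusion_list) > 0) {
    unknown <- setdiff(exclusion_list$participant_id, ids)
    if (length(unknown)) {
      warning("exclusion list references unknown participant(s): ",
              paste(unknown, collapse = ", "))
    }
  }
  keep <- vapply(logs, function(lg) {
    if (lg$track_id == return_track) return(FALSE)
    if (length(setdiff(lg$flags, "signal_loss")) > 0) return(FALSE)
    if (!is.null(exclusion_list) && nrow(exclusion_list) > 0) {
      hit <- exclusion_list$participant_id == lg$participant_id &
        exclusion_list$track_id == lg$track_id
      if (any(hit)) return(FALSE)
    }
    TRUE
  }, logical(1))
  out <- logs[keep]
  n_candidate <- sum(vapply(logs, function(lg) lg$track_id != return_track,
                            logical(1)))
  attr(out, "retained") <- length(out)
  attr(out, "n_excluded") <- n_candidate - length(out)
  out
}

#' Complete-case participant filter
#'
#' Keeps only participants who completed all analyzed tracks (needed for
#' trajectory clustering and the latent profile analysis, which operate on
#' across-track aggregates).
#'
#' @param tracks list of `track_log`s after [select_analysis_tracks()].
#' @param analysis_tracks required track ids, default 1:5.
#' @return filtered list with attribute `"participants"`: data frame of
#'   per-group retained participant counts.
#' @export
complete_case_filter <- function(tracks, analysis_tracks = 1:5) {
  ids <- vapply(tracks, `[[`, character(1), "participant_id")
  tk <- vapply(tracks, function(lg) as.numeric(lg$track_id), numeric(1))
  complete <- vapply(split(tk, ids), function(v) {
    all(analysis_tracks %in% v)
  }, logical(1))
  keep_ids <- names(complete)[complete]
  out <- tracks[ids %in% keep_ids]
  grp <- vapply(out, `[[`, character(1), "group")
  pid <- vapply(out, `[[`, character(1), "participant_id")
  per_group <- unique(data.frame(participant_id = pid, group = grp))
  attr(out, "participants") <- as.data.frame(table(group = per_group$group),
                                             responseName = "n")
  out
}

#' Extract the walking phase of a track
#'
#' Splits a track log at its app events: `full_fixes` are the fixes between
#' the start-map close and arrival, help intervals are built from paired
#' `help_open`/`help_close` events (an unpaired open is closed at the next
#' event or track end, with a warning), and `walking_fixes` are the full
#' fixes minus those inside help intervals. The number of map views is the
#' number of help intervals.
#'
#' @param track a `track_log` whose events include `start_close` and
#'   `arrive`; a missing arrival flags the track `incomplete` and uses the
#'   last fix.
#' @return an object of class `clean_track`: `participant_id`, `group`,
#'   `track_id`, `full_fixes`, `walking_fixes`, `help_intervals` (data frame
#'   `t_open`, `t_close`), `n_map_views`, `flags`.
#' @export
extract_walking_phase <- function(track) {
  stopifnot(inherits(track, "track_log"))
  fx <- track$fixes
  flags <- track$flags
  i_start <- which(fx$event == "start_close")[1]
  if (is.na(i_start)) i_start <- 1
  i_arr <- which(fx$event == "arrive")[1]
  if (is.na(i_arr)) {
    flags <- union(flags, "incomplete")
    i_arr <- nrow(fx)
  }
  full <- fx[i_start:i_arr, , drop = FALSE]

  opens <- full$t[full$event == "help_open"]
  closes <- full$t[full$event == "help_close"]
  iv <- NULL
  for (t_open in opens) {
    t_close <- closes[closes > t_open][1]
    if (is.na(t_close)) {
      warning("unpaired help_open at t=", t_open, "; closing at track end")
      t_close <- full$t[nrow(full)]
    }
    iv <- rbind(iv, data.frame(t_open = t_open, t_close = t_close))
  }
  if (is.null(iv)) iv <- data.frame(t_open = numeric(0), t_close = numeric(0))

  in_help <- rep(FALSE, nrow(full))
  for (r in seq_len(nrow(iv))) {
    in_help <- in_help | (full$t > iv$t_open[r] & full$t < iv$t_close[r]) |
      full$phase == "help"
  }
  structure(list(
    participant_id = track$participant_id,
    group = track$group,
    track_id = track$track_id,
    full_fixes = full,
    walking_fixes = full[!in_help, , drop = FALSE],
    help_intervals = iv,
    n_map_views = nrow(iv),
    flags = flags
  ), class = "clean_track")
}

#' Run the full ingest pipeline
#'
#' parse -> clean -> POI trim -> track selection -> complete-case filter ->
#' walking-phase extraction, with row counts recorded at every stage. The
#' complete-case subsample is used for trajectory clustering and the latent
#' profile analysis; the all-tracks set feeds the mixed models.
#'
#' @param logs list of `track_log`s (e.g. [parse_logs()] or a cohort's
#'   `$logs`), or a `wayfinding_cohort`.
#' @param route_map route map (taken from the cohort if available).
#' @param exclusion_list data frame of flagged (participant, track) pairs;
#'   defaults to the cohort's injected exclusions when a cohort is given.
#' @param poi_radius_m,max_speed_mps,max_gap_s cleaning thresholds.
#' @return list with `analysis_tracks` (clean_track list, all participants),
#'   `complete_tracks` (clean_track list, complete cases), `counts` (named
#'   stage counts), `participants_complete` (per-group table).
#' @export
ingest_pipeline <- function(logs, route_map = NULL, exclusion_list = NULL,
                            poi_radius_m = 15, max_speed_mps = 10,
                            max_gap_s = 30) {
  if (inherits(logs, "wayfinding_cohort")) {
    if (is.null(route_map)) route_map <- logs$route_map
    if (is.null(exclusion_list)) exclusion_list <- logs$exclusions
    logs <- logs$logs
  }
  if (is.null(route_map)) stop("route_map required")
  cleaned <- lapply(logs, function(lg) {
    trim_poi_zone(clean_trajectory(lg, max_speed_mps, max_gap_s),
                  route_map, poi_radius_m)
  })
  n_all <- length(cleaned)
  selected <- select_analysis_tracks(cleaned, exclusion_list)
  complete <- complete_case_filter(selected)
  counts <- c(tracks_total = n_all,
              tracks_candidate = n_all -
                sum(vapply(cleaned, function(l) l$track_id == 6, logical(1))),
              tracks_analyzed = length(selected),
              tracks_complete_case = length(complete),
              participants_complete =
                length(unique(vapply(complete, `[[`, character(1),
                                     "participant_id"))))
  list(
    analysis_tracks = lapply(selected, extract_walking_phase),
    complete_tracks = lapply(complete, extract_walking_phase),
    counts = counts,
    participants_complete = attr(complete, "participants")
  )
}
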