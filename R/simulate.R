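#' Group-level behavioral parameters for the cohort simulator
#'
#' Encodes the generative behavior of one participant group: walking speed,
#' wrong-turn probability per decision point, orientation-stop rates (a
#' zero-inflated Poisson law per track), map-view rate, and GPS noise.
#' Defaults for the three study groups are provided by
#' [default_group_behaviors()].
#'
#' @param group label, one of `"YA"`, `"OA"`, `"SCD"`.
#' @param speed_mean,speed_sd between-participant mean and sd of walking
#'   speed (m/s).
#' @param p_wrong_turn probability of a wrong turn at each decision point.
#' @param stop_rate_per_decision_point expected orientation stops per
#'   decision point (Poisson rate scale), conditional on not being a
#'   structural zero.
#' @param stop_rate_track additional flat per-track stop rate (background
#'   stops on edges), default 0.
#' @param stop_zero_inflation structural-zero probability of the per-track
#'   stop count.
#' @param map_view_rate expected map views per track.
#' @param gps_noise_sd marginal sd of the GPS positioning noise in meters
#'   (applied in a local tangent frame, temporally AR(1) correlated).
#' @param sd_log_stop_rate,sd_log_map_rate between-participant log-normal
#'   heterogeneity of the stop and map-view rates (random-intercept sd on
#'   the log scale).
#' @return an object of class `group_behavior` (a validated list).
#' @export
group_behavior <- function(group,
                           speed_mean, speed_sd,
                           p_wrong_turn,
                           stop_rate_per_decision_point,
                           stop_rate_track = 0,
                           stop_zero_inflation = 0.25,
                           map_view_rate = 0.5,
                           gps_noise_sd = 2,
                           sd_log_stop_rate = 0.6,
                           sd_log_map_rate = 0.6) {
  gb <- list(group = group, speed_mean = speed_mean, speed_sd = speed_sd,
             p_wrong_turn = p_wrong_turn,
             stop_rate_per_decision_point = stop_rate_per_decision_point,
             stop_rate_track = stop_rate_track,
             stop_zero_inflation = stop_zero_inflation,
             map_view_rate = map_view_rate,
             gps_noise_sd = gps_noise_sd,
             sd_log_stop_rate = sd_log_stop_rate,
             sd_log_map_rate = sd_log_map_rate)
  nums <- unlist(gb[-1])
  if (any(!is.finite(nums)) || any(nums < 0)) {
    stop("group_behavior parameters must be finite and non-negative")
  }
  if (p_wrong_turn > 1 || stop_zero_inflation >= 1) {
    stop("probabilities out of range")
  }
  structure(gb, class = "group_behavior")
}

#' Default group behaviors of the simulated cohort
#'
#' Free generator parameters chosen to reproduce the direction and rough
#' magnitude of the observed group effects: younger adults (YA) walk
#' fastest and rarely stop or consult the map; patients with subjective
#' cognitive decline (SCD) stop roughly twice as often per decision point
#' as healthy older adults (OA) and view the map more often, while OA and
#' SCD walking speeds are similar. These are generative-scale choices, not
#' estimates from any cohort.
#'
#' @return named list of three [group_behavior()] objects (`YA`, `OA`, `SCD`).
#' @export
default_group_behaviors <- function() {
  list(
    YA  = group_behavior("YA",  speed_mean = 1.45, speed_sd = 0.10,
                         p_wrong_turn = 0.03,
                         stop_rate_per_decision_point = 0.085,
                         stop_zero_inflation = 0.35, map_view_rate = 0.16),
    OA  = group_behavior("OA",  speed_mean = 1.25, speed_sd = 0.10,
                         p_wrong_turn = 0.06,
                         stop_rate_per_decision_point = 0.22,
                         stop_zero_inflation = 0.25, map_view_rate = 0.52),
    SCD = group_behavior("SCD", speed_mean = 1.22, speed_sd = 0.10,
                         p_wrong_turn = 0.07,
                         stop_rate_per_decision_point = 0.43,
                         stop_zero_inflation = 0.25, map_view_rate = 1.15)
  )
}

# draw participant-level realized parameters from a group behavior
.draw_participant_params <- function(gb, seed) {
  set.seed(seed)
  list(
    group = gb$group,
    speed = max(0.4, rnorm(1, gb$speed_mean, gb$speed_sd)),
    p_wrong_turn = gb$p_wrong_turn,
    stop_rate_per_decision_point =
      gb$stop_rate_per_decision_point * exp(rnorm(1, 0, gb$sd_log_stop_rate)),
    stop_rate_track = gb$stop_rate_track * exp(rnorm(1, 0, gb$sd_log_stop_rate)),
    stop_zero_inflation = gb$stop_zero_inflation,
    map_view_rate = gb$map_view_rate * exp(rnorm(1, 0, gb$sd_log_map_rate)),
    gps_noise_sd = gb$gps_noise_sd
  )
}

# arc-length positions of polyline vertices (meters frame)
.arc_positions <- function(xy) {
  d <- sqrt(rowSums((xy[-1, , drop = FALSE] - xy[-nrow(xy), , drop = FALSE])^2))
  c(0, cumsum(d))
}

# point at arc position s on a polyline given vertex arc positions
.point_at_arc <- function(xy, arc, s) {
  s <- min(max(s, 0), arc[length(arc)])
  i <- findInterval(s, arc, rightmost.closed = TRUE)
  i <- min(i, nrow(xy) - 1)
  f <- if (arc[i + 1] > arc[i]) (s - arc[i]) / (arc[i + 1] - arc[i]) else 0
  xy[i, ] + f * (xy[i + 1, ] - xy[i, ])
}

#' Simulate one participant x track log
#'
#' Walks the track polyline at the participant's speed, inserting wrong-turn
#' out-and-back detours at decision points, stationary dwell intervals for
#' orientation stops (attached to decision points) and map views (help
#' phases), and emits GPS fixes on a strict 2 s grid with AR(1)-correlated
#' Gaussian positioning noise applied in a local meters frame. App events
#' are emitted as in the task protocol: the start map closes after 8 m
#' walked or an 18 s timeout (whichever comes first), help open/close pairs
#' bracket map views, and arrival is followed by a QR scan.
#'
#' @param params participant parameter list (from a [group_behavior()] draw;
#'   see [simulate_cohort()]), or a `group_behavior` (then drawn here).
#' @param route_map a [build_route_map()] object.
#' @param track_id track to walk.
#' @param seed integer seed; the same (params, seed) yields a byte-identical
#'   log.
#' @param participant_id,group identifiers stored in the log.
#' @return an object of class `track_log`: list with `participant_id`,
#'   `group`, `track_id`, `fixes` (data frame `t`, `lat`, `lon`, `phase`,
#'   `event`), `flags` (character), and `truth` (realized counts).
#' @export
simulate_track <- function(params, route_map, track_id, seed,
                           participant_id = "P001", group = NULL) {
  if (inherits(params, "group_behavior")) {
    params <- .draw_participant_params(params, seed)
  }
  nums <- unlist(params[names(params) != "group"])
  if (any(!is.finite(nums))) stop("non-finite participant parameters")
  if (is.null(group)) group <- params$group
  tr <- .get_track(route_map, track_id)
  lat0 <- route_map$pois$lat[1]; lon0 <- route_map$pois$lon[1]
  set.seed(seed)

  base_xy <- .to_local(tr$coords[, 1], tr$coords[, 2], lat0, lon0)
  base_arc <- .arc_positions(base_xy)
  node_arc <- base_arc[tr$decision_nodes]

  # wrong-turn detours: out-and-back spurs of 20-60 m inserted at decision
  # nodes, perpendicular to the incoming edge
  xy <- base_xy
  wrong <- 0L
  if (length(tr$decision_nodes) > 0 && params$p_wrong_turn > 0) {
    take <- runif(length(tr$decision_nodes)) < params$p_wrong_turn
    for (ni in rev(which(take))) {
      v <- tr$decision_nodes[ni]
      dir <- xy[v, ] - xy[v - 1, ]
      dir <- dir / sqrt(sum(dir^2))
      perp <- c(-dir[2], dir[1]) * sample(c(-1, 1), 1)
      out <- runif(1, 20, 60) / 2
      spur <- rbind(xy[v, ] + perp * out * 0.5, xy[v, ] + perp * out)
      xy <- rbind(xy[1:v, , drop = FALSE], spur, spur[1, ],
                  xy[v:nrow(xy), , drop = FALSE])
      wrong <- wrong + 1L
    }
  }
  arc <- .arc_positions(xy)
  total_len <- arc[length(arc)]
  # stops are attached to the decision nodes' arc positions on the base
  # route; small offsets from inserted detours are immaterial for counts
  node_arc_adj <- node_arc

  # dwell events: orientation stops at decision nodes, map views anywhere
  dp <- tr$decision_points
  lambda <- params$stop_rate_per_decision_point * dp + params$stop_rate_track
  n_stops <- if (runif(1) < params$stop_zero_inflation) 0L else rpois(1, lambda)
  # stops occupy distinct positions (decision nodes first, then edge
  # positions kept >= 15 m apart) so each dwell is a separate stay event
  stop_arc <- numeric(0)
  if (n_stops > 0) {
    n_at_nodes <- min(n_stops, dp)
    if (n_at_nodes > 0) {
      stop_arc <- node_arc_adj[sample.int(dp, n_at_nodes)]
    }
    extra <- n_stops - n_at_nodes
    tries <- 0
    while (extra > 0 && tries < 50) {
      cand <- runif(1, 0.1, 0.9) * total_len
      if (all(abs(cand - stop_arc) >= 15)) {
        stop_arc <- c(stop_arc, cand)
        extra <- extra - 1
      }
      tries <- tries + 1
    }
    n_stops <- length(stop_arc) # what was actually placed is the truth
    stop_arc <- sort(stop_arc)
  }
  stop_dur <- if (n_stops > 0) runif(n_stops, 8, 15) else numeric(0)

  n_help <- rpois(1, params$map_view_rate)
  # map views happen during walking, i.e. after the ~8 m start window
  help_arc <- if (n_help > 0) {
    sort(runif(n_help, min(12, 0.3 * total_len), 0.95 * total_len))
  } else numeric(0)
  help_dur <- if (n_help > 0) runif(n_help, 8, 25) else numeric(0)

  dwells <- data.frame(
    arc = c(stop_arc, help_arc),
    dur = c(stop_dur, help_dur),
    kind = rep(c("stop", "help"), c(n_stops, n_help))
  )
  dwells <- dwells[order(dwells$arc), , drop = FALSE]

  # piecewise time/arc schedule: constant speed, pauses at dwell positions
  v <- params$speed
  brk_t <- 0; brk_s <- 0; seg <- list()
  cur_t <- 0; cur_s <- 0
  help_iv <- NULL
  for (i in seq_len(nrow(dwells))) {
    s_k <- dwells$arc[i]
    cur_t <- cur_t + (s_k - cur_s) / v
    cur_s <- s_k
    t_open <- cur_t
    cur_t <- cur_t + dwells$dur[i]
    seg[[length(seg) + 1]] <- c(t_open, cur_t, s_k, dwells$kind[i])
    if (dwells$kind[i] == "help") {
      help_iv <- rbind(help_iv, c(t_open, cur_t))
    }
  }
  t_end <- cur_t + (total_len - cur_s) / v

  # position at time t given the dwell schedule
  pos_at <- function(t) {
    s <- NA_real_
    tt <- 0; ss <- 0
    for (sg in seg) {
      t0 <- as.numeric(sg[1]); t1 <- as.numeric(sg[2]); s_k <- as.numeric(sg[3])
      if (t < t0) { s <- ss + (t - tt) * v; return(min(s, total_len)) }
      if (t <= t1) return(s_k)
      tt <- t1; ss <- s_k
    }
    min(ss + (t - tt) * v, total_len)
  }

  t_grid <- seq(0, ceiling(t_end / 2) * 2, by = 2)
  s_grid <- vapply(t_grid, pos_at, numeric(1))
  pts <- t(vapply(s_grid, function(s) .point_at_arc(xy, arc, s), numeric(2)))

  # AR(1) positioning noise, marginal sd = gps_noise_sd in each axis
  n <- length(t_grid)
  if (params$gps_noise_sd > 0) {
    phi <- 0.98
    innov_sd <- params$gps_noise_sd * sqrt(1 - phi^2)
    ex <- ey <- numeric(n)
    ex[1] <- rnorm(1, 0, params$gps_noise_sd)
    ey[1] <- rnorm(1, 0, params$gps_noise_sd)
    for (i in seq_len(n - 1)) {
      ex[i + 1] <- phi * ex[i] + rnorm(1, 0, innov_sd)
      ey[i + 1] <- phi * ey[i] + rnorm(1, 0, innov_sd)
    }
    pts <- pts + cbind(ex, ey)
  }
  ll <- .from_local(pts[, 1], pts[, 2], lat0, lon0)

  # phases and events on the fix grid
  walked <- s_grid
  i_close <- which(walked >= 8 | t_grid >= 18)[1]
  if (is.na(i_close)) i_close <- n
  phase <- rep("walking", n)
  phase[seq_len(max(i_close - 1, 0))] <- "start"
  event <- rep("", n)
  event[i_close] <- "start_close"
  if (!is.null(help_iv)) {
    for (r in seq_len(nrow(help_iv))) {
      inside <- t_grid >= help_iv[r, 1] & t_grid <= help_iv[r, 2]
      phase[inside & seq_len(n) >= i_close] <- "help"
      idx <- seq_len(n)
      io <- which(t_grid >= help_iv[r, 1] & event == "" & idx < n)[1]
      ic <- rev(which(t_grid <= help_iv[r, 2] & event == "" & idx < n &
                        idx > ifelse(is.na(io), 0, io)))[1]
      if (!is.na(io)) event[io] <- "help_open"
      if (!is.na(ic)) event[ic] <- "help_close"
    }
  }
  # arrival at the last fix; append a short capture phase with the QR scan
  event[n] <- "arrive"
  cap_t <- t_grid[n] + c(2, 4)
  cap_ll <- ll[c(n, n), , drop = FALSE]
  fixes <- data.frame(
    t = c(t_grid, cap_t),
    lat = c(ll[, 1], cap_ll[, 1]),
    lon = c(ll[, 2], cap_ll[, 2]),
    phase = c(phase, "capture", "capture"),
    event = c(event, "", "qr_scan"),
    stringsAsFactors = FALSE
  )

  structure(list(
    participant_id = participant_id,
    group = group,
    track_id = track_id,
    fixes = fixes,
    flags = character(0),
    truth = list(speed = v, n_stops = n_stops, n_map_views = n_help,
                 n_wrong_turns = wrong, path_length_m = total_len)
  ), class = "track_log")
}

#' @export
print.track_log <- function(x, ...) {
  cat(sprintf("track_log %s track %s (%s): %d fixes, %.0f s%s\n",
              x$participant_id, x$track_id, x$group, nrow(x$fixes),
              diff(range(x$fixes$t)),
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}

#' Cohort configuration for the simulator
#'
#' @param n named integer vector of group sizes; the default is the study
#'   design of 24 younger adults, 25 healthy older adults and 23 SCD
#'   patients.
#' @param behaviors named list of [group_behavior()] objects.
#' @param exclusions `NULL`, `"study"` for the study-design exclusion
#'   pattern (9 tracks flagged for technical problems / protocol violations
#'   across 8 participants, and 3 SCD dropouts missing 5 analyzed tracks in
#'   total), or a data frame with columns `participant_index`, `track_id`,
#'   `type` (`"flag"` or `"missing"`), `reason`.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n = c(YA = 24, OA = 25, SCD = 23),
                          behaviors = default_group_behaviors(),
                          exclusions = NULL) {
  if (any(n < 1)) stop("group sizes must be >= 1")
  stopifnot(all(names(n) %in% names(behaviors)))
  structure(list(n = n, behaviors = behaviors, exclusions = exclusions),
            class = "cohort_config")
}

# study-design exclusion pattern, on participant indices within the cohort:
# 9 flagged tracks from 8 participants (1 YA, 5 OA, 2 SCD; one OA twice),
# and 3 SCD dropouts whose missing analyzed tracks total 5 (dropout after
# tracks 3, 3 and 4; track 6 missing as well).
.study_exclusions <- function(n) {
  ya <- seq_len(n[["YA"]])
  oa <- n[["YA"]] + seq_len(n[["OA"]])
  scd <- n[["YA"]] + n[["OA"]] + seq_len(n[["SCD"]])
  flags <- data.frame(
    participant_index = c(ya[1], oa[1], oa[1], oa[2], oa[3], oa[4], oa[5],
                          scd[1], scd[2]),
    track_id = c(2, 1, 4, 3, 5, 2, 1, 3, 5),
    type = "flag",
    reason = "technical_problem"
  )
  miss <- do.call(rbind, lapply(seq_along(c(3, 3, 4)), function(i) {
    after <- c(3, 3, 4)[i]
    p <- scd[2 + i]
    data.frame(participant_index = p, track_id = seq(after + 1, 6),
               type = "missing", reason = "dropout")
  }))
  rbind(flags, miss)
}

#' Simulate a full wayfinding cohort
#'
#' Generates per-participant, per-track GPS logs for a cohort, with
#' per-participant parameter draws from the group behaviors and optional
#' injected exclusions (flagged tracks and dropouts). Reproducible under a
#' single master seed: participant- and track-level seeds are derived by a
#' fixed counter scheme, so the cohort does not depend on generation order.
#'
#' @param config a [cohort_config()].
#' @param seed integer master seed.
#' @param route_map route to walk; defaults to [build_route_map()].
#' @return an object of class `wayfinding_cohort`: list with `logs` (list of
#'   `track_log`), `participants` (data frame with `participant_id`, `group`,
#'   `sex`, `familiarity`), `truth` (one row per participant x track with the
#'   realized parameters and counts), `exclusions` (data frame
#'   `participant_id`, `track_id`, `reason` for flagged tracks), and
#'   `route_map`.
#' @examples
#' coh <- simulate_cohort(cohort_config(n = c(YA = 2, OA = 2, SCD = 2)), seed = 1)
#' length(coh$logs)  # 6 participants x 6 tracks
#' @export
simulate_cohort <- function(config = cohort_config(), seed,
                            route_map = build_route_map()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n
  groups <- rep(names(n), n)
  n_total <- sum(n)
  ids <- sprintf("P%03d", seq_len(n_total))
  if (anyDuplicated(ids)) stop("duplicated participant ids")

  excl <- config$exclusions
  if (identical(excl, "study")) excl <- .study_exclusions(n)

  set.seed(.derive_seed(seed, 0L))
  sex <- ifelse(seq_len(n_total) %% 2 == 0, "female", "male")
  fam_mean <- c(YA = 12.7, OA = 14.1, SCD = 8.9)
  fam_sd <- c(YA = 9.15, OA = 8.77, SCD = 6.27)
  familiarity <- pmin(28, pmax(0, round(
    rnorm(n_total, fam_mean[groups], fam_sd[groups]))))
  participants <- data.frame(participant_id = ids, group = groups,
                             sex = sex, familiarity = familiarity)

  track_ids <- vapply(route_map$tracks, `[[`, numeric(1), "track_id")
  logs <- list(); truth <- list(); excl_out <- list()
  for (p in seq_len(n_total)) {
    params <- .draw_participant_params(config$behaviors[[groups[p]]],
                                       .derive_seed(seed, p))
    for (tk in track_ids) {
      e <- if (!is.null(excl)) {
        excl[excl$participant_index == p & excl$track_id == tk, , drop = FALSE]
      } else NULL
      if (!is.null(e) && nrow(e) > 0 && e$type[1] == "missing") next
      log <- simulate_track(params, route_map, tk,
                            seed = .derive_seed(seed, p, tk),
                            participant_id = ids[p], group = groups[p])
      if (!is.null(e) && nrow(e) > 0 && e$type[1] == "flag") {
        log$flags <- c(log$flags, e$reason[1])
        excl_out[[length(excl_out) + 1]] <- data.frame(
          participant_id = ids[p], track_id = tk, reason = e$reason[1])
      }
      logs[[length(logs) + 1]] <- log
      truth[[length(truth) + 1]] <- data.frame(
        participant_id = ids[p], group = groups[p], track_id = tk,
        speed = log$truth$speed, n_stops = log$truth$n_stops,
        n_map_views = log$truth$n_map_views,
        n_wrong_turns = log$truth$n_wrong_turns,
        stop_rate_per_decision_point = params$stop_rate_per_decision_point,
        map_view_rate = params$map_view_rate)
    }
  }
  structure(list(
    logs = logs,
    participants = participants,
    truth = do.call(rbind, truth),
    exclusions = if (length(excl_out)) do.call(rbind, excl_out) else
      data.frame(participant_id = character(0), track_id = numeric(0),
                 reason = character(0)),
    route_map = route_map,
    seed = seed
  ), class = "wayfinding_cohort")
}

#' @export
print.wayfinding_cohort <- function(x, ...) {
  cat(sprintf("wayfinding_cohort: %d participants (%s), %d track logs, %d flagged\n",
              nrow(x$participants),
              paste(names(table(x$participants$group)),
                    table(x$participants$group), sep = "=", collapse = " "),
              length(x$logs), nrow(x$exclusions)))
  invisible(x)
}

#' Write track logs to CSV
#'
#' One row per GPS fix with columns `participant_id`, `group`, `track_id`,
#' `t_epoch_s`, `lat`, `lon`, `phase`, `event`, and `flag` (empty unless the
#' track was marked for exclusion). [parse_logs()] reads the format back
#' losslessly.
#'
#' @param logs list of `track_log` objects (or a `wayfinding_cohort`).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_track_logs <- function(logs, path) {
  if (inherits(logs, "wayfinding_cohort")) logs <- logs$logs
  rows <- lapply(logs, function(lg) {
    data.frame(participant_id = lg$participant_id, group = lg$group,
               track_id = lg$track_id, t_epoch_s = lg$fixes$t,
               lat = lg$fixes$lat, lon = lg$fixes$lon,
               phase = lg$fixes$phase, event = lg$fixes$event,
               flag = if (length(lg$flags)) lg$flags[1] else "")
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
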