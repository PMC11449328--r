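rm_default <- build_route_map()

test_that("parse_logs validates schema and ranges", {
  df <- data.frame(participant_id = "P1", group = "OA", track_id = 1,
                   t_epoch_s = c(0, 2), lat = c(52.1, 91), lon = 11.6,
                   phase = "walking", event = "")
  expect_error(parse_logs(df), "out of range")
  expect_error(parse_logs(df[, -4]), "missing mandatory")
  df$lat <- 52.1
  logs <- parse_logs(df)
  expect_length(logs, 1)
  expect_s3_class(logs[[1]], "track_log")
})

test_that("parsing is invariant to row order", {
  coh <- small_cohort(seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_track_logs(coh, path)
  df <- read.csv(path)
  set.seed(1)
  shuffled <- df[sample.int(nrow(df)), ]
  a <- parse_logs(df)
  b <- parse_logs(shuffled)
  key <- names(a)[1]
  expect_equal(b[[key]]$fixes[, c("t", "lat", "lon")],
               a[[key]]$fixes[, c("t", "lat", "lon")],
               ignore_attr = TRUE)
})

test_that("cleaning removes duplicates and speed artifacts, idempotently", {
  lg <- simulate_track(default_group_behaviors()$OA, rm_default, 1,
                       seed = 21)
  # duplicate timestamp: first kept
  fx <- lg$fixes
  dup <- fx[3, ]; dup$lat <- dup$lat + 1e-4
  lg2 <- lg
  lg2$fixes <- rbind(fx[1:3, ], dup, fx[4:nrow(fx), ])
  cleaned <- clean_trajectory(lg2)
  expect_equal(nrow(cleaned$fixes), nrow(fx))
  expect_equal(cleaned$fixes$lat[3], fx$lat[3])
  expect_equal(cleaned$cleaning$n_duplicates, 1)

  # a fix 500 m off implies 250 m/s over 2 s and is removed
  lg3 <- lg
  lg3$fixes$lat[10] <- lg3$fixes$lat[10] + 500 / (pi * 6371000 / 180)
  cleaned3 <- clean_trajectory(lg3)
  expect_equal(cleaned3$cleaning$n_speed_artifacts, 1)
  expect_equal(nrow(cleaned3$fixes), nrow(fx) - 1)

  # idempotence on clean input
  expect_equal(clean_trajectory(cleaned3)$fixes, cleaned3$fixes)
  # a long gap flags signal loss
  lg4 <- lg
  lg4$fixes$t[20:nrow(fx)] <- lg4$fixes$t[20:nrow(fx)] + 60
  expect_true("signal_loss" %in% clean_trajectory(lg4)$flags)
})

test_that("POI trim removes exactly the approach inside the radius", {
  # synthetic straight approach ending at the POI at 1.5 m/s, 2 s fixes
  m_per_deg <- pi * 6371000 / 180
  poi <- c(lat = 52.1, lon = 11.6)
  n <- 30
  # 3 m per fix; tiny offset keeps the 15 m fix off the radius boundary
  dist_left <- (n - seq_len(n)) * 3 + 0.01
  fixes <- data.frame(t = seq(0, by = 2, length.out = n),
                      lat = unname(poi["lat"]) - dist_left / m_per_deg,
                      lon = unname(poi["lon"]), phase = "walking", event = "")
  fixes$event[n] <- "arrive"
  lg <- structure(list(participant_id = "P1", group = "OA", track_id = 1,
                       fixes = fixes, flags = character(0)),
                  class = "track_log")
  rmx <- rm_default
  rmx$pois$lat[match("POI1", rmx$pois$poi_id)] <- poi["lat"]
  rmx$pois$lon[match("POI1", rmx$pois$poi_id)] <- poi["lon"]
  out <- trim_poi_zone(lg, rmx, radius_m = 15)
  # fixes at 12, 9, 6, 3, 0 m are inside; exactly floor(15/3) = 5 removed
  expect_equal(nrow(out$fixes), n - 5)
  # the arrival event is retained on the boundary fix
  expect_equal(out$fixes$event[nrow(out$fixes)], "arrive")
  # radius 0 is the identity
  expect_equal(trim_poi_zone(lg, rmx, radius_m = 0)$fixes, fixes)
})

test_that("track selection drops the return track and listed exclusions", {
  coh <- small_cohort(seed = 3) # 9 participants x 6 tracks
  sel <- select_analysis_tracks(coh$logs, NULL)
  expect_equal(length(sel), 9 * 5)
  excl <- data.frame(participant_id = c("P001", "P002"), track_id = c(1, 3))
  sel2 <- select_analysis_tracks(coh$logs, excl)
  expect_equal(length(sel2), 9 * 5 - 2)
  expect_warning(
    select_analysis_tracks(coh$logs,
                           data.frame(participant_id = "ZZZ", track_id = 1)),
    "unknown participant")
})

test_that("retained count equals 5n - |E| - |D| for injected patterns", {
  n <- 6
  coh <- small_cohort(seed = 8, n = c(YA = 2, OA = 2, SCD = 2))
  for (n_excl in c(0, 2, 4)) {
    excl <- if (n_excl > 0) {
      data.frame(participant_id = sprintf("P%03d", seq_len(n_excl)),
                 track_id = rep(c(2, 4), length.out = n_excl))
    } else NULL
    sel <- select_analysis_tracks(coh$logs, excl)
    expect_equal(length(sel), 5 * n - n_excl)
  }
})

test_that("complete-case filter keeps only participants with all 5 tracks", {
  coh <- small_cohort(seed = 4, n = c(YA = 2, OA = 2, SCD = 2))
  sel <- select_analysis_tracks(coh$logs)
  # all complete: identity
  cc <- complete_case_filter(sel)
  expect_equal(length(cc), length(sel))
  # remove one track of P001: participant drops out entirely
  sel2 <- Filter(function(l) !(l$participant_id == "P001" && l$track_id == 2),
                 sel)
  cc2 <- complete_case_filter(sel2)
  expect_false("P001" %in% vapply(cc2, `[[`, character(1), "participant_id"))
  expect_equal(length(cc2), (6 - 1) * 5)
})

test_that("study-design fixture reproduces the published filter counts", {
  coh <- simulate_cohort(cohort_config(exclusions = "study"), seed = 1)
  ing <- ingest_pipeline(coh)
  expect_equal(unname(ing$counts["tracks_analyzed"]), 346)
  expect_equal(unname(ing$counts["tracks_complete_case"]), 305)
  expect_equal(unname(ing$counts["participants_complete"]), 61)
  pc <- ing$participants_complete
  expect_equal(pc$n[match(c("YA", "OA", "SCD"), pc$group)], c(23, 20, 18))
})

test_that("walking-phase extraction separates help intervals", {
  lg <- simulate_track(default_group_behaviors()$SCD, rm_default, 3,
                       seed = 31)
  ct <- extract_walking_phase(lg)
  expect_s3_class(ct, "clean_track")
  expect_equal(ct$n_map_views, nrow(ct$help_intervals))
  # walking fixes are a subset of full fixes
  expect_true(all(ct$walking_fixes$t %in% ct$full_fixes$t))
  # help-phase fixes are excluded from walking
  n_help_fixes <- sum(ct$full_fixes$phase == "help")
  expect_equal(nrow(ct$full_fixes) - nrow(ct$walking_fixes), n_help_fixes)
  # no help events: walking == full
  gb <- default_group_behaviors()$OA
  gb$map_view_rate <- 0
  lg2 <- simulate_track(gb, rm_default, 1, seed = 1)
  ct2 <- extract_walking_phase(lg2)
  expect_equal(ct2$n_map_views, 0)
  expect_equal(nrow(ct2$walking_fixes), nrow(ct2$full_fixes))
})

test_that("unpaired help events and missing arrivals are tolerated", {
  gb <- default_group_behaviors()$OA
  gb$map_view_rate <- 0 # no real help events; the injected open stays unpaired
  lg <- simulate_track(gb, rm_default, 1, seed = 2)
  fx <- lg$fixes
  i_mid <- floor(nrow(fx) / 2)
  fx$event[i_mid] <- "help_open"
  lg$fixes <- fx
  expect_warning(ct <- extract_walking_phase(lg), "unpaired")
  expect_equal(ct$n_map_views, 1)
  lg2 <- simulate_track(gb, rm_default, 1, seed = 2)
  lg2$fixes <- lg2$fixes[lg2$fixes$event != "arrive", ]
  ct2 <- extract_walking_phase(lg2)
  expect_true("incomplete" %in% ct2$flags)
})
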