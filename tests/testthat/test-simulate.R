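rm_default <- build_route_map()

noiseless <- function() {
  gb <- group_behavior("OA", speed_mean = 1.25, speed_sd = 0,
                       p_wrong_turn = 0, stop_rate_per_decision_point = 0,
                       stop_zero_inflation = 0, map_view_rate = 0,
                       gps_noise_sd = 0, sd_log_stop_rate = 0,
                       sd_log_map_rate = 0)
  gb
}

test_that("simulation is deterministic given (params, seed)", {
  gb <- default_group_behaviors()$SCD
  a <- simulate_track(gb, rm_default, 3, seed = 99)
  b <- simulate_track(gb, rm_default, 3, seed = 99)
  expect_identical(a, b)
  c <- simulate_track(gb, rm_default, 3, seed = 100)
  expect_false(identical(a$fixes, c$fixes))
})

test_that("noiseless walk length matches the optimal track length", {
  for (tk in 1:5) {
    lg <- simulate_track(noiseless(), rm_default, tk, seed = 5)
    walked <- path_length_m(lg$fixes)
    opt <- rm_default$tracks[[tk]]$optimal_length_m
    # sampled fixes cut corners: each right-angle turn shortens the summed
    # chord length by at most (1 - sqrt(2)/2) * step ~ 0.74 m, plus at most
    # one fix interval (2.5 m) of grid slack at the ends
    slack <- 2.5 + 0.74 * rm_default$tracks[[tk]]$decision_points
    expect_lte(walked, opt + 2.5)
    expect_gte(walked, opt - slack)
    expect_equal(lg$truth$n_stops, 0)
    expect_equal(lg$truth$n_map_views, 0)
  }
})

test_that("timestamps are strictly increasing on an exact 2 s grid", {
  lg <- simulate_track(default_group_behaviors()$OA, rm_default, 1, seed = 3)
  expect_true(all(diff(lg$fixes$t) == 2))
})

test_that("an inserted stop produces a stationary fix cluster", {
  gb <- noiseless()
  gb$stop_rate_per_decision_point <- 50 # force stops
  found <- FALSE
  for (s in 1:10) {
    lg <- simulate_track(gb, rm_default, 1, seed = s)
    if (lg$truth$n_stops >= 1) {
      # at least 4 consecutive fixes within 1 m somewhere
      fx <- lg$fixes
      d <- haversine_m(fx$lat[-nrow(fx)], fx$lon[-nrow(fx)],
                       fx$lat[-1], fx$lon[-1])
      runs <- rle(d < 1)
      expect_true(any(runs$lengths[runs$values] >= 3))
      found <- TRUE
      break
    }
  }
  expect_true(found)
})

test_that("the app event protocol is respected", {
  lg <- simulate_track(default_group_behaviors()$OA, rm_default, 1, seed = 12)
  ev <- lg$fixes$event
  expect_equal(sum(ev == "start_close"), 1)
  expect_equal(sum(ev == "arrive"), 1)
  expect_equal(sum(ev == "qr_scan"), 1)
  expect_equal(sum(ev == "help_open"), sum(ev == "help_close"))
  i_close <- which(ev == "start_close")
  # map closes after at most 8 m walked or 18 s
  expect_lte(lg$fixes$t[i_close], 20)
  expect_lt(which(ev == "start_close"), which(ev == "arrive"))
})

test_that("unknown tracks and bad parameters are rejected", {
  expect_error(simulate_track(default_group_behaviors()$OA, rm_default, 99,
                              seed = 1), "absent")
  p <- wayfindr:::.draw_participant_params(default_group_behaviors()$OA, 1)
  p$speed <- NaN
  expect_error(simulate_track(p, rm_default, 1, seed = 1), "non-finite")
  expect_error(group_behavior("OA", 1.2, 0.1, p_wrong_turn = -0.2,
                              stop_rate_per_decision_point = 0.1), "finite")
})

test_that("the default cohort has the study design", {
  coh <- simulate_cohort(cohort_config(), seed = 2)
  expect_equal(nrow(coh$participants), 72)
  expect_equal(as.vector(table(coh$participants$group)[c("YA", "OA", "SCD")]),
               c(24, 25, 23))
  expect_length(coh$logs, 72 * 6)
  expect_equal(nrow(coh$truth), 72 * 6)
})

test_that("exclusion injections are flagged in exactly the right logs", {
  coh <- simulate_cohort(cohort_config(exclusions = "study"), seed = 2)
  # 9 flagged tracks
  expect_equal(nrow(coh$exclusions), 9)
  flagged <- vapply(coh$logs, function(l) length(l$flags) > 0, logical(1))
  expect_equal(sum(flagged), 9)
  # dropouts: 3 SCD participants with missing tracks, 5 analyzed ones in total
  n_logs <- table(vapply(coh$logs, `[[`, character(1), "participant_id"))
  short <- n_logs[n_logs < 6]
  expect_length(short, 3)
  miss_analyzed <- sum(vapply(names(short), function(id) {
    tks <- vapply(Filter(function(l) l$participant_id == id, coh$logs),
                  function(l) l$track_id, numeric(1))
    sum(!(1:5 %in% tks))
  }, numeric(1)))
  expect_equal(miss_analyzed, 5)
})

test_that("group sizes below one are rejected and ids unique", {
  expect_error(cohort_config(n = c(YA = 0, OA = 2, SCD = 2)), ">= 1")
  coh <- small_cohort()
  expect_false(anyDuplicated(coh$participants$participant_id) > 0)
})

test_that("stop counts follow the configured zero-inflated Poisson law", {
  # marginal zero fraction at the generator's own parameters, n = 10,000
  gb <- default_group_behaviors()$OA
  set.seed(123)
  n <- 10000
  dp <- 5
  rate <- gb$stop_rate_per_decision_point *
    exp(rnorm(n, 0, gb$sd_log_stop_rate)) # per-participant heterogeneity
  lam <- rate * dp
  y <- ifelse(runif(n) < gb$stop_zero_inflation, 0L, rpois(n, lam))
  p0_expected <- mean(gb$stop_zero_inflation +
                        (1 - gb$stop_zero_inflation) * exp(-lam))
  p0_obs <- mean(y == 0)
  mc_sd <- sqrt(p0_expected * (1 - p0_expected) / n)
  expect_lt(abs(p0_obs - p0_expected), 3 * mc_sd)
})

test_that("a doubled SCD stop rate yields more stops than OA", {
  # direct Monte-Carlo under the generator's own law (cheap surrogate of
  # whole-cohort simulation), 50 seeds
  wins <- 0
  for (s in 1:50) {
    set.seed(s)
    oa <- r_zip(200, 1.0, 0.25)
    scd <- r_zip(200, 2.0, 0.25)
    wins <- wins + (mean(scd) > mean(oa))
  }
  expect_gte(wins / 50, 0.95)
})

test_that("track logs roundtrip through CSV", {
  coh <- small_cohort(seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_track_logs(coh, path)
  logs2 <- parse_logs(path)
  expect_length(logs2, length(coh$logs))
  orig <- coh$logs[[7]]
  back <- logs2[[paste(orig$participant_id, orig$track_id, sep = "\r")]]
  expect_equal(back$fixes$lat, orig$fixes$lat)
  expect_equal(back$fixes$t, orig$fixes$t)
  expect_equal(back$group, orig$group)
})
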