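test_that("model specs build the intended formulas", {
  sp <- model_spec("stops", family = "zipoisson")
  expect_match(deparse1(sp$formula), "group \\+ familiarity \\+ sex")
  expect_match(deparse1(sp$formula), "1 \\| track_id")
  sp2 <- model_spec("stops", family = "zipoisson", decision_points = TRUE,
                    random = "participant")
  expect_match(deparse1(sp2$formula), "group \\* decision_points")
  expect_false(grepl("track_id", deparse1(sp2$formula)))
  sp3 <- model_spec("distance_m", transform = "log")
  expect_match(deparse1(sp3$formula), "^log\\(distance_m\\)")
})

test_that("zero-variance LMM reduces to ordinary least squares", {
  d <- sim_lmm_design(n_per_group = 20, sigma_p = 0, sigma_t = 0, seed = 5)
  fit <- fit_lmm(model_spec("y"), d)
  ols <- lm(y ~ group + familiarity + sex,
            data = transform(d, group = factor(group, c("OA", "SCD"))))
  keep <- !is.na(coef(ols))
  expect_equal(fit$coefficients$estimate[match(names(coef(ols))[keep],
                                               fit$coefficients$term)],
               unname(coef(ols)[keep]), tolerance = 1e-5)
})

test_that("LMM recovers simulated fixed and random effects", {
  ests <- vapply(1:25, function(s) {
    d <- sim_lmm_design(n_per_group = 50, beta_scd = 0.5, sigma_p = 0.3,
                        sigma_t = 0.2, seed = s)
    fit <- fit_lmm(model_spec("y"), d)
    c(beta = fit$coefficients$estimate[fit$coefficients$term == "groupSCD"],
      vp = unname(fit$varcomp["participant_id"]),
      vt = unname(fit$varcomp["track_id"]))
  }, numeric(3))
  mc_se <- apply(ests, 1, sd) / sqrt(ncol(ests))
  expect_lt(abs(mean(ests["beta", ]) - 0.5), 3 * mc_se["beta"])
  expect_lt(abs(mean(ests["vp", ]) - 0.09), max(3 * mc_se["vp"], 0.02))
  # track variance has only 5 levels: noisy, allow generous MC slack
  expect_lt(abs(mean(ests["vt", ]) - 0.04), max(3 * mc_se["vt"], 0.03))
})

test_that("Satterthwaite tests return positive df and match z in the limit", {
  d <- sim_lmm_design(n_per_group = 60, seed = 11)
  fit <- fit_lmm(model_spec("y"), d)
  st <- satterthwaite_tests(fit)
  expect_true(all(st$df > 0))
  # large df: t-test p close to the z-test p
  z_p <- 2 * pnorm(-abs(st$t))
  big <- st$df > 50
  expect_equal(st$p[big], z_p[big], tolerance = 0.01)
})

test_that("pi = 0, variance 0 ZIP matches a plain Poisson regression", {
  set.seed(21)
  n_p <- 100 # participants, 4 observations each, no participant effect
  g_p <- rep(c("OA", "SCD"), each = n_p / 2)
  d <- expand.grid(p = seq_len(n_p), track_id = 1:4)
  g <- g_p[d$p]
  y <- rpois(nrow(d), exp(0.3 + 0.6 * (g == "SCD")))
  d <- data.frame(participant_id = sprintf("P%03d", d$p), group = g,
                  track_id = d$track_id, stops = y, familiarity = 0,
                  sex = "female")
  spec <- model_spec("stops", family = "zipoisson", random = "participant",
                     covariates = character(0))
  fit <- suppressWarnings(fit_zigmm(spec, d))
  glm_fit <- glm(y ~ g, family = poisson())
  co <- fit$coefficients
  # the free zero-inflation intercept sits at the boundary and trades off
  # against the count intercept; compare marginal log-means
  expect_equal(co$estimate[co$term == "(Intercept)"] + log(1 - fit$zi_prob),
               unname(coef(glm_fit)[1]), tolerance = 1e-2)
  expect_equal(co$estimate[co$term == "groupSCD"],
               unname(coef(glm_fit)[2]), tolerance = 1e-2)
  expect_lt(fit$zi_prob, 0.05)
  expect_lt(fit$varcomp[["participant_id"]], 1e-4)
  # non-integer response is rejected
  d$stops <- d$stops + 0.5
  expect_error(fit_zigmm(spec, d), "counts")
})

test_that("ZIP mixed model recovers a group effect at the observed scale", {
  ests <- vapply(1:15, function(s) {
    d <- sim_zip_design(n_per_group = 50, beta_scd = 0.67, sigma_p = 0.6,
                        pi0 = 0.2, seed = s)
    spec <- model_spec("stops", family = "zipoisson", random = "participant")
    fit <- fit_zigmm(spec, d)
    fit$coefficients$estimate[fit$coefficients$term == "groupSCD"]
  }, numeric(1))
  mc_se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - 0.67), 3 * mc_se)
})

test_that("model comparison computes delta AIC and R2 per family", {
  d <- sim_lmm_design(n_per_group = 30, seed = 31)
  sp <- model_spec("y")
  sp0 <- sp
  sp0$formula <- update(sp$formula, . ~ . - group)
  full <- fit_lmm(sp, d)
  basic <- fit_lmm(sp0, d)
  cmp <- model_comparison(full, basic)
  expect_equal(cmp$delta_AIC, full$AIC - basic$AIC)
  expect_gte(cmp$R2, 0)
  expect_lte(cmp$R2, 1)
  expect_identical(cmp$R2_method, "marginal")
  # identical models: delta AIC 0
  cmp0 <- model_comparison(full, full)
  expect_equal(cmp0$delta_AIC, 0)
  # a null model explains ~ nothing
  expect_lt(basic$marginal_R2, 0.05)
})

test_that("the decision-point interaction is detected when planted", {
  # SCD stop rate grows with decision points, others flat
  simulate_dp <- function(seed, slope_scd = 0.2) {
    set.seed(seed)
    n <- 60
    g <- rep(c("OA", "SCD"), each = n / 2)
    u <- rnorm(n, 0, 0.4)
    d <- expand.grid(p = 1:n, track_id = 1:5)
    dp <- c(5, 3, 9, 4, 6)[d$track_id]
    eta <- -0.3 + u[d$p] + ifelse(g[d$p] == "SCD", slope_scd * (dp - 5.4), 0)
    fam <- round(runif(n, 0, 28))
    data.frame(participant_id = sprintf("P%03d", d$p), group = g[d$p],
               track_id = d$track_id, decision_points = dp,
               stops = r_zip(nrow(d), exp(eta), 0.2),
               familiarity = fam[d$p],
               sex = rep(c("f", "m"), length.out = nrow(d)))
  }
  hits <- 0
  for (s in 1:15) {
    fit <- suppressWarnings(decision_point_model(simulate_dp(s)))
    co <- fit$coefficients
    est <- co$estimate[co$term == "groupSCD:decision_points"]
    hits <- hits + (est > 0)
  }
  expect_gte(hits / 15, 0.9)
  # the coefficient set matches the interaction-model specification
  fit <- suppressWarnings(decision_point_model(simulate_dp(1)))
  expect_setequal(fit$coefficients$term,
                  c("(Intercept)", "groupSCD", "decision_points",
                    "familiarity", "sexm", "groupSCD:decision_points"))
})

test_that("the five performance models run on a simulated cohort", {
  coh <- simulate_cohort(cohort_config(n = c(YA = 8, OA = 8, SCD = 8)),
                         seed = 17)
  ing <- ingest_pipeline(coh)
  ft <- build_feature_table(ing$analysis_tracks, coh$route_map)
  mods <- suppressWarnings(fit_performance_models(ft$tracks, coh$participants))
  for (m in c("distance", "duration", "speed")) {
    expect_s3_class(mods[[m]]$full, "lmm_fit")
  }
  expect_s3_class(mods$map_views$full, "zigmm_fit")
  expect_s3_class(mods$stops$full, "zigmm_fit")
  for (m in c("distance", "duration", "speed", "map_views", "stops")) {
    expect_true(all(c("groupYA", "groupSCD") %in%
                      mods[[m]]$full$coefficients$term))
    expect_true(is.finite(mods[[m]]$comparison$delta_AIC))
  }
})
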