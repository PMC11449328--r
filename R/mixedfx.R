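#' Model specification for the group-difference mixed models
#'
#' Describes one of the five performance-measure models: response and
#' transform, distribution family, fixed effects (group with healthy older
#' adults as the reference level, campus familiarity, sex, optionally the
#' number of decision points and its interaction with group), and the
#' random-intercept structure (crossed participant and track intercepts, or
#' participant only).
#'
#' @param response column name of the response in the data.
#' @param transform `"identity"` or `"log"` (natural log).
#' @param family `"gaussian"`, `"zipoisson"` or `"zinegbin"` (zero-inflated
#'   Poisson / negative binomial with log link, intercept-only
#'   zero-inflation).
#' @param decision_points add a fixed effect for decision points and a
#'   group x decision-points interaction.
#' @param random `"participant_track"` (crossed intercepts) or
#'   `"participant"`.
#' @param covariates additional fixed-effect column names, default
#'   `c("familiarity", "sex")`.
#' @return a `model_spec` list with the model `formula`.
#' @export
model_spec <- function(response,
                       transform = c("identity", "log"),
                       family = c("gaussian", "zipoisson", "zinegbin"),
                       decision_points = FALSE,
                       random = c("participant_track", "participant"),
                       covariates = c("familiarity", "sex")) {
  transform <- match.arg(transform)
  family <- match.arg(family)
  random <- match.arg(random)
  lhs <- if (transform == "log") sprintf("log(%s)", response) else response
  grp <- if (decision_points) "group * decision_points" else "group"
  re <- if (random == "participant_track") {
    "(1 | participant_id) + (1 | track_id)"
  } else {
    "(1 | participant_id)"
  }
  f <- stats::as.formula(paste(lhs, "~", paste(c(grp, covariates), collapse = " + "),
                               "+", re))
  structure(list(response = response, transform = transform, family = family,
                 decision_points = decision_points, random = random,
                 covariates = covariates, formula = f),
            class = "model_spec")
}

# releveled copy of the data: OA is the reference group
.prep_model_data <- function(data) {
  stopifnot(all(c("participant_id") %in% names(data)))
  if (!is.null(data$group)) {
    lev <- intersect(c("OA", "YA", "SCD"), unique(as.character(data$group)))
    data$group <- factor(data$group, levels = lev)
  }
  if (!is.null(data$sex)) data$sex <- factor(data$sex)
  data
}

#' Fit a Gaussian linear mixed model
#'
#' Linear mixed model with the spec's fixed effects and random intercepts,
#' fitted by maximum likelihood (REML optional) via \pkg{lme4}/\pkg{lmerTest}.
#' Wald 95% confidence intervals (estimate +/- 1.96 SE) and two-sided
#' t-tests with Satterthwaite degrees of freedom are reported per fixed
#' effect; boundary variance estimates of 0 are legitimate.
#'
#' @param spec a [model_spec()] with `family = "gaussian"`.
#' @param data per-track feature rows joined with participant covariates.
#' @param REML use REML instead of ML, default FALSE.
#' @return object of class `lmm_fit`: `coefficients` (data frame with
#'   `estimate`, `se`, `ci_lo`, `ci_hi`, `df`, `t`, `p`), `varcomp` (named
#'   variances incl. residual), `loglik`, `AIC`, `marginal_R2`, `fit` (the
#'   merMod), `spec`.
#' @export
fit_lmm <- function(spec, data, REML = FALSE) {
  stopifnot(inherits(spec, "model_spec"), spec$family == "gaussian")
  data <- .prep_model_data(data)
  fit <- lmerTest::lmer(spec$formula, data = data, REML = REML)
  fe <- coef(summary(fit))
  coefs <- data.frame(
    term = rownames(fe),
    estimate = fe[, "Estimate"],
    se = fe[, "Std. Error"],
    ci_lo = fe[, "Estimate"] - 1.96 * fe[, "Std. Error"],
    ci_hi = fe[, "Estimate"] + 1.96 * fe[, "Std. Error"],
    df = fe[, "df"],
    t = fe[, "t value"],
    p = fe[, "Pr(>|t|)"],
    row.names = NULL
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  varcomp <- setNames(vc$vcov, ifelse(vc$grp == "Residual", "residual", vc$grp))
  structure(list(coefficients = coefs, varcomp = varcomp,
                 loglik = as.numeric(logLik(fit)), AIC = AIC(fit),
                 marginal_R2 = .marginal_r2(fit), fit = fit, spec = spec),
            class = "lmm_fit")
}

# marginal R^2: variance of the fixed-effect predictor over total variance
.marginal_r2 <- function(fit) {
  var_fix <- var(as.numeric(stats::model.matrix(fit) %*% lme4::fixef(fit)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_fix / (var_fix + sum(vc$vcov))
}

#' Satterthwaite tests for the fixed effects of an LMM
#'
#' Per-coefficient t statistics with Satterthwaite-approximated degrees of
#' freedom and two-sided p-values (via \pkg{lmerTest}). Falls back to
#' z-tests with a warning when the approximation fails.
#'
#' @param fit an `lmm_fit`.
#' @return data frame `term`, `t`, `df`, `p`.
#' @export
satterthwaite_tests <- function(fit) {
  stopifnot(inherits(fit, "lmm_fit"))
  co <- fit$coefficients
  if (any(!is.finite(co$df))) {
    warning("Satterthwaite df unavailable; using z-tests")
    co$p <- 2 * pnorm(-abs(co$t))
    co$df <- Inf
  }
  co[, c("term", "t", "df", "p")]
}

#' Fit a zero-inflated count mixed model
#'
#' Zero-inflated Poisson or negative-binomial mixed model with log link,
#' intercept-only zero inflation on the logit scale, and the spec's random
#' intercepts, fitted by maximum likelihood (Laplace approximation) via
#' \pkg{glmmTMB}. Count-part coefficients get Wald CIs and two-sided
#' z-tests.
#'
#' @param spec a [model_spec()] with a count family.
#' @param data per-track feature rows joined with participant covariates.
#' @return object of class `zigmm_fit`: `coefficients` (count part),
#'   `zi_intercept` (logit), `zi_prob`, `theta` (NB dispersion or NA),
#'   `varcomp`, `loglik`, `AIC`, `fit`, `spec`.
#' @export
fit_zigmm <- function(spec, data) {
  stopifnot(inherits(spec, "model_spec"),
            spec$family %in% c("zipoisson", "zinegbin"))
  y <- data[[spec$response]]
  if (any(y < 0) || any(y != round(y))) stop("response must be counts")
  data <- .prep_model_data(data)
  fam <- if (spec$family == "zipoisson") poisson() else glmmTMB::nbinom2()
  fit <- suppressWarnings(
    glmmTMB::glmmTMB(spec$formula, data = data, ziformula = ~1, family = fam))
  if (!is.finite(AIC(fit))) {
    # nlminb occasionally stalls on small samples; restart with BFGS
    fit <- suppressWarnings(glmmTMB::glmmTMB(
      spec$formula, data = data, ziformula = ~1, family = fam,
      control = glmmTMB::glmmTMBControl(optimizer = stats::optim,
                                        optArgs = list(method = "BFGS"))))
    if (!is.finite(AIC(fit))) {
      warning("zero-inflated fit did not converge to a finite AIC")
    }
  }
  sm <- summary(fit)
  fe <- sm$coefficients$cond
  coefs <- data.frame(
    term = rownames(fe),
    estimate = fe[, "Estimate"],
    se = fe[, "Std. Error"],
    ci_lo = fe[, "Estimate"] - 1.96 * fe[, "Std. Error"],
    ci_hi = fe[, "Estimate"] + 1.96 * fe[, "Std. Error"],
    z = fe[, "z value"],
    p = fe[, "Pr(>|z|)"],
    row.names = NULL
  )
  zi <- sm$coefficients$zi["(Intercept)", "Estimate"]
  vc <- glmmTMB::VarCorr(fit)$cond
  varcomp <- vapply(vc, function(m) as.numeric(m[1, 1]), numeric(1))
  structure(list(coefficients = coefs, zi_intercept = zi,
                 zi_prob = stats::plogis(zi),
                 theta = if (spec$family == "zinegbin")
                   glmmTMB::sigma(fit) else NA_real_,
                 varcomp = varcomp,
                 loglik = as.numeric(logLik(fit)), AIC = AIC(fit),
                 fit = fit, spec = spec),
            class = "zigmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("linear mixed model:", deparse(x$spec$formula), "\n")
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' @export
print.zigmm_fit <- function(x, ...) {
  cat(sprintf("zero-inflated %s mixed model (zi prob %.3f):\n",
              x$spec$family, x$zi_prob))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Compare a full model against its basic (no-group) model
#'
#' `delta_AIC = AIC_full - AIC_basic` (negative favors the full model).
#' For Gaussian models the marginal R-squared of the full model is
#' reported; for count models McFadden's pseudo R-squared
#' `1 - LL_full / LL_basic` (the pseudo R-squared method is not uniquely
#' defined; the choice is labeled in the output).
#'
#' @param full,basic fitted models (`lmm_fit` or `zigmm_fit`) on the same
#'   data, `basic` lacking the group term.
#' @return named list `delta_AIC`, `R2`, `R2_method`.
#' @export
model_comparison <- function(full, basic) {
  n_full <- stats::nobs(full$fit)
  n_basic <- stats::nobs(basic$fit)
  if (n_full != n_basic) stop("models were fitted to different data")
  if (inherits(full, "lmm_fit")) {
    list(delta_AIC = full$AIC - basic$AIC, R2 = full$marginal_R2,
         R2_method = "marginal")
  } else {
    list(delta_AIC = full$AIC - basic$AIC,
         R2 = 1 - full$loglik / basic$loglik,
         R2_method = "McFadden")
  }
}

#' Decision-point interaction model of orientation stops
#'
#' Zero-inflated Poisson mixed model of per-track orientation stops with
#' fixed effects for group, the number of decision points, their
#' interaction, familiarity and sex, and a participant random intercept.
#' A positive SCD x decision-points coefficient indicates that SCD
#' patients' stops increase more steeply with intersection density.
#'
#' @param data feature rows joined with participant covariates and
#'   per-track `decision_points`.
#' @param response response column, default `"stops"`.
#' @return a `zigmm_fit` containing the interaction coefficients.
#' @export
decision_point_model <- function(data, response = "stops") {
  spec <- model_spec(response, family = "zipoisson", decision_points = TRUE,
                     random = "participant")
  fit_zigmm(spec, data)
}

#' Fit the five performance-measure models
#'
#' Fits, per performance measure, the full mixed model (group + familiarity
#' + sex, crossed participant/track intercepts) and the basic model without
#' the group term: log-linear mixed models for wayfinding distance and
#' duration, a linear mixed model for movement speed, a zero-inflated
#' negative-binomial model for map views, and a zero-inflated Poisson model
#' for orientation stops.
#'
#' @param features per-track feature table (`$tracks` of
#'   [build_feature_table()]).
#' @param participants data frame with `participant_id`, `group`, `sex`,
#'   `familiarity`.
#' @return list with one element per measure: `full`, `basic`,
#'   `comparison`; plus `data` (the merged model frame).
#' @export
fit_performance_models <- function(features, participants) {
  data <- merge(features, participants[, c("participant_id", "sex",
                                           "familiarity")],
                by = "participant_id")
  specs <- list(
    distance  = model_spec("distance_m", transform = "log"),
    duration  = model_spec("duration_s", transform = "log"),
    speed     = model_spec("speed_mps"),
    map_views = model_spec("map_views", family = "zinegbin"),
    stops     = model_spec("stops", family = "zipoisson")
  )
  out <- lapply(specs, function(sp) {
    basic_sp <- sp
    basic_sp$formula <- update(sp$formula, . ~ . - group)
    fitter <- if (sp$family == "gaussian") fit_lmm else fit_zigmm
    full <- fitter(sp, data)
    basic <- fitter(basic_sp, data)
    list(full = full, basic = basic,
         comparison = model_comparison(full, basic))
  })
  out$data <- data
  out
}
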