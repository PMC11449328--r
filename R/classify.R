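#' Logistic regression of SCD status on orientation stops
#'
#' Maximum-likelihood logistic regression (IRLS via [stats::glm()]) of a
#' binary status indicator on a single predictor (in the pipeline: the mean
#' number of orientation stops per completed track). Reports the slope's
#' odds ratio with a Wald 95% CI and the likelihood-ratio test against the
#' intercept-only model. Complete separation is flagged rather than
#' silently diverging.
#'
#' @param x numeric predictor.
#' @param y binary outcome (0/1, logical, or a 2-level factor; the second
#'   level / 1 is the positive class).
#' @return object of class `logistic_fit`: `coefficients` (intercept and
#'   slope with `se`, `ci_lo`, `ci_hi`, `z`, `p`), `odds_ratio` with CI,
#'   `lr_chisq`, `lr_df`, `lr_p`, `separation` flag, `fit` (the glm).
#' @export
fit_logistic <- function(x, y) {
  y <- .as_binary(y)
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (length(y) < 10) stop("need n >= 10")
  fit <- suppressWarnings(glm(y ~ x, family = binomial()))
  sep <- !fit$converged || any(abs(coef(fit)) > 20)
  if (sep) {
    warning("possible complete separation; estimates unreliable ",
            "(consider a penalized refit)")
  }
  sm <- coef(summary(fit))
  coefs <- data.frame(
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    se = sm[, "Std. Error"],
    ci_lo = sm[, "Estimate"] - 1.96 * sm[, "Std. Error"],
    ci_hi = sm[, "Estimate"] + 1.96 * sm[, "Std. Error"],
    z = sm[, "z value"],
    p = sm[, "Pr(>|z|)"],
    row.names = NULL
  )
  null <- glm(y ~ 1, family = binomial())
  lr <- as.numeric(2 * (logLik(fit) - logLik(null)))
  structure(list(
    coefficients = coefs,
    odds_ratio = exp(coefs$estimate[2]),
    odds_ratio_ci = exp(c(coefs$ci_lo[2], coefs$ci_hi[2])),
    lr_chisq = lr, lr_df = 1, lr_p = pchisq(lr, 1, lower.tail = FALSE),
    separation = sep, fit = fit
  ), class = "logistic_fit")
}

.as_binary <- function(y) {
  if (is.factor(y)) as.integer(y == levels(y)[2])
  else if (is.logical(y)) as.integer(y)
  else {
    stopifnot(all(y %in% c(0, 1)))
    as.integer(y)
  }
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("logistic fit: OR=%.2f (95%% CI %.2f-%.2f), LR chi^2(1)=%.2f, p=%.4f\n",
              x$odds_ratio, x$odds_ratio_ci[1], x$odds_ratio_ci[2],
              x$lr_chisq, x$lr_p))
  invisible(x)
}

#' Leave-one-out cross-validated classification accuracy
#'
#' Refits the univariate logistic model n times, each time excluding one
#' observation, and classifies the left-out observation as positive when
#' its predicted probability reaches `threshold`. A non-convergent refit
#' counts the fold as incorrect, with a warning. The accuracy CI is a Wald
#' binomial interval; the method is recorded in the output since interval
#' choices differ between conventions.
#'
#' @param x numeric predictor.
#' @param y binary outcome.
#' @param threshold classification threshold on the predicted probability,
#'   default 0.5.
#' @return list `accuracy`, `ci` (Wald 95%), `ci_method`, `n_correct`,
#'   `n_total`, `majority_rate`, `predictions` (per-fold data frame).
#' @export
loo_accuracy <- function(x, y, threshold = 0.5) {
  y <- .as_binary(y)
  if (min(table(y)) < 3) stop("need at least 3 observations per class")
  n <- length(y)
  pred <- numeric(n)
  for (i in seq_len(n)) {
    fit_i <- suppressWarnings(glm(y[-i] ~ x[-i], family = binomial()))
    if (!fit_i$converged) {
      warning("fold ", i, " did not converge; counted as incorrect")
      pred[i] <- NA
    } else {
      eta <- coef(fit_i)[1] + coef(fit_i)[2] * x[i]
      pred[i] <- stats::plogis(eta)
    }
  }
  correct <- !is.na(pred) & ((pred >= threshold) == (y == 1))
  acc <- sum(correct) / n
  se <- sqrt(acc * (1 - acc) / n)
  list(accuracy = acc,
       ci = c(max(0, acc - 1.96 * se), min(1, acc + 1.96 * se)),
       ci_method = "wald",
       n_correct = sum(correct), n_total = n,
       majority_rate = max(table(y)) / n,
       predictions = data.frame(x = x, y = y, prob = pred, correct = correct))
}

#' ROC analysis with DeLong confidence interval
#'
#' ROC curve over thresholds at midpoints between consecutive distinct
#' predictor values (plus the infinities), AUC by the Mann-Whitney
#' estimator with ties counted 1/2, and DeLong SE and 95% CI, via
#' \pkg{pROC}. Direction is fixed: higher predictor values indicate the
#' positive class. A constant predictor yields AUC 0.5 with a warning.
#'
#' @param x numeric predictor (e.g. mean orientation stops).
#' @param y binary outcome (positive class = 1).
#' @return object of class `roc_result`: `points` (data frame `threshold`,
#'   `sensitivity`, `specificity`), `auc`, `auc_se`, `auc_ci`, `roc` (the
#'   pROC object or NULL).
#' @export
roc_auc <- function(x, y) {
  y <- .as_binary(y)
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (length(unique(x)) < 2) {
    warning("constant predictor; AUC is 0.5")
    return(structure(list(
      points = data.frame(threshold = c(-Inf, Inf), sensitivity = c(1, 0),
                          specificity = c(0, 1)),
      auc = 0.5, auc_se = NA_real_, auc_ci = c(NA_real_, NA_real_),
      roc = NULL), class = "roc_result"))
  }
  r <- pROC::roc(response = y, predictor = x, levels = c(0, 1),
                 direction = "<", quiet = TRUE)
  # pROC warns that SE/CI of a degenerate AUC = 1 curve are trivial; the
  # values themselves are correct
  ci <- suppressWarnings(as.numeric(pROC::ci.auc(r, method = "delong")))
  se <- suppressWarnings(sqrt(pROC::var(r, method = "delong")))
  pts <- data.frame(threshold = r$thresholds,
                    sensitivity = r$sensitivities,
                    specificity = r$specificities)
  pts <- pts[order(pts$threshold), ]
  rownames(pts) <- NULL
  structure(list(points = pts, auc = as.numeric(pROC::auc(r)),
                 auc_se = se, auc_ci = ci[c(1, 3)], roc = r),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC=%.3f (SE=%.3f, 95%% CI %.2f-%.2f), %d thresholds\n",
              x$auc, x$auc_se, x$auc_ci[1], x$auc_ci[2], nrow(x$points)))
  invisible(x)
}

#' Constrained optimal cutpoints on a ROC curve
#'
#' Two cutpoints: the threshold maximizing sensitivity subject to
#' specificity >= `min_constraint`, and the threshold maximizing
#' specificity subject to sensitivity >= `min_constraint`. Ties are broken
#' towards the higher constrained metric, then the lower threshold. An
#' explicit empty result is returned when no threshold meets a constraint.
#'
#' @param roc a `roc_result`.
#' @param min_constraint floor for the constrained metric, default 0.5.
#' @return list `max_sensitivity` and `max_specificity`, each a one-row
#'   data frame (`threshold`, `sensitivity`, `specificity`) or NULL when
#'   infeasible.
#' @export
select_cutpoints <- function(roc, min_constraint = 0.5) {
  pts <- roc$points
  pick <- function(target, constrained) {
    ok <- pts[pts[[constrained]] >= min_constraint, , drop = FALSE]
    if (!nrow(ok)) return(NULL)
    ok <- ok[order(-ok[[target]], -ok[[constrained]], ok$threshold), ,
             drop = FALSE]
    ok[1, c("threshold", "sensitivity", "specificity")]
  }
  list(max_sensitivity = pick("sensitivity", "specificity"),
       max_specificity = pick("specificity", "sensitivity"))
}

#' End-to-end SCD classification from participant features
#'
#' Restricts to the two older-adult groups, uses the mean orientation stops
#' per completed track as the predictor and SCD membership as the outcome,
#' and runs the full classifier evaluation: logistic fit, LOO accuracy,
#' ROC/AUC, constrained cutpoints.
#'
#' @param participant_features `$participants` of [build_feature_table()].
#' @param groups the two classes, negative first; default `c("OA", "SCD")`.
#' @return list `fit`, `loo`, `roc`, `cutpoints`, `data`.
#' @export
classify_scd <- function(participant_features, groups = c("OA", "SCD")) {
  d <- participant_features[participant_features$group %in% groups, ,
                            drop = FALSE]
  x <- d$stops_per_track
  y <- as.integer(d$group == groups[2])
  fit <- fit_logistic(x, y)
  roc <- roc_auc(x, y)
  list(fit = fit,
       loo = loo_accuracy(x, y),
       roc = roc,
       cutpoints = select_cutpoints(roc),
       data = data.frame(participant_id = d$participant_id, x = x, y = y))
}
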