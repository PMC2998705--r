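# Inverse-regression age prediction with nonparametric bootstrap confidence
# intervals and leave-one-out cross-validation.

#' Plug-in inverse-regression age prediction
#'
#' Inverts the calibration line: `age = (v - alpha) / beta` where `v` is
#' the sample's redundancy-variate score under the trained model. The
#' estimate is returned unclipped: negative ages (and ages beyond the
#' training range) are possible and expected for individuals near the
#' boundary, simply as a result of calibration error.
#'
#' @param model a fitted `age_model` (see [fit_age_model()]).
#' @param x one sample's logcontrast values (named vector) or a matrix with
#'   samples in rows.
#' @param beta_tol invertibility tolerance relative to the unit training
#'   variate SD (default 1e-8).
#' @return numeric vector of plug-in age estimates (days).
#' @export
predict_age <- function(model, x, beta_tol = 1e-8) {
  .check(inherits(model, "age_model"), "model must be a fitted age_model")
  if (abs(model$beta) <= beta_tol) {
    .err("calibration slope is numerically zero; the model cannot be inverted",
         "mozage_model_error")
  }
  (score_variate(model, x) - model$alpha) / model$beta
}

# One bootstrap replicate: resample individuals with replacement, refit the
# whole chain (standardization, redundancy weights, calibration line), and
# predict the fixed held-out sample. Returns NA for a degenerate resample.
.boot_one <- function(X, ages, x, n, prediction_interval, beta_tol) {
  idx <- sample.int(n, n, replace = TRUE)
  f <- .chain_fit(X[idx, , drop = FALSE], ages[idx])
  if (is.null(f) || abs(f$beta) <= beta_tol) return(NA_real_)
  v <- sum(f$w * (x - f$mu) / f$s)
  e <- if (prediction_interval) f$residuals[sample.int(n, 1L)] else 0
  (v - e - f$alpha) / f$beta
}

#' Bootstrap age prediction with percentile confidence interval
#'
#' Nonparametric pairs bootstrap: the `n` training individuals are
#' resampled with replacement `B` times; for each resample the whole
#' estimation chain (standardization constants, redundancy weights,
#' calibration line) is refitted and the held-out sample's age recomputed.
#' The 95% confidence interval is the 2.5th-97.5th percentile of the `B`
#' estimates and the predicted age is their median (which by construction
#' lies inside the interval).
#'
#' With `interval = "prediction"` (the default) each replicate additionally
#' resamples one calibration residual from the refitted model and perturbs
#' the held-out score by it before inversion, so the interval represents
#' the error of the age prediction itself — model uncertainty plus the
#' individual-level spread around the calibration line. With
#' `interval = "calibration"` only the refitted chain varies, giving a
#' narrower interval that reflects model uncertainty alone. Both collapse
#' to zero width on noise-free data.
#'
#' Resamples with constant age, no age association, or a numerically zero
#' slope are rejected and redrawn (the redraw count is returned); more than
#' 50% degenerate draws is an error.
#'
#' @param X training logcontrast matrix (individuals x genes).
#' @param ages known training ages (days).
#' @param x the new sample's logcontrast values (named numeric vector).
#' @param B number of bootstrap replicates (>= 100; default 1000).
#' @param seed integer seed; results are deterministic given the seed.
#' @param interval `"prediction"` (default) or `"calibration"`; see
#'   Details.
#' @param sample_id optional id stored in the result.
#' @param conf confidence level (default 0.95).
#' @param beta_tol slope invertibility tolerance.
#' @return object of class `age_prediction`: list with `sample_id`,
#'   `plug_in_age`, `predicted_age` (bootstrap median), `ci_low`,
#'   `ci_high`, `n_bootstrap`, `n_redraws`, `seed`.
#' @export
bootstrap_predict <- function(X, ages, x, B = 1000, seed = 1L,
                              interval = c("prediction", "calibration"),
                              sample_id = NA_character_, conf = 0.95,
                              beta_tol = 1e-8) {
  X <- .as_logcontrast_matrix(X)
  interval <- match.arg(interval)
  # canonical row order: resampling then depends only on the set of training
  # individuals, not on the order they were supplied in
  if (!is.null(rownames(X))) {
    ord <- order(rownames(X))
    X <- X[ord, , drop = FALSE]
    ages <- ages[ord]
  }
  .check(.is_count(B, min = 100L), "B must be an integer >= 100", "mozage_config_error")
  .check(.is_number(conf) && conf > 0 && conf < 1, "conf must lie in (0, 1)",
         "mozage_config_error")
  n <- nrow(X)
  .check(length(ages) == n && all(is.finite(ages)), "ages must match rows of X")
  full <- fit_age_model(X, ages)
  xv <- x
  if (!is.null(names(xv))) xv <- xv[full$redundancy$gene_ids]
  .check(length(xv) == ncol(X) && all(is.finite(xv)),
         "x must provide a finite value for every model gene", "mozage_data_error")
  xv <- as.numeric(xv)
  plug_in <- predict_age(full, stats::setNames(xv, full$redundancy$gene_ids),
                         beta_tol = beta_tol)
  pred_int <- interval == "prediction"
  est <- numeric(B)
  n_redraws <- 0L
  max_redraws <- ceiling(B)                     # >50% degenerate -> error
  withr::with_seed(seed, {
    for (b in seq_len(B)) {
      repeat {
        val <- .boot_one(X, ages, xv, n, pred_int, beta_tol)
        if (!is.na(val)) break
        n_redraws <- n_redraws + 1L
        if (n_redraws > max_redraws) {
          .err("more than 50% of bootstrap resamples were degenerate",
               "mozage_data_error")
        }
      }
      est[b] <- val
    }
  })
  qs <- stats::quantile(est, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  structure(list(sample_id = sample_id, plug_in_age = plug_in,
                 predicted_age = stats::median(est),
                 ci_low = qs[1], ci_high = qs[2],
                 n_bootstrap = B, n_redraws = n_redraws, seed = seed,
                 interval = interval),
            class = "age_prediction")
}

#' @export
print.age_prediction <- function(x, ...) {
  cat(sprintf("Age prediction%s: %.2f days (95%% CI %.2f to %.2f; plug-in %.2f; B = %d)\n",
              if (is.na(x$sample_id)) "" else paste0(" for ", x$sample_id),
              x$predicted_age, x$ci_low, x$ci_high, x$plug_in_age, x$n_bootstrap))
  invisible(x)
}

#' Leave-one-out cross-validation of the age-grading assay
#'
#' Each individual is removed in turn; the redundancy model and calibration
#' line are refitted on the remaining `n - 1` individuals and the held-out
#' individual's age predicted, with a bootstrap confidence interval when
#' `B >= 100` (set `B = 0` for fast plug-in-only validation). Per-sample
#' bootstrap seeds are derived deterministically from the master seed and
#' the sample id, so results do not depend on sample order.
#'
#' @param X logcontrast matrix of known-age individuals (rownames used as
#'   sample ids).
#' @param ages known ages (days).
#' @param B bootstrap replicates per fold (0 = plug-in only; default 500).
#' @param seed master seed.
#' @param interval see [bootstrap_predict()].
#' @param conf confidence level.
#' @return object of class `validation_report`: list with `predictions`
#'   (per-sample data frame: `sample_id`, `true_age`, `plug_in_age`,
#'   `predicted_age`, `ci_low`, `ci_high`, `residual` = predicted - true,
#'   `error`), `mean_abs_residual` (days), `mean_ci_halfwidth` (days, NA if
#'   `B = 0`), `n`, `B`, `seed`. Per-fold failures are recorded in the
#'   `error` column, not fatal to the run.
#' @examples
#' sim <- simulate_qpcr(qpcr_sim_config(seed = 11, sigma_biological = 0,
#'                                      sigma_technical = 0))
#' lc <- logcontrast(aggregate_replicates(sim$ct))
#' fem <- sim$samples[sim$samples$sex == "F", ]
#' rep <- loocv(lc[fem$sample_id, ], fem$age_days, B = 0)
#' rep$mean_abs_residual   # ~0: the noise-free model is exact
#' @export
loocv <- function(X, ages, B = 500, seed = 1L,
                  interval = c("prediction", "calibration"), conf = 0.95) {
  X <- .as_logcontrast_matrix(X)
  interval <- match.arg(interval)
  n <- nrow(X)
  p <- ncol(X)
  .check(length(ages) == n && all(is.finite(ages)), "ages must match rows of X")
  .check(n >= p + 3, sprintf("need n >= p + 3 individuals (n = %d, p = %d)", n, p),
         "mozage_model_error")
  .check(B == 0 || .is_count(B, min = 100L), "B must be 0 or an integer >= 100",
         "mozage_config_error")
  ids <- rownames(X)
  if (is.null(ids)) ids <- sprintf("sample%03d", seq_len(n))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    xi <- stats::setNames(X[i, ], colnames(X))
    res <- tryCatch({
      if (B >= 100) {
        bp <- bootstrap_predict(X[-i, , drop = FALSE], ages[-i], xi, B = B,
                                seed = .child_seed(seed, ids[i]),
                                interval = interval, sample_id = ids[i],
                                conf = conf)
        data.frame(sample_id = ids[i], true_age = ages[i],
                   plug_in_age = bp$plug_in_age, predicted_age = bp$predicted_age,
                   ci_low = bp$ci_low, ci_high = bp$ci_high,
                   error = NA_character_, stringsAsFactors = FALSE)
      } else {
        m <- fit_age_model(X[-i, , drop = FALSE], ages[-i])
        pa <- predict_age(m, xi)
        data.frame(sample_id = ids[i], true_age = ages[i],
                   plug_in_age = pa, predicted_age = pa,
                   ci_low = NA_real_, ci_high = NA_real_,
                   error = NA_character_, stringsAsFactors = FALSE)
      }
    }, error = function(e) {
      data.frame(sample_id = ids[i], true_age = ages[i],
                 plug_in_age = NA_real_, predicted_age = NA_real_,
                 ci_low = NA_real_, ci_high = NA_real_,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
    rows[[i]] <- res
  }
  pred <- do.call(rbind, rows)
  pred$residual <- pred$predicted_age - pred$true_age
  ok <- !is.na(pred$predicted_age)
  structure(list(
    predictions = pred,
    mean_abs_residual = mean(abs(pred$residual[ok])),
    mean_ci_halfwidth = if (B >= 100) mean((pred$ci_high - pred$ci_low)[ok] / 2)
                        else NA_real_,
    n = n, B = B, seed = seed, interval = interval),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Leave-one-out validation (n = %d, B = %d)\n", x$n, x$B))
  cat(sprintf("  mean |residual|: %.2f days\n", x$mean_abs_residual))
  if (!is.na(x$mean_ci_halfwidth)) {
    cat(sprintf("  mean 95%% CI halfwidth: +/- %.2f days\n", x$mean_ci_halfwidth))
  }
  fails <- sum(!is.na(x$predictions$error))
  if (fails > 0) cat(sprintf("  failed folds: %d\n", fails))
  invisible(x)
}

#' Residual-versus-predicted-age bias diagnostic
#'
#' Regresses the signed cross-validation residuals on predicted age; a
#' curved (misspecified) age-expression relationship shows up as a
#' significant slope. Note that even under a perfectly specified model this
#' slope has a positive expectation of roughly
#' `Var(error)/(Var(age) + Var(error))`: inverse-regression estimates
#' spread beyond the true age range, so large predictions tend to
#' overshoot and small ones undershoot. The regression of residuals on
#' *true* age, reported alongside, is free of this artefact and is the
#' cleaner null check when true ages are available.
#'
#' @param report a [loocv()] `validation_report` (or a data frame with
#'   `predicted_age` and `residual` columns, optionally `true_age`).
#' @return list with `bias_slope`, `bias_intercept`, `slope_p_value` (the
#'   regression on predicted age), `true_age_slope`, `true_age_p_value`
#'   (on true age; NA if true ages are absent), and `table` (per-point
#'   data frame `sample_id`, `predicted_age`, `residual`, suitable for
#'   plotting or writing to CSV).
#' @export
bias_diagnostic <- function(report) {
  pred <- if (inherits(report, "validation_report")) report$predictions else report
  .check(is.data.frame(pred) && all(c("predicted_age", "residual") %in% names(pred)),
         "report must contain predicted_age and residual")
  pred <- pred[!is.na(pred$predicted_age) & !is.na(pred$residual), , drop = FALSE]
  .check(nrow(pred) >= 3, "need >= 3 predictions for the bias diagnostic",
         "mozage_data_error")
  if (stats::sd(pred$predicted_age) == 0) {
    .err("predicted ages are constant; bias regression undefined", "mozage_data_error")
  }
  fit <- stats::lm(residual ~ predicted_age, data = pred)
  sm <- summary(fit)$coefficients
  ta_slope <- ta_p <- NA_real_
  if ("true_age" %in% names(pred) && stats::sd(pred$true_age) > 0) {
    fit_ta <- stats::lm(residual ~ true_age, data = pred)
    sm_ta <- summary(fit_ta)$coefficients
    ta_slope <- unname(coef(fit_ta)[2])
    ta_p <- unname(sm_ta["true_age", "Pr(>|t|)"])
  }
  list(bias_slope = unname(coef(fit)[2]),
       bias_intercept = unname(coef(fit)[1]),
       slope_p_value = unname(sm["predicted_age", "Pr(>|t|)"]),
       true_age_slope = ta_slope,
       true_age_p_value = ta_p,
       table = pred[, intersect(c("sample_id", "true_age", "predicted_age", "residual"),
                                names(pred)), drop = FALSE])
}
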