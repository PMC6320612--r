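#' Cross-validated fitter wrappers
#'
#' Adapters with the uniform `(features, scores, seed, ...)` signature that
#' [crossval_estimates()] expects.
#'
#' @param features feature data frame (only the columns each model uses are
#'   consumed).
#' @param scores expert scores.
#' @param seed RNG seed (ignored by the deterministic proxy fit).
#' @param ... forwarded to the underlying fitter.
#' @return a fitted score model.
#' @export
fit_activity_proxy <- function(features, scores, seed = NULL, ...) {
  calibrate_activity_proxy(features$rms_env, scores, ...)
}

#' Run the full static-test analysis on a feature table
#'
#' Fits the activity-level proxy and the rebalanced spasm-severity model
#' and produces 10-fold out-of-fold estimates for both, plus the derived
#' laterality-of-activity estimates, in one tidy estimates table ready for
#' [evaluation_report()].
#'
#' @param features feature table from [cohort_features()] on a static
#'   cohort (must carry `activity_level` and `spasm_severity` score columns
#'   and the static feature columns).
#' @param seed RNG seed driving fold splits and rebalancing draws.
#' @param k number of cross-validation folds.
#' @return a list: `estimates` (data frame with `test`, `score_type`,
#'   `model_kind`, `estimate`, `score` and the trial keys), `models` (the
#'   full-data fits), `report` (the [evaluation_report()]).
#' @export
run_static_analysis <- function(features, seed = NULL, k = 10) {
  act <- crossval_estimates(features, features$activity_level,
                            fit_activity_proxy, k = k, seed = seed)
  spa <- crossval_estimates(features, features$spasm_severity,
                            fit_spasm_model, k = k,
                            seed = if (is.null(seed)) NULL else seed + 1000L)
  keys <- features[, c("trial_id", "subject_id", "test", "muscle", "side")]
  est <- rbind(
    cbind(keys, score_type = "activity_level", model_kind = "linear",
          estimate = as.numeric(act), score = features$activity_level),
    cbind(keys, score_type = "spasm_severity", model_kind = "linear",
          estimate = as.numeric(spa), score = features$spasm_severity)
  )
  est <- rbind(est, derive_laterality_estimates(est))
  models <- list(
    activity = fit_activity_proxy(features, features$activity_level),
    spasm = fit_spasm_model(features, features$spasm_severity, seed = seed)
  )
  list(estimates = est, models = models, report = evaluation_report(est))
}

#' Run the full dynamic-test analysis on a feature table
#'
#' Produces 10-fold out-of-fold estimates of the activity-level and
#' amplitude-modulation scores with the rebalanced linear model and/or the
#' bagged-tree model, plus the derived laterality estimates.
#'
#' @param features feature table from [cohort_features()] on a dynamic
#'   cohort.
#' @param seed RNG seed.
#' @param model_kind `"forest"`, `"linear"` or `"both"`.
#' @param k number of cross-validation folds.
#' @return as [run_static_analysis()].
#' @export
run_dynamic_analysis <- function(features, seed = NULL,
                                 model_kind = c("forest", "linear", "both"),
                                 k = 10) {
  model_kind <- match.arg(model_kind)
  kinds <- if (model_kind == "both") c("linear", "forest") else model_kind
  keys <- features[, c("trial_id", "subject_id", "test", "muscle", "side")]
  est <- NULL
  models <- list()
  off <- 0L
  for (kind in kinds) {
    fitter <- if (kind == "forest") fit_dynamic_forest else fit_dynamic_linear
    for (st in c("activity_level", "amplitude_modulation")) {
      off <- off + 1000L
      oof <- crossval_estimates(features[, dynamic_feature_names],
                                features[[st]], fitter, k = k,
                                seed = if (is.null(seed)) NULL else seed + off)
      est <- rbind(est, cbind(keys, score_type = st, model_kind = kind,
                              estimate = as.numeric(oof),
                              score = features[[st]]))
      models[[paste(kind, st, sep = ".")]] <-
        fitter(features[, dynamic_feature_names], features[[st]],
               seed = if (is.null(seed)) NULL else seed + off,
               score_type = st)
    }
    est <- rbind(est, derive_laterality_estimates(
      est[est$model_kind == kind & est$score_type == "activity_level", ]))
  }
  list(estimates = est, models = models, report = evaluation_report(est))
}

# Turn per-side activity estimates into laterality-of-activity rows:
# |right - left| of both the estimates and the expert scores, per trial.
derive_laterality_estimates <- function(est) {
  act <- est[est$score_type == "activity_level", ]
  out <- NULL
  for (kind in unique(act$model_kind)) {
    a <- act[act$model_kind == kind, ]
    left <- a[a$side == "left", ]
    right <- a[a$side == "right", ]
    right <- right[match(left$trial_id, right$trial_id), ]
    keep <- !is.na(right$trial_id)
    left <- left[keep, ]; right <- right[keep, ]
    if (nrow(left) == 0L) next
    out <- rbind(out, data.frame(
      trial_id = left$trial_id, subject_id = left$subject_id,
      test = left$test, muscle = left$muscle, side = "both",
      score_type = "laterality_of_activity", model_kind = kind,
      estimate = laterality(left$estimate, right$estimate),
      score = laterality(left$score, right$score)
    ))
  }
  out
}
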