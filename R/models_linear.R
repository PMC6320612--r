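#' Rebalance a heavily skewed ordinal-score training set
#'
#' The distribution of clinical scores is strongly zero-inflated (most
#' muscles at rest show no spasms), so an unweighted fit tracks the majority
#' class and ignores the rare high scores. Following the standard
#' down-sampling remedy, the majority class is randomly down-sampled
#' *without replacement* to 10% of the total sample count; this is repeated
#' `n_repeats` times to give `n_repeats` training sets whose fitted
#' coefficients are later averaged.
#'
#' @param scores integer vector of 0-10 scores.
#' @param n_repeats number of rebalanced training sets.
#' @param frac target majority-class size as a fraction of the total sample
#'   count.
#' @param majority_class the class to down-sample. Defaults to the class
#'   with the largest number of instances; for spasm severity this is the
#'   score-0 class.
#' @param seed RNG seed; identical seeds give identical training sets.
#' @return a list of `n_repeats` integer index vectors into `scores`. When
#'   the majority class is already at or below the target size, every set is
#'   the full data set.
#' @export
rebalance_datasets <- function(scores, n_repeats = 10, frac = 0.10,
                               majority_class = NULL, seed = NULL) {
  if (anyNA(scores) || any(scores != round(scores) | scores < 0 | scores > 10))
    stop("scores must be integers in 0..10", call. = FALSE)
  n <- length(scores)
  if (is.null(majority_class)) {
    tab <- table(scores)
    majority_class <- as.numeric(names(tab)[which.max(tab)])
  }
  maj_idx <- which(scores == majority_class)
  other_idx <- which(scores != majority_class)
  target <- round(frac * n)
  if (target < 1L)
    stop("majority-class target size is below 1 sample; increase `frac` or n",
         call. = FALSE)
  if (length(maj_idx) <= target)
    return(replicate(n_repeats, seq_len(n), simplify = FALSE))
  with_seed(seed, lapply(seq_len(n_repeats), function(i)
    sort(c(other_idx, sample(maj_idx, target)))))
}

# Average OLS fits over rebalanced training sets. X: numeric data frame,
# y: scores; rows with y > max_fit_score are excluded from fitting (but not
# from prediction downstream). Also returns averaged standardized
# coefficients with t-based 95% CIs.
fit_rebalanced_ols <- function(X, y, n_repeats = 10, frac = 0.10,
                               majority_class = NULL, max_fit_score = NULL,
                               seed = NULL) {
  X <- as.data.frame(X)
  if (any(!vapply(X, is.numeric, logical(1))))
    stop("all feature columns must be numeric", call. = FALSE)
  sets <- rebalance_datasets(y, n_repeats = n_repeats, frac = frac,
                             majority_class = majority_class, seed = seed)
  p <- ncol(X)
  coefs <- matrix(NA_real_, length(sets), p + 1L)
  std_coefs <- matrix(NA_real_, length(sets), p)
  std_se <- matrix(NA_real_, length(sets), p)
  dfs <- numeric(length(sets))
  for (i in seq_along(sets)) {
    idx <- sets[[i]]
    if (!is.null(max_fit_score)) idx <- idx[y[idx] <= max_fit_score]
    Xi <- as.matrix(X[idx, , drop = FALSE])
    yi <- y[idx]
    if (var(yi) == 0)
      stop("degenerate training set: all scores identical", call. = FALSE)
    M <- cbind(`(Intercept)` = 1, Xi)
    if (qr(M)$rank < ncol(M))
      stop("feature columns are not linearly independent", call. = FALSE)
    fit <- lm.fit(M, yi)
    coefs[i, ] <- fit$coefficients
    # standardized coefficients: fit on z-scored predictors and response
    Zs <- scale(Xi)
    ys <- as.numeric(scale(yi))
    sfit <- lm(ys ~ Zs)
    # summary() warns on exact fits (zero residual variance); the SEs are
    # still the quantities we report, so keep the computation quiet
    sm <- withCallingHandlers(
      summary(sfit)$coefficients,
      warning = function(w) {
        if (grepl("essentially perfect fit", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    std_coefs[i, ] <- sm[-1L, 1L]
    std_se[i, ] <- sm[-1L, 2L]
    dfs[i] <- length(yi) - p - 1L
  }
  list(
    intercept = mean(coefs[, 1L]),
    coefficients = setNames(colMeans(coefs[, -1L, drop = FALSE]), names(X)),
    std_coefficients = data.frame(
      feature = names(X),
      estimate = colMeans(std_coefs),
      ci95 = qt(0.975, mean(dfs)) * colMeans(std_se)
    ),
    n_repeats = length(sets)
  )
}

new_linear_score_model <- function(coefficients, intercept, features,
                                   std_coefficients = NULL, test = NA,
                                   score_type = NA, n_repeats = 1L) {
  structure(
    list(coefficients = coefficients, intercept = intercept,
         features = features, std_coefficients = std_coefficients,
         test = test, score_type = score_type, n_repeats = n_repeats),
    class = c("linear_score_model", "score_model")
  )
}

#' Calibrate the activity-level proxy for a static test
#'
#' During static (rest) tests the expert's activity-level score tracks the
#' EMG amplitude, so the envelope RMS serves as a proxy for the score. The
#' proxy is calibrated by a single-feature least-squares fit of the expert
#' score on the envelope RMS, by default without an intercept so that a
#' silent muscle maps to score 0. Separate models are fit per test
#' condition.
#'
#' @param rms_env numeric vector of envelope RMS values (uV).
#' @param scores paired expert activity-level scores.
#' @param intercept include an intercept term (default `FALSE`).
#' @param test test-condition label stored in the model.
#' @return a `linear_score_model` with the single feature `rms_env`.
#' @export
calibrate_activity_proxy <- function(rms_env, scores, intercept = FALSE,
                                     test = NA) {
  if (length(rms_env) != length(scores))
    stop("rms_env and scores must be paired", call. = FALSE)
  if (length(scores) < 10L)
    stop("need at least 10 score/RMS pairs", call. = FALSE)
  if (length(unique(scores)) < 3L)
    stop("need at least 3 distinct score values to calibrate the proxy",
         call. = FALSE)
  if (var(rms_env) == 0)
    stop("degenerate predictor: envelope RMS has zero variance", call. = FALSE)
  if (intercept) {
    fit <- lm(scores ~ rms_env)
    new_linear_score_model(setNames(coef(fit)[2L], "rms_env"), coef(fit)[1L],
                           "rms_env", test = test,
                           score_type = "activity_level")
  } else {
    b <- sum(rms_env * scores) / sum(rms_env^2)
    new_linear_score_model(c(rms_env = b), 0, "rms_env", test = test,
                           score_type = "activity_level")
  }
}

#' Fit the rebalanced linear model for spasm severity
#'
#' Spasm severity during static tests is estimated from three features of
#' the band-passed EMG: its RMS and the signal power in the 50-100 Hz and
#' 100-200 Hz bands. Because score-0 instances dominate, the score-0 class
#' is down-sampled to 10% of the total sample size, 10 times
#' ([rebalance_datasets()]); because instances with scores above 5 are rare,
#' each fit uses only instances with scores 0-5 and the model is then
#' applied to all the data. The 10 coefficient vectors are averaged.
#' Standardized coefficients (with t-based 95% CIs) expose the relative
#' importance of each feature.
#'
#' @param features data frame containing columns `rms_filt`, `e_50_100`,
#'   `e_100_200` (extra columns are ignored).
#' @param scores expert spasm-severity scores, integers 0-10.
#' @param seed RNG seed for the rebalancing draws.
#' @param n_repeats,frac rebalancing parameters, see [rebalance_datasets()].
#' @param max_fit_score fit only on instances with scores up to this value.
#' @param test test-condition label stored in the model.
#' @return a `linear_score_model` over the three spasm features.
#' @export
fit_spasm_model <- function(features, scores, seed = NULL, n_repeats = 10,
                            frac = 0.10, max_fit_score = 5, test = NA) {
  miss <- setdiff(spasm_feature_names, names(features))
  if (length(miss))
    stop("missing spasm feature column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  X <- features[, spasm_feature_names, drop = FALSE]
  fit <- fit_rebalanced_ols(X, scores, n_repeats = n_repeats, frac = frac,
                            majority_class = 0, max_fit_score = max_fit_score,
                            seed = seed)
  new_linear_score_model(fit$coefficients, fit$intercept, spasm_feature_names,
                         fit$std_coefficients, test = test,
                         score_type = "spasm_severity",
                         n_repeats = fit$n_repeats)
}

#' Fit the rebalanced linear model for a dynamic-test score
#'
#' Same rebalance-fit-average procedure as [fit_spasm_model()], applied to
#' the 11 dynamic features. The majority class (the score value with the
#' largest number of instances) is down-sampled; no score-range restriction
#' is applied, since that restriction addressed the sparse high spasm
#' scores specifically.
#'
#' @param features data frame containing the 11 dynamic feature columns.
#' @param scores expert scores (activity level or amplitude modulation).
#' @inheritParams fit_spasm_model
#' @param score_type label stored in the model.
#' @return a `linear_score_model` over the 11 dynamic features.
#' @export
fit_dynamic_linear <- function(features, scores, seed = NULL, n_repeats = 10,
                               frac = 0.10, test = NA,
                               score_type = "activity_level") {
  miss <- setdiff(dynamic_feature_names, names(features))
  if (length(miss))
    stop("missing dynamic feature column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  X <- features[, dynamic_feature_names, drop = FALSE]
  fit <- fit_rebalanced_ols(X, scores, n_repeats = n_repeats, frac = frac,
                            seed = seed)
  new_linear_score_model(fit$coefficients, fit$intercept,
                         dynamic_feature_names, fit$std_coefficients,
                         test = test, score_type = score_type,
                         n_repeats = fit$n_repeats)
}

#' Predict clinical scores from a fitted linear model
#'
#' @param object a `linear_score_model`.
#' @param newdata data frame containing the model's feature columns.
#' @param clip clip predictions to the 0-10 scale (default).
#' @param ... unused.
#' @return numeric vector of score estimates.
#' @export
predict.linear_score_model <- function(object, newdata, clip = TRUE, ...) {
  miss <- setdiff(object$features, names(newdata))
  if (length(miss))
    stop("newdata lacks feature column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  X <- as.matrix(newdata[, object$features, drop = FALSE])
  est <- drop(X %*% object$coefficients) + object$intercept
  if (clip) clip_score(est) else est
}

#' @export
print.linear_score_model <- function(x, ...) {
  cat(sprintf("<linear_score_model> %s / %s (%d rebalanced fit(s) averaged)\n",
              x$score_type, x$test, x$n_repeats))
  cat("  intercept:", format(x$intercept, digits = 4), "\n")
  print(round(x$coefficients, 6))
  invisible(x)
}

#' Laterality of activity
#'
#' The laterality score of a muscle is the absolute difference between the
#' right-side and left-side scores of that muscle (expert scores or model
#' estimates alike).
#'
#' @param left,right numeric score vectors, or data frames with key columns
#'   (`muscle`, `test`, `score_type` — whichever are present are checked to
#'   match) and a `value` column.
#' @return absolute left/right score differences, same shape as the numeric
#'   input.
#' @export
laterality <- function(left, right) {
  if (is.data.frame(left) || is.data.frame(right)) {
    if (!is.data.frame(left) || !is.data.frame(right))
      stop("left and right must both be data frames or both numeric",
           call. = FALSE)
    if (nrow(left) != nrow(right))
      stop("left and right must have the same number of rows", call. = FALSE)
    for (key in intersect(c("muscle", "test", "score_type"),
                          intersect(names(left), names(right))))
      if (!identical(as.character(left[[key]]), as.character(right[[key]])))
        stop("left/right key mismatch in column `", key, "`", call. = FALSE)
    return(abs(right$value - left$value))
  }
  if (length(left) != length(right))
    stop("left and right must have equal length", call. = FALSE)
  abs(right - left)
}
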