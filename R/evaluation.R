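#' Root-mean-square error between estimates and expert scores
#'
#' @param estimates numeric vector of model estimates.
#' @param scores paired expert scores.
#' @return `sqrt(mean((estimates - scores)^2))`, in score points.
#' @export
rmse <- function(estimates, scores) {
  if (length(estimates) != length(scores))
    stop("estimates and scores must be paired", call. = FALSE)
  if (length(estimates) == 0L) stop("empty input", call. = FALSE)
  sqrt(mean((estimates - scores)^2))
}

#' Regression coefficient between estimates and expert scores
#'
#' Least-squares slope of the estimates on the expert scores, without an
#' intercept, so that perfect agreement reads exactly 1. The 95% confidence
#' interval half-width is t-based. Outliers are never removed.
#'
#' @inheritParams rmse
#' @return a list with `coefficient` and `ci95` (half-width).
#' @export
regression_coefficient_ci <- function(estimates, scores) {
  if (length(estimates) != length(scores))
    stop("estimates and scores must be paired", call. = FALSE)
  n <- length(scores)
  if (n < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (var(scores) == 0) stop("scores have zero variance", call. = FALSE)
  sxx <- sum(scores^2)
  b <- sum(scores * estimates) / sxx
  rss <- sum((estimates - b * scores)^2)
  se <- sqrt(rss / (n - 1L) / sxx)
  list(coefficient = b, ci95 = qt(0.975, n - 1L) * se)
}

#' Per-class box-plot summaries of the score estimates
#'
#' For each expert score value observed, summarizes the distribution of the
#' model estimates the way the accuracy box plots are drawn: median,
#' interquartile box, and whiskers spanning the non-outlier range. Outliers
#' are values beyond 1.5 times the interquartile range from the quartiles;
#' they are excluded from the whiskers only — every accuracy metric in the
#' package uses all pairs.
#'
#' @inheritParams rmse
#' @return a data frame with one row per non-empty class: `score`, `n`,
#'   `median`, `q1`, `q3`, `whisker_lo`, `whisker_hi`, `n_outliers`.
#' @export
class_summaries <- function(estimates, scores) {
  if (length(estimates) != length(scores))
    stop("estimates and scores must be paired", call. = FALSE)
  out <- lapply(sort(unique(scores)), function(s) {
    e <- estimates[scores == s]
    q <- quantile(e, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    inlier <- e >= q[1] - 1.5 * iqr & e <= q[3] + 1.5 * iqr
    data.frame(score = s, n = length(e), median = q[2], q1 = q[1], q3 = q[3],
               whisker_lo = min(e[inlier]), whisker_hi = max(e[inlier]),
               n_outliers = sum(!inlier))
  })
  do.call(rbind, out)
}

#' Estimation error as a function of the expert score
#'
#' Groups the signed errors (estimate minus expert score) by expert score
#' and quantifies any systematic bias trend as the least-squares slope of
#' the error on the score. A model that compresses the score range (as a
#' misspecified linear model does on non-linearly related features) shows a
#' negative trend: overestimation at low scores, underestimation at high
#' scores.
#'
#' @inheritParams rmse
#' @return a list with `by_score` (data frame `score`, `n`, `mean_error`,
#'   `sd_error`) and `bias_trend` (slope of error vs score).
#' @export
error_by_score <- function(estimates, scores) {
  if (length(estimates) != length(scores))
    stop("estimates and scores must be paired", call. = FALSE)
  err <- estimates - scores
  by_score <- do.call(rbind, lapply(sort(unique(scores)), function(s)
    data.frame(score = s, n = sum(scores == s),
               mean_error = mean(err[scores == s]),
               sd_error = if (sum(scores == s) > 1L) sd(err[scores == s]) else 0)))
  trend <- if (length(unique(scores)) > 1L)
    unname(coef(lm(err ~ scores))[2L]) else 0
  list(by_score = by_score, bias_trend = trend)
}

#' Evaluate a set of score estimates
#'
#' Combines the accuracy metrics into one report row per evaluated
#' combination, mirroring the layout of the accuracy tables: RMSE, the
#' estimate-vs-score regression coefficient with its 95% CI, and the sample
#' count.
#'
#' @param estimates data frame with columns `test`, `score_type`,
#'   `model_kind`, `estimate`, `score`.
#' @return an `evaluation_report` data frame with one row per
#'   (test, score_type, model_kind): `n`, `rmse`, `rc`, `rc_ci95`.
#' @export
evaluation_report <- function(estimates) {
  need <- c("test", "score_type", "model_kind", "estimate", "score")
  miss <- setdiff(need, names(estimates))
  if (length(miss))
    stop("estimates table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  groups <- unique(estimates[, c("test", "score_type", "model_kind")])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    sel <- estimates$test == g$test & estimates$score_type == g$score_type &
      estimates$model_kind == g$model_kind
    e <- estimates$estimate[sel]
    s <- estimates$score[sel]
    rc <- regression_coefficient_ci(e, s)
    data.frame(test = g$test, score_type = g$score_type,
               model_kind = g$model_kind, n = sum(sel), rmse = rmse(e, s),
               rc = rc$coefficient, rc_ci95 = rc$ci95)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("evaluation_report", "data.frame")
  out
}
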