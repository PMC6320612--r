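#' Stratified cross-validation folds
#'
#' Assigns each sample to one of `k` folds. Folds are stratified by score
#' value where class sizes permit (samples of each class are shuffled and
#' dealt round-robin across folds), so that the heavily imbalanced score
#' distributions do not leave folds without rare classes.
#'
#' @param scores vector used for stratification.
#' @param k number of folds.
#' @param seed RNG seed.
#' @param stratify stratify by score value (default).
#' @return integer vector of fold assignments in `1..k`.
#' @export
make_folds <- function(scores, k = 10, seed = NULL, stratify = TRUE) {
  n <- length(scores)
  if (k < 2L || k > n) stop("need 2 <= k <= n folds", call. = FALSE)
  with_seed(seed, {
    folds <- integer(n)
    if (stratify) {
      offset <- 0L
      for (cls in sort(unique(scores))) {
        idx <- sample(which(scores == cls))
        folds[idx] <- 1L + (offset + seq_along(idx) - 1L) %% k
        offset <- offset + length(idx)
      }
    } else {
      folds <- sample(rep_len(seq_len(k), n))
    }
    folds
  })
}

#' Out-of-fold score estimates via k-fold cross-validation
#'
#' Produces one estimate per sample, each from a model that never saw that
#' sample: the data is split into `k` folds, a model is fit on the
#' complement of each fold with `fit_fun` and applied to the held-out fold.
#' This is how all accuracy figures in the package are computed.
#'
#' @param features data frame of feature columns.
#' @param scores expert scores paired with `features`.
#' @param fit_fun function `(features, scores, seed, ...)` returning a model
#'   with a `predict` method, e.g. [fit_spasm_model()] or
#'   [fit_dynamic_forest()].
#' @param k number of folds.
#' @param seed RNG seed controlling both the fold split and the per-fold
#'   fits.
#' @param ... forwarded to `fit_fun`.
#' @return numeric vector of clipped out-of-fold estimates, with the fold
#'   assignment attached as attribute `"folds"`.
#' @export
crossval_estimates <- function(features, scores, fit_fun, k = 10,
                               seed = NULL, ...) {
  features <- as.data.frame(features)
  n <- nrow(features)
  if (n != length(scores))
    stop("features and scores must be paired", call. = FALSE)
  folds <- make_folds(scores, k = k, seed = seed)
  est <- numeric(n)
  for (f in seq_len(k)) {
    hold <- folds == f
    model <- fit_fun(features[!hold, , drop = FALSE], scores[!hold],
                     seed = if (is.null(seed)) NULL else seed + f, ...)
    est[hold] <- predict(model, features[hold, , drop = FALSE], clip = TRUE)
  }
  attr(est, "folds") <- folds
  est
}
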