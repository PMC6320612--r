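#' Bagged regression trees for dynamic-test scores
#'
#' Fits a bootstrap-aggregated ensemble of 100 regression trees (variance
#' reduction splits, minimum leaf size 10, no feature subsampling at splits
#' — pure bagging). Each tree is grown on a bootstrap resample of the
#' training set; the resample masks are stored so out-of-bag error and
#' permutation importance can be computed afterwards. Bagging is robust to
#' class imbalance, so no rebalancing is applied.
#'
#' @param features data frame of numeric feature columns.
#' @param scores expert scores, one per row of `features`.
#' @param n_trees number of trees in the ensemble.
#' @param min_leaf minimum number of training samples per leaf.
#' @param seed RNG seed; identical seeds give identical ensembles.
#' @param test,score_type labels stored in the model.
#' @return an object of class `forest_score_model`.
#' @export
fit_dynamic_forest <- function(features, scores, n_trees = 100, min_leaf = 10,
                               seed = NULL, test = NA,
                               score_type = "activity_level") {
  X <- as.data.frame(features)
  X <- X[, vapply(X, is.numeric, logical(1)), drop = FALSE]
  if (ncol(X) == 0L) stop("no numeric feature columns", call. = FALSE)
  n <- nrow(X)
  if (n < 30L)
    stop("need at least 30 training samples for the tree ensemble", call. = FALSE)
  if (n <= min_leaf)
    stop("fewer samples than the minimum leaf size", call. = FALSE)
  if (length(scores) != n)
    stop("features and scores must be paired", call. = FALSE)
  ctrl <- rpart::rpart.control(minsplit = 2L * min_leaf, minbucket = min_leaf,
                               cp = 0, xval = 0, maxcompete = 0,
                               maxsurrogate = 0, maxdepth = 30)
  dat <- cbind(.score = scores, X)
  with_seed(seed, {
    inbag <- matrix(0L, n, n_trees)
    trees <- vector("list", n_trees)
    for (b in seq_len(n_trees)) {
      idx <- sample.int(n, n, replace = TRUE)
      inbag[, b] <- tabulate(idx, nbins = n)
      trees[[b]] <- rpart::rpart(.score ~ ., data = dat[idx, , drop = FALSE],
                                 method = "anova", control = ctrl)
    }
    structure(
      list(trees = trees, inbag = inbag, features = names(X),
           x = X, y = scores, n_trees = n_trees, min_leaf = min_leaf,
           test = test, score_type = score_type),
      class = c("forest_score_model", "score_model")
    )
  })
}

#' Predict clinical scores from a bagged-tree model
#'
#' The ensemble estimate is the mean of the individual tree predictions,
#' clipped to the 0-10 scale.
#'
#' @param object a `forest_score_model`.
#' @param newdata data frame containing the model's feature columns.
#' @param clip clip predictions to the 0-10 scale (default).
#' @param ... unused.
#' @return numeric vector of score estimates.
#' @export
predict.forest_score_model <- function(object, newdata, clip = TRUE, ...) {
  miss <- setdiff(object$features, names(newdata))
  if (length(miss))
    stop("newdata lacks feature column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  nd <- as.data.frame(newdata)[, object$features, drop = FALSE]
  preds <- vapply(object$trees, function(tr) unname(predict(tr, nd)),
                  numeric(nrow(nd)))
  est <- if (nrow(nd) == 1L) mean(preds) else rowMeans(preds)
  if (clip) clip_score(est) else est
}

#' @export
print.forest_score_model <- function(x, ...) {
  cat(sprintf("<forest_score_model> %s / %s: %d trees, min leaf %d, %d x %d training set\n",
              x$score_type, x$test, x$n_trees, x$min_leaf,
              nrow(x$x), length(x$features)))
  invisible(x)
}

#' Out-of-bag permutation importance
#'
#' For each tree, the samples left out of its bootstrap resample (the
#' out-of-bag samples) give an honest test set. The importance of a feature
#' is the mean increase in out-of-bag squared prediction error when that
#' feature's values are permuted among the out-of-bag samples, averaged
#' over trees. Uninformative features score near zero.
#'
#' @param model a `forest_score_model` (the training data and bootstrap
#'   masks are stored in the model).
#' @param seed RNG seed for the permutations.
#' @param n_perm permutations averaged per tree and feature; more
#'   permutations reduce the Monte-Carlo noise of the importance estimate.
#' @return named numeric vector of importances (increase in MSE, score
#'   units squared), one per feature, in training-column order.
#' @export
oob_importance <- function(model, seed = NULL, n_perm = 4) {
  stopifnot(inherits(model, "forest_score_model"))
  X <- model$x
  y <- model$y
  p <- length(model$features)
  with_seed(seed, {
    imp <- numeric(p)
    used <- 0L
    for (b in seq_len(model$n_trees)) {
      oob <- which(model$inbag[, b] == 0L)
      if (length(oob) < 2L) {
        warning("tree ", b, " has fewer than 2 out-of-bag samples; skipped",
                call. = FALSE)
        next
      }
      tr <- model$trees[[b]]
      Xo <- X[oob, , drop = FALSE]
      err0 <- mean((y[oob] - unname(predict(tr, Xo)))^2)
      for (j in seq_len(p)) {
        d_err <- 0
        for (r in seq_len(n_perm)) {
          Xp <- Xo
          Xp[[j]] <- Xp[[j]][sample.int(length(oob))]
          d_err <- d_err + mean((y[oob] - unname(predict(tr, Xp)))^2) - err0
        }
        imp[j] <- imp[j] + d_err / n_perm
      }
      used <- used + 1L
    }
    if (used == 0L) stop("no tree had out-of-bag samples", call. = FALSE)
    setNames(imp / used, model$features)
  })
}
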