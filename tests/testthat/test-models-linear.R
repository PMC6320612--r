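test_that("activity proxy recovers an exact linear relation and validates input", {
  rms_env <- seq(0.5, 5, by = 0.5)
  model <- calibrate_activity_proxy(rms_env, 2 * rms_env)
  expect_equal(unname(model$coefficients), 2, tolerance = 1e-12)
  expect_equal(model$intercept, 0)
  est <- predict(model, data.frame(rms_env = rms_env), clip = FALSE)
  expect_equal(rmse(est, 2 * rms_env), 0, tolerance = 1e-12)
  expect_error(calibrate_activity_proxy(rms_env[1:5], 2 * rms_env[1:5]),
               "at least 10")
  expect_error(calibrate_activity_proxy(rms_env, rep(3, 10)), "distinct")
  expect_error(calibrate_activity_proxy(rep(2, 12), rep(0:2, 4)),
               "degenerate")
})

test_that("activity proxy recovers a noisy slope within 3 standard errors", {
  set.seed(21)
  n <- 200
  x <- runif(n, 1, 60)
  truth <- 0.16
  y <- truth * x + rnorm(n, sd = 0.5)
  model <- calibrate_activity_proxy(x, y)
  se <- sqrt(sum((y - unname(model$coefficients) * x)^2) / (n - 1) / sum(x^2))
  expect_lt(abs(unname(model$coefficients) - truth), 3 * se)
})

test_that("rebalancing down-samples the majority class to round(frac * n)", {
  scores <- c(rep(0L, 700), rep(1:10, 30))
  sets <- rebalance_datasets(scores, seed = 5)
  expect_length(sets, 10)
  for (s in sets) {
    expect_length(s, 400)                       # 100 zeros + 300 others
    expect_equal(sum(scores[s] == 0), 100)      # round(0.10 * 1000)
    expect_equal(sum(scores[s] > 0), 300)       # minority kept whole
    expect_false(anyDuplicated(s) > 0)          # without replacement
  }
  # determinism
  expect_identical(rebalance_datasets(scores, seed = 5),
                   rebalance_datasets(scores, seed = 5))
  # no-op when the majority class is already small enough
  bal <- rep(0:9, each = 10)
  sets2 <- rebalance_datasets(bal, seed = 1)
  expect_true(all(vapply(sets2, identical, logical(1), seq_along(bal))))
  expect_error(rebalance_datasets(c(0L, 0L, 1L), frac = 0.1), "below 1")
  expect_error(rebalance_datasets(c(0, 11)), "0..10")
})

test_that("spasm model on noiseless linear data equals closed-form OLS", {
  set.seed(9)
  n <- 300
  s <- sample(0:10, n, replace = TRUE,
              prob = zero_inflated_probs(0.5, 0.7))
  z1 <- sample(0:3, n, replace = TRUE)
  z2 <- sample(0:3, n, replace = TRUE)
  feats <- data.frame(rms_filt = s - z1 - z2, e_50_100 = z1, e_100_200 = z2)
  model <- fit_spasm_model(feats, s, seed = 17)
  expect_equal(model$n_repeats, 10)
  oracle <- ols_oracle(feats, s)                # exact fit: beta = (0,1,1,1)
  expect_equal(unname(model$coefficients), unname(oracle[-1]),
               tolerance = 1e-6)
  expect_equal(model$intercept, unname(oracle[1]), tolerance = 1e-6)
  est <- predict(model, feats)
  expect_equal(rmse(est, s), 0, tolerance = 1e-6)
  # rank-deficient features are rejected
  feats_bad <- feats
  feats_bad$e_100_200 <- 2 * feats_bad$e_50_100
  expect_error(fit_spasm_model(feats_bad, s, seed = 17), "independent")
})

test_that("standardized coefficients rank the driving feature first", {
  set.seed(23)
  n <- 400
  s <- sample(0:10, n, replace = TRUE, prob = zero_inflated_probs(0.5, 0.75))
  feats <- data.frame(rms_filt = rnorm(n, 10, 2),
                      e_50_100 = 40 * s + rnorm(n, sd = 10),
                      e_100_200 = rnorm(n, 50, 15))
  model <- fit_spasm_model(feats, s, seed = 3)
  std <- model$std_coefficients
  expect_equal(std$feature[which.max(abs(std$estimate))], "e_50_100")
  expect_true(all(std$ci95 >= 0))
})

test_that("dynamic linear model exactly recovers a noiseless relation", {
  set.seed(31)
  n <- 250
  s <- sample(0:10, n, replace = TRUE, prob = discretized_normal_probs(4, 2.5))
  feats <- as.data.frame(matrix(rnorm(n * 11, 10, 3), n))
  names(feats) <- c("rms_env", "p2p", "rms_quiet", "t_active",
                    "burst_rms_1", "burst_rms_2", "burst_rms_3", "dom_rms",
                    "burst_var_1", "burst_var_2", "burst_var_3")
  feats$burst_rms_1 <- s                         # sole informative feature
  model <- fit_dynamic_linear(feats, s, seed = 4)
  expect_equal(unname(model$coefficients["burst_rms_1"]), 1, tolerance = 1e-6)
  expect_lt(max(abs(model$coefficients[names(model$coefficients) !=
                                         "burst_rms_1"])), 1e-6)
  expect_equal(predict(model, feats, clip = FALSE), as.numeric(s),
               tolerance = 1e-6)
})

test_that("permuted labels yield near-zero coefficients and regression coefficient", {
  set.seed(37)
  n <- 400
  feats <- as.data.frame(matrix(rnorm(n * 3, 20, 5), n))
  names(feats) <- c("rms_filt", "e_50_100", "e_100_200")
  s <- sample(0:10, n, replace = TRUE, prob = zero_inflated_probs(0.4, 0.8))
  model <- fit_spasm_model(feats, s, seed = 11)
  est <- predict(model, feats, clip = FALSE)
  expect_lt(abs(cor(est, s)), 0.2)
  for (nm in names(model$coefficients)) {
    z <- abs(model$coefficients[nm]) * sd(feats[[nm]]) / sd(s)
    expect_lt(unname(z), 0.2)                  # standardized scale near 0
  }
})

test_that("predictions are clipped to the ordinal scale", {
  model <- calibrate_activity_proxy(seq(1, 10, length.out = 12),
                                    seq(1, 10, length.out = 12))
  expect_equal(predict(model, data.frame(rms_env = 12.3)), 10)
  expect_equal(predict(model, data.frame(rms_env = -3)), 0)
  expect_equal(predict(model, data.frame(rms_env = 4)), 4, tolerance = 1e-9)
  expect_error(predict(model, data.frame(other = 1)), "lacks feature")
})

test_that("10-fold CV produces exactly one honest out-of-fold estimate per sample", {
  set.seed(41)
  n <- 100
  feats <- data.frame(rms_env = runif(n, 1, 50), .row_id = seq_len(n))
  scores <- sample(0:10, n, replace = TRUE)
  probe_training_log$rows <- list()
  est <- crossval_estimates(feats, scores, fit_probe, k = 10, seed = 2)
  folds <- attr(est, "folds")
  expect_length(est, n)
  expect_equal(sort(unique(folds)), 1:10)
  expect_length(probe_training_log$rows, 10)
  for (f in 1:10)                                # fold f never trains on fold f
    expect_length(intersect(probe_training_log$rows[[f]], which(folds == f)), 0)
  # stratification spreads each class across folds
  big_class <- which(scores == as.integer(names(which.max(table(scores)))))
  expect_gt(length(unique(folds[big_class])), 5)
})

test_that("laterality is the absolute left-right difference with key checking", {
  expect_equal(laterality(5, 5), 0)
  expect_equal(laterality(2, 7), 5)
  expect_equal(laterality(7, 2), 5)              # symmetric under swap
  expect_equal(laterality(0, 10), 10)
  left <- data.frame(muscle = "scalene", test = "rest_sitting",
                     score_type = "activity_level", value = 3)
  right <- left
  right$value <- 8
  expect_equal(laterality(left, right), 5)
  right$muscle <- "triceps"
  expect_error(laterality(left, right), "mismatch")
  expect_error(laterality(1:3, 1:2), "equal length")
})
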