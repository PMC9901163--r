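test_that("random_split uses largest-remainder rounding and is reproducible", {
  s10 <- random_split(10, seed = 1)
  expect_equal(lengths(s10), c(train = 8L, val = 1L, test = 1L))
  s1128 <- random_split(1128, seed = 2)
  expect_equal(lengths(s1128), c(train = 902L, val = 113L, test = 113L))
  expect_identical(random_split(50, seed = 9), random_split(50, seed = 9))
  # disjoint and exhaustive
  all_idx <- sort(unname(unlist(s1128)))
  expect_identical(all_idx, 1:1128)
  expect_error(random_split(2), "at least 3")
})

test_that("regression metrics agree with independent reference implementations", {
  for (case in 1:5) {
    y <- ffinet:::with_seed(100 + case, stats::rnorm(40))
    yhat <- ffinet:::with_seed(200 + case, y + stats::rnorm(40, sd = 0.5))
    expect_equal(metric_rmse(y, yhat), sqrt(sum((y - yhat)^2) / 40),
                 tolerance = 1e-10)
    expect_equal(metric_mae(y, yhat), sum(abs(y - yhat)) / 40,
                 tolerance = 1e-10)
    # Pearson r against the textbook covariance formula
    r_ref <- sum((y - mean(y)) * (yhat - mean(yhat))) /
      sqrt(sum((y - mean(y))^2) * sum((yhat - mean(yhat))^2))
    expect_equal(metric_pearson(y, yhat), r_ref, tolerance = 1e-10)
    # SD against an lm() fit of y on yhat
    fit <- stats::lm(y ~ yhat)
    expect_equal(metric_sd(y, yhat),
                 sqrt(sum(stats::residuals(fit)^2) / (40 - 1)),
                 tolerance = 1e-10)
  }
})

test_that("metric identities: perfect and affine predictions", {
  y <- ffinet:::with_seed(7, stats::rnorm(25))
  expect_equal(metric_rmse(y, y), 0)
  expect_equal(metric_mae(y, y), 0)
  expect_equal(metric_pearson(y, y), 1)
  expect_equal(metric_sd(y, y), 0, tolerance = 1e-12)
  # affine transform: r = 1 and SD = 0, but RMSE > 0
  yh <- 2 * y + 1
  expect_equal(metric_pearson(y, yh), 1)
  expect_equal(metric_sd(y, yh), 0, tolerance = 1e-10)
  expect_gt(metric_rmse(y, yh), 0)
})

test_that("ROC-AUC matches brute-force pair counting, with masking", {
  expect_equal(metric_roc_auc(c(0, 1, 1, 0), c(0.1, 0.9, 0.8, 0.2)), 1.0)
  for (case in 1:5) {
    y <- ffinet:::with_seed(300 + case, stats::rbinom(30, 1, 0.4))
    s <- ffinet:::with_seed(400 + case, stats::rnorm(30))
    pos <- which(y == 1); neg <- which(y == 0)
    wins <- 0
    for (i in pos) for (j in neg)
      wins <- wins + (s[i] > s[j]) + 0.5 * (s[i] == s[j])
    expect_equal(metric_roc_auc(y, s), wins / (length(pos) * length(neg)),
                 tolerance = 1e-10)
  }
  # single-class task skipped with warning, multi-task macro average
  labels <- cbind(c(0, 1, 1, 0), c(1, 1, 1, 1))
  scores <- cbind(c(0.1, 0.9, 0.8, 0.2), c(0.5, 0.5, 0.5, 0.5))
  expect_warning(auc <- metric_roc_auc_masked(labels, scores), "single class")
  expect_equal(auc, 1.0)
  # masked entries excluded: without the NA row this task is separable
  labels2 <- cbind(c(1, 0, 1, NA))
  scores2 <- cbind(c(0.9, 0.1, 0.8, 0.95))
  expect_equal(metric_roc_auc_masked(labels2, scores2), 1.0)
})

test_that("fitting is deterministic per seed and honours patience", {
  ds <- fixture_dataset()
  cfg <- tiny_config(n_layers = 1)
  tc <- ffinet_train_config(batch_size = 16, max_epochs = 6, patience = 30,
                            seed = 4)
  f1 <- fit_ffinet(ffinet_model(cfg), ds$records, split = ds$split,
                   train_config = tc)
  f2 <- fit_ffinet(ffinet_model(cfg), ds$records, split = ds$split,
                   train_config = tc)
  expect_identical(f1$history, f2$history)
  expect_identical(flatten_params(f1$model$params),
                   flatten_params(f2$model$params))
  # best-so-far validation curve is monotone nonincreasing
  expect_true(all(diff(f1$history$best_val) <= 1e-12))
  # patience = 0 stops at the first non-improving epoch
  f0 <- fit_ffinet(ffinet_model(cfg), ds$records, split = ds$split,
                   train_config = ffinet_train_config(batch_size = 16,
                                                      max_epochs = 50,
                                                      patience = 0, seed = 4))
  worse <- which(f0$history$val_loss > cummin(f0$history$val_loss) + 1e-12)
  if (length(worse)) expect_equal(nrow(f0$history), worse[1])
})

test_that("training improves held-out correlation over the untrained model", {
  ds <- fixture_dataset()
  held <- c(ds$split$val, ds$split$test)
  cfg <- tiny_config(hidden_dim = 16, n_heads = 2, n_layers = 2)
  before <- evaluate_ffinet(ffinet_model(cfg), ds$records[held],
                            labels = ds$labels[held])
  fit <- fit_ffinet(ffinet_model(cfg), ds$records, split = ds$split,
                    train_config = ffinet_train_config(batch_size = 16,
                                                       max_epochs = 40,
                                                       patience = 30,
                                                       seed = 11))
  after <- evaluate_ffinet(fit$model, ds$records[held],
                           labels = ds$labels[held])
  expect_gt(after$pearson_r, max(before$pearson_r, 0, na.rm = TRUE))
})

test_that("run_repeats aggregates mean and sd across seeds", {
  fake <- function(seed) c(rmse = seed * 0.1, r = 1 - seed * 0.01)
  agg <- run_repeats(fake, seeds = 1:3)
  expect_equal(agg$mean[agg$metric == "rmse"], 0.2)
  expect_equal(agg$sd[agg$metric == "rmse"], stats::sd(c(0.1, 0.2, 0.3)))
  expect_warning(one <- run_repeats(fake, seeds = 2), "single run")
  expect_equal(one$sd, c(0, 0))
  # identical seeds give zero spread
  same <- run_repeats(fake, seeds = c(2, 2, 2))
  expect_equal(same$sd, c(0, 0))
})

test_that("checkpoints round-trip parameters and statistics", {
  ds <- fixture_dataset()
  cfg <- tiny_config(n_layers = 1)
  fit <- fit_ffinet(ffinet_model(cfg), ds$records, split = ds$split,
                    train_config = ffinet_train_config(batch_size = 16,
                                                       max_epochs = 2,
                                                       seed = 2))
  path <- tempfile(fileext = ".json")
  save_checkpoint(fit$model, path)
  back <- load_checkpoint(path)
  expect_equal(flatten_params(back$params), flatten_params(fit$model$params))
  expect_equal(back$basis_stats$m2$mean, fit$model$basis_stats$m2$mean)
  expect_equal(back$label_stats, fit$model$label_stats)
  p1 <- predict(fit$model, ds$records[1:3])
  p2 <- predict(back, ds$records[1:3])
  expect_equal(p1, p2, tolerance = 1e-12)
})
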