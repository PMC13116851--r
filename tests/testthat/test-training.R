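quick_cfg <- function(seed = 1, epochs = 6) {
  desk_train_config(seed = seed, epochs = epochs, batch_size = 12)
}

test_that("accuracy is a two-decimal percentage of correct argmaxes", {
  ds <- generate_dataset(tiny_spec(seed = 2, noise_sd = 0.1))
  m <- tiny_model(ds)
  acc <- evaluate(m, ds$val)
  expect_true(acc >= 0 && acc <= 100)
  expect_equal(acc, round_half_up(acc, 2))
  expect_error(evaluate(m, list(x = ds$val$x, y = integer(0))), "empty")
  expect_error(evaluate(m, ds$val, mask = rep(FALSE, 4)), "active view")
  # the published ratios: 93/108 and 90/108 correct
  expect_equal(round_half_up(100 * 93 / 108, 2), 86.11)
  expect_equal(round_half_up(100 * 90 / 108, 2), 83.33)
})

test_that("fusion training history tracks epochs, beta and gates", {
  ds <- generate_dataset(tiny_spec(seed = 3))
  fit <- train_fusion(ds, lambda_sparsity = 0.1,
                      model = tiny_model(ds), config = quick_cfg())
  h <- fit$history
  expect_equal(nrow(h), 6)
  expect_equal(h$beta[1], 0.67)
  expect_equal(h$beta[6], 0.1)
  expect_true(all(diff(h$beta) < 0))
  expect_true(all(is.finite(h$total)))
  expect_equal(length(h$retention[[1]]), 4)
  expect_true(all(h$lambda_sparsity == 0.1))
  # the fit carries a deterministic mask consistent with its gate state
  expect_equal(unname(fit$mask),
               unname(deterministic_mask(fit$gate_state, fit$model$gate)))
  expect_equal(fit$retained_views, ds$view_names[fit$mask])
})

test_that("identical config and seed reproduce the training run exactly", {
  ds <- generate_dataset(tiny_spec(seed = 5))
  f1 <- train_fusion(ds, 0.2, model = tiny_model(ds), config = quick_cfg(9))
  f2 <- train_fusion(ds, 0.2, model = tiny_model(ds), config = quick_cfg(9))
  expect_identical(f1$history$total, f2$history$total)
  expect_identical(f1$model$params$alpha, f2$model$params$alpha)
  expect_identical(f1$accuracy, f2$accuracy)
})

test_that("single-view training reports one accuracy per view", {
  ds <- generate_dataset(tiny_spec(seed = 4))
  cfg <- quick_cfg()
  cfg$epochs_single <- 8
  fit <- train_single_view(ds, config = cfg)
  expect_equal(nrow(fit$accuracy_table), 4)
  expect_setequal(fit$accuracy_table$view_name, ds$view_names)
  expect_true(all(fit$accuracy_table$accuracy >= 0 &
                    fit$accuracy_table$accuracy <= 100))
  expect_equal(fit$best_accuracy, max(fit$accuracy_table$accuracy))
  expect_equal(nrow(fit$history), 8)
})

test_that("the informative views win the single-view comparison", {
  # planted signal in views 1-2 only; the best single view must be one
  # of them, and by a wide margin over the uninformative views
  accs <- c()
  for (s in c(31, 32)) {
    ds <- generate_dataset(tiny_spec(seed = s, n_train = 60, n_val = 30))
    cfg <- desk_train_config(seed = s, batch_size = 20)
    cfg$epochs_single <- 25
    fit <- train_single_view(ds, config = cfg)
    tab <- fit$accuracy_table
    expect_true(fit$best_view %in% c("view01", "view02"))
    informative <- mean(tab$accuracy[1:2])
    uninformative <- mean(tab$accuracy[3:4])
    expect_gt(informative, uninformative + 10)
  }
})

test_that("extreme sparsity pressure suppresses all views", {
  ds <- generate_dataset(tiny_spec(seed = 6))
  fit <- train_fusion(ds, lambda_sparsity = 50, model = tiny_model(ds),
                      config = quick_cfg(epochs = 100))
  expect_equal(sum(fit$mask), 0)
  # the no-view configuration can only express the class prior
  maj <- sparseviews:::majority_accuracy(ds$train$y, ds$val$y)
  expect_equal(fit$accuracy, maj)
})

test_that("zero sparsity keeps informative views open on planted data", {
  ds <- generate_dataset(tiny_spec(seed = 7, n_train = 60, n_val = 12))
  cfg <- desk_train_config(seed = 7, epochs = 25, batch_size = 20)
  cfg$eval_every <- 0
  fit <- train_fusion(ds, lambda_sparsity = 0, config = cfg)
  ret <- retention_probability(fit$model$params$alpha, 0.1,
                               fit$model$gate)
  expect_true(all(ret[1:2] > 0.5))
})

test_that("cosine warm restarts return to the peak rate at each restart", {
  lr <- vapply(0:69, function(e)
    sparseviews:::cosine_warm_restart_lr(e, 0.02, restart_period = 10,
                                         mult = 2), numeric(1))
  expect_equal(lr[1], 0.02)
  expect_equal(lr[11], 0.02)   # restart at epoch 10
  expect_equal(lr[31], 0.02)   # next period is 20 epochs
  expect_lt(lr[10], 0.001)
  expect_true(all(lr <= 0.02 + 1e-12))
})

test_that("the sweep assembles a labelled table with one row per lambda", {
  ds <- generate_dataset(tiny_spec(seed = 8, n_train = 36, n_val = 12))
  cfg <- quick_cfg(seed = 8, epochs = 5)
  cfg$eval_every <- 0
  tab <- run_sweep(ds, lambda_grid = c(0.2, 0.4), config = cfg)
  expect_s3_class(tab, "sweep_table")
  expect_equal(nrow(tab), 3)   # baseline + two lambdas
  expect_equal(tab$lambda, c(0, 0.2, 0.4))
  expect_equal(tab$view_count[1], 4)
  expect_true("configuration" %in% names(tab))
  expect_equal(tab$configuration[1], "all-view")
  expect_true(all(tab$flops[order(tab$view_count)] ==
                    sort(tab$flops)))
  # single-lambda grid gives a two-row table
  tab1 <- run_sweep(ds, lambda_grid = 0.3, config = cfg)
  expect_equal(nrow(tab1), 2)
})

test_that("prediction output has k rows per specimen", {
  ds <- generate_dataset(tiny_spec(seed = 9))
  fit <- train_fusion(ds, 0, model = tiny_model(ds),
                      config = quick_cfg(epochs = 3))
  preds <- predict_topk_specimens(fit, ds$val, k = 3)
  expect_equal(nrow(preds), 3 * length(ds$val$y))
  expect_equal(unique(table(preds$specimen_id)), 3L)
  expect_true(all(preds$confidence > 0 & preds$confidence < 1))
  # ranks are descending in confidence within a specimen
  by_spec <- split(preds, preds$specimen_id)
  for (b in by_spec) expect_true(all(diff(b$confidence[order(b$rank)]) <= 0))
})

test_that("tidiers and plots expose the fit as tibbles and ggplots", {
  ds <- generate_dataset(tiny_spec(seed = 10))
  fit <- train_fusion(ds, 0.1, model = tiny_model(ds),
                      config = quick_cfg(epochs = 4))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 4 * 4)   # epochs x views
  expect_named(td, c("epoch", "view_name", "retention_probability",
                     "beta"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$epochs, 4)
  expect_s3_class(autoplot(fit), "ggplot")
  tab <- sweep_table(calyptratae_rows(), n_views = 8,
                     baseline_flops = 11.31, baseline_accuracy = 87.04)
  expect_s3_class(autoplot(label_configurations(tab)), "ggplot")
  expect_equal(glance(tab)$recommended_lambda, 0.4)
})
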