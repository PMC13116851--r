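test_that("generation is deterministic in the seed and shaped as specified", {
  spec <- tiny_spec(seed = 5)
  d1 <- generate_dataset(spec)
  d2 <- generate_dataset(spec)
  expect_identical(d1$train$x, d2$train$x)
  expect_identical(d1$val$y, d2$val$y)
  expect_equal(dim(d1$train$x), c(24, 4, 5))
  expect_equal(dim(d1$val$x), c(12, 4, 5))
  expect_equal(length(unique(d1$manifest$specimen_id)), 36)
  # stratified: every class appears in both splits
  expect_setequal(unique(d1$train$y), 1:3)
  expect_setequal(unique(d1$val$y), 1:3)
})

test_that("a 512-specimen 12-species 8-view manifest mirrors the fly dataset", {
  spec <- synthetic_spec(n_classes = 12, n_views = 8,
                         informative_views = 1:5,
                         n_train = 404, n_val = 108, feature_dim = 4,
                         seed = 2)
  ds <- generate_dataset(spec)
  expect_equal(length(ds$train$y), 404)
  expect_equal(length(ds$val$y), 108)
  expect_equal(length(unique(ds$manifest$specimen_id)), 512)
  expect_equal(length(unique(ds$manifest$species)), 12)
  expect_equal(nrow(ds$manifest), 512 * 8)
})

test_that("noise-free features are separable only in planted views", {
  spec <- tiny_spec(seed = 3, noise_sd = 0)
  ds <- generate_dataset(spec)
  S <- ground_truth_views(spec)
  # outside S all classes share the zero mean exactly
  for (v in setdiff(seq_len(spec$n_views), S)) {
    expect_equal(max(abs(ds$train$x[, v, ])), 0)
  }
  # inside S class means differ
  v <- S[1]
  m1 <- colMeans(ds$train$x[ds$train$y == 1, v, , drop = FALSE][, 1, ])
  m2 <- colMeans(ds$train$x[ds$train$y == 2, v, , drop = FALSE][, 1, ])
  expect_gt(sqrt(sum((m1 - m2)^2)), 0.5)
})

test_that("linear probes succeed inside the planted subset and fail outside", {
  # nearest-class-mean probe per view, averaged over seeds
  probe_acc <- function(ds, v) {
    xtr <- ds$train$x[, v, ]
    xva <- ds$val$x[, v, ]
    mus <- lapply(sort(unique(ds$train$y)), function(c)
      colMeans(xtr[ds$train$y == c, , drop = FALSE]))
    pred <- apply(xva, 1, function(row)
      which.min(vapply(mus, function(m) sum((row - m)^2), numeric(1))))
    mean(pred == ds$val$y)
  }
  accs_in <- c(); accs_out <- c()
  for (s in 1:3) {
    spec <- synthetic_spec(seed = s)
    ds <- generate_dataset(spec)
    S <- ground_truth_views(spec)
    accs_in <- c(accs_in, vapply(S, function(v) probe_acc(ds, v),
                                 numeric(1)))
    accs_out <- c(accs_out, vapply(setdiff(1:8, S),
                                   function(v) probe_acc(ds, v),
                                   numeric(1)))
  }
  chance <- 1 / 6
  se <- sqrt(chance * (1 - chance) / 60)
  expect_true(all(accs_in > chance + 3 * se))
  expect_lt(mean(accs_out), chance + 3 * se)
})

test_that("recovery score is the Jaccard index with the empty convention", {
  expect_equal(recovery_score(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(recovery_score(1, 2), 0)
  expect_equal(recovery_score(c(1, 2), c(1, 3)), 1 / 3)
  expect_equal(recovery_score(integer(0), integer(0)), 1)
  expect_equal(recovery_score(integer(0), 1:2), 0)
  expect_equal(recovery_score(c("a", "b"), c("b", "a")), 1)
})

test_that("ground truth accessor returns the planted subset unchanged", {
  expect_equal(ground_truth_views(tiny_spec()), c(1L, 2L))
  sp <- synthetic_spec(n_views = 4, informative_views = 1:4,
                       n_classes = 2, n_train = 8, n_val = 4)
  expect_equal(ground_truth_views(sp), 1:4)
  sp1 <- synthetic_spec(n_views = 4, informative_views = 3,
                        n_classes = 2, n_train = 8, n_val = 4)
  expect_equal(ground_truth_views(sp1), 3L)
})

test_that("image mode renders class-dependent views only inside S", {
  spec <- synthetic_spec(n_classes = 3, n_views = 3,
                         informative_views = 1, mode = "image",
                         image_size = 16, n_train = 6, n_val = 3,
                         noise_sd = 0, seed = 4)
  ds <- generate_dataset(spec)
  i1 <- which(ds$train$y == 1)[1]
  i2 <- which(ds$train$y == 2)[1]
  # informative view differs between classes
  expect_gt(max(abs(ds$train$x[[i1]][[1]] - ds$train$x[[i2]][[1]])), 0.1)
  # uninformative view is identical across classes
  expect_equal(ds$train$x[[i1]][[2]], ds$train$x[[i2]][[2]])
})

test_that("spec validation rejects impossible configurations", {
  expect_error(synthetic_spec(informative_views = 9), "informative_views")
  expect_error(synthetic_spec(n_train = 3, n_classes = 6) |>
                 generate_dataset(), "stratify")
  expect_error(synthetic_spec(redundancy_rho = 1), "redundancy_rho")
  expect_error(synthetic_spec(signal_strength = 0), "signal_strength")
})

test_that("written datasets round-trip through the manifest reader", {
  dir <- withr::local_tempdir()
  ds <- generate_dataset(tiny_spec(seed = 6))
  write_dataset(ds, dir)
  loaded <- load_dataset(dir)
  expect_equal(loaded$view_names, ds$view_names)
  expect_equal(loaded$class_names, ds$class_names)
  expect_equal(loaded$train$y, ds$train$y)
  expect_equal(loaded$train$x, ds$train$x, tolerance = 1e-10)
  expect_equal(loaded$val$x, ds$val$x, tolerance = 1e-10)
})

test_that("image datasets write the manifest + image-folder layout", {
  dir <- withr::local_tempdir()
  spec <- synthetic_spec(n_classes = 2, n_views = 2,
                         informative_views = 1, mode = "image",
                         image_size = 16, n_train = 4, n_val = 2, seed = 9)
  ds <- generate_dataset(spec)
  write_dataset(ds, dir)
  man <- read_manifest(file.path(dir, "manifest.csv"))
  expect_true(all(file.exists(man$image_path)))
  loaded <- load_dataset(dir)
  expect_equal(loaded$spec$mode, "image")
  # pixel data survive the PNG round trip at 8-bit precision
  expect_equal(loaded$train$x[[1]][[1]], ds$train$x[[1]][[1]],
               tolerance = 1 / 255)
})
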