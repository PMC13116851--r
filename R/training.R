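#' Training configuration
#'
#' Defaults mirror the production recipe for fine-tuning a pretrained
#' backbone: AdamW with learning rate 1e-6 and weight decay 5e-3 under a
#' cosine-annealing warm-restart schedule, 300 fusion epochs. The
#' reference-tiny model trains from random initialization and uses the
#' [desk_train_config()] preset instead (higher learning rate, fewer
#' epochs); both are plain configs and every field can be overridden.
#'
#' @param lr Initial learning rate (default 1e-6).
#' @param weight_decay Decoupled weight decay (default 5e-3).
#' @param epochs Fusion-stage epochs (default 300).
#' @param epochs_single Single-view pretraining epochs (default 100).
#' @param batch_size Minibatch size; the class-balanced sampler needs
#'   `batch_size >= 2 * n_classes` for in-batch contrastive positives
#'   (default 32).
#' @param restart_period,restart_mult Warm-restart schedule: first restart
#'   after `restart_period` epochs, each period `restart_mult` times longer
#'   (defaults 10, 2).
#' @param lr_min_frac Floor of the cosine schedule as a fraction of `lr`
#'   (default 0.01).
#' @param eval_every Epoch interval for validation evaluation during
#'   training; 0 disables per-epoch evaluation (default 1).
#' @param seed RNG seed controlling initialization, batching and gate noise.
#' @return An object of class `train_config`.
#' @export
train_config <- function(lr = 1e-6, weight_decay = 5e-3, epochs = 300,
                         epochs_single = 100, batch_size = 32,
                         restart_period = 10, restart_mult = 2,
                         lr_min_frac = 0.01, eval_every = 1, seed = 1) {
  stopifnot(lr > 0, epochs >= 1, epochs_single >= 1, batch_size >= 2,
            weight_decay >= 0, restart_period >= 1, restart_mult >= 1)
  structure(list(lr = lr, weight_decay = weight_decay, epochs = epochs,
                 epochs_single = epochs_single, batch_size = batch_size,
                 restart_period = restart_period,
                 restart_mult = restart_mult, lr_min_frac = lr_min_frac,
                 eval_every = eval_every, seed = as.integer(seed)),
            class = "train_config")
}

#' Desk-scale training preset for the reference-tiny model
#'
#' AdamW at learning rate 0.02, 100 fusion epochs with one warm restart at
#' epoch 50, 30 single-view pretraining epochs, class-balanced batches of
#' 48. These are the study conditions used by the package's own
#' planted-signal experiments.
#'
#' @param seed RNG seed.
#' @param epochs Fusion-stage epochs (default 100).
#' @param batch_size Minibatch size (default 48).
#' @param restart_period First warm-restart epoch (default 50).
#' @param ... Further overrides passed to [train_config()].
#' @return A [train_config()].
#' @export
desk_train_config <- function(seed = 1, epochs = 100, batch_size = 48,
                              restart_period = 50, ...) {
  train_config(lr = 0.02, epochs = epochs, epochs_single = 30,
               batch_size = batch_size, restart_period = restart_period,
               eval_every = 1, seed = seed, ...)
}

# Class-balanced batch index list: per-class shuffles dealt round-robin so
# every window of >= 2*C consecutive samples contains in-batch positives.
balanced_batches <- function(y, batch_size) {
  classes <- unique(y)
  per_class <- lapply(classes, function(c) sample(which(y == c)))
  n <- length(y)
  order_all <- integer(0)
  maxlen <- max(lengths(per_class))
  for (i in seq_len(maxlen)) {
    for (k in seq_along(per_class)) {
      if (i <= length(per_class[[k]])) {
        order_all <- c(order_all, per_class[[k]][i])
      }
    }
  }
  split(order_all, ceiling(seq_len(n) / batch_size))
}

subset_batch <- function(x, idx, mode) {
  if (mode == "feature") x[idx, , , drop = FALSE] else x[idx]
}

default_model <- function(dataset, config_seed, d = 16, n_queries = 1) {
  spec <- dataset$spec
  enc <- if (spec$mode == "feature") {
    encoder_config(input_mode = "feature", feature_dim = spec$feature_dim,
                   embedding_dim = d, hidden_dim = d,
                   n_queries = n_queries)
  } else {
    encoder_config(input_mode = "image", input_size = 64, patch_grid = 4,
                   embedding_dim = d, hidden_dim = d,
                   n_queries = n_queries)
  }
  fus <- fusion_config(n_classes = length(dataset$class_names), d = d)
  init_model(enc, fus, gate_config(), dataset$view_names,
             dataset$class_names, seed = config_seed)
}

#' Top-1 validation accuracy of a view configuration
#'
#' Fraction of specimens whose argmax prediction matches the label, times
#' 100, rounded to two decimals. Dropped views are excluded from attention
#' and pooling entirely (hard selection).
#'
#' @param model An `sv_model`.
#' @param data A list with `x` (batch input) and `y` (labels), e.g. the
#'   `val` element of an `sv_dataset`.
#' @param mask Logical view mask with at least one active view.
#' @param loss_cfg A [loss_config()] (only the forward pass is used).
#' @return Accuracy in percent (2 decimals).
#' @export
evaluate <- function(model, data, mask = rep(TRUE, length(model$view_names)),
                     loss_cfg = loss_config()) {
  stopifnot(inherits(model, "sv_model"))
  if (length(data$y) == 0) stop("empty validation set")
  if (!any(mask)) stop("mask must have at least one active view")
  fw <- model_loss_grad(model, data$x, data$y, loss_cfg, beta = 1,
                        u = NULL, zmask = as.numeric(mask), active = mask,
                        compute_grads = FALSE)
  pred <- max.col(fw$probs, ties.method = "first")
  round_half_up(100 * mean(pred == data$y), 2)
}

# Accuracy convention for a configuration that retained no views: the
# classifier can only express the class prior, so score the majority class.
majority_accuracy <- function(y_train, y_val) {
  maj <- as.integer(names(which.max(table(y_train))))
  round_half_up(100 * mean(y_val == maj), 2)
}

#' Single-view pretraining of the shared encoder
#'
#' Trains the shared-weight encoder with one linear classification head per
#' view (loss: mean over views of per-view cross-entropy), then reports
#' per-view Top-1 validation accuracy. The best single view is the
#' single-view baseline against which fusion is compared.
#'
#' @param dataset An `sv_dataset`.
#' @param model Optional `sv_model` to start from; a fresh reference-tiny
#'   model is initialized when `NULL`.
#' @param config A [train_config()].
#' @return A list of class `sv_single_fit`: `model`, `accuracy_table`
#'   (tibble `view_name`, `accuracy`), `best_view`, `best_accuracy`,
#'   `history` (per-epoch tibble).
#' @export
train_single_view <- function(dataset, model = NULL,
                              config = desk_train_config()) {
  stopifnot(inherits(dataset, "sv_dataset"))
  set.seed(config$seed)
  if (is.null(model)) model <- default_model(dataset, config$seed)
  opt <- adamw_init(model$params)
  mode <- dataset$spec$mode
  hist <- vector("list", config$epochs_single)
  for (e in seq_len(config$epochs_single)) {
    lr_e <- cosine_warm_restart_lr(e - 1, config$lr, config$restart_period,
                                   config$restart_mult, config$lr_min_frac)
    batches <- balanced_batches(dataset$train$y, config$batch_size)
    losses <- numeric(length(batches))
    for (bi in seq_along(batches)) {
      idx <- batches[[bi]]
      res <- single_view_loss_grad(model,
                                   subset_batch(dataset$train$x, idx, mode),
                                   dataset$train$y[idx])
      if (!is.finite(res$loss)) stop("divergent loss in single-view stage")
      st <- adamw_step(model$params, res$grads, opt, lr_e,
                       config$weight_decay)
      model$params <- st$params
      opt <- st$opt
      losses[bi] <- res$loss
    }
    hist[[e]] <- tibble::tibble(epoch = e, loss = mean(losses), lr = lr_e)
  }
  # per-view validation accuracy through the per-view heads
  fw <- single_view_loss_grad(model, dataset$val$x, dataset$val$y,
                              compute_grads = FALSE)
  acc <- vapply(fw$probs_views, function(pr) {
    round_half_up(100 * mean(max.col(pr, ties.method = "first") ==
                               dataset$val$y), 2)
  }, numeric(1))
  tab <- tibble::tibble(view_name = dataset$view_names, accuracy = acc)
  best <- which.max(acc)
  structure(list(model = model, accuracy_table = tab,
                 best_view = dataset$view_names[best],
                 best_accuracy = acc[best],
                 history = dplyr::bind_rows(hist)),
            class = "sv_single_fit")
}

#' Gated multi-view fusion training
#'
#' The second training stage: per step, Hard-Concrete gates are sampled at
#' the annealed temperature (one noise draw per view per forward pass),
#' tokens are gated and fused, and the compound objective (cross-entropy +
#' supervised contrastive + lambda_sparsity * expected-L0) is minimized
#' with AdamW under a cosine warm-restart schedule. The returned history
#' carries per-epoch loss components and per-view retention probabilities;
#' the final evaluation applies the deterministic threshold mask with
#' dropped views removed entirely.
#'
#' @param dataset An `sv_dataset`.
#' @param lambda_sparsity Weight of the expected-L0 penalty.
#' @param model Optional starting `sv_model` (e.g. from
#'   [train_single_view()]); fresh initialization when `NULL`.
#' @param config A [train_config()].
#' @param loss_cfg A [loss_config()]; its `lambda_sparsity` is overridden
#'   by the `lambda_sparsity` argument.
#' @return A list of class `sv_fusion_fit`: `model`, `history`
#'   (`sv_history` tibble), `gate_state`, `mask`, `retained_views`,
#'   `accuracy` (final Top-1 %, deterministic mask), `lambda_sparsity`.
#' @export
train_fusion <- function(dataset, lambda_sparsity = 0, model = NULL,
                         config = desk_train_config(),
                         loss_cfg = loss_config()) {
  stopifnot(inherits(dataset, "sv_dataset"))
  loss_cfg$lambda_sparsity <- lambda_sparsity
  set.seed(config$seed)
  if (is.null(model)) model <- default_model(dataset, config$seed)
  gate_cfg <- model$gate
  V <- length(model$view_names)
  opt <- adamw_init(model$params)
  mode <- dataset$spec$mode
  E <- config$epochs
  hist <- vector("list", E)
  for (e in seq_len(E)) {
    beta <- anneal_beta(e - 1, E, gate_cfg)
    lr_e <- cosine_warm_restart_lr(e - 1, config$lr, config$restart_period,
                                   config$restart_mult, config$lr_min_frac)
    batches <- balanced_batches(dataset$train$y, config$batch_size)
    comp <- matrix(0, length(batches), 4)
    for (bi in seq_along(batches)) {
      idx <- batches[[bi]]
      u <- stats::runif(V)
      res <- model_loss_grad(model,
                             subset_batch(dataset$train$x, idx, mode),
                             dataset$train$y[idx], loss_cfg, beta, u = u)
      if (!is.finite(res$breakdown$total)) {
        stop("divergent loss at epoch ", e, " (non-finite total)")
      }
      st <- adamw_step(model$params, res$grads, opt, lr_e,
                       config$weight_decay)
      model$params <- st$params
      opt <- st$opt
      comp[bi, ] <- c(res$breakdown$ce, res$breakdown$contrast,
                      res$breakdown$l0, res$breakdown$total)
    }
    state_e <- gate_state(model$params$alpha, beta, model$view_names)
    ret <- retention_probability(model$params$alpha, beta, gate_cfg)
    val_acc <- NA_real_
    if (config$eval_every > 0 && (e %% config$eval_every == 0 ||
                                  e == E)) {
      mask_e <- deterministic_mask(state_e, gate_cfg)
      val_acc <- if (any(mask_e)) {
        evaluate(model, dataset$val, mask_e, loss_cfg)
      } else {
        majority_accuracy(dataset$train$y, dataset$val$y)
      }
    }
    hist[[e]] <- tibble::tibble(
      epoch = e, ce = mean(comp[, 1]), contrast = mean(comp[, 2]),
      l0 = mean(comp[, 3]), total = mean(comp[, 4]), beta = beta,
      lr = lr_e, lambda_sparsity = lambda_sparsity,
      val_accuracy = val_acc,
      retention = list(stats::setNames(ret, model$view_names))
    )
  }
  history <- dplyr::bind_rows(hist)
  class(history) <- c("sv_history", class(history))
  final_state <- gate_state(model$params$alpha, gate_cfg$beta_end,
                            model$view_names)
  mask <- deterministic_mask(final_state, gate_cfg)
  acc <- if (any(mask)) {
    evaluate(model, dataset$val, mask, loss_cfg)
  } else {
    majority_accuracy(dataset$train$y, dataset$val$y)
  }
  structure(list(model = model, history = history,
                 gate_state = final_state, mask = mask,
                 retained_views = model$view_names[mask],
                 accuracy = acc, lambda_sparsity = lambda_sparsity,
                 config = config, loss_config = loss_cfg),
            class = "sv_fusion_fit")
}

#' Theoretical per-view encoder cost in GFLOPs
#'
#' Multiply-accumulate count (times two) of one view's pass through the
#' reference-tiny encoder: stem, key/value maps, query attention and the
#' output projection. Fusion-layer cost is excluded: total cost is linear
#' in the number of encoded views, which is what makes the FLOPs column of
#' a sweep table proportional to the retained view count.
#'
#' @param encoder An [encoder_config()].
#' @return GFLOPs per view (full precision; round at presentation).
#' @export
flops_per_view <- function(encoder) {
  stopifnot(inherits(encoder, "encoder_config"))
  Fin <- encoder_input_dim(encoder)
  P <- if (encoder$input_mode == "feature") 1 else encoder$patch_grid^2
  H <- encoder$hidden_dim
  nq <- encoder$n_queries
  D <- encoder$embedding_dim
  ops <- 2 * (P * Fin * H) +       # stem
    2 * (2 * P * H * H) +          # key and value maps
    2 * (nq * P * H) +             # attention scores
    2 * (nq * P * H) +             # attention-weighted sum
    2 * (nq * H * D)               # output projection
  ops / 1e9
}

#' Sparsity-weight sweep over lambda
#'
#' Runs one independent gated fusion training per lambda value (fresh
#' initialization, identical seed policy) plus the lambda = 0 all-view
#' baseline, and assembles the labelled sweep table: retained views,
#' Top-1 accuracy under the deterministic mask, accuracy drop, linear
#' FLOPs, FLOPs saved, and configuration labels with the margin-based
#' recommendation.
#'
#' @param dataset An `sv_dataset`.
#' @param lambda_grid Lambda values to sweep (default `seq(0.1, 0.5, 0.1)`).
#' @param config A [train_config()].
#' @param loss_cfg Base [loss_config()].
#' @param margin_pp Accuracy margin for the recommendation rule, in
#'   percentage points (default 1.0).
#' @param model_factory Function `(seed) -> sv_model` for fresh
#'   initializations; defaults to the reference-tiny architecture sized to
#'   the dataset.
#' @return A labelled [sweep_table()]; failed lambda runs are recorded with
#'   `NA` accuracy and flagged in the `failed` column.
#' @export
run_sweep <- function(dataset, lambda_grid = seq(0.1, 0.5, by = 0.1),
                      config = desk_train_config(),
                      loss_cfg = loss_config(), margin_pp = 1.0,
                      model_factory = NULL) {
  stopifnot(length(lambda_grid) >= 1, all(lambda_grid > 0))
  if (is.null(model_factory)) {
    model_factory <- function(seed) default_model(dataset, seed)
  }
  V <- length(dataset$view_names)
  per_view <- flops_per_view(model_factory(config$seed)$encoder)
  one_run <- function(lam) {
    fit <- tryCatch(
      train_fusion(dataset, lambda_sparsity = lam,
                   model = model_factory(config$seed), config = config,
                   loss_cfg = loss_cfg),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      return(tibble::tibble(lambda = lam, retained_views = list(character()),
                            view_count = NA_integer_, accuracy = NA_real_,
                            failed = TRUE))
    }
    tibble::tibble(lambda = lam,
                   retained_views = list(fit$retained_views),
                   view_count = sum(fit$mask), accuracy = fit$accuracy,
                   failed = FALSE)
  }
  # all-view baseline: lambda = 0, evaluated with every view active
  fit0 <- train_fusion(dataset, lambda_sparsity = 0,
                       model = model_factory(config$seed), config = config,
                       loss_cfg = loss_cfg)
  acc0 <- evaluate(fit0$model, dataset$val,
                   rep(TRUE, V), fit0$loss_config)
  base_row <- tibble::tibble(lambda = 0,
                             retained_views = list(dataset$view_names),
                             view_count = V, accuracy = acc0,
                             failed = FALSE)
  recs <- dplyr::bind_rows(base_row,
                           dplyr::bind_rows(lapply(lambda_grid, one_run)))
  tab <- sweep_table(recs, n_views = V,
                     baseline_flops = V * per_view,
                     baseline_accuracy = acc0, margin_pp = margin_pp)
  label_configurations(tab)
}

#' Top-k species predictions for a set of specimens
#'
#' Runs the fused model under a view mask and reports the `k` most probable
#' species per specimen with confidence scores.
#'
#' @param fit An `sv_fusion_fit` (or a list with `model` and `mask`).
#' @param data A list with `x`, `y` (optional) and `specimen_id`.
#' @param k Predictions per specimen (default 3).
#' @return A tibble with `specimen_id`, `rank`, `species`, `confidence`.
#' @export
predict_topk_specimens <- function(fit, data, k = 3) {
  model <- fit$model
  mask <- fit$mask %||% rep(TRUE, length(model$view_names))
  n <- if (!is.null(data$y)) length(data$y) else
    if (model$encoder$input_mode == "feature") dim(data$x)[1] else
      length(data$x)
  fw <- model_loss_grad(model, data$x, rep(1L, n), loss_config(),
                        beta = 1, u = NULL, zmask = as.numeric(mask),
                        active = mask, compute_grads = FALSE)
  probs <- fw$probs
  colnames(probs) <- model$class_names
  ids <- data$specimen_id %||% sprintf("spec%04d", seq_len(n))
  purrr::map_dfr(seq_len(n), function(i) {
    out <- predict_topk(probs[i, ], k)
    out$specimen_id <- ids[i]
    out[, c("specimen_id", "rank", "species", "confidence")]
  })
}
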