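#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fusion training history
#'
#' Long format: one row per epoch and view with the retention probability
#' at that epoch's temperature, alongside the temperature itself.
#'
#' @param x An `sv_history`.
#' @param ... Unused.
#' @return A tibble with `epoch`, `view_name`, `retention_probability`,
#'   `beta`.
#' @export
tidy.sv_history <- function(x, ...) {
  traj <- gate_trajectories(x)
  dplyr::left_join(traj,
                   tibble::as_tibble(x)[, c("epoch", "beta")],
                   by = "epoch")
}

#' @rdname tidy.sv_history
#' @export
tidy.sv_fusion_fit <- function(x, ...) tidy.sv_history(x$history, ...)

#' One-row summary of a fusion fit
#'
#' @param x An `sv_fusion_fit`.
#' @param ... Unused.
#' @return A tibble with the sparsity weight, epochs trained, retained
#'   view count, expected L0 at the final state, and final Top-1 accuracy.
#' @export
glance.sv_fusion_fit <- function(x, ...) {
  tibble::tibble(
    lambda_sparsity = x$lambda_sparsity,
    epochs = nrow(x$history),
    n_retained = sum(x$mask),
    expected_l0 = expected_l0(x$gate_state, x$model$gate),
    accuracy = x$accuracy
  )
}

#' Tidy a gate state
#'
#' @param x A [gate_state()].
#' @param ... Optionally `config`, a [gate_config()].
#' @return A tibble with `view_name`, `alpha`, `retention_probability`.
#' @export
tidy.gate_state <- function(x, ...) {
  dots <- list(...)
  cfg <- dots$config %||% gate_config()
  tibble::tibble(
    view_name = x$view_names %||% paste0("view", seq_along(x$alpha)),
    alpha = x$alpha,
    retention_probability = retention_probability(x$alpha, x$beta, cfg)
  )
}

#' Tidy a sweep table
#'
#' Flattens the retained-view list column into a comma-separated string and
#' keeps the seven published columns.
#'
#' @param x A [sweep_table()].
#' @param ... Unused.
#' @return A plain tibble.
#' @export
tidy.sweep_table <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$retained_views <- vapply(out$retained_views, function(v) {
    if (is.null(v) || length(v) == 0) NA_character_
    else paste(v, collapse = ",")
  }, character(1))
  out
}

#' One-row summary of a sweep
#'
#' @param x A [sweep_table()].
#' @param ... Unused.
#' @return Baseline and recommended-configuration summary columns.
#' @export
glance.sweep_table <- function(x, ...) {
  meta <- sweep_meta(x)
  rec <- select_recommended(x)
  tibble::tibble(
    n_views = meta$n_views,
    baseline_accuracy = meta$baseline_accuracy,
    baseline_flops = flops_total(meta$n_views, meta$per_view_flops),
    recommended_lambda = rec$lambda,
    recommended_views = rec$view_count,
    recommended_accuracy = rec$accuracy,
    recommended_flops = rec$flops,
    flops_saved = rec$flops_saved
  )
}

#' Tidy a single-view pretraining fit
#'
#' @param x An `sv_single_fit`.
#' @param ... Unused.
#' @return The per-view accuracy table.
#' @export
tidy.sv_single_fit <- function(x, ...) x$accuracy_table

#' @rdname tidy.sv_single_fit
#' @export
glance.sv_single_fit <- function(x, ...) {
  tibble::tibble(best_view = x$best_view, best_accuracy = x$best_accuracy,
                 epochs = nrow(x$history))
}
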