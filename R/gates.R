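#' Hard-Concrete gate configuration
#'
#' The stretched, clipped binary-concrete ("Hard-Concrete") distribution puts
#' positive probability mass at exactly 0 and exactly 1 while remaining
#' differentiable in between, which is what makes an expected-L0 penalty on
#' the number of active views trainable by gradient descent. `gate_config()`
#' holds the stretch interval `(gamma, zeta)`, the temperature annealing
#' endpoints, and the retention-probability cutoff used to derive a
#' deterministic test-time view mask.
#'
#' @param zeta Upper stretch bound, must exceed 1 (default 1.1).
#' @param gamma Lower stretch bound, must be negative (default -0.1).
#' @param beta_start Initial concrete temperature (default 0.67).
#' @param beta_end Final concrete temperature after annealing (default 0.1).
#' @param selection_threshold Retention-probability cutoff for the
#'   deterministic mask, in (0, 1) (default 0.5).
#'
#' @return An object of class `gate_config`.
#' @examples
#' cfg <- gate_config()
#' retention_probability(0, 0.67, cfg)
#' @export
gate_config <- function(zeta = 1.1, gamma = -0.1, beta_start = 0.67,
                        beta_end = 0.1, selection_threshold = 0.5) {
  stopifnot(
    "gamma must be < 0" = gamma < 0,
    "zeta must be > 1" = zeta > 1,
    "temperatures must satisfy 0 < beta_end <= beta_start" =
      beta_end > 0 && beta_end <= beta_start,
    "selection_threshold must be in (0,1)" =
      selection_threshold > 0 && selection_threshold < 1
  )
  structure(
    list(zeta = zeta, gamma = gamma, beta_start = beta_start,
         beta_end = beta_end, selection_threshold = selection_threshold),
    class = "gate_config"
  )
}

#' Per-view gate state
#'
#' One learnable logit `alpha` per view plus the current temperature `beta`.
#' `alpha` parameterizes the Hard-Concrete distribution of each view's gate;
#' `beta` is annealed towards `beta_end` during training.
#'
#' @param alpha Numeric vector of gate logits, one per view.
#' @param beta Current temperature (scalar, positive).
#' @param view_names Optional character vector naming the views.
#'
#' @return An object of class `gate_state`.
#' @export
gate_state <- function(alpha, beta, view_names = NULL) {
  stopifnot(
    "alpha must be a non-empty numeric vector" =
      is.numeric(alpha) && length(alpha) >= 1 && all(is.finite(alpha)),
    "beta must be a positive scalar" =
      is.numeric(beta) && length(beta) == 1 && beta > 0
  )
  if (!is.null(view_names)) stopifnot(length(view_names) == length(alpha))
  structure(list(alpha = as.numeric(alpha), beta = beta,
                 view_names = view_names),
            class = "gate_state")
}

sigmoid <- function(x) 1 / (1 + exp(-x))
logit <- function(p) log(p) - log1p(-p)

#' Sample stochastic Hard-Concrete gates
#'
#' Draws one gate value per view by the reparameterization
#' `z_i = clip(sigma((logit(u_i) + alpha_i) / beta) * (zeta - gamma) + gamma, 0, 1)`
#' with uniform noise `u_i`. Values are clipped to `[0, 1]` with positive
#' probability of landing exactly on either boundary, so a sampled gate can
#' switch a view fully off (or on) while the interior remains differentiable
#' in `alpha`. The derivative of each `z_i` with respect to `alpha_i`
#' (zero in the clipped region) is returned alongside for use by the
#' training engine.
#'
#' @param state A [gate_state()].
#' @param config A [gate_config()].
#' @param u Uniform noise vector in the open interval (0, 1), one value per
#'   view. Supplying it explicitly makes sampling reproducible; by default it
#'   is drawn from the session RNG.
#'
#' @return A list of class `gate_sample` with components `u`, `z` and
#'   `dz_dalpha`.
#' @examples
#' s <- gate_state(alpha = c(0, -5, 10), beta = 0.67)
#' sample_gates(s, gate_config(), u = c(0.5, 0.5, 0.5))$z
#' @export
sample_gates <- function(state, config = gate_config(),
                         u = stats::runif(length(state$alpha))) {
  stopifnot(inherits(state, "gate_state"), inherits(config, "gate_config"))
  if (length(u) != length(state$alpha)) {
    stop("noise vector length must equal the number of views")
  }
  if (any(u <= 0 | u >= 1)) {
    stop("invalid noise: u components must lie strictly inside (0, 1)")
  }
  span <- config$zeta - config$gamma
  s <- sigmoid((logit(u) + state$alpha) / state$beta)
  raw <- s * span + config$gamma
  z <- pmin(pmax(raw, 0), 1)
  dz <- ifelse(raw > 0 & raw < 1, s * (1 - s) * span / state$beta, 0)
  structure(list(u = u, z = z, dz_dalpha = dz), class = "gate_sample")
}

#' Probability that a gate is open
#'
#' Closed-form retention probability `P(z > 0) = sigma(alpha - beta *
#' log(-gamma / zeta))` of the Hard-Concrete gate. This is the per-view
#' summand of the expected-L0 penalty and the quantity tracked per epoch in
#' gate-trajectory logs.
#'
#' @param alpha Gate logit(s); vectorized.
#' @param beta Temperature.
#' @param config A [gate_config()].
#'
#' @return Probability (vector) in (0, 1), strictly increasing in `alpha`.
#' @export
retention_probability <- function(alpha, beta, config = gate_config()) {
  stopifnot(inherits(config, "gate_config"), beta >= 0)
  sigmoid(alpha - beta * log(-config$gamma / config$zeta))
}

#' Expected L0 norm of the view gates
#'
#' Sum over views of the retention probabilities
#' `sum_i sigma(alpha_i - beta * log(-gamma / zeta))`: the expected number of
#' active views under the current gate state, used as the differentiable
#' sparsity penalty.
#'
#' @param state A [gate_state()].
#' @param config A [gate_config()].
#' @return Scalar in (0, N) for N views.
#' @export
expected_l0 <- function(state, config = gate_config()) {
  stopifnot(inherits(state, "gate_state"))
  sum(retention_probability(state$alpha, state$beta, config))
}

# Gradient of expected_l0 w.r.t. alpha: sigma'(alpha - beta * log(-gamma/zeta))
expected_l0_grad <- function(state, config = gate_config()) {
  p <- retention_probability(state$alpha, state$beta, config)
  p * (1 - p)
}

#' Boundary probabilities of the Hard-Concrete gate
#'
#' Closed forms for the point masses at the clipped boundaries:
#' `P(z = 0) = sigma(beta * log(-gamma / zeta) - alpha)` and
#' `P(z = 1) = sigma(alpha - beta * log((1 - gamma) / (zeta - 1)))`.
#' With the default stretch (`zeta` = 1.1, `gamma` = -0.1) both log terms
#' equal `log(11)`, so at `alpha = 0` the two masses coincide. Primarily an
#' analytic oracle for validating the sampler.
#'
#' @inheritParams retention_probability
#' @return A list with components `p_zero` and `p_one` (vectorized in
#'   `alpha`).
#' @export
boundary_probabilities <- function(alpha, beta, config = gate_config()) {
  stopifnot(inherits(config, "gate_config"), beta >= 0)
  if (config$zeta <= 1) stop("p_one undefined for zeta <= 1")
  p_zero <- sigmoid(beta * log(-config$gamma / config$zeta) - alpha)
  p_one <- sigmoid(alpha - beta * log((1 - config$gamma) / (config$zeta - 1)))
  list(p_zero = p_zero, p_one = p_one)
}

#' Anneal the concrete temperature
#'
#' Linear schedule from `beta_start` at epoch 0 to `beta_end` at the final
#' epoch. A single-epoch run uses `beta_start`.
#'
#' @param epoch Zero-based epoch index, `0 <= epoch < total_epochs`.
#' @param total_epochs Number of training epochs (>= 1).
#' @param config A [gate_config()].
#' @return Temperature for this epoch.
#' @export
anneal_beta <- function(epoch, total_epochs, config = gate_config()) {
  stopifnot(inherits(config, "gate_config"))
  if (total_epochs < 1) stop("total_epochs must be >= 1")
  if (any(epoch < 0 | epoch >= total_epochs)) {
    stop("epoch must satisfy 0 <= epoch < total_epochs")
  }
  if (total_epochs == 1) return(rep(config$beta_start, length(epoch)))
  frac <- epoch / (total_epochs - 1)
  config$beta_start + (config$beta_end - config$beta_start) * frac
}

#' Deterministic test-time view mask
#'
#' A view is retained iff its retention probability exceeds the configured
#' selection threshold. Retained gates are treated as exactly 1 at inference
#' and dropped views are not encoded at all, which is what the linear
#' FLOPs-per-view accounting assumes.
#'
#' @param state A [gate_state()].
#' @param config A [gate_config()].
#' @return Logical vector, `TRUE` for retained views (named if the state
#'   carries view names).
#' @examples
#' deterministic_mask(gate_state(c(5, -5), beta = 0.1), gate_config())
#' @export
deterministic_mask <- function(state, config = gate_config()) {
  stopifnot(inherits(state, "gate_state"))
  p <- retention_probability(state$alpha, state$beta, config)
  mask <- p > config$selection_threshold
  if (!is.null(state$view_names)) names(mask) <- state$view_names
  mask
}

#' @export
print.gate_state <- function(x, ...) {
  p <- retention_probability(x$alpha, x$beta)
  nm <- x$view_names %||% paste0("view", seq_along(x$alpha))
  cat(sprintf("<gate_state> %d views, beta = %.3f\n", length(x$alpha), x$beta))
  print(tibble::tibble(view = nm, alpha = x$alpha,
                       retention_probability = p))
  invisible(x)
}
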