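#' Loss configuration for the compound objective
#'
#' The training objective is
#' `L_total = L_CE + lambda_contrast * L_contrast + lambda_sparsity * L_L0`:
#' standard cross-entropy, a supervised contrastive term that sharpens the
#' separation of sibling species in representation space, and the expected-L0
#' view-sparsity penalty whose weight is swept to trace the accuracy/cost
#' Pareto frontier.
#'
#' @param lambda_contrast Weight of the supervised contrastive term
#'   (default 0.2).
#' @param lambda_sparsity Weight of the expected-L0 term (default 0; set per
#'   sweep point).
#' @param tau Contrastive temperature (default 0.1).
#' @return An object of class `loss_config`.
#' @export
loss_config <- function(lambda_contrast = 0.2, lambda_sparsity = 0,
                        tau = 0.1) {
  stopifnot(
    "tau must be > 0" = tau > 0,
    "lambda weights must be >= 0" =
      lambda_contrast >= 0 && lambda_sparsity >= 0
  )
  structure(list(lambda_contrast = lambda_contrast,
                 lambda_sparsity = lambda_sparsity, tau = tau),
            class = "loss_config")
}

#' Mean cross-entropy of predicted class probabilities
#'
#' Mean negative log-probability of the true class. Probabilities below
#' `eps` at the true class are clamped (with a message) rather than
#' producing an infinite loss.
#'
#' @param probabilities Numeric matrix, one row per sample, one column per
#'   class; rows sum to 1.
#' @param labels Integer class indices in `1..ncol(probabilities)`.
#' @param eps Clamp floor for the true-class probability.
#' @return Non-negative scalar.
#' @examples
#' cross_entropy(matrix(c(0.5, 0.5), 1), 1) # log(2)
#' @export
cross_entropy <- function(probabilities, labels, eps = 1e-12) {
  probabilities <- rbind(probabilities)
  stopifnot(nrow(probabilities) == length(labels),
            all(labels >= 1), all(labels <= ncol(probabilities)))
  p_true <- probabilities[cbind(seq_along(labels), labels)]
  if (any(p_true < eps)) {
    message("cross_entropy: ", sum(p_true < eps),
            " true-class probabilities clamped to eps")
    p_true <- pmax(p_true, eps)
  }
  mean(-log(p_true))
}

#' Supervised contrastive loss
#'
#' For each anchor with at least one same-class partner in the batch,
#' `-(1/|P(i)|) * sum_{p in P(i)} log( exp(s_ip / tau) / sum_{a != i}
#' exp(s_ia / tau) )` where `s` is cosine similarity between internally
#' L2-normalized representations; the loss is averaged over eligible
#' anchors. Anchors without positives are skipped; a batch with no eligible
#' anchors scores 0.
#'
#' @param representations Numeric matrix, one row per sample.
#' @param labels Class labels (any atomic type; compared with `==`).
#' @param tau Temperature (> 0).
#' @return Non-negative scalar.
#' @export
supervised_contrastive <- function(representations, labels, tau = 0.1) {
  representations <- rbind(representations)
  n <- nrow(representations)
  if (n < 2) stop("supervised_contrastive requires a batch of at least 2")
  stopifnot(length(labels) == n, tau > 0)
  nrm <- sqrt(rowSums(representations^2))
  nrm[nrm == 0] <- 1
  g <- representations / nrm
  sim <- tcrossprod(g) / tau
  same <- outer(labels, labels, `==`)
  diag(same) <- FALSE
  # log-sum-exp over all non-self candidates, per anchor
  off <- !diag(TRUE, n)
  losses <- vapply(seq_len(n), function(i) {
    pos <- which(same[i, ])
    if (length(pos) == 0) return(NA_real_)
    cand <- sim[i, off[i, ]]
    lse <- max(cand) + log(sum(exp(cand - max(cand))))
    mean(lse - sim[i, pos])
  }, numeric(1))
  eligible <- !is.na(losses)
  if (!any(eligible)) return(0)
  mean(losses[eligible])
}

# Gradient of supervised_contrastive w.r.t. the raw representations.
# Returns the loss and its gradient matrix; used by the training engine.
supcon_grad <- function(representations, labels, tau = 0.1) {
  n <- nrow(representations)
  stopifnot(n >= 2)
  nrm <- sqrt(rowSums(representations^2))
  nrm[nrm == 0] <- 1
  g <- representations / nrm
  sim <- tcrossprod(g) / tau
  same <- outer(labels, labels, `==`)
  diag(same) <- FALSE
  n_pos <- rowSums(same)
  eligible <- n_pos > 0
  n_e <- sum(eligible)
  if (n_e == 0) {
    return(list(loss = 0, grad = matrix(0, n, ncol(representations))))
  }
  expm <- exp(sim - apply(sim, 1, max))
  diag(expm) <- 0
  denom <- rowSums(expm)
  soft <- expm / denom                       # softmax over non-self, per row
  # dL/dsim[a,b] for eligible anchors a (b != a)
  G <- matrix(0, n, n)
  G[eligible, ] <- (soft[eligible, , drop = FALSE] -
                      same[eligible, , drop = FALSE] /
                        n_pos[eligible]) / n_e
  diag(G) <- 0
  loss_terms <- vapply(which(eligible), function(i) {
    lse <- log(denom[i]) + apply(sim, 1, max)[i]
    mean(lse - sim[i, same[i, ]])
  }, numeric(1))
  loss <- mean(loss_terms)
  # sim = g g^T / tau  =>  dL/dg = (G + G^T) g / tau
  dg <- (G + t(G)) %*% g / tau
  # back through row-normalization g = r / ||r||
  dot <- rowSums(dg * g)
  grad <- (dg - g * dot) / nrm
  list(loss = loss, grad = grad)
}

#' Combine loss components into the compound objective
#'
#' @param ce Cross-entropy value.
#' @param contrast Supervised contrastive value.
#' @param l0 Expected-L0 value.
#' @param config A [loss_config()].
#' @return A one-row tibble of class `loss_breakdown` with columns `ce`,
#'   `contrast`, `l0`, `total`.
#' @examples
#' total_loss(1, 2, 4, loss_config(lambda_contrast = 0.2,
#'                                 lambda_sparsity = 0.5)) # total 3.4
#' @export
total_loss <- function(ce, contrast, l0, config = loss_config()) {
  stopifnot(inherits(config, "loss_config"),
            is.finite(ce), is.finite(contrast), is.finite(l0))
  total <- ce + config$lambda_contrast * contrast +
    config$lambda_sparsity * l0
  structure(tibble::tibble(ce = ce, contrast = contrast, l0 = l0,
                           total = total),
            class = c("loss_breakdown", class(tibble::tibble())))
}
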