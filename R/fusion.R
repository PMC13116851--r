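#' Fusion configuration
#'
#' Multi-head self-attention fusion over the per-view tokens: 8 heads by
#' default, one encoder block (attention + feed-forward, both residual),
#' followed by mean pooling of the active output tokens into a single
#' specimen representation.
#'
#' @param n_classes Number of species labels (>= 2).
#' @param d Token dimension D; must be divisible by `n_heads` (default 16).
#' @param n_heads Attention heads (default 8).
#' @param n_layers Encoder block count (default 1).
#' @param ff_ratio Feed-forward width ratio (default 4).
#' @return An object of class `fusion_config`.
#' @export
fusion_config <- function(n_classes, d = 16, n_heads = 8, n_layers = 1,
                          ff_ratio = 4) {
  stopifnot(n_classes >= 2, d %% n_heads == 0, n_layers >= 1,
            ff_ratio >= 1)
  if (n_layers != 1) {
    stop("the reference fusion module implements a single encoder block")
  }
  structure(list(n_classes = n_classes, d = d, n_heads = n_heads,
                 n_layers = n_layers, ff_ratio = ff_ratio),
            class = "fusion_config")
}

#' Build position-encoded view tokens
#'
#' `e_i = v_i + PE_i`: each provided view embedding is shifted by its
#' learnable view-specific positional encoding; views absent from the input
#' are marked inactive so downstream attention and pooling skip them.
#'
#' @param embeddings List of `view_embedding` objects (from
#'   [encode_view()]) or a list of `list(v = vector, view_index = 0-based
#'   integer)`.
#' @param table `N x D` matrix of positional encodings (the `PE` block of a
#'   model's fusion parameters).
#' @return A list of class `token_set` with `tokens` (`N x D` matrix, zero
#'   rows for absent views) and `active_mask` (logical length N).
#' @export
make_tokens <- function(embeddings, table) {
  stopifnot(is.list(embeddings), is.matrix(table))
  N <- nrow(table)
  idx <- vapply(embeddings, function(e) as.integer(e$view_index),
                integer(1))
  if (anyDuplicated(idx)) stop("duplicate view_index in embeddings")
  if (any(idx < 0 | idx >= N)) stop("view_index out of range")
  tokens <- matrix(0, N, ncol(table))
  active <- rep(FALSE, N)
  for (e in embeddings) {
    i <- as.integer(e$view_index) + 1L
    tokens[i, ] <- e$v + table[i, ]
    active[i] <- TRUE
  }
  structure(list(tokens = tokens, active_mask = active),
            class = "token_set")
}

#' Apply gate values to a token set
#'
#' Scales token `i` by `z_i`. A gate of exactly zero removes the view from
#' the active set, so that soft gating during training and hard removal at
#' inference produce identical attention computations.
#'
#' @param tokens A [make_tokens()] `token_set`.
#' @param z Numeric gate vector, one value per view slot.
#' @return The gated `token_set`.
#' @export
apply_gates <- function(tokens, z) {
  stopifnot(inherits(tokens, "token_set"))
  if (length(z) != nrow(tokens$tokens)) {
    stop("gate vector length must equal the number of view slots")
  }
  tokens$tokens <- tokens$tokens * z
  tokens$active_mask <- tokens$active_mask & z > 0
  tokens
}

#' Fuse view tokens into a specimen representation
#'
#' Multi-head self-attention over the active tokens (softmax normalized
#' over active keys only) with residual connection, a residual feed-forward
#' block, then mean pooling of the active output tokens. Because attention
#' is a set operation and pooling is symmetric, permuting tokens together
#' with their positional encodings leaves the output unchanged.
#'
#' @param tokens A gated `token_set`.
#' @param params Fusion parameter block (`fus` element of an
#'   [init_model()] model's parameters).
#' @param config A [fusion_config()].
#' @return Numeric fused vector of length D.
#' @export
fuse <- function(tokens, params, config) {
  stopifnot(inherits(tokens, "token_set"), inherits(config, "fusion_config"))
  if (!any(tokens$active_mask)) stop("no active views to fuse")
  # tokens are already built (PE added) and gated, so run the engine on the
  # token matrix directly with identity gates and the PE term zeroed out
  ff <- fusion_forward(zero_pe(params), config, emb = tokens$tokens,
                       z = rep(1, nrow(tokens$tokens)),
                       active = tokens$active_mask, B = 1)
  as.vector(ff$fused)
}

zero_pe <- function(params) {
  params$PE <- params$PE * 0
  params
}

#' Classify a fused representation
#'
#' Linear head plus softmax; probabilities are strictly positive and sum
#' to 1.
#'
#' @param fused Numeric vector (length D) or `B x D` matrix.
#' @param head Parameter list with `Wc` (`D x C`) and `bc` (length C).
#' @param class_names Optional class labels for naming the output.
#' @return Probability vector (or matrix, one row per sample).
#' @export
classify <- function(fused, head, class_names = NULL) {
  fused <- rbind(fused)
  stopifnot(all(is.finite(fused)))
  logits <- sweep(fused %*% head$Wc, 2, head$bc, `+`)
  probs <- softmax_rows(logits)
  if (!is.null(class_names)) colnames(probs) <- class_names
  if (nrow(probs) == 1) probs <- probs[1, ] else probs
}

#' Top-k predictions from class probabilities
#'
#' Ranks classes by descending probability, breaking ties by class index
#' (stable, reproducible reports).
#'
#' @param probabilities Numeric probability vector, optionally named.
#' @param k Number of predictions to return (default 3); `1 <= k <=`
#'   number of classes.
#' @return A tibble with columns `rank`, `class_index`, `species` (if
#'   names are available) and `confidence`.
#' @export
predict_topk <- function(probabilities, k = 3) {
  if (k < 1) stop("k must be >= 1")
  if (k > length(probabilities)) stop("k exceeds the number of classes")
  ord <- order(-probabilities, seq_along(probabilities))
  top <- ord[seq_len(k)]
  out <- tibble::tibble(
    rank = seq_len(k),
    class_index = top,
    confidence = as.numeric(probabilities[top])
  )
  if (!is.null(names(probabilities))) {
    out$species <- names(probabilities)[top]
    out <- out[, c("rank", "class_index", "species", "confidence")]
  }
  out
}
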