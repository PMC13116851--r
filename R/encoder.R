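#' Encoder configuration
#'
#' The per-view encoder is pluggable behind a contract: all views share one
#' parameter set (weight sharing), spatial features are aggregated by
#' learnable-query cross-attention pooling, and the output is a fixed-size
#' view embedding. The built-in `"reference-tiny"` backbone (a linear patch
#' stem with tanh nonlinearity plus query pooling) is small enough to train
#' on one CPU and is used throughout the test suite; named production
#' backbones can be registered when the runtime provides them.
#'
#' @param backbone_name Encoder identifier (default `"reference-tiny"`).
#' @param input_mode `"feature"` (each view is a feature vector) or
#'   `"image"` (each view is an RGB image).
#' @param embedding_dim Output view-embedding dimension D (default 16).
#' @param hidden_dim Stem width H (default 16).
#' @param n_queries Learnable query count for pooling (default 1).
#' @param input_size Square side length images are resized to before
#'   encoding (default 224).
#' @param patch_grid Patches per side in image mode (default 4, i.e. 16
#'   spatial positions).
#' @param feature_dim Input feature dimension in feature mode (default 16).
#' @param norm_mean,norm_sd Per-channel normalization constants applied
#'   before the stem (defaults 0.5 / 0.5; set to the ImageNet constants when
#'   using a pretrained production backbone).
#' @return An object of class `encoder_config`.
#' @export
encoder_config <- function(backbone_name = "reference-tiny",
                           input_mode = c("feature", "image"),
                           embedding_dim = 16, hidden_dim = 16,
                           n_queries = 1, input_size = 224,
                           patch_grid = 4, feature_dim = 16,
                           norm_mean = 0.5, norm_sd = 0.5) {
  input_mode <- match.arg(input_mode)
  stopifnot(embedding_dim >= 2, n_queries >= 1, hidden_dim >= 1,
            input_size >= patch_grid, patch_grid >= 1, feature_dim >= 1,
            norm_sd > 0)
  if (input_mode == "image" && input_size %% patch_grid != 0) {
    stop("input_size must be divisible by patch_grid")
  }
  structure(list(backbone_name = backbone_name, input_mode = input_mode,
                 embedding_dim = embedding_dim, hidden_dim = hidden_dim,
                 n_queries = n_queries, input_size = input_size,
                 patch_grid = patch_grid, feature_dim = feature_dim,
                 norm_mean = norm_mean, norm_sd = norm_sd),
            class = "encoder_config")
}

encoder_input_dim <- function(cfg) {
  if (cfg$input_mode == "feature") {
    cfg$feature_dim
  } else {
    (cfg$input_size / cfg$patch_grid)^2 * 3
  }
}

#' Preprocess a raw RGB image
#'
#' Scales pixel values to `[0, 1]` (8-bit inputs are divided by 255) and
#' bilinearly resizes to the configured square input size. Deterministic.
#'
#' @param image Numeric `H x W x 3` array.
#' @param config An [encoder_config()].
#' @return `input_size x input_size x 3` array in `[0, 1]`.
#' @export
preprocess <- function(image, config) {
  stopifnot(inherits(config, "encoder_config"))
  if (!(is.array(image) && length(dim(image)) == 3 && dim(image)[3] == 3)) {
    stop("format error: expected an H x W x 3 RGB array")
  }
  if (max(image) > 1) image <- image / 255
  image[image < 0] <- 0
  image[image > 1] <- 1
  n <- config$input_size
  if (dim(image)[1] == n && dim(image)[2] == n) return(image)
  resize_bilinear(image, n, n)
}

# Bilinear resize via EBImage when available, with an internal fallback of
# the same interpolation.
resize_bilinear <- function(image, h, w) {
  if (requireNamespace("EBImage", quietly = TRUE)) {
    eb <- EBImage::Image(aperm(image, c(2, 1, 3)), colormode = "Color")
    out <- EBImage::resize(eb, w = w, h = h, filter = "bilinear")
    return(aperm(EBImage::imageData(out), c(2, 1, 3)))
  }
  H <- dim(image)[1]; W <- dim(image)[2]
  # single-pixel degenerate axes fall back to constant fill
  yi <- if (h == 1) rep(1, 1) else seq(1, H, length.out = h)
  xi <- if (w == 1) rep(1, 1) else seq(1, W, length.out = w)
  y0 <- pmin(floor(yi), H - 1); y0[H == 1] <- 1
  x0 <- pmin(floor(xi), W - 1); x0[W == 1] <- 1
  if (H == 1) { y0 <- rep(1, h); fy <- rep(0, h) } else fy <- yi - y0
  if (W == 1) { x0 <- rep(1, w); fx <- rep(0, w) } else fx <- xi - x0
  y1 <- pmin(y0 + 1, H); x1 <- pmin(x0 + 1, W)
  out <- array(0, c(h, w, 3))
  for (ch in 1:3) {
    m <- image[, , ch]
    out[, , ch] <- (1 - fy) %o% (1 - fx) * m[y0, x0, drop = FALSE] +
      (1 - fy) %o% fx * m[y0, x1, drop = FALSE] +
      fy %o% (1 - fx) * m[y1, x0, drop = FALSE] +
      fy %o% fx * m[y1, x1, drop = FALSE]
  }
  out
}

#' Augmentation configuration
#'
#' Training-time augmentation mirrors common practice for specimen
#' photographs taken under heterogeneous lab conditions: flips, rotation
#' within +/-60 degrees, brightness/contrast/saturation jitter, and random
#' rectangular erasing (occlusion simulation).
#'
#' @param p_hflip,p_vflip Flip probabilities (defaults 0.5, 0.5).
#' @param p_rotate Probability of rotating (default 1), with angle drawn
#'   uniformly in `[-max_angle, max_angle]`.
#' @param max_angle Rotation bound in degrees (default 60).
#' @param p_jitter Probability of colour jitter (default 0.8).
#' @param jitter_strength Max relative change of brightness, contrast and
#'   saturation (default 0.2).
#' @param p_erase Probability of random erasing (default 0.25).
#' @param erase_frac Range of erased-area fraction (default c(0.02, 0.2)).
#' @return An object of class `augment_config`.
#' @export
augment_config <- function(p_hflip = 0.5, p_vflip = 0.5, p_rotate = 1,
                           max_angle = 60, p_jitter = 0.8,
                           jitter_strength = 0.2, p_erase = 0.25,
                           erase_frac = c(0.02, 0.2)) {
  structure(list(p_hflip = p_hflip, p_vflip = p_vflip, p_rotate = p_rotate,
                 max_angle = max_angle, p_jitter = p_jitter,
                 jitter_strength = jitter_strength, p_erase = p_erase,
                 erase_frac = erase_frac),
            class = "augment_config")
}

#' Randomly augment a view image
#'
#' Applies, each with its configured probability: horizontal/vertical flip,
#' rotation uniform in `[-max_angle, +max_angle]`, colour jitter and random
#' erasing. Fully determined by the R RNG state, so seeding the session RNG
#' reproduces the augmentation exactly. Output has the input's shape with
#' values clipped to `[0, 1]`.
#'
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param config An [augment_config()].
#' @return Augmented array of the same shape.
#' @export
augment <- function(image, config = augment_config()) {
  stopifnot(is.array(image), length(dim(image)) == 3)
  if (stats::runif(1) < config$p_hflip) {
    image <- image[, rev(seq_len(dim(image)[2])), , drop = FALSE]
  }
  if (stats::runif(1) < config$p_vflip) {
    image <- image[rev(seq_len(dim(image)[1])), , , drop = FALSE]
  }
  if (stats::runif(1) < config$p_rotate) {
    angle <- stats::runif(1, -config$max_angle, config$max_angle)
    image <- rotate_image(image, angle)
  }
  if (stats::runif(1) < config$p_jitter) {
    s <- config$jitter_strength
    bright <- stats::runif(1, 1 - s, 1 + s)
    contr <- stats::runif(1, 1 - s, 1 + s)
    sat <- stats::runif(1, 1 - s, 1 + s)
    image <- image * bright
    mu <- mean(image)
    image <- (image - mu) * contr + mu
    gray <- array(rep((image[, , 1] + image[, , 2] + image[, , 3]) / 3, 3),
                  dim = dim(image))
    image <- gray + (image - gray) * sat
  }
  if (stats::runif(1) < config$p_erase) {
    H <- dim(image)[1]; W <- dim(image)[2]
    frac <- stats::runif(1, config$erase_frac[1], config$erase_frac[2])
    aspect <- stats::runif(1, 0.3, 3.3)
    eh <- max(1, round(sqrt(frac * H * W * aspect)))
    ew <- max(1, round(sqrt(frac * H * W / aspect)))
    eh <- min(eh, H); ew <- min(ew, W)
    y <- sample.int(H - eh + 1, 1)
    x <- sample.int(W - ew + 1, 1)
    image[y:(y + eh - 1), x:(x + ew - 1), ] <- 0.5
  }
  image[image < 0] <- 0
  image[image > 1] <- 1
  image
}

# Rotation about the image centre, bilinear, same output size, 0.5 fill.
rotate_image <- function(image, angle_deg) {
  if (angle_deg == 0) return(image)
  if (requireNamespace("EBImage", quietly = TRUE)) {
    eb <- EBImage::Image(aperm(image, c(2, 1, 3)), colormode = "Color")
    out <- EBImage::rotate(eb, angle_deg, filter = "bilinear",
                           output.dim = dim(eb)[1:2], bg.col = "grey50")
    return(aperm(EBImage::imageData(out), c(2, 1, 3)))
  }
  H <- dim(image)[1]; W <- dim(image)[2]
  th <- angle_deg * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  yy <- matrix(seq_len(H), H, W)
  xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  ys <- cos(th) * (yy - cy) - sin(th) * (xx - cx) + cy
  xs <- sin(th) * (yy - cy) + cos(th) * (xx - cx) + cx
  out <- array(0.5, dim(image))
  y0 <- floor(ys); x0 <- floor(xs)
  fy <- ys - y0; fx <- xs - x0
  valid <- y0 >= 1 & y0 < H & x0 >= 1 & x0 < W
  for (ch in 1:3) {
    m <- image[, , ch]
    plane <- matrix(0.5, H, W)
    idx <- which(valid)
    p00 <- m[cbind(y0[idx], x0[idx])]
    p01 <- m[cbind(y0[idx], x0[idx] + 1)]
    p10 <- m[cbind(y0[idx] + 1, x0[idx])]
    p11 <- m[cbind(y0[idx] + 1, x0[idx] + 1)]
    plane[idx] <- (1 - fy[idx]) * ((1 - fx[idx]) * p00 + fx[idx] * p01) +
      fy[idx] * ((1 - fx[idx]) * p10 + fx[idx] * p11)
    out[, , ch] <- plane
  }
  out
}

# Split a preprocessed image into the non-overlapping patch grid and
# flatten each patch (with normalization) into a row vector.
patchify <- function(image, cfg) {
  g <- cfg$patch_grid
  n <- cfg$input_size
  ps <- n / g
  out <- matrix(0, g * g, ps * ps * 3)
  k <- 0
  for (gy in seq_len(g)) {
    for (gx in seq_len(g)) {
      k <- k + 1
      patch <- image[((gy - 1) * ps + 1):(gy * ps),
                     ((gx - 1) * ps + 1):(gx * ps), , drop = FALSE]
      out[k, ] <- (as.vector(patch) - cfg$norm_mean) / cfg$norm_sd
    }
  }
  out
}

#' Learnable-query attention pooling
#'
#' Aggregates a `P x H` spatial feature map into a single embedding: each
#' of `n_queries` learnable queries cross-attends over the P positions
#' (scaled dot-product, softmax over positions), the per-query outputs are
#' concatenated and projected to the embedding dimension. With no positional
#' terms in the keys the result is invariant to the order of positions.
#'
#' @param spatial_features Numeric `P x H` matrix.
#' @param pooling Parameter list with `Qp` (`n_queries x H`), `Wk`, `Wv`
#'   (`H x H`), `Wo` (`(n_queries*H) x D`), `bo` (length D) — the `enc`
#'   parameter block of an [init_model()] model minus the stem.
#' @return Numeric embedding vector of length D.
#' @export
query_pool <- function(spatial_features, pooling) {
  X <- rbind(spatial_features)
  P <- nrow(X); H <- ncol(X)
  stopifnot(P >= 1, ncol(pooling$Qp) == H)
  K <- X %*% pooling$Wk
  Vv <- X %*% pooling$Wv
  sc <- pooling$Qp %*% t(K) / sqrt(H)          # nq x P
  A <- exp(sc - apply(sc, 1, max))
  A <- A / rowSums(A)
  O <- A %*% Vv                                 # nq x H
  # flatten in the engine's (query-fastest) column order
  ocat <- as.vector(O)
  as.vector(ocat %*% pooling$Wo + pooling$bo)
}

#' Encode one view with the shared-weight encoder
#'
#' Runs the reference-tiny encoder on a single preprocessed view: feature
#' mode takes the raw feature vector, image mode patchifies the image first;
#' both then pass through the shared stem and [query_pool()]. The same
#' parameter set serves every view (weight-sharing contract).
#'
#' @param x A feature vector (feature mode) or preprocessed
#'   `input_size x input_size x 3` image (image mode).
#' @param model An [init_model()] model.
#' @param view_name Name of the view being encoded; must belong to the
#'   model's view vocabulary.
#' @return A list of class `view_embedding` with `v` (length-D vector) and
#'   `view_index` (0-based slot).
#' @export
encode_view <- function(x, model, view_name) {
  stopifnot(inherits(model, "sv_model"))
  if (!view_name %in% model$view_names) {
    stop("unknown view: '", view_name, "' is not in the view vocabulary")
  }
  cfg <- model$encoder
  if (cfg$input_mode == "feature") {
    stopifnot(length(x) == cfg$feature_dim)
    xs <- array(x, c(1, 1, cfg$feature_dim))
  } else {
    pm <- patchify(preprocess(x, cfg), cfg)
    xs <- array(pm, c(1, dim(pm)))
  }
  emb <- encoder_forward(model$params$enc, xs)$emb
  structure(list(v = as.vector(emb),
                 view_index = match(view_name, model$view_names) - 1L,
                 view_name = view_name),
            class = "view_embedding")
}
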