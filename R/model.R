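# Reference-tiny multi-view model: shared per-view encoder (linear stem +
# learnable-query attention pooling), gated 8-head self-attention fusion,
# linear classifier and contrastive projection head. Written with explicit
# analytic backpropagation (no autodiff); every gradient path is covered by
# finite-difference tests.
#
# Tensor layout: a batch of B specimens x V views is stored view-major as
# R = B*V rows, row r = (v-1)*B + b. Spatial features are R x P x Fin
# arrays (P = 1 in feature mode, a patch grid in image mode).

#' Initialize a reference-tiny multi-view model
#'
#' Builds the parameter set for the shared-weight encoder, learnable
#' view-specific positional encodings, multi-head self-attention fusion
#' block, classifier and contrastive projection head, plus one Hard-Concrete
#' gate logit per view. All views share a single encoder parameter set.
#'
#' @param encoder_config An [encoder_config()].
#' @param fusion_config A [fusion_config()].
#' @param gate_config A [gate_config()].
#' @param view_names Character vector of view names (length N).
#' @param class_names Character vector of species labels (length >= 2).
#' @param seed RNG seed for the random initialization.
#' @param alpha_init Initial gate logit for every view (default 1, i.e.
#'   gates start mostly open).
#' @return An object of class `sv_model`.
#' @export
init_model <- function(encoder_config, fusion_config,
                       gate_config = gate_config(),
                       view_names, class_names, seed = 1, alpha_init = 1) {
  stopifnot(inherits(encoder_config, "encoder_config"),
            inherits(fusion_config, "fusion_config"),
            length(class_names) >= 2, length(view_names) >= 1)
  V <- length(view_names)
  C <- length(class_names)
  D <- fusion_config$d
  H <- encoder_config$hidden_dim
  nq <- encoder_config$n_queries
  Fin <- encoder_input_dim(encoder_config)
  if (fusion_config$n_classes != C) {
    stop("fusion_config$n_classes must match length(class_names)")
  }
  set.seed(seed)
  rmat <- function(a, b) matrix(stats::rnorm(a * b, sd = sqrt(2 / (a + b))),
                                a, b)
  params <- list(
    enc = list(
      W1 = rmat(Fin, H), b1 = numeric(H),
      Qp = rmat(nq, H), Wk = rmat(H, H), Wv = rmat(H, H),
      Wo = rmat(nq * H, D), bo = numeric(D)
    ),
    fus = list(
      PE = rmat(V, D) * 0.1,
      Wq = rmat(D, D), Wk = rmat(D, D), Wv = rmat(D, D),
      Wo = rmat(D, D), bo = numeric(D),
      W1 = rmat(D, fusion_config$ff_ratio * D),
      b1 = numeric(fusion_config$ff_ratio * D),
      W2 = rmat(fusion_config$ff_ratio * D, D), b2 = numeric(D)
    ),
    head = list(Wc = rmat(D, C), bc = numeric(C),
                Wproj = rmat(D, D)),
    sv_heads = lapply(seq_len(V), function(v) {
      list(W = rmat(D, C), b = numeric(C))
    }),
    alpha = rep(alpha_init, V)
  )
  structure(list(
    params = params,
    encoder = encoder_config,
    fusion = fusion_config,
    gate = gate_config,
    view_names = view_names,
    class_names = class_names
  ), class = "sv_model")
}

#' @export
print.sv_model <- function(x, ...) {
  cat(sprintf(
    "<sv_model> %d views, %d classes, D = %d, %d heads; encoder: %s\n",
    length(x$view_names), length(x$class_names), x$fusion$d,
    x$fusion$n_heads, x$encoder$backbone_name))
  invisible(x)
}

# 0/1 matrix mapping embedding columns to attention heads
head_mask <- function(D, n_heads) {
  dh <- D / n_heads
  M <- matrix(0, D, n_heads)
  for (h in seq_len(n_heads)) M[((h - 1) * dh + 1):(h * dh), h] <- 1
  M
}

# ---- encoder forward/backward (stem + query pooling) ----------------------

# xs: R x P x Fin array -> list(emb = R x D, cache)
encoder_forward <- function(p, xs) {
  dms <- dim(xs)
  R <- dms[1]; P <- dms[2]; Fin <- dms[3]
  H <- ncol(p$W1); nq <- nrow(p$Qp); D <- ncol(p$Wo)
  Xf <- matrix(xs, R * P, Fin)                      # (r,p)-major rows
  Hh <- tanh(sweep(Xf %*% p$W1, 2, p$b1, `+`))      # (R*P) x H
  K <- Hh %*% p$Wk
  Vv <- Hh %*% p$Wv
  if (P == 1) {
    # softmax over a single position is identically 1
    A <- array(1, c(R, nq, 1))
    sc <- A
    O <- array(0, c(R, nq, H))
    for (q in seq_len(nq)) O[, q, ] <- Vv
  } else {
    # attention of nq queries over P positions, per row r
    sc <- array(0, c(R, nq, P))                     # scores
    for (q in seq_len(nq)) {
      for (pp in seq_len(P)) {
        rows <- (pp - 1) * R + seq_len(R)
        sc[, q, pp] <- K[rows, , drop = FALSE] %*% p$Qp[q, ] / sqrt(H)
      }
    }
    A <- sc
    for (q in seq_len(nq)) {
      scq <- matrix(sc[, q, ], R, P)
      e <- exp(scq - scq[cbind(seq_len(R),
                               max.col(scq, ties.method = "first"))])
      A[, q, ] <- e / rowSums(e)
    }
    O <- array(0, c(R, nq, H))
    for (q in seq_len(nq)) {
      for (pp in seq_len(P)) {
        rows <- (pp - 1) * R + seq_len(R)
        O[, q, ] <- O[, q, ] + A[, q, pp] * Vv[rows, , drop = FALSE]
      }
    }
  }
  Ocat <- matrix(O, R, nq * H)   # column blocks are queries? see note below
  # O is R x nq x H; matrix() flattens (q fastest within column index h):
  # column index = (h-1)*nq + q. Wo rows must follow the same layout; they
  # do, because Wo is only ever used through this flattening.
  emb <- sweep(Ocat %*% p$Wo, 2, p$bo, `+`)
  list(emb = emb,
       cache = list(Xf = Xf, Hh = Hh, K = K, Vv = Vv, A = A, O = O,
                    Ocat = Ocat, R = R, P = P, nq = nq, H = H))
}

# demb: R x D -> list(grads, dxs = NULL)
encoder_backward <- function(p, cache, demb) {
  R <- cache$R; P <- cache$P; nq <- cache$nq; H <- cache$H
  g <- list()
  g$Wo <- crossprod(cache$Ocat, demb)
  g$bo <- colSums(demb)
  dOcat <- demb %*% t(p$Wo)
  dO <- array(dOcat, c(R, nq, H))
  dA <- array(0, c(R, nq, P))
  dVv <- matrix(0, R * P, H)
  for (q in seq_len(nq)) {
    for (pp in seq_len(P)) {
      rows <- (pp - 1) * R + seq_len(R)
      dA[, q, pp] <- rowSums(dO[, q, ] * cache$Vv[rows, , drop = FALSE])
      dVv[rows, ] <- dVv[rows, ] + cache$A[, q, pp] * dO[, q, ]
    }
  }
  dsc <- array(0, c(R, nq, P))
  for (q in seq_len(nq)) {
    Aq <- matrix(cache$A[, q, ], R, P)
    dAq <- matrix(dA[, q, ], R, P)
    sdot <- rowSums(dAq * Aq)
    dsc[, q, ] <- Aq * (dAq - sdot)
  }
  dK <- matrix(0, R * P, H)
  g$Qp <- matrix(0, nq, H)
  for (q in seq_len(nq)) {
    for (pp in seq_len(P)) {
      rows <- (pp - 1) * R + seq_len(R)
      dK[rows, ] <- dK[rows, ] +
        outer(dsc[, q, pp], p$Qp[q, ]) / sqrt(H)
      g$Qp[q, ] <- g$Qp[q, ] +
        colSums(dsc[, q, pp] * cache$K[rows, , drop = FALSE]) / sqrt(H)
    }
  }
  g$Wk <- crossprod(cache$Hh, dK)
  g$Wv <- crossprod(cache$Hh, dVv)
  dHh <- dK %*% t(p$Wk) + dVv %*% t(p$Wv)
  dS1 <- dHh * (1 - cache$Hh^2)
  g$W1 <- crossprod(cache$Xf, dS1)
  g$b1 <- colSums(dS1)
  g
}

# ---- fusion forward/backward ----------------------------------------------

# emb: R x D (view-major), z: gate values per view (length V), active:
# logical length V. Returns fused B x D and cache. Inactive views (z == 0 or
# absent) are excluded from attention and pooling.
fusion_forward <- function(p, cfg, emb, z, active, B) {
  V <- nrow(p$PE); D <- ncol(p$PE)
  Hd <- cfg$n_heads
  dh <- D / Hd
  M <- head_mask(D, Hd)
  T0 <- emb + p$PE[rep(seq_len(V), each = B), , drop = FALSE]
  Tk <- T0 * rep(z, each = B)
  act <- which(active & z > 0)
  if (length(act) == 0) stop("no active views to fuse")
  Q <- Tk %*% p$Wq; K <- Tk %*% p$Wk; Vv <- Tk %*% p$Wv
  nA <- length(act)
  SC <- array(0, c(B, Hd, nA, nA))
  rows_of <- function(v) (v - 1) * B + seq_len(B)
  for (i in seq_len(nA)) {
    Qi <- Q[rows_of(act[i]), , drop = FALSE]
    for (j in seq_len(nA)) {
      Kj <- K[rows_of(act[j]), , drop = FALSE]
      SC[, , i, j] <- ((Qi * Kj) %*% M) / sqrt(dh)
    }
  }
  # softmax over j
  A <- SC
  for (i in seq_len(nA)) {
    m <- SC[, , i, 1]
    if (nA > 1) for (j in 2:nA) m <- pmax(m, SC[, , i, j])
    s <- 0
    for (j in seq_len(nA)) {
      A[, , i, j] <- exp(SC[, , i, j] - m)
      s <- s + A[, , i, j]
    }
    for (j in seq_len(nA)) A[, , i, j] <- A[, , i, j] / s
  }
  AO <- matrix(0, V * B, D)
  for (i in seq_len(nA)) {
    acc <- matrix(0, B, D)
    for (j in seq_len(nA)) {
      Aexp <- matrix(A[, , i, j], B, Hd) %*% t(M)   # B x D
      acc <- acc + Aexp * Vv[rows_of(act[j]), , drop = FALSE]
    }
    AO[rows_of(act[i]), ] <- acc
  }
  MH <- matrix(0, V * B, D)
  act_rows <- as.integer(unlist(lapply(act, rows_of)))
  MH[act_rows, ] <- sweep(AO[act_rows, , drop = FALSE] %*% p$Wo, 2,
                          p$bo, `+`)
  U <- Tk + MH
  Smid <- sweep(U[act_rows, , drop = FALSE] %*% p$W1, 2, p$b1, `+`)
  Fmid <- pmax(Smid, 0)
  U2 <- U
  U2[act_rows, ] <- U[act_rows, , drop = FALSE] +
    sweep(Fmid %*% p$W2, 2, p$b2, `+`)
  fused <- matrix(0, B, D)
  for (v in act) fused <- fused + U2[rows_of(v), , drop = FALSE]
  fused <- fused / length(act)
  list(fused = fused,
       cache = list(T0 = T0, Tk = Tk, Q = Q, K = K, Vv = Vv, A = A,
                    AO = AO, U = U, Fmid = Fmid, act = act,
                    act_rows = act_rows, B = B, V = V, D = D, Hd = Hd,
                    dh = dh, M = M, z = z))
}

fusion_backward <- function(p, cache, dfused) {
  B <- cache$B; V <- cache$V; D <- cache$D
  Hd <- cache$Hd; dh <- cache$dh; M <- cache$M
  act <- cache$act; nA <- length(act); act_rows <- cache$act_rows
  rows_of <- function(v) (v - 1) * B + seq_len(B)
  g <- list()
  dU2 <- matrix(0, V * B, D)
  for (v in act) dU2[rows_of(v), ] <- dfused / nA
  dU2a <- dU2[act_rows, , drop = FALSE]
  # FFN
  dFmid <- dU2a %*% t(p$W2)
  g$W2 <- crossprod(cache$Fmid, dU2a)
  g$b2 <- colSums(dU2a)
  dSmid <- dFmid * (cache$Fmid > 0)
  Ua <- cache$U[act_rows, , drop = FALSE]
  g$W1 <- crossprod(Ua, dSmid)
  g$b1 <- colSums(dSmid)
  dU <- dU2
  dU[act_rows, ] <- dU2a + dSmid %*% t(p$W1)
  # MHSA output projection
  dMHa <- dU[act_rows, , drop = FALSE]
  AOa <- cache$AO[act_rows, , drop = FALSE]
  g$Wo <- crossprod(AOa, dMHa)
  g$bo <- colSums(dMHa)
  dAO <- matrix(0, V * B, D)
  dAO[act_rows, ] <- dMHa %*% t(p$Wo)
  # attention
  dA <- array(0, c(B, Hd, nA, nA))
  dVv <- matrix(0, V * B, D)
  for (i in seq_len(nA)) {
    dAOi <- dAO[rows_of(act[i]), , drop = FALSE]
    for (j in seq_len(nA)) {
      Vj <- cache$Vv[rows_of(act[j]), , drop = FALSE]
      dA[, , i, j] <- (dAOi * Vj) %*% M
      Aexp <- matrix(cache$A[, , i, j], B, Hd) %*% t(M)
      dVv[rows_of(act[j]), ] <- dVv[rows_of(act[j]), ] + Aexp * dAOi
    }
  }
  dSC <- array(0, c(B, Hd, nA, nA))
  for (i in seq_len(nA)) {
    sdot <- 0
    for (j in seq_len(nA)) sdot <- sdot + dA[, , i, j] * cache$A[, , i, j]
    for (j in seq_len(nA)) {
      dSC[, , i, j] <- cache$A[, , i, j] * (dA[, , i, j] - sdot)
    }
  }
  dQ <- matrix(0, V * B, D)
  dK <- matrix(0, V * B, D)
  for (i in seq_len(nA)) {
    for (j in seq_len(nA)) {
      dSCe <- matrix(dSC[, , i, j], B, Hd) %*% t(M) / sqrt(dh)
      dQ[rows_of(act[i]), ] <- dQ[rows_of(act[i]), ] +
        dSCe * cache$K[rows_of(act[j]), , drop = FALSE]
      dK[rows_of(act[j]), ] <- dK[rows_of(act[j]), ] +
        dSCe * cache$Q[rows_of(act[i]), , drop = FALSE]
    }
  }
  g$Wq <- crossprod(cache$Tk, dQ)
  g$Wk <- crossprod(cache$Tk, dK)
  g$Wv <- crossprod(cache$Tk, dVv)
  dTk <- dU + dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dVv %*% t(p$Wv)
  # gates: dL/dz_v = sum_b <dTk[row], T0[row]>
  dz <- numeric(V)
  for (v in act) {
    dz[v] <- sum(dTk[rows_of(v), , drop = FALSE] *
                   cache$T0[rows_of(v), , drop = FALSE])
  }
  dT0 <- dTk * rep(cache$z, each = B)
  g$PE <- matrix(0, V, D)
  for (v in seq_len(V)) g$PE[v, ] <- colSums(dT0[rows_of(v), , drop = FALSE])
  list(grads = g, demb = dT0, dz = dz)
}

# ---- full compound-loss forward + backward --------------------------------

# x: batch input (feature mode: B x V x F array; image mode: list of lists
# of images already preprocessed), y: labels 1..C, u: gate noise (length V)
# or NULL for deterministic gates z = zmask.
model_loss_grad <- function(model, x, y, loss_cfg, beta,
                            u = NULL, zmask = NULL, active = NULL,
                            compute_grads = TRUE) {
  p <- model$params
  V <- length(model$view_names)
  B <- length(y)
  xs <- as_spatial(x, model)
  if (is.null(active)) active <- rep(TRUE, V)
  state <- gate_state(p$alpha, beta, model$view_names)
  if (!is.null(u)) {
    gs <- sample_gates(state, model$gate, u)
    z <- gs$z
    dz_dalpha <- gs$dz_dalpha
  } else {
    z <- if (is.null(zmask)) rep(1, V) else as.numeric(zmask)
    dz_dalpha <- numeric(V)
  }
  # all gates closed: no views reach attention. The classifier can only
  # express its bias (the class prior); sparsity still drives alpha.
  if (!any(active & z > 0)) {
    D <- model$fusion$d
    logits <- matrix(p$head$bc, B, length(p$head$bc), byrow = TRUE)
    probs <- softmax_rows(logits)
    ce <- cross_entropy(probs, y)
    l0 <- expected_l0(state, model$gate)
    breakdown <- total_loss(ce, 0, l0, loss_cfg)
    out <- list(breakdown = breakdown, probs = probs, z = z,
                fused = matrix(0, B, D))
    if (!compute_grads) return(out)
    C <- ncol(probs)
    onehot <- matrix(0, B, C)
    onehot[cbind(seq_len(B), y)] <- 1
    dlogits <- (probs - onehot) / B
    out$grads <- list(
      head = list(bc = colSums(dlogits)),
      alpha = loss_cfg$lambda_sparsity *
        expected_l0_grad(state, model$gate))
    return(out)
  }
  ef <- encoder_forward(p$enc, xs)
  ff <- fusion_forward(p$fus, model$fusion, ef$emb, z, active, B)
  fused <- ff$fused
  logits <- sweep(fused %*% p$head$Wc, 2, p$head$bc, `+`)
  probs <- softmax_rows(logits)
  ce <- cross_entropy(probs, y)
  gproj <- fused %*% p$head$Wproj
  if (loss_cfg$lambda_contrast > 0 && B >= 2) {
    sc <- supcon_grad(gproj, y, loss_cfg$tau)
  } else {
    sc <- list(loss = if (B >= 2) supervised_contrastive(gproj, y,
                                                         loss_cfg$tau)
               else 0,
               grad = matrix(0, B, ncol(gproj)))
  }
  l0 <- expected_l0(state, model$gate)
  breakdown <- total_loss(ce, sc$loss, l0, loss_cfg)
  out <- list(breakdown = breakdown, probs = probs, z = z, fused = fused)
  if (!compute_grads) return(out)

  C <- ncol(probs)
  onehot <- matrix(0, B, C)
  onehot[cbind(seq_len(B), y)] <- 1
  dlogits <- (probs - onehot) / B
  g_head <- list(
    Wc = crossprod(fused, dlogits),
    bc = colSums(dlogits),
    Wproj = crossprod(fused, sc$grad) * loss_cfg$lambda_contrast
  )
  dfused <- dlogits %*% t(p$head$Wc) +
    loss_cfg$lambda_contrast * sc$grad %*% t(p$head$Wproj)
  fb <- fusion_backward(p$fus, ff$cache, dfused)
  eg <- encoder_backward(p$enc, ef$cache, fb$demb)
  dalpha <- fb$dz * dz_dalpha +
    loss_cfg$lambda_sparsity * expected_l0_grad(state, model$gate)
  out$grads <- list(enc = eg, fus = fb$grads, head = g_head, alpha = dalpha)
  out
}

# Single-view stage: shared encoder + one linear head per view; loss is the
# mean over views of per-view cross-entropy.
single_view_loss_grad <- function(model, x, y, compute_grads = TRUE) {
  p <- model$params
  V <- length(model$view_names)
  B <- length(y)
  C <- length(model$class_names)
  xs <- as_spatial(x, model)
  ef <- encoder_forward(p$enc, xs)
  demb <- matrix(0, nrow(ef$emb), ncol(ef$emb))
  g_heads <- vector("list", V)
  ce_views <- numeric(V)
  probs_views <- vector("list", V)
  onehot <- matrix(0, B, C)
  onehot[cbind(seq_len(B), y)] <- 1
  for (v in seq_len(V)) {
    rows <- (v - 1) * B + seq_len(B)
    ev <- ef$emb[rows, , drop = FALSE]
    logits <- sweep(ev %*% p$sv_heads[[v]]$W, 2, p$sv_heads[[v]]$b, `+`)
    pr <- softmax_rows(logits)
    probs_views[[v]] <- pr
    ce_views[v] <- cross_entropy(pr, y)
    if (compute_grads) {
      dlog <- (pr - onehot) / (B * V)
      g_heads[[v]] <- list(W = crossprod(ev, dlog), b = colSums(dlog))
      demb[rows, ] <- dlog %*% t(p$sv_heads[[v]]$W)
    }
  }
  out <- list(loss = mean(ce_views), ce_views = ce_views,
              probs_views = probs_views)
  if (compute_grads) {
    out$grads <- list(enc = encoder_backward(p$enc, ef$cache, demb),
                      sv_heads = g_heads)
  }
  out
}

softmax_rows <- function(x) {
  m <- x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  e <- exp(x - m)
  e / rowSums(e)
}

# Convert a batch to the R x P x Fin spatial layout.
as_spatial <- function(x, model) {
  if (model$encoder$input_mode == "feature") {
    stopifnot(is.array(x), length(dim(x)) == 3)
    B <- dim(x)[1]; V <- dim(x)[2]; Fd <- dim(x)[3]
    array(x, c(B * V, 1, Fd))
  } else {
    # list (specimens) of lists (views) of H x W x 3 images
    B <- length(x); V <- length(x[[1]])
    cfg <- model$encoder
    first <- patchify(preprocess(x[[1]][[1]], cfg), cfg)
    P <- nrow(first); Fin <- ncol(first)
    xs <- array(0, c(B * V, P, Fin))
    for (b in seq_len(B)) {
      for (v in seq_len(V)) {
        xs[(v - 1) * B + b, , ] <- patchify(preprocess(x[[b]][[v]], cfg), cfg)
      }
    }
    xs
  }
}

# ---- AdamW ----------------------------------------------------------------

adamw_init <- function(params) {
  zero_like <- function(x) {
    if (is.list(x)) lapply(x, zero_like) else x * 0
  }
  list(m = zero_like(params), v = zero_like(params), t = 0)
}

# Applies decoupled weight decay to weight matrices only (not biases, gate
# logits or positional encodings).
adamw_step <- function(params, grads, opt, lr, weight_decay = 5e-3,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1
  t <- opt$t
  walk <- function(p, g, m, v, path) {
    if (is.list(p)) {
      nms <- names(p)
      for (nm in nms) {
        if (is.null(g[[nm]])) next
        res <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]], c(path, nm))
        p[[nm]] <- res$p; m[[nm]] <- res$m; v[[nm]] <- res$v
      }
      return(list(p = p, m = m, v = v))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    leaf <- path[length(path)]
    decay <- is.matrix(p) && !leaf %in% c("PE", "alpha")
    p <- p - lr * (mhat / (sqrt(vhat) + eps) + if (decay) weight_decay * p
                   else 0)
    list(p = p, m = m, v = v)
  }
  res <- walk(params, grads, opt$m, opt$v, character(0))
  list(params = res$p, opt = list(m = res$m, v = res$v, t = t))
}

# Cosine annealing with warm restarts (epoch-level).
cosine_warm_restart_lr <- function(epoch, lr, restart_period = 10,
                                   mult = 2, lr_min_frac = 0.01) {
  stopifnot(epoch >= 0, restart_period >= 1, mult >= 1)
  t_i <- restart_period
  t_cur <- epoch
  while (t_cur >= t_i) {
    t_cur <- t_cur - t_i
    t_i <- t_i * mult
  }
  lr_min <- lr * lr_min_frac
  lr_min + (lr - lr_min) / 2 * (1 + cos(pi * t_cur / t_i))
}
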