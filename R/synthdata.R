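#' Specification of a synthetic multi-view dataset
#'
#' Emulates the structure of a multi-view specimen collection: `n_classes`
#' species, `n_views` named anatomical views per specimen, with class signal
#' planted only in the views listed in `informative_views`. The generator is
#' built so that the planted views are complementary rather than redundant:
#' all informative views carry a shared coarse signal separating class
#' groups, while the fine within-group contrast (think sibling-species
#' pairs) is carried by exactly one informative view each. Dropping any
#' planted view therefore costs real accuracy, which is what a minimal-view
#' selection method must detect.
#'
#' @param n_classes Number of species C (default 6).
#' @param n_views Number of views V (default 8).
#' @param informative_views Integer indices (1-based) of the planted subset
#'   S (default `c(1, 2, 3)`); must be non-empty.
#' @param mode `"feature"` (each view is a feature vector) or `"image"`
#'   (each view is rendered as a small RGB image).
#' @param feature_dim Feature dimension per view in feature mode
#'   (default 16).
#' @param image_size Side length of rendered square images in image mode
#'   (default 64).
#' @param signal_strength Norm of each planted mean component (coarse group
#'   direction and within-group contrast); default 3.
#' @param noise_sd Standard deviation of additive Gaussian noise
#'   (default 1).
#' @param redundancy_rho In `[0, 1)`: how much of each view's unique
#'   within-group contrast leaks into the other informative views (0 =
#'   fully complementary, default).
#' @param n_train,n_val Training and validation sample counts (defaults
#'   240 / 60).
#' @param seed RNG seed making generation fully deterministic (default 1).
#'
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_classes = 6, n_views = 8,
                           informative_views = c(1, 2, 3),
                           mode = c("feature", "image"),
                           feature_dim = 16, image_size = 64,
                           signal_strength = 3, noise_sd = 1,
                           redundancy_rho = 0,
                           n_train = 240, n_val = 60, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(
    n_classes >= 2, n_views >= 1,
    length(informative_views) >= 1,
    all(informative_views %in% seq_len(n_views)),
    !anyDuplicated(informative_views),
    signal_strength > 0, noise_sd >= 0,
    redundancy_rho >= 0, redundancy_rho < 1,
    n_train >= 1, n_val >= 1, feature_dim >= 2, image_size >= 8
  )
  structure(list(
    n_classes = n_classes, n_views = n_views,
    informative_views = sort(as.integer(informative_views)),
    mode = mode, feature_dim = feature_dim, image_size = image_size,
    signal_strength = signal_strength, noise_sd = noise_sd,
    redundancy_rho = redundancy_rho,
    n_train = n_train, n_val = n_val, seed = as.integer(seed)
  ), class = "synthetic_spec")
}

#' The planted informative-view subset
#'
#' @param spec A [synthetic_spec()].
#' @return Integer vector of 1-based view indices.
#' @export
ground_truth_views <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  spec$informative_views
}

#' Jaccard recovery score between a selected and the planted view set
#'
#' `|selected intersect truth| / |selected union truth|`; 1 iff the sets are
#' equal, 0 iff they are disjoint (two empty sets score 1 by convention).
#'
#' @param selected Integer or character vector of selected views.
#' @param truth The planted subset in the same representation.
#' @return Scalar in `[0, 1]`.
#' @examples
#' recovery_score(c(1, 2), c(1, 3)) # 1/3
#' @export
recovery_score <- function(selected, truth) {
  selected <- unique(selected)
  truth <- unique(truth)
  u <- length(union(selected, truth))
  if (u == 0) return(1)
  length(intersect(selected, truth)) / u
}

# Class mean construction (feature mode).
#
# Classes are partitioned round-robin into |S| groups. Every informative
# view carries the group direction u_g (norm = signal_strength); the k-th
# informative view additionally carries the within-group contrast w_c (norm
# = signal_strength) of the classes in group k. redundancy_rho leaks each
# contrast into the other informative views.
synth_class_means <- function(spec) {
  C <- spec$n_classes
  V <- spec$n_views
  S <- spec$informative_views
  Fd <- spec$feature_dim
  K <- length(S)
  group <- ((seq_len(C) - 1) %% K) + 1
  rand_unit <- function() {
    x <- stats::rnorm(Fd)
    x / sqrt(sum(x^2))
  }
  u_group <- lapply(seq_len(K), function(g) rand_unit())
  w_class <- lapply(seq_len(C), function(c) rand_unit())
  mu <- array(0, dim = c(C, V, Fd))
  rho <- spec$redundancy_rho
  for (c in seq_len(C)) {
    g <- group[c]
    for (k in seq_len(K)) {
      own <- as.numeric(g == k)
      weight <- (1 - rho) * own + rho
      mu[c, S[k], ] <- spec$signal_strength *
        (u_group[[g]] + weight * w_class[[c]])
    }
  }
  list(mu = mu, group = group)
}

# Class templates (image mode): a class-specific bar pattern rendered into
# informative views, one shared class-independent blob elsewhere.
synth_render_view <- function(spec, class_idx, view_idx, informative, rng_noise) {
  n <- spec$image_size
  img <- array(0.5, dim = c(n, n, 3))
  if (informative) {
    # horizontal band whose position and colour channel encode the class
    band <- max(1, round(n * (class_idx / (spec$n_classes + 1))))
    h <- max(2, n %/% 12)
    rows <- pmin(pmax(band:(band + h), 1), n)
    ch <- (class_idx - 1) %% 3 + 1
    img[rows, , ch] <- 1
    # vertical stripe encoding the view so views are not identical
    col <- max(1, round(n * (view_idx / (spec$n_views + 1))))
    img[, pmin(pmax(col:(col + 1), 1), n), ] <- 0.8
  } else {
    # class-independent texture: fixed diagonal
    idx <- cbind(seq_len(n), seq_len(n))
    for (ch in 1:3) img[cbind(idx, ch)] <- 0.9
  }
  img <- img + rng_noise * spec$noise_sd / 10
  array(pmin(pmax(img, 0), 1), dim = dim(img))
}

#' Generate a synthetic multi-view dataset
#'
#' Deterministic in `spec$seed`. In feature mode view `j` of a class-`c`
#' specimen is `mu[c, j, ] + eps` with `eps ~ N(0, noise_sd^2)` and
#' `mu[c, j, ] = 0` outside the planted subset. In image mode informative
#' views render a class-specific geometric template plus pixel noise and
#' uninformative views a shared class-independent template. The split into
#' train and validation is stratified by class.
#'
#' @param spec A [synthetic_spec()].
#' @return A list of class `sv_dataset` with components `train` and `val`
#'   (each a list with `x`, `y`, `specimen_id`), `manifest` (a tibble with
#'   one row per specimen/view), `view_names`, `class_names`, and `spec`.
#'   In feature mode `x` is an `n x V x F` array; in image mode `x` is a
#'   list (specimens) of lists (views) of `H x W x 3` arrays.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  C <- spec$n_classes
  V <- spec$n_views
  n_total <- spec$n_train + spec$n_val
  if (spec$n_train < C) stop("n_train < n_classes: cannot stratify the split")
  set.seed(spec$seed)
  view_names <- sprintf("view%02d", seq_len(V))
  class_names <- sprintf("species%02d", seq_len(C))
  # round-robin class assignment gives every class floor/ceil(n/C) specimens
  y_all <- rep(seq_len(C), length.out = n_total)
  specimen_id <- sprintf("spec%04d", seq_len(n_total))

  if (spec$mode == "feature") {
    means <- synth_class_means(spec)
    x_all <- array(0, dim = c(n_total, V, spec$feature_dim))
    for (i in seq_len(n_total)) {
      eps <- matrix(stats::rnorm(V * spec$feature_dim, sd = spec$noise_sd),
                    V, spec$feature_dim)
      x_all[i, , ] <- means$mu[y_all[i], , ] + eps
    }
  } else {
    x_all <- lapply(seq_len(n_total), function(i) {
      lapply(seq_len(V), function(v) {
        noise <- array(stats::rnorm(spec$image_size^2 * 3),
                       dim = c(spec$image_size, spec$image_size, 3))
        synth_render_view(spec, y_all[i], v,
                          v %in% spec$informative_views, noise)
      })
    })
  }

  # stratified split: within each class, first slots to train by proportion
  idx_train <- integer(0)
  for (c in seq_len(C)) {
    members <- which(y_all == c)
    k <- round(length(members) * spec$n_train / n_total)
    k <- min(max(k, 1), length(members) - 1)
    idx_train <- c(idx_train, members[seq_len(k)])
  }
  idx_train <- sort(idx_train)
  # adjust to the exact requested count, preserving stratification as far
  # as possible
  extra <- setdiff(seq_len(n_total), idx_train)
  if (length(idx_train) > spec$n_train) {
    idx_train <- idx_train[seq_len(spec$n_train)]
  } else if (length(idx_train) < spec$n_train) {
    idx_train <- sort(c(idx_train,
                        extra[seq_len(spec$n_train - length(idx_train))]))
  }
  idx_val <- setdiff(seq_len(n_total), idx_train)

  subset_x <- function(idx) {
    if (spec$mode == "feature") {
      x_all[idx, , , drop = FALSE]
    } else {
      x_all[idx]
    }
  }
  manifest <- tidyr::expand_grid(
    specimen_id = specimen_id,
    view_name = view_names
  )
  manifest$species <- class_names[y_all[match(manifest$specimen_id,
                                              specimen_id)]]
  manifest$split <- ifelse(match(manifest$specimen_id, specimen_id) %in%
                             idx_train, "train", "val")
  manifest$image_path <- NA_character_
  manifest <- manifest[, c("specimen_id", "species", "view_name",
                           "image_path", "split")]

  structure(list(
    train = list(x = subset_x(idx_train), y = y_all[idx_train],
                 specimen_id = specimen_id[idx_train]),
    val = list(x = subset_x(idx_val), y = y_all[idx_val],
               specimen_id = specimen_id[idx_val]),
    manifest = manifest,
    view_names = view_names,
    class_names = class_names,
    spec = spec
  ), class = "sv_dataset")
}

#' @export
print.sv_dataset <- function(x, ...) {
  cat(sprintf(
    "<sv_dataset> %s mode: %d classes x %d views, %d train / %d val, planted S = {%s}\n",
    x$spec$mode, x$spec$n_classes, x$spec$n_views,
    length(x$train$y), length(x$val$y),
    paste(x$spec$informative_views, collapse = ", ")))
  invisible(x)
}

#' Write a synthetic dataset to disk in the manifest + image-folder layout
#'
#' Renders image-mode datasets as PNG files and writes the manifest CSV that
#' [read_manifest()] consumes, so generated data are format-identical to a
#' real photographed collection. Feature-mode datasets are written as a wide
#' per-view feature CSV next to the manifest.
#'
#' @param dataset An `sv_dataset` from [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest file path.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "sv_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spec <- dataset$spec
  manifest <- dataset$manifest
  all_ids <- unique(manifest$specimen_id)
  if (spec$mode == "image") {
    img_dir <- file.path(dir, "images")
    dir.create(img_dir, showWarnings = FALSE)
    xs <- c(dataset$train$x, dataset$val$x)
    ids <- c(dataset$train$specimen_id, dataset$val$specimen_id)
    for (i in seq_along(ids)) {
      for (v in seq_along(dataset$view_names)) {
        path <- file.path(img_dir, sprintf("%s_%s.png", ids[i],
                                           dataset$view_names[v]))
        png::writePNG(aperm(xs[[i]][[v]], c(1, 2, 3)), path)
        sel <- manifest$specimen_id == ids[i] &
          manifest$view_name == dataset$view_names[v]
        manifest$image_path[sel] <- path
      }
    }
  } else {
    feat <- rbind(
      feature_long(dataset$train, dataset$view_names),
      feature_long(dataset$val, dataset$view_names)
    )
    readr::write_csv(feat, file.path(dir, "features.csv"))
    manifest$image_path <- file.path(dir, "features.csv")
  }
  path <- file.path(dir, "manifest.csv")
  readr::write_csv(manifest, path)
  invisible(path)
}

feature_long <- function(split, view_names) {
  n <- length(split$y)
  V <- length(view_names)
  Fd <- dim(split$x)[3]
  rows <- tidyr::expand_grid(specimen_id = split$specimen_id,
                             view_name = view_names)
  mat <- matrix(aperm(split$x, c(2, 1, 3)), nrow = n * V, ncol = Fd)
  colnames(mat) <- sprintf("f%02d", seq_len(Fd))
  dplyr::bind_cols(rows, tibble::as_tibble(mat))
}
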