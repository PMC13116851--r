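#' Read a specimen/view manifest
#'
#' The manifest CSV is the dataset entry point: one row per specimen and
#' view with columns `specimen_id`, `species`, `view_name`, `image_path`
#' (and optionally `split`). Specimens may miss some views (fusion treats
#' them as inactive tokens); duplicate (specimen, view) pairs are an error.
#' Rows whose image path does not exist are collected into a load report
#' attached as the `"load_report"` attribute.
#'
#' @param path Path to the manifest CSV.
#' @return A tibble of class `sv_manifest` with attributes `view_names`,
#'   `species_names` and `load_report`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  if (file.size(path) == 0) stop("empty manifest file")
  m <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("specimen_id", "species", "view_name", "image_path")
  missing_cols <- setdiff(required, names(m))
  if (length(missing_cols) > 0) {
    stop("manifest is missing required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(m) == 0) stop("manifest has no rows")
  dup <- duplicated(m[, c("specimen_id", "view_name")])
  if (any(dup)) {
    stop("duplicate (specimen_id, view_name) pairs in manifest: ",
         paste(utils::head(m$specimen_id[dup], 3), collapse = ", "))
  }
  has_path <- !is.na(m$image_path)
  unreadable <- m[has_path & !file.exists(m$image_path), , drop = FALSE]
  if (nrow(unreadable) > 0) {
    message("manifest load report: ", nrow(unreadable),
            " image paths do not exist")
  }
  structure(tibble::as_tibble(m),
            class = c("sv_manifest", class(tibble::tibble())),
            view_names = sort(unique(m$view_name)),
            species_names = sort(unique(m$species)),
            load_report = tibble::as_tibble(unreadable))
}

#' Load a dataset directory written by [write_dataset()]
#'
#' Reads the manifest plus either the feature CSV (feature mode) or the
#' per-view PNG images (image mode) and reassembles the train/validation
#' structure.
#'
#' @param dir Dataset directory containing `manifest.csv`.
#' @return An `sv_dataset`.
#' @export
load_dataset <- function(dir) {
  manifest <- read_manifest(file.path(dir, "manifest.csv"))
  view_names <- attr(manifest, "view_names")
  class_names <- attr(manifest, "species_names")
  V <- length(view_names)
  ids <- unique(manifest$specimen_id)
  sp <- manifest$species[match(ids, manifest$specimen_id)]
  y <- match(sp, class_names)
  split <- if ("split" %in% names(manifest)) {
    manifest$split[match(ids, manifest$specimen_id)]
  } else rep("train", length(ids))
  feat_path <- file.path(dir, "features.csv")
  if (file.exists(feat_path)) {
    feat <- readr::read_csv(feat_path, show_col_types = FALSE,
                            progress = FALSE)
    fcols <- grep("^f[0-9]+$", names(feat), value = TRUE)
    Fd <- length(fcols)
    x_all <- array(0, c(length(ids), V, Fd))
    row_id <- match(feat$specimen_id, ids)
    row_v <- match(feat$view_name, view_names)
    fm <- as.matrix(feat[, fcols])
    for (r in seq_len(nrow(feat))) x_all[row_id[r], row_v[r], ] <- fm[r, ]
    mode <- "feature"
    subset_x <- function(idx) x_all[idx, , , drop = FALSE]
    spec <- list(mode = "feature", feature_dim = Fd, n_views = V,
                 n_classes = length(class_names))
  } else {
    x_all <- lapply(ids, function(id) {
      lapply(view_names, function(v) {
        p <- manifest$image_path[manifest$specimen_id == id &
                                   manifest$view_name == v]
        if (length(p) == 0 || is.na(p) || !file.exists(p)) return(NULL)
        read_image(p)
      })
    })
    mode <- "image"
    subset_x <- function(idx) x_all[idx]
    dims <- dim(x_all[[1]][[1]])
    spec <- list(mode = "image", image_size = dims[1], n_views = V,
                 n_classes = length(class_names))
  }
  idx_train <- which(split == "train")
  idx_val <- which(split == "val")
  if (length(idx_val) == 0) idx_val <- idx_train
  structure(list(
    train = list(x = subset_x(idx_train), y = y[idx_train],
                 specimen_id = ids[idx_train]),
    val = list(x = subset_x(idx_val), y = y[idx_val],
               specimen_id = ids[idx_val]),
    manifest = manifest, view_names = view_names,
    class_names = class_names, spec = spec
  ), class = "sv_dataset")
}

# PNG (and, when EBImage is present, JPEG/TIFF) reader returning H x W x 3
read_image <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
  } else if (requireNamespace("EBImage", quietly = TRUE)) {
    img <- aperm(EBImage::imageData(EBImage::readImage(path)), c(2, 1, 3))
  } else {
    stop("unsupported image format: ", path)
  }
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] == 4) img <- img[, , 1:3, drop = FALSE]
  img
}

sweep_csv_headers <- c("λ", "Number of Parts", "Accuracy (%)",
                       "Accuracy Drop (%)", "FLOPs (G)", "FLOPs Saved (%)",
                       "Configuration")

#' Write a sweep table in the published seven-column format
#'
#' Columns: lambda, Number of Parts, Accuracy (%), Accuracy Drop (%),
#' FLOPs (G), FLOPs Saved (%), Configuration; numeric cells at two
#' decimals. Labels are computed first if absent.
#'
#' @param table A [sweep_table()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_sweep_csv <- function(table, path) {
  stopifnot(inherits(table, "sweep_table"))
  if (!"configuration" %in% names(table)) {
    table <- label_configurations(table)
  }
  out <- tibble::tibble(
    lambda = format(table$lambda, trim = TRUE),
    parts = table$view_count,
    acc = sprintf("%.2f", table$accuracy),
    drop = sprintf("%.2f", table$accuracy_drop),
    flops = sprintf("%.2f", table$flops),
    saved = sprintf("%.2f", table$flops_saved),
    conf = tools_toTitle(table$configuration)
  )
  names(out) <- sweep_csv_headers
  readr::write_csv(out, path)
  invisible(path)
}

# Table labels are printed capitalized ("All-view"); computation uses
# lower case throughout.
tools_toTitle <- function(x) {
  ifelse(is.na(x) | x == "", x,
         paste0(toupper(substring(x, 1, 1)), substring(x, 2)))
}

#' Read a sweep table from the seven-column CSV format
#'
#' Accepts hand-written tables in the published layout, including merged
#' lambda cells like `"0.1, 0.2"` (split into one record per lambda). The
#' view vocabulary size is taken as the maximum part count and the
#' baseline FLOPs/accuracy from the corresponding all-view row, so the
#' margin rule and labelling can be re-applied to a printed table.
#'
#' @param path CSV path.
#' @param margin_pp Margin stored on the table (default 1.0).
#' @return A [sweep_table()] (the printed Configuration column, if present,
#'   is kept in `configuration`).
#' @export
read_sweep_csv <- function(path, margin_pp = 1.0) {
  m <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(m) < 6) stop("not a sweep table: expected >= 6 columns")
  names(m)[1:6] <- c("lambda", "view_count", "accuracy", "accuracy_drop",
                     "flops", "flops_saved")
  if (ncol(m) >= 7) names(m)[7] <- "configuration"
  # split merged lambda cells
  lam_list <- strsplit(as.character(m$lambda), "[,;] *")
  m <- m[rep(seq_len(nrow(m)), lengths(lam_list)), , drop = FALSE]
  m$lambda <- as.numeric(unlist(lam_list))
  n_views <- max(m$view_count)
  base <- m[m$view_count == n_views, , drop = FALSE]
  if (nrow(base) == 0) stop("no all-view row in sweep CSV")
  base <- base[which.min(base$lambda), ]
  recs <- tibble::tibble(lambda = m$lambda, view_count = m$view_count,
                         accuracy = m$accuracy, flops = m$flops)
  tab <- sweep_table(recs, n_views = n_views, baseline_flops = base$flops,
                     baseline_accuracy = base$accuracy,
                     margin_pp = margin_pp)
  if ("configuration" %in% names(m)) {
    tab$configuration <- tolower(m$configuration[order(m$lambda)])
  }
  tab
}

#' Per-epoch gate trajectories in long format
#'
#' The data behind retention-probability-vs-epoch plots: one row per epoch
#' and view with the closed-form retention probability at that epoch's
#' temperature.
#'
#' @param history An `sv_history` (from [train_fusion()]) or an
#'   `sv_fusion_fit`.
#' @return A tibble with `epoch`, `view_name`, `retention_probability`.
#' @export
gate_trajectories <- function(history) {
  if (inherits(history, "sv_fusion_fit")) history <- history$history
  stopifnot("retention" %in% names(history))
  purrr::map_dfr(seq_len(nrow(history)), function(i) {
    r <- history$retention[[i]]
    tibble::tibble(epoch = history$epoch[i], view_name = names(r),
                   retention_probability = as.numeric(r))
  })
}

#' Write gate trajectories to CSV
#'
#' @inheritParams gate_trajectories
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_gate_trajectories <- function(history, path) {
  readr::write_csv(gate_trajectories(history), path)
  invisible(path)
}

#' Write the per-epoch training log to CSV
#'
#' Columns: epoch, ce, contrast, l0, total, beta, lambda_sparsity (and
#' validation accuracy when recorded).
#'
#' @inheritParams gate_trajectories
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_history_csv <- function(history, path) {
  if (inherits(history, "sv_fusion_fit")) history <- history$history
  cols <- intersect(c("epoch", "ce", "contrast", "l0", "total", "beta",
                      "lambda_sparsity", "val_accuracy"), names(history))
  readr::write_csv(tibble::as_tibble(history)[, cols], path)
  invisible(path)
}

#' Write top-k predictions to CSV
#'
#' One row per specimen and rank with species and confidence; when a
#' manifest is supplied the per-view image paths of each specimen are
#' appended as one column per view.
#'
#' @param predictions Tibble from [predict_topk_specimens()].
#' @param path Output CSV path.
#' @param manifest Optional `sv_manifest` supplying image paths.
#' @return Invisibly, `path`.
#' @export
write_predictions <- function(predictions, path, manifest = NULL) {
  out <- predictions
  if (!is.null(manifest)) {
    paths <- tidyr::pivot_wider(
      manifest[, c("specimen_id", "view_name", "image_path")],
      names_from = "view_name", values_from = "image_path",
      names_prefix = "path_")
    out <- dplyr::left_join(out, paths, by = "specimen_id")
  }
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a structured run configuration
#'
#' YAML with sections mirroring the package's config constructors:
#' `encoder`, `fusion`, `gate`, `loss`, `train`, `sweep`, `data`, plus
#' scalar `seed` and `output_dir`. Unknown sections or unknown keys within
#' a section are rejected.
#'
#' @param path YAML file path.
#' @return A list with config objects for each present section.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- c("encoder", "fusion", "gate", "loss", "train", "sweep",
               "data", "seed", "output_dir")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown) > 0) {
    stop("unknown config sections: ", paste(unknown, collapse = ", "))
  }
  build <- function(section, ctor) {
    if (is.null(raw[[section]])) return(NULL)
    do.call(ctor, raw[[section]])
  }
  list(
    encoder = build("encoder", encoder_config),
    fusion = build("fusion", fusion_config),
    gate = build("gate", gate_config),
    loss = build("loss", loss_config),
    train = build("train", train_config),
    data = build("data", synthetic_spec),
    sweep = raw$sweep,
    seed = raw$seed,
    output_dir = raw$output_dir
  )
}
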