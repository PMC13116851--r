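#' Round half-up to a fixed number of decimals
#'
#' Published accuracy and FLOPs tables round halves away from zero, whereas
#' base R's `round()` rounds half to even; all table cells in this package go
#' through this helper.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 2).
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

#' Total FLOPs of a view configuration
#'
#' The shared-weight design makes theoretical cost linear in the number of
#' encoded views: `view_count * per_view_flops`, in GFLOPs, rounded to two
#' decimals. The per-view cost is typically derived from a measured all-view
#' baseline as `baseline_flops / n_views` at full precision (e.g. 11.31 G
#' over 8 views gives 1.41375 G per view, so 5 views cost 7.07 G).
#'
#' @param view_count Number of retained views (>= 0); vectorized.
#' @param per_view_flops GFLOPs per encoded view.
#' @param digits Decimals to round to; the default 2 is the precision of
#'   published tables. Desk-scale encoders cost micro-GFLOPs, so sweep
#'   tables built from them carry more digits automatically.
#' @return GFLOPs, rounded.
#' @examples
#' flops_total(5, 11.31 / 8) # 7.07
#' @export
flops_total <- function(view_count, per_view_flops, digits = 2) {
  stopifnot(all(view_count >= 0, na.rm = TRUE), per_view_flops >= 0)
  round_half_up(view_count * per_view_flops, digits)
}

#' Percentage of FLOPs saved relative to a baseline
#'
#' `(baseline - config) / baseline * 100`, rounded to two decimals. The
#' configuration cost is taken as supplied (i.e. already rounded to the
#' 2-decimal table precision), which is what reproduces the published
#' savings column from its FLOPs column.
#'
#' @param baseline_flops All-view baseline cost (G), > 0.
#' @param config_flops Cost of the configuration (G); vectorized.
#' @return Percent saved, 2 decimals.
#' @examples
#' flops_saved_pct(11.31, 7.07) # 37.49
#' @export
flops_saved_pct <- function(baseline_flops, config_flops) {
  stopifnot(baseline_flops > 0, all(config_flops >= 0, na.rm = TRUE))
  round_half_up((baseline_flops - config_flops) / baseline_flops * 100, 2)
}

#' Accuracy drop relative to the all-view baseline
#'
#' `baseline - config` in percentage points, two decimals; negative when a
#' reduced configuration beats the baseline.
#'
#' @param baseline_acc Baseline Top-1 accuracy in percent.
#' @param config_acc Configuration accuracy in percent; vectorized.
#' @return Drop in percentage points, 2 decimals.
#' @export
accuracy_drop <- function(baseline_acc, config_acc) {
  stopifnot(baseline_acc >= 0, baseline_acc <= 100,
            all(config_acc >= 0, na.rm = TRUE),
            all(config_acc <= 100, na.rm = TRUE))
  round_half_up(baseline_acc - config_acc, 2)
}

#' Pareto frontier of accuracy/FLOPs records
#'
#' Returns the non-dominated subset: a record is dominated when some other
#' record has accuracy at least as high and FLOPs at most as high, with at
#' least one strict inequality. Output rows are ordered by FLOPs ascending
#' (stable within ties).
#'
#' @param records A data frame with numeric columns `accuracy` and `flops`.
#' @return The non-dominated rows, as a tibble ordered by `flops`.
#' @examples
#' pareto_frontier(tibble::tibble(accuracy = c(90, 80), flops = c(10, 12)))
#' @export
pareto_frontier <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 1,
            all(c("accuracy", "flops") %in% names(records)))
  acc <- records$accuracy
  fl <- records$flops
  keep <- vapply(seq_len(nrow(records)), function(i) {
    !any(acc >= acc[i] & fl <= fl[i] & (acc > acc[i] | fl < fl[i]))
  }, logical(1))
  out <- tibble::as_tibble(records[keep, , drop = FALSE])
  out[order(out$flops), , drop = FALSE]
}

#' Build a sweep table from per-lambda records
#'
#' Collects the all-view baseline and the per-lambda sweep outcomes into a
#' `sweep_table`: a tibble with the drop and saved columns computed from the
#' baseline, sorted by lambda, plus table-level metadata (total view count
#' and per-view cost).
#'
#' @param records Data frame with columns `lambda`, `view_count`, `accuracy`
#'   and optionally `flops` and `retained_views` (list column of character
#'   vectors). The baseline may be included as the `lambda = 0` /
#'   all-view row or supplied via `baseline_accuracy`.
#' @param n_views Total number of views N in the vocabulary.
#' @param baseline_flops Measured (or theoretical) all-view cost in G; the
#'   per-view cost is `baseline_flops / n_views` at full precision.
#' @param baseline_accuracy Baseline accuracy in percent. Defaults to the
#'   accuracy of the row with `view_count == n_views` and smallest lambda.
#' @param margin_pp Accuracy-drop margin (percentage points) used later by
#'   [select_recommended()]; stored on the table (default 1.0).
#'
#' @return A tibble of class `sweep_table` with columns `lambda`,
#'   `retained_views`, `view_count`, `accuracy`, `accuracy_drop`, `flops`,
#'   `flops_saved`.
#' @export
sweep_table <- function(records, n_views, baseline_flops,
                        baseline_accuracy = NULL, margin_pp = 1.0) {
  stopifnot(is.data.frame(records), nrow(records) >= 1,
            all(c("lambda", "view_count", "accuracy") %in% names(records)),
            n_views >= 1, baseline_flops > 0)
  per_view <- baseline_flops / n_views
  # keep at least two significant digits of the per-view cost visible
  fl_digits <- max(2, ceiling(-log10(per_view)) + 2)
  tab <- tibble::as_tibble(records)
  if (!"retained_views" %in% names(tab)) {
    tab$retained_views <- vector("list", nrow(tab))
  }
  if (!"flops" %in% names(tab)) {
    tab$flops <- flops_total(tab$view_count, per_view, fl_digits)
  }
  tab <- tab[order(tab$lambda), , drop = FALSE]
  if (is.null(baseline_accuracy)) {
    full <- tab[tab$view_count == n_views, , drop = FALSE]
    if (nrow(full) == 0) {
      stop("no all-view row found; supply baseline_accuracy explicitly")
    }
    baseline_accuracy <- full$accuracy[which.min(full$lambda)]
  }
  tab$accuracy_drop <- accuracy_drop(baseline_accuracy, tab$accuracy)
  tab$flops_saved <- flops_saved_pct(flops_total(n_views, per_view,
                                                 fl_digits),
                                     tab$flops)
  tab <- tab[, c("lambda", "retained_views", "view_count", "accuracy",
                 "accuracy_drop", "flops", "flops_saved",
                 setdiff(names(tab), c("lambda", "retained_views",
                                       "view_count", "accuracy",
                                       "accuracy_drop", "flops",
                                       "flops_saved")))]
  structure(tab,
            class = c("sweep_table", class(tibble::tibble())),
            n_views = n_views,
            per_view_flops = per_view,
            baseline_flops = baseline_flops,
            baseline_accuracy = baseline_accuracy,
            margin_pp = margin_pp)
}

sweep_meta <- function(table) {
  list(n_views = attr(table, "n_views"),
       per_view_flops = attr(table, "per_view_flops"),
       baseline_flops = attr(table, "baseline_flops"),
       baseline_accuracy = attr(table, "baseline_accuracy"),
       margin_pp = attr(table, "margin_pp"))
}

#' Select the recommended minimal-view configuration
#'
#' Applies the margin rule: among sweep records whose accuracy drop from the
#' all-view baseline is at most `margin_pp` percentage points, pick the one
#' with the fewest retained views; ties are broken by lower FLOPs, then
#' higher accuracy, then lower lambda (so the selection always lies on the
#' Pareto frontier of the qualifying records). If no record qualifies the
#' all-view baseline row is returned.
#'
#' @param table A [sweep_table()].
#' @param margin_pp Margin in percentage points (default: the table's stored
#'   margin, 1.0 unless overridden).
#' @return The selected record as a one-row tibble.
#' @export
select_recommended <- function(table, margin_pp = NULL) {
  stopifnot(inherits(table, "sweep_table"), nrow(table) >= 1)
  meta <- sweep_meta(table)
  margin_pp <- margin_pp %||% meta$margin_pp
  qual <- table[!is.na(table$accuracy_drop) &
                  table$accuracy_drop <= margin_pp, , drop = FALSE]
  if (nrow(qual) == 0) {
    base <- table[table$view_count == meta$n_views, , drop = FALSE]
    if (nrow(base) == 0) stop("no qualifying record and no baseline row")
    return(tibble::as_tibble(base[which.min(base$lambda), , drop = FALSE]))
  }
  ord <- order(qual$view_count, qual$flops, -qual$accuracy, qual$lambda)
  tibble::as_tibble(qual[ord[1], , drop = FALSE])
}

#' Label sweep configurations
#'
#' Adds the `configuration` column: the all-view baseline rows are labelled
#' `all-view`; the record chosen by the margin rule, `recommended`; remaining
#' single-view rows, `single-view`; remaining rows within the margin,
#' `reduced`; rows beyond the margin, `aggressive`. Idempotent.
#'
#' @param table A [sweep_table()].
#' @param margin_pp Margin override in percentage points.
#' @return The table with a `configuration` character column.
#' @export
label_configurations <- function(table, margin_pp = NULL) {
  stopifnot(inherits(table, "sweep_table"))
  meta <- sweep_meta(table)
  margin_pp <- margin_pp %||% meta$margin_pp
  rec <- select_recommended(table, margin_pp)
  labels <- character(nrow(table))
  failed <- is.na(table$view_count) | is.na(table$accuracy)
  vc <- table$view_count
  is_all <- !failed & vc == meta$n_views
  is_rec <- !failed & !is_all & table$lambda == rec$lambda &
    vc == rec$view_count
  qualifies <- !failed & table$accuracy_drop <= margin_pp
  labels[failed] <- "failed"
  labels[is_all] <- "all-view"
  labels[is_rec] <- "recommended"
  rest <- !failed & !is_all & !is_rec
  labels[rest & vc == 1] <- "single-view"
  labels[rest & vc != 1 & qualifies] <- "reduced"
  labels[rest & vc != 1 & !qualifies] <- "aggressive"
  table$configuration <- labels
  table
}

#' @export
print.sweep_table <- function(x, ...) {
  meta <- sweep_meta(x)
  cat(sprintf(
    "<sweep_table> N = %d views, baseline %.2f G (%.4f G/view), baseline accuracy %.2f%%\n",
    meta$n_views, meta$baseline_flops, meta$per_view_flops,
    meta$baseline_accuracy))
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
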