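METRIC_NAMES <- c("iou", "dice", "accuracy", "precision", "recall",
                  "sensitivity", "f1", "specificity")

#' Pixel-wise confusion counts for a binary mask pair
#'
#' Tallies true/false positives/negatives with 1 = foreground.
#'
#' @param pred,truth binary {0, 1} matrices of equal shape.
#' @return one-row tibble with `tp`, `fp`, `fn`, `tn`; the four always sum
#'   to the pixel count.
#' @export
confusion_counts <- function(pred, truth) {
  assert_binary_mask(pred, "pred")
  assert_binary_mask(truth, "truth")
  assert_same_shape(pred, truth, "mask pair")
  tp <- sum(pred == 1L & truth == 1L)
  fp <- sum(pred == 1L & truth == 0L)
  fn <- sum(pred == 0L & truth == 1L)
  tn <- sum(pred == 0L & truth == 0L)
  tibble::tibble(tp = tp, fp = fp, fn = fn, tn = tn)
}

ratio_or <- function(num, den, if_empty) if (den > 0) num / den else if_empty

#' The eight segmentation metrics from confusion counts
#'
#' Computes IoU (Jaccard), Dice, accuracy, precision, recall, sensitivity,
#' F1 and specificity. Recall and sensitivity are the same quantity and are
#' reported twice to keep the conventional eight-column layout; F1 equals
#' Dice on binary masks. Degenerate 0/0 denominators are defined as 1 when
#' both masks are empty on the relevant side (perfect agreement on nothing)
#' and 0 when only one side is empty, so every metric is total.
#'
#' @param counts a one-row tibble from [confusion_counts()] (or any list
#'   with `tp`, `fp`, `fn`, `tn`).
#' @param case_id label for the case; default `NA`.
#' @return one-row tibble: `case_id` plus the eight metrics, each in
#'   \[0, 1\].
#' @export
metrics_row <- function(counts, case_id = NA_character_) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  stopifnot(length(tp) == 1L, all(c(tp, fp, fn, tn) >= 0))
  total <- tp + fp + fn + tn
  if (total == 0) stop("empty masks (zero pixels)", call. = FALSE)
  iou  <- ratio_or(tp, tp + fp + fn, 1)
  dice <- ratio_or(2 * tp, 2 * tp + fp + fn, 1)
  precision <- ratio_or(tp, tp + fp, if (fn == 0) 1 else 0)
  recall    <- ratio_or(tp, tp + fn, if (fp == 0) 1 else 0)
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall)
  else if (tp + fp + fn == 0) 1 else 0
  specificity <- ratio_or(tn, tn + fp, if (fn == 0) 1 else 0)
  tibble::tibble(case_id = as.character(case_id),
                 iou = iou, dice = dice,
                 accuracy = (tp + tn) / total,
                 precision = precision, recall = recall,
                 sensitivity = recall, f1 = f1,
                 specificity = specificity)
}

#' Evaluate one predicted mask against ground truth
#'
#' Convenience composition of [confusion_counts()] and [metrics_row()].
#'
#' @inheritParams confusion_counts
#' @param case_id label for the case.
#' @return one-row metrics tibble.
#' @export
mask_metrics <- function(pred, truth, case_id = NA_character_) {
  metrics_row(confusion_counts(pred, truth), case_id)
}

#' Dice coefficient implied by an IoU value
#'
#' The Dice-Jaccard identity `D = 2J / (1 + J)`; useful for consistency
#' checks of reported score tables.
#'
#' @param j IoU (Jaccard) values in \[0, 1\]; vectorized.
#' @return Dice values in \[0, 1\].
#' @examples
#' dice_from_iou(c(0, 0.5, 1))
#' @export
dice_from_iou <- function(j) {
  if (!is.numeric(j) || any(j < 0) || any(j > 1))
    stop("`j` must lie in [0, 1]", call. = FALSE)
  2 * j / (1 + j)
}

#' Aggregate per-case metric rows into a report
#'
#' Bundles the rows with their per-metric arithmetic mean. Means are taken
#' over the full-precision values; rendering rounds last (4 decimals).
#'
#' @param rows tibble/data frame of per-case rows as from [metrics_row()]
#'   (one or more rows; must contain the eight metric columns).
#' @return a `metrics_report` with `$rows` and `$mean_row`.
#' @export
metrics_report <- function(rows) {
  rows <- tibble::as_tibble(rows)
  if (nrow(rows) == 0L) stop("cannot aggregate an empty set of rows", call. = FALSE)
  missing <- setdiff(METRIC_NAMES, names(rows))
  if (length(missing))
    stop(sprintf("rows are missing metric columns: %s", toString(missing)),
         call. = FALSE)
  mean_row <- dplyr::summarise(rows, dplyr::across(dplyr::all_of(METRIC_NAMES), mean))
  mean_row <- tibble::add_column(mean_row, case_id = "mean", .before = 1L)
  structure(list(rows = rows, mean_row = mean_row), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  fmt <- function(df) {
    out <- df
    out[METRIC_NAMES] <- lapply(out[METRIC_NAMES],
                                function(v) formatC(v, digits = digits, format = "f"))
    out
  }
  cat(sprintf("<metrics_report> %d case(s)\n", nrow(x$rows)))
  print(as.data.frame(fmt(x$rows[c("case_id", METRIC_NAMES)])), row.names = FALSE)
  cat("mean:\n")
  print(as.data.frame(fmt(x$mean_row[c("case_id", METRIC_NAMES)])), row.names = FALSE)
  invisible(x)
}

#' Tidy per-case rows of a metrics report
#' @param x a `metrics_report`.
#' @param ... unused.
#' @return the per-case tibble.
#' @importFrom generics tidy
#' @export
tidy.metrics_report <- function(x, ...) x$rows

#' One-row summary (the mean row) of a metrics report
#' @param x a `metrics_report`.
#' @param ... unused.
#' @return one-row tibble of per-metric means.
#' @importFrom generics glance
#' @export
glance.metrics_report <- function(x, ...) x$mean_row

#' Plot a metrics report
#'
#' Dot plot of every metric per case with the mean as a horizontal line per
#' facet.
#'
#' @param object a `metrics_report`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.metrics_report <- function(object, ...) {
  long <- tidyr::pivot_longer(object$rows, dplyr::all_of(METRIC_NAMES),
                              names_to = "metric", values_to = "value")
  mlong <- tidyr::pivot_longer(object$mean_row, dplyr::all_of(METRIC_NAMES),
                               names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$case_id, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(data = mlong,
                        ggplot2::aes(yintercept = .data$value),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::facet_wrap(~metric, nrow = 2) +
    ggplot2::labs(x = "case", y = "score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Per-metric difference between two reports (rounded-mean convention)
#'
#' Computes `delta = mean_a - mean_b` for each metric with both means first
#' rounded (half-up) to the 4 rendered decimals, mirroring how deltas are
#' usually quoted from published 4-decimal tables.
#'
#' @param a,b `metrics_report` objects.
#' @return tibble with `metric`, `mean_a`, `mean_b`, `delta`.
#' @export
compare_reports <- function(a, b) {
  stopifnot(inherits(a, "metrics_report"), inherits(b, "metrics_report"))
  r4 <- function(x) round_half_up(x * 1e4) / 1e4
  ma <- r4(unlist(a$mean_row[METRIC_NAMES]))
  mb <- r4(unlist(b$mean_row[METRIC_NAMES]))
  tibble::tibble(metric = METRIC_NAMES,
                 mean_a = unname(ma), mean_b = unname(mb),
                 delta = unname(ma - mb))
}

#' Evaluate directories (or single files) of predicted vs truth masks
#'
#' Pairs files by sorted name when given directories, reads each pair with
#' [read_mask()], and aggregates into a [metrics_report()].
#'
#' @param pred,truth mask files or directories of mask files (PNG or NIfTI).
#' @return a `metrics_report`.
#' @export
evaluate_masks <- function(pred, truth) {
  expand <- function(p) if (dir.exists(p)) sort(list.files(p, full.names = TRUE)) else p
  pf <- expand(pred); tf <- expand(truth)
  if (length(pf) == 0L || length(pf) != length(tf))
    stop(sprintf("prediction and truth sets differ in size (%d vs %d)",
                 length(pf), length(tf)), call. = FALSE)
  rows <- dplyr::bind_rows(lapply(seq_along(pf), function(i) {
    mask_metrics(read_mask(pf[i]), read_mask(tf[i]),
                 case_id = sub("\\.[^.]+$", "", basename(pf[i])))
  }))
  metrics_report(rows)
}

#' Write a metrics report to CSV or JSON
#'
#' @param report a `metrics_report`.
#' @param path output `.csv` or `.json` path; CSV appends the mean row with
#'   `case_id = "mean"`, JSON stores `rows` and `mean_row` separately.
#' @return invisibly, `path`.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "metrics_report"))
  if (grepl("\\.csv$", path)) {
    utils::write.csv(rbind(report$rows[c("case_id", METRIC_NAMES)],
                           report$mean_row[c("case_id", METRIC_NAMES)]),
                     path, row.names = FALSE)
  } else if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(rows = report$rows, mean_row = report$mean_row),
                         path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  } else {
    stop(sprintf("unsupported report format (use .csv or .json): %s", path),
         call. = FALSE)
  }
  invisible(path)
}

#' Read a metrics report written by [write_report()]
#' @param path `.csv` or `.json` report path.
#' @return a `metrics_report`.
#' @export
read_report <- function(path) {
  if (grepl("\\.csv$", path)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    metrics_report(df[df$case_id != "mean", , drop = FALSE])
  } else if (grepl("\\.json$", path)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    metrics_report(obj$rows)
  } else {
    stop(sprintf("unsupported report format: %s", path), call. = FALSE)
  }
}

#' Bundled example scores: MedSAM liver segmentation under three
#' preprocessing variants
#'
#' Per-case liver-segmentation scores of a MedSAM evaluation over ten
#' abdominal CT cases, under three preprocessing variants: plain min-max
#' `normalization`, `window` adjustment, and the `proposed` dual-path
#' fusion. Bundled as plain CSV to demonstrate report aggregation and the
#' rounded-mean delta arithmetic on published-style 4-decimal tables.
#'
#' @return tibble with `variant`, `case_id` and the eight metric columns.
#' @examples
#' scores <- example_scores()
#' rep <- metrics_report(scores[scores$variant == "proposed", ])
#' glance(rep)
#' @export
example_scores <- function() {
  path <- system.file("extdata", "medsam_liver_scores.csv",
                      package = "ctenhance", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                                    colClasses = c(case_id = "character")))
}
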