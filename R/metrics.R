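#' Pixel-level confusion counts between a prediction and the ground truth
#'
#' True positives are liver pixels predicted liver; true negatives are
#' background pixels predicted background; false positives are background
#' pixels predicted liver; false negatives are liver pixels predicted
#' background.
#'
#' @param pred,truth Binary grids of identical shape (or
#'   `segmentation_mask` / `image_volume` objects, whose `$values` /
#'   `$mask` are used).
#' @return A `confusion_counts` list (tp, tn, fp, fn).
#' @export
confusion <- function(pred, truth) {
  p <- if (inherits(pred, "segmentation_mask")) pred$values
       else if (inherits(pred, "image_volume")) pred$mask else pred
  t <- if (inherits(truth, "image_volume")) truth$mask else truth
  if (!identical(dim(p), dim(t))) stop("prediction and truth shapes differ")
  if (!is_binary(p) || !is_binary(t)) stop("inputs must be binary")
  structure(list(tp = sum(p == 1 & t == 1), tn = sum(p == 0 & t == 0),
                 fp = sum(p == 1 & t == 0), fn = sum(p == 0 & t == 1)),
            class = "confusion_counts")
}

safe_ratio <- function(num, den) if (den == 0) NaN else num / den

#' The eight evaluation metrics from confusion counts
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy
#' `(TP+TN)/total`, precision `TP/(TP+FP)`, `FPR = 1 - SP`,
#' `FNR = 1 - SE`, Dice `2TP/(FP+2TP+FN)` and Jaccard `DSC/(2-DSC)`.
#' Ratios with a zero denominator are reported as `NaN` and flagged in
#' `$undefined`, never silently zero (empty-liver slices are common and
#' silent zeros would bias aggregates).
#'
#' @param counts A [confusion()] result, or anything coercible via
#'   `confusion()` when `truth` is supplied.
#' @param id Label for the evaluation unit.
#' @return A `metrics_report` with fields se, sp, acc, precision, fpr, fnr,
#'   jsi, dsc (fractions), the counts and an `undefined` character vector.
#' @export
report <- function(counts, id = "unit") {
  stopifnot(inherits(counts, "confusion_counts"))
  tot <- counts$tp + counts$tn + counts$fp + counts$fn
  if (tot == 0) stop("all-zero confusion counts")
  se <- safe_ratio(counts$tp, counts$tp + counts$fn)
  sp <- safe_ratio(counts$tn, counts$tn + counts$fp)
  prec <- safe_ratio(counts$tp, counts$tp + counts$fp)
  dsc <- safe_ratio(2 * counts$tp, counts$fp + 2 * counts$tp + counts$fn)
  r <- list(se = se, sp = sp, acc = (counts$tp + counts$tn) / tot,
            precision = prec, fpr = 1 - sp, fnr = 1 - se,
            jsi = if (is.nan(dsc)) NaN else jsi_from_dsc(dsc), dsc = dsc,
            counts = counts, id = id)
  r$undefined <- names(which(vapply(r[c("se", "sp", "acc", "precision",
                                        "fpr", "fnr", "jsi", "dsc")], is.nan, TRUE)))
  structure(r, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %s\n", x$id))
  cat(sprintf("  DSC %.4f  JSI %.4f  ACC %.4f  Precision %.4f\n",
              x$dsc, x$jsi, x$acc, x$precision))
  cat(sprintf("  SE %.4f  SP %.4f  FNR %.4f  FPR %.4f\n",
              x$se, x$sp, x$fnr, x$fpr))
  invisible(x)
}

#' Jaccard index from the Dice coefficient
#'
#' `JSI = DSC / (2 - DSC)`; the inverse is `DSC = 2 * JSI / (1 + JSI)`.
#'
#' @param dsc Dice coefficient(s) in [0, 1].
#' @return Jaccard index, same length.
#' @export
jsi_from_dsc <- function(dsc) {
  if (any(dsc < 0 | dsc > 1)) stop("dsc must lie in [0, 1]")
  dsc / (2 - dsc)
}

#' Aggregate metric reports across units
#'
#' `mean_of_metrics` averages each metric across units (the convention of
#' per-dataset summary rows), excluding flagged undefined values with a
#' warning; `pooled_counts` sums the confusion counts and recomputes the
#' metrics. The two differ whenever unit sizes differ.
#'
#' @param reports List of `metrics_report` objects.
#' @param mode `"mean_of_metrics"` or `"pooled_counts"`.
#' @param id Label for the aggregate.
#' @return A `metrics_report` (for `mean_of_metrics` the counts are the
#'   pooled counts but the metrics are the means).
#' @export
aggregate_reports <- function(reports, mode = c("mean_of_metrics", "pooled_counts"),
                              id = "aggregate") {
  mode <- match.arg(mode)
  if (length(reports) == 0) stop("no reports to aggregate")
  stopifnot(all(vapply(reports, inherits, TRUE, "metrics_report")))
  pooled <- structure(list(
    tp = sum(vapply(reports, function(r) r$counts$tp, 0)),
    tn = sum(vapply(reports, function(r) r$counts$tn, 0)),
    fp = sum(vapply(reports, function(r) r$counts$fp, 0)),
    fn = sum(vapply(reports, function(r) r$counts$fn, 0))), class = "confusion_counts")
  if (mode == "pooled_counts") return(report(pooled, id = id))
  out <- report(pooled, id = id)
  for (m in c("se", "sp", "acc", "precision", "fpr", "fnr", "jsi", "dsc")) {
    vals <- vapply(reports, `[[`, 0, m)
    if (any(is.nan(vals))) {
      warning(sprintf("excluding %d undefined value(s) of %s from the mean",
                      sum(is.nan(vals)), m))
      vals <- vals[!is.nan(vals)]
    }
    out[[m]] <- if (length(vals)) mean(vals) else NaN
  }
  out$undefined <- names(which(vapply(out[c("se", "sp", "acc", "precision",
                                            "fpr", "fnr", "jsi", "dsc")], is.nan, TRUE)))
  out
}

#' Write metric reports as a CSV table
#'
#' Columns follow the conventional results-table layout: `DSC%`, `JSI%`,
#' `ACC%`, `Precision%`, `SE%`, `SP%` as percentages and `FNR`, `FPR` as
#' fractions.
#'
#' @param reports A `metrics_report` or list of them.
#' @param path Output CSV path.
#' @return The data frame written, invisibly.
#' @export
write_metrics_csv <- function(reports, path) {
  if (inherits(reports, "metrics_report")) reports <- list(reports)
  df <- do.call(rbind, lapply(reports, function(r) {
    data.frame(id = r$id, `DSC%` = 100 * r$dsc, `JSI%` = 100 * r$jsi,
               `ACC%` = 100 * r$acc, `Precision%` = 100 * r$precision,
               `SE%` = 100 * r$se, `SP%` = 100 * r$sp,
               FNR = r$fnr, FPR = r$fpr, check.names = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
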