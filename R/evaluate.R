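#' Pixelwise confusion counts for binary segmentation
#'
#' Exact pixel matching between a predicted and a ground-truth mask, with the
#' positive class assigned to border pixels.
#'
#' @param pred,gt Binary 0/1 matrices of identical dimensions.
#' @return An object of class `confusion_counts`: list with `TP`, `FP`, `FN`,
#'   `TN`.
#' @export
confusion_counts <- function(pred, gt) {
  if (!all(dim(pred) == dim(gt))) stop("`pred` and `gt` dimensions differ")
  p <- .as_binary(pred)
  g <- .as_binary(gt)
  structure(list(TP = sum(p == 1L & g == 1L),
                 FP = sum(p == 1L & g == 0L),
                 FN = sum(p == 0L & g == 1L),
                 TN = sum(p == 0L & g == 0L)),
            class = "confusion_counts")
}

#' Segmentation metrics from confusion counts
#'
#' Precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, intersection-over-union
#' `TP/(TP+FP+FN)` and Dice coefficient `2TP/(2TP+FP+FN)`. A metric whose
#' denominator is zero is reported as `NA` (undefined) rather than 0, so
#' degenerate images do not silently bias aggregates.
#'
#' @param counts A [confusion_counts()] object.
#' @return An object of class `metrics_report`: list with `precision`,
#'   `recall`, `iou`, `dsc` and the `counts`.
#' @export
seg_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  sdiv <- function(num, den) if (den == 0) NA_real_ else num / den
  with(counts, structure(
    list(precision = sdiv(TP, TP + FP),
         recall = sdiv(TP, TP + FN),
         iou = sdiv(TP, TP + FP + FN),
         dsc = sdiv(2 * TP, 2 * TP + FP + FN),
         counts = counts),
    class = "metrics_report"
  ))
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("precision %.4f | recall %.4f | IOU %.4f | DSC %.4f\n",
              x$precision, x$recall, x$iou, x$dsc))
  invisible(x)
}

.read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  .as_binary(m)
}

#' Evaluate a directory of predicted masks against ground truth
#'
#' Pairs files by name between the two directories, computes per-image
#' metrics, and reports both the micro average (metrics of the pooled pixel
#' counts) and the macro average (mean of per-image metrics, undefined values
#' excluded). Files present in only one directory are skipped with a warning.
#'
#' @param pred_dir,gt_dir Directories of binary PNG masks with matching file
#'   names.
#' @param pattern File pattern (default `"\\.png$"`).
#' @return List with `per_image` (data.frame), `micro` and `macro`
#'   (`metrics_report`-like lists), and `n_images`.
#' @export
evaluate_dir <- function(pred_dir, gt_dir, pattern = "\\.png$") {
  pf <- sort(list.files(pred_dir, pattern = pattern))
  gf <- sort(list.files(gt_dir, pattern = pattern))
  common <- intersect(pf, gf)
  extra <- setdiff(union(pf, gf), common)
  if (length(extra)) {
    warning("skipping unmatched files: ", paste(extra, collapse = ", "))
  }
  if (!length(common)) stop("no matching mask pairs found")
  rows <- lapply(common, function(f) {
    cc <- confusion_counts(.read_mask_png(file.path(pred_dir, f)),
                           .read_mask_png(file.path(gt_dir, f)))
    m <- seg_metrics(cc)
    data.frame(file = f, TP = cc$TP, FP = cc$FP, FN = cc$FN, TN = cc$TN,
               precision = m$precision, recall = m$recall,
               iou = m$iou, dsc = m$dsc)
  })
  per_image <- do.call(rbind, rows)
  pooled <- structure(list(TP = sum(per_image$TP), FP = sum(per_image$FP),
                           FN = sum(per_image$FN), TN = sum(per_image$TN)),
                      class = "confusion_counts")
  micro <- seg_metrics(pooled)
  macro <- list(precision = mean(per_image$precision, na.rm = TRUE),
                recall = mean(per_image$recall, na.rm = TRUE),
                iou = mean(per_image$iou, na.rm = TRUE),
                dsc = mean(per_image$dsc, na.rm = TRUE))
  list(per_image = per_image, micro = micro, macro = macro,
       n_images = length(common))
}

#' Write an evaluation report to JSON and CSV
#'
#' @param ev Result of [evaluate_dir()].
#' @param json_path,csv_path Output file paths (either may be `NULL`).
#' @return `ev`, invisibly.
#' @export
write_metrics <- function(ev, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    out <- list(per_image = ev$per_image,
                micro = ev$micro[c("precision", "recall", "iou", "dsc")],
                macro = ev$macro)
    jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  if (!is.null(csv_path)) {
    utils::write.csv(ev$per_image, csv_path, row.names = FALSE)
  }
  invisible(ev)
}
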