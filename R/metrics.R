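# Segmentation evaluation: Dice, sensitivity, Jaccard and Pearson correlation
# (PPMCC), computed per image from pixel confusion counts and aggregated as
# mean and population standard deviation.

#' Threshold a probability map into a binary mask
#'
#' @param pred probability array or matrix in \[0, 1\].
#' @param threshold decision threshold in (0, 1); a pixel is lesion when its
#'   probability is greater than or equal to the threshold.
#' @return binary array of the same shape.
#' @export
binarize <- function(pred, threshold = 0.5) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1) {
    stop("threshold must be a single number in (0, 1)")
  }
  out <- (pred >= threshold) * 1
  if (!is.null(dim(pred))) dim(out) <- dim(pred)
  out
}

#' Pixel confusion counts between two binary masks
#'
#' @param pred_mask,gt_mask binary arrays of identical shape (values 0/1).
#' @return object of class `confusion_counts` with fields `tp`, `fp`, `tn`,
#'   `fn` and `n` (total pixels).
#' @export
confusion <- function(pred_mask, gt_mask) {
  check_same_shape(pred_mask, gt_mask, "pred_mask", "gt_mask")
  if (!all(pred_mask %in% c(0, 1)) || !all(gt_mask %in% c(0, 1))) {
    stop("confusion() requires binary masks; binarize() predictions first")
  }
  p <- as.logical(pred_mask); g <- as.logical(gt_mask)
  structure(list(tp = sum(p & g), fp = sum(p & !g),
                 tn = sum(!p & !g), fn = sum(!p & g),
                 n = length(p)),
            class = "confusion_counts")
}

# shared empty-vs-empty convention: perfect agreement scores 1
both_empty <- function(c) (c$tp + c$fn) == 0L && (c$tp + c$fp) == 0L

#' Dice coefficient from confusion counts
#' @param c a [confusion()] result.
#' @return `2*TP / (2*TP + FP + FN)` in \[0, 1\]; 1 when prediction and ground
#'   truth are both empty.
#' @export
dsc <- function(c) {
  if (both_empty(c)) return(1)
  2 * c$tp / (2 * c$tp + c$fp + c$fn)
}

#' Sensitivity (recall) from confusion counts
#' @inheritParams dsc
#' @return `TP / (TP + FN)`; 1 when both masks are empty.
#' @export
sen <- function(c) {
  if (both_empty(c)) return(1)
  if (c$tp + c$fn == 0L) return(1)   # empty ground truth: nothing to miss
  c$tp / (c$tp + c$fn)
}

#' Jaccard index from confusion counts
#' @inheritParams dsc
#' @return `TP / (TP + FP + FN)`; 1 when both masks are empty.
#' @export
jac <- function(c) {
  if (both_empty(c)) return(1)
  c$tp / (c$tp + c$fp + c$fn)
}

#' Pearson correlation between prediction and ground truth
#'
#' Flattens both inputs over pixels and returns the Pearson product-moment
#' correlation coefficient. Accepts soft probability maps or binary masks.
#'
#' @param pred prediction (probabilities or binary), any shape.
#' @param gt ground-truth mask of the same shape.
#' @return correlation in \[-1, 1\], or `NA` (with a warning) when either
#'   input is constant — such images are excluded from aggregation.
#' @export
ppmcc <- function(pred, gt) {
  check_same_shape(pred, gt, "pred", "gt")
  x <- as.vector(pred); y <- as.vector(gt)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("ppmcc undefined for constant input; returning NA")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Evaluate a set of predictions
#'
#' Computes per-image Dice, sensitivity, Jaccard and PPMCC plus their mean and
#' population standard deviation (n divisor).
#'
#' @param preds list of probability maps (each (H, W) matrix or (1, H, W)).
#' @param gts list of binary ground-truth masks, same length.
#' @param threshold binarisation threshold for the overlap metrics.
#' @param ids optional image identifiers.
#' @return object of class `metric_report`: list with `per_image` (data frame)
#'   and `summary` (data frame of mean/sd per metric).
#' @export
evaluate_set <- function(preds, gts, threshold = 0.5, ids = NULL) {
  if (length(preds) == 0L) stop("empty evaluation set")
  if (length(preds) != length(gts)) stop("preds and gts must have equal length")
  if (is.null(ids)) ids <- sprintf("img%03d", seq_along(preds))
  rows <- lapply(seq_along(preds), function(i) {
    cm <- confusion(binarize(preds[[i]], threshold), gts[[i]])
    d <- dsc(cm); j <- jac(cm)
    stopifnot(abs(d - 2 * j / (1 + j)) < 1e-12)   # algebraic identity guard
    data.frame(id = ids[i], dsc = d, sen = sen(cm), jac = j,
               ppmcc = suppressWarnings(ppmcc(preds[[i]], gts[[i]])))
  })
  per_image <- do.call(rbind, rows)
  pop_sd <- function(x) {
    x <- x[!is.na(x)]
    sqrt(mean((x - mean(x))^2))
  }
  summary <- data.frame(
    metric = c("dsc", "sen", "jac", "ppmcc"),
    mean = vapply(per_image[, c("dsc", "sen", "jac", "ppmcc")],
                  function(x) mean(x, na.rm = TRUE), numeric(1)),
    sd = vapply(per_image[, c("dsc", "sen", "jac", "ppmcc")], pop_sd, numeric(1)),
    row.names = NULL)
  structure(list(per_image = per_image, summary = summary),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("Metric report over %d images:\n", nrow(x$per_image)))
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  %-6s %6.4f +/- %6.4f\n", x$summary$metric[i],
                x$summary$mean[i], x$summary$sd[i]))
  }
  invisible(x)
}

#' Write a metric report to CSV and JSON
#'
#' The CSV holds one row per image plus one summary row per metric; the JSON
#' mirrors the report structure.
#'
#' @param report a [evaluate_set()] result.
#' @param csv_path,json_path output paths (either may be `NULL` to skip).
#' @export
write_metric_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    per <- report$per_image
    per$row_type <- "image"
    summ <- data.frame(id = paste0("mean_", report$summary$metric),
                       dsc = NA, sen = NA, jac = NA, ppmcc = NA,
                       row_type = "summary")
    for (i in seq_len(nrow(report$summary))) {
      summ[[report$summary$metric[i]]][i] <- report$summary$mean[i]
    }
    utils::write.csv(rbind(per, summ), csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(per_image = report$per_image,
                              summary = report$summary),
                         json_path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(report)
}
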