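# Field-of-view restricted evaluation: confusion counts, summary metrics and
# the ROC curve / AUC.  Only pixels inside the FoV mask are ever counted.

#' Confusion counts inside the field of view
#'
#' Binarises the probability map at `threshold` and counts true/false
#' positives/negatives over the pixels where `fov` is 1.  Pixels outside the
#' FoV never contribute.
#'
#' @param y_map binary ground-truth map.
#' @param p_map probability map, same shape.
#' @param fov binary field-of-view mask, same shape.
#' @param threshold binarisation threshold in (0, 1).
#' @return object of class `confusion` with fields `TP`, `TN`, `FP`, `FN`.
#' @export
confusion <- function(y_map, p_map, fov, threshold = 0.5) {
  if (!all(dim(y_map) == dim(p_map)) || !all(dim(y_map) == dim(fov)))
    stop_fmt("y_map, p_map and fov must share the same shape")
  if (threshold <= 0 || threshold >= 1) stop_fmt("threshold must be in (0,1)")
  keep <- fov > 0
  if (!any(keep)) stop_fmt("FoV mask is empty")
  y <- y_map[keep] > 0
  p <- p_map[keep] >= threshold
  out <- list(TP = sum(y & p), TN = sum(!y & !p),
              FP = sum(!y & p), FN = sum(y & !p))
  class(out) <- "confusion"
  out
}

#' Summary metrics from confusion counts
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(FP+TN)` and F1 `2TP/(2TP+FP+FN)`.
#'
#' @param cm a [confusion()] object.
#' @return list with `ACC`, `SE`, `SP`, `F1`, each in `[0, 1]`.
#' @export
summary_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion"))
  tot <- cm$TP + cm$TN + cm$FP + cm$FN
  if (tot == 0) stop_fmt("undefined metric ACC: no evaluated pixels")
  if (cm$TP + cm$FN == 0) stop_fmt("undefined metric SE: no positive pixels")
  if (cm$FP + cm$TN == 0) stop_fmt("undefined metric SP: no negative pixels")
  if (2 * cm$TP + cm$FP + cm$FN == 0) stop_fmt("undefined metric F1")
  list(ACC = (cm$TP + cm$TN) / tot,
       SE = cm$TP / (cm$TP + cm$FN),
       SP = cm$TN / (cm$FP + cm$TN),
       F1 = 2 * cm$TP / (2 * cm$TP + cm$FP + cm$FN))
}

#' ROC curve and AUC inside the field of view
#'
#' Sweeps thresholds over the unique score values (ties grouped), accumulates
#' (FPR, TPR) pairs with fixed endpoints (0,0) and (1,1), and integrates by
#' the trapezoidal rule.
#'
#' @inheritParams confusion
#' @return list with `auc` and `curve` (data.frame with columns `FPR`, `TPR`).
#' @export
roc_auc <- function(y_map, p_map, fov) {
  keep <- fov > 0
  if (!any(keep)) stop_fmt("FoV mask is empty")
  y <- y_map[keep] > 0
  s <- p_map[keep]
  npos <- sum(y); nneg <- sum(!y)
  if (npos == 0 || nneg == 0)
    stop_fmt("ROC undefined: ground truth inside FoV has a single class")
  o <- order(s, decreasing = TRUE)
  y <- y[o]; s <- s[o]
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- which(!duplicated(s, fromLast = TRUE))   # group tied scores
  tpr <- c(0, tp[last] / npos, 1)
  fpr <- c(0, fp[last] / nneg, 1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(auc = auc, curve = data.frame(FPR = fpr, TPR = tpr))
}

#' Evaluate a prediction and write a metrics report
#'
#' Computes FoV-restricted confusion metrics and AUC for one or more
#' prediction/label pairs (pooled over all FoV pixels), and writes a JSON
#' report, an aligned-text table (columns ACC/SE/SP/F1/AUC) and the ROC curve
#' as CSV.
#'
#' @param y_maps,p_maps,fovs lists of equally shaped arrays (or single
#'   arrays).
#' @param out_dir output directory; created if missing.
#' @param threshold binarisation threshold for the confusion metrics.
#' @param name row label used in the report.
#' @return the metrics list, invisibly.
#' @export
evaluate_maps <- function(y_maps, p_maps, fovs, out_dir, threshold = 0.5,
                          name = "model") {
  if (!is.list(y_maps)) { y_maps <- list(y_maps); p_maps <- list(p_maps); fovs <- list(fovs) }
  keep_y <- unlist(lapply(seq_along(y_maps), function(i) y_maps[[i]][fovs[[i]] > 0]))
  keep_p <- unlist(lapply(seq_along(y_maps), function(i) p_maps[[i]][fovs[[i]] > 0]))
  all_fov <- array(1, dim = c(length(keep_y), 1))
  ym <- array(keep_y, dim = dim(all_fov)); pm <- array(keep_p, dim = dim(all_fov))
  cm <- confusion(ym, pm, all_fov, threshold)
  met <- summary_metrics(cm)
  roc <- roc_auc(ym, pm, all_fov)
  met$AUC <- roc$auc
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(c(list(model = name), met, cm[c("TP", "TN", "FP", "FN")]),
                       file.path(out_dir, "metrics.json"), auto_unbox = TRUE,
                       digits = NA)
  hdr <- sprintf("%-12s %8s %8s %8s %8s %8s", "Method", "ACC", "SE", "SP", "F1", "AUC")
  row <- sprintf("%-12s %8.4f %8.4f %8.4f %8.4f %8.4f", name,
                 met$ACC, met$SE, met$SP, met$F1, met$AUC)
  writeLines(c(hdr, row), file.path(out_dir, "metrics.txt"))
  utils::write.csv(roc$curve, file.path(out_dir, "roc_curve.csv"), row.names = FALSE)
  invisible(met)
}

#' Dice coefficient of two binary maps
#' @param a,b binary arrays of equal shape.
#' @return `2|a&b| / (|a|+|b|)`; 1 if both are empty.
#' @export
dice_coefficient <- function(a, b) {
  a <- a > 0; b <- b > 0
  den <- sum(a) + sum(b)
  if (den == 0) return(1)
  2 * sum(a & b) / den
}
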