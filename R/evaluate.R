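# Detector evaluation in the COCO style: greedy confidence-ordered matching
# of detections to ground truth at each IoU threshold of the 0.50:0.05:0.95
# sweep, per-class average precision by 101-point interpolation, and mAP as
# the mean over the full class x threshold grid.

COCO_IOU_THRESHOLDS <- seq(0.50, 0.95, by = 0.05)

#' Evaluate detections against ground truth
#'
#' For each class and IoU threshold, detections are sorted by descending
#' confidence (stable for ties) and greedily matched within their frame to
#' the unmatched ground-truth box of highest IoU at or above the threshold
#' (ties resolve to the lower truth index). The first detection on a truth
#' is a true positive; duplicates are false positives. AP is the 101-point
#' interpolated area under the precision-recall curve; `map_coco` averages
#' AP over both classes and the ten thresholds 0.50:0.05:0.95. Classes with
#' no ground-truth instances are excluded from the mean.
#'
#' @param detections data frame with columns `frame_id`, `class`, `x_min`,
#'   `y_min`, `x_max`, `y_max`, `confidence` (see [detections_to_df()]).
#' @param truths data frame with the same box columns (no confidence).
#' @param iou_thresholds numeric vector of thresholds.
#' @return an `evaluation_report`: list with `per_class_ap` (class x
#'   threshold matrix), `map_coco`, and `pr_points` (per-class
#'   precision-recall curve at the first threshold).
#' @export
evaluate <- function(detections, truths,
                     iou_thresholds = COCO_IOU_THRESHOLDS) {
  stopifnot(is.data.frame(truths))
  if (nrow(detections) > 0) {
    unknown <- setdiff(unique(detections$frame_id), unique(truths$frame_id))
    if (length(unknown))
      stop("detections reference frame ids absent from the ground truth: ",
           paste(utils::head(unknown, 3), collapse = ", "))
  }
  classes <- sort(unique(truths$class))
  ap <- matrix(0, nrow = length(classes), ncol = length(iou_thresholds),
               dimnames = list(classes, sprintf("%.2f", iou_thresholds)))
  pr_points <- list()
  for (cl in classes) {
    det_c <- detections[detections$class == cl, , drop = FALSE]
    tr_c <- truths[truths$class == cl, , drop = FALSE]
    for (k in seq_along(iou_thresholds)) {
      res <- match_class(det_c, tr_c, iou_thresholds[k])
      ap[cl, k] <- average_precision(res$tp, nrow(tr_c))
      if (k == 1L)
        pr_points[[cl]] <- pr_curve(res$tp, nrow(tr_c))
    }
  }
  structure(list(per_class_ap = ap,
                 map_coco = if (length(ap)) mean(ap) else 0,
                 pr_points = pr_points,
                 iou_thresholds = iou_thresholds),
            class = "evaluation_report")
}

# greedy matching for one class at one threshold; returns TP flags in
# confidence order
match_class <- function(det_c, tr_c, thr) {
  n <- nrow(det_c)
  if (n == 0L) return(list(tp = logical(0)))
  ord <- order(-det_c$confidence)  # stable: ties keep original order
  tp <- logical(n)
  used <- rep(FALSE, nrow(tr_c))
  for (r in seq_len(n)) {
    d <- det_c[ord[r], ]
    db <- bbox(d$x_min, d$y_min, d$x_max, d$y_max)
    best_i <- NA_integer_; best_iou <- 0
    if (nrow(tr_c) > 0) {
      in_frame <- which(tr_c$frame_id == d$frame_id & !used)
      for (i in in_frame) {
        t <- tr_c[i, ]
        v <- iou(db, bbox(t$x_min, t$y_min, t$x_max, t$y_max))
        if (v > best_iou) { best_iou <- v; best_i <- i }  # strict > keeps lower index on ties
      }
    }
    if (!is.na(best_i) && best_iou >= thr) {
      tp[r] <- TRUE
      used[best_i] <- TRUE
    }
  }
  list(tp = tp)
}

pr_curve <- function(tp, n_pos) {
  if (length(tp) == 0L)
    return(data.frame(recall = numeric(), precision = numeric()))
  ctp <- cumsum(tp); cfp <- cumsum(!tp)
  data.frame(recall = if (n_pos > 0) ctp / n_pos else rep(0, length(tp)),
             precision = ctp / (ctp + cfp))
}

# COCO 101-point interpolated AP
average_precision <- function(tp, n_pos) {
  if (n_pos == 0L) return(NA_real_)
  if (length(tp) == 0L) return(0)
  pr <- pr_curve(tp, n_pos)
  # interpolated precision: max precision at any recall >= r
  p_int <- rev(cummax(rev(pr$precision)))
  grid <- seq(0, 1, by = 0.01)
  vals <- vapply(grid, function(r) {
    ok <- pr$recall >= r
    if (any(ok)) max(p_int[ok]) else 0
  }, 0)
  mean(vals)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  cat(sprintf("  mAP (COCO %.2f:%.2f): %.4f\n",
              min(x$iou_thresholds), max(x$iou_thresholds), x$map_coco))
  m <- rowMeans(x$per_class_ap)
  for (cl in rownames(x$per_class_ap))
    cat(sprintf("  AP[%s] mean over thresholds: %.4f\n", cl, m[cl]))
  invisible(x)
}

#' Run a detector over frames and collect detections
#'
#' @param frames list of `annotated_frame` objects.
#' @param detector function `frame -> list of detection` (default [detect()]).
#' @return data frame as accepted by [evaluate()].
#' @export
detect_frames <- function(frames, detector = detect) {
  rows <- lapply(frames, function(f)
    detections_to_df(detector(f), frame_id = f$frame_id))
  do.call(rbind, rows)
}
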