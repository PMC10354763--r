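#' Axis-aligned bounding box (half-open pixel intervals)
#'
#' Boxes are half-open intervals `[x_min, x_max) x [y_min, y_max)` in
#' continuous pixel coordinates, origin at the image top-left, x rightward,
#' y downward. Width is `x_max - x_min`; area is width times height.
#'
#' @param x_min,y_min,x_max,y_max box corners in pixels.
#' @return an object of class `bbox` (named numeric vector).
#' @export
bbox <- function(x_min, y_min, x_max, y_max) {
  b <- c(x_min = as.numeric(x_min), y_min = as.numeric(y_min),
         x_max = as.numeric(x_max), y_max = as.numeric(y_max))
  if (any(!is.finite(b))) stop("bbox coordinates must be finite")
  if (b["x_min"] >= b["x_max"] || b["y_min"] >= b["y_max"])
    stop("degenerate bbox: require x_min < x_max and y_min < y_max")
  if (any(b[c("x_min", "y_min")] < 0))
    stop("bbox coordinates must be non-negative")
  structure(b, class = "bbox")
}

bbox_width  <- function(b) unname(b["x_max"] - b["x_min"])
bbox_height <- function(b) unname(b["y_max"] - b["y_min"])
bbox_area   <- function(b) bbox_width(b) * bbox_height(b)

#' @export
format.bbox <- function(x, ...) {
  sprintf("bbox [%.1f, %.1f, %.1f, %.1f]",
          x["x_min"], x["y_min"], x["x_max"], x["y_max"])
}

#' @export
print.bbox <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Box center
#' @param b a [bbox()].
#' @return numeric `(x, y)` in pixels.
#' @export
bbox_center <- function(b) {
  c(x = unname(b["x_min"] + b["x_max"]) / 2,
    y = unname(b["y_min"] + b["y_max"]) / 2)
}

intersection_area <- function(a, b) {
  w <- min(a["x_max"], b["x_max"]) - max(a["x_min"], b["x_min"])
  h <- min(a["y_max"], b["y_max"]) - max(a["y_min"], b["y_min"])
  if (w <= 0 || h <= 0) return(0)
  unname(w * h)
}

#' Intersection over union of two boxes
#'
#' The matching criterion used throughout detector evaluation: intersection
#' area divided by union area, in `[0, 1]`, symmetric in its arguments.
#'
#' @param a,b boxes created with [bbox()].
#' @return scalar IoU in `[0, 1]`.
#' @export
#' @examples
#' iou(bbox(0, 0, 10, 10), bbox(5, 0, 15, 10))  # 50/150
iou <- function(a, b) {
  a <- as_bbox(a); b <- as_bbox(b)
  inter <- intersection_area(a, b)
  inter / (bbox_area(a) + bbox_area(b) - inter)
}

as_bbox <- function(b) {
  if (inherits(b, "bbox")) return(b)
  if (is.numeric(b) && length(b) == 4L) return(bbox(b[1], b[2], b[3], b[4]))
  stop("not a bbox")
}

#' Does box `inner` lie entirely within box `outer`?
#' @param inner,outer boxes created with [bbox()].
#' @return logical.
#' @export
bbox_contains <- function(outer, inner) {
  inner["x_min"] >= outer["x_min"] && inner["x_max"] <= outer["x_max"] &&
    inner["y_min"] >= outer["y_min"] && inner["y_max"] <= outer["y_max"]
}

clip_bbox <- function(b, width, height) {
  x0 <- max(0, min(b["x_min"], width)); x1 <- max(0, min(b["x_max"], width))
  y0 <- max(0, min(b["y_min"], height)); y1 <- max(0, min(b["y_max"], height))
  if (x0 >= x1 || y0 >= y1) return(NULL)
  bbox(x0, y0, x1, y1)
}

#' A single detector output
#'
#' @param class_label `"droplet"` or `"particle"`.
#' @param box a [bbox()].
#' @param confidence score in `[0, 1]`.
#' @return an object of class `detection`.
#' @export
detection <- function(class_label, box, confidence = 1) {
  class_label <- match.arg(class_label, c("droplet", "particle"))
  if (!is.numeric(confidence) || confidence < 0 || confidence > 1)
    stop("confidence must lie in [0, 1]")
  structure(list(class_label = class_label, box = as_bbox(box),
                 confidence = as.numeric(confidence)),
            class = "detection")
}

#' @export
format.detection <- function(x, ...) {
  sprintf("%s %s conf=%.2f", x$class_label, format(x$box), x$confidence)
}

#' @export
print.detection <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

detections_of_class <- function(dets, class_label) {
  Filter(function(d) d$class_label == class_label, dets)
}

#' Convert a list of detections to a data frame
#'
#' @param dets list of [detection()] objects.
#' @param frame_id optional frame identifier recycled across rows.
#' @return data frame with columns `frame_id`, `class`, `x_min`, `y_min`,
#'   `x_max`, `y_max`, `confidence`.
#' @export
detections_to_df <- function(dets, frame_id = NA_character_) {
  if (length(dets) == 0L)
    return(data.frame(frame_id = character(), class = character(),
                      x_min = numeric(), y_min = numeric(),
                      x_max = numeric(), y_max = numeric(),
                      confidence = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, lapply(dets, function(d) {
    data.frame(frame_id = frame_id, class = d$class_label,
               x_min = unname(d$box["x_min"]), y_min = unname(d$box["y_min"]),
               x_max = unname(d$box["x_max"]), y_max = unname(d$box["y_max"]),
               confidence = d$confidence, stringsAsFactors = FALSE)
  }))
}
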